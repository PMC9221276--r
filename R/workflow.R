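# Workflow orchestration: the three analysis stages behind one
# configuration surface.  Configurations are plain lists (or YAML paths);
# every output file starts with a provenance header (tool version, config
# hash, seed) and contains no timestamps, so reruns with the same config
# and seed are byte-identical.

as_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  if (!is.list(config)) stop_config("config must be a list or a YAML path")
  config
}

ensure_out_dir <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop_config("config must set out_dir")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_io(paste("cannot create out_dir:", out_dir))
  out_dir
}

wf_log <- function(config, level, ...) {
  verbosity <- config$verbosity %||% 1
  if (verbosity >= level) message("[cypsom] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the kinetics workflow: fit, SOM curves, effector verdicts
#'
#' Loads a rate table (from `config$rates`, a CSV path, or generated from
#' `config$preset`), fits the occupancy model to the effector-free rows,
#' refits the effector binding parameters on the rows with effector
#' present (when any), writes SOM curves over the fitted model, and
#' classifies the effector mode with [classify_effector_mode()].
#'
#' Config fields: `rates` or `preset`; `out_dir`; optional `seed`
#' (default 1), `init` ([params_to_config()] spelling), `free_base`,
#' `free_effector`, `threshold_som`, `threshold_rate`, `verbosity`.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with `fit_base`, `fit_effector` (or `NULL`),
#'   `curve`, `verdict` (or `NULL`), `converged` and the output paths.
#' @export
run_kinetics_workflow <- function(config) {
  config <- as_run_config(config)
  out_dir <- ensure_out_dir(config)
  seed <- config$seed %||% 1L

  if (!is.null(config$preset)) {
    preset <- scenario_presets(config$preset)
    if (preset$kind != "kinetics")
      stop_config(paste("preset is not a kinetics preset:", config$preset))
    design <- preset$design
    design$seed <- as.integer(seed)
    data <- generate_rate_dataset(preset$true_params, design,
                                  effector = preset$effector)
    wf_log(config, 1, "generated preset dataset ", sQuote(config$preset),
           " (", nrow(data), " rows)")
  } else if (!is.null(config$rates)) {
    data <- read_rate_csv(config$rates)
    wf_log(config, 1, "read ", nrow(data), " rows from ", config$rates)
  } else {
    stop_config("config must provide either 'rates' (CSV path) or 'preset'")
  }

  init <- if (!is.null(config$init)) config_to_params(config$init)
          else occupancy_params(kd_prod_s = 5, kd_allo_s = 15)
  free_base <- config$free_base %||% c("kd_prod_s", "kd_allo_s", "f4oh_ss")

  base_rows <- data[data$x_um == 0, , drop = FALSE]
  if (nrow(base_rows) == 0)
    stop_input("rate data has no effector-free (x_um = 0) rows to fit the baseline")
  fit_base <- fit_rate_data(base_rows, init, free = free_base, seed = seed)
  wf_log(config, 2, "baseline fit converged: ", fit_base$converged)

  x_rows <- data[data$x_um > 0, , drop = FALSE]
  fit_eff <- NULL
  verdict <- NULL
  if (nrow(x_rows) > 0) {
    init_eff <- fit_base$params
    init_eff$kd_allo_x <- config$init_kd_allo_x %||% 10
    init_eff$f4oh_sx <- init_eff$f4oh_ss
    free_eff <- config$free_effector %||% c("kd_allo_x", "f4oh_sx")
    fit_eff <- fit_rate_data(data, init_eff, free = free_eff, seed = seed)
    verdict <- classify_effector_mode(
      fit_base, data,
      threshold_som = config$threshold_som %||% 0.2,
      threshold_rate = config$threshold_rate %||% 0.2)
    wf_log(config, 1, "effector verdict: ", verdict$mode)
  } else {
    wf_log(config, 1, "no effector rows: skipping effector fit and verdict")
  }

  curve_params <- if (!is.null(fit_eff)) fit_eff$params else fit_base$params
  curve <- som_curve(curve_params, s_grid = sort(unique(data$s_um)),
                     x_levels = sort(unique(data$x_um)))
  header <- provenance_header(seed, config)
  curve_path <- file.path(out_dir, "som_curve.csv")
  write_csv_with_header(curve, curve_path, header)

  fit_summary <- function(fit) {
    if (is.null(fit)) return(NULL)
    list(estimates = as.list(fit$estimates),
         se = as.list(fit$se),
         identifiable = as.list(fit$identifiable),
         rss = fit$rss, converged = fit$converged, n_obs = fit$n_obs)
  }
  report <- list(tool = paste("cypsom", pkg_version()),
                 config_hash = config_hash(config),
                 seed = seed,
                 effector = attr(data, "effector") %||% "unknown",
                 baseline_fit = fit_summary(fit_base),
                 effector_fit = fit_summary(fit_eff),
                 verdict = if (!is.null(verdict)) {
                   list(mode = verdict$mode, som_shift = verdict$som_shift,
                        rate_shift = verdict$rate_shift,
                        n_matched = verdict$n_matched)
                 })
  report_path <- file.path(out_dir, "fit_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  converged <- fit_base$converged && (is.null(fit_eff) || fit_eff$converged)
  if (!converged)
    wf_log(config, 1, "warning: at least one fit did not converge")
  invisible(list(fit_base = fit_base, fit_effector = fit_eff,
                 curve = curve, verdict = verdict, converged = converged,
                 paths = c(som_curve = curve_path, report = report_path)))
}

resolve_condition_traj <- function(cond) {
  if (!is.null(cond$traj)) return(cond$traj)
  if (is.null(cond$topology)) stop_config("condition is missing 'topology'")
  read_trajectory(cond$topology, cond$trajectory)
}

#' Run the trajectory workflow: classification, contacts, comparison
#'
#' For every condition, scans the trajectory for productive/selective
#' frames, writes the per-frame classification and C1/C4 distance
#' histograms, and counts residue-ligand contacts over the productive
#' frames.  With two or more conditions, the first two are compared with
#' [contact_differential()].
#'
#' Config fields: `conditions` (list of lists with `label`, `topology`,
#' `trajectory` or an in-memory `traj`); `out_dir`; optional `selections`
#' (default [toy_selections()]), `residues`, `stride`, `thresholds`
#' (`productive_cutoff`, `selective_cutoff`, `contact_cutoff`),
#' `bin_edges`, `seed`, `verbosity`.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with per-condition `scans` and `contacts`,
#'   the `differential` (or `NULL`), and a `summary` data frame.
#' @export
run_trajectory_workflow <- function(config) {
  config <- as_run_config(config)
  out_dir <- ensure_out_dir(config)
  seed <- config$seed %||% 1L
  conds <- config$conditions
  if (is.null(conds) || length(conds) == 0)
    stop_config("config must list at least one condition")
  selections <- config$selections %||% toy_selections()
  th_cfg <- config$thresholds %||% list()
  thresholds <- classification_thresholds(
    productive_cutoff = th_cfg$productive_cutoff %||% 4.5,
    selective_cutoff = th_cfg$selective_cutoff %||% 5.5,
    contact_cutoff = th_cfg$contact_cutoff %||% 4.0)
  stride <- config$stride %||% 1
  residues <- as.integer(config$residues %||%
                           names(.default_contact_probs))
  bin_edges <- config$bin_edges %||% seq(2, 12, by = 0.5)
  header <- provenance_header(seed, config)

  scans <- list()
  contacts <- list()
  summary_rows <- list()
  for (cond in conds) {
    label <- cond$label %||% "condition"
    traj <- resolve_condition_traj(cond)
    scan <- scan_trajectory(traj, selections, thresholds, stride = stride)
    write_csv_with_header(scan$frames,
                          file.path(out_dir, paste0("frames_", label, ".csv")),
                          header)
    for (w in c("c1", "c4")) {
      hist <- distance_histogram(scan, which = w, bin_edges = bin_edges,
                                 productive_only = (w == "c4"))
      write_csv_with_header(hist,
                            file.path(out_dir,
                                      paste0("hist_", w, "_", label, ".csv")),
                            header)
    }
    mask <- rep(FALSE, n_frames(traj))
    mask[scan$frames$frame + 1L] <- scan$frames$productive
    ct <- contact_counts(traj, config$ligand %||% "resname MDZ",
                         residues, mask,
                         contact_cutoff = thresholds$contact_cutoff,
                         condition = label)
    write_csv_with_header(
      data.frame(residue = ct$residue_ids,
                 count = unname(ct$counts),
                 n_frames = ct$n_frames,
                 frequency = unname(ct$counts) / max(ct$n_frames, 1)),
      file.path(out_dir, paste0("contacts_", label, ".csv")), header)
    s <- scan$summary
    summary_rows[[label]] <- data.frame(
      condition = label, n_total = s$n_total,
      n_productive = s$n_productive,
      productive_fraction = s$productive_fraction,
      n_selective = s$n_selective, n_nonselective = s$n_nonselective,
      selective_fraction = if (s$n_productive > 0)
        s$n_selective / s$n_productive else NA_real_,
      nonselective_fraction = if (s$n_productive > 0)
        s$n_nonselective / s$n_productive else NA_real_)
    scans[[label]] <- scan
    contacts[[label]] <- ct
    wf_log(config, 1, "condition ", label, ": ", s$n_productive,
           " productive of ", s$n_total, " frames")
  }

  differential <- NULL
  if (length(contacts) >= 2) {
    differential <- contact_differential(contacts[[1]], contacts[[2]],
                                         major_threshold =
                                           config$major_threshold %||% 0.5)
    write_csv_with_header(as.data.frame(differential),
                          file.path(out_dir, "contact_differential.csv"),
                          header)
    if (length(contacts) > 2)
      wf_log(config, 1, "more than two conditions: differential computed ",
             "for the first two only")
  } else {
    wf_log(config, 1, "single condition: contact differential skipped")
  }

  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  write_csv_with_header(summary, file.path(out_dir, "condition_summary.csv"),
                        header)
  invisible(list(scans = scans, contacts = contacts,
                 differential = differential, summary = summary))
}

#' Generate synthetic fixtures from a scenario preset
#'
#' Materialises a [scenario_presets()] bundle (or an explicit spec) as
#' files under `out_dir`, together with a YAML manifest recording paths,
#' the seed and a summary of the generating truth.
#'
#' Config fields: `preset` (name); `out_dir`; optional `seed` (overrides
#' the preset's stored seeds), `verbosity`.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, the manifest as a list.
#' @export
make_synthetic <- function(config) {
  config <- as_run_config(config)
  out_dir <- ensure_out_dir(config)
  if (is.null(config$preset)) stop_config("config must name a preset")
  preset <- scenario_presets(config$preset)
  seed <- as.integer(config$seed %||%
                       (if (preset$kind == "kinetics") preset$design$seed
                        else preset$conditions[[1]]$seed))

  manifest <- list(preset = preset$name, kind = preset$kind, seed = seed,
                   tool = paste("cypsom", pkg_version()), paths = list())
  if (preset$kind == "kinetics") {
    design <- preset$design
    design$seed <- seed
    data <- generate_rate_dataset(preset$true_params, design,
                                  effector = preset$effector)
    rate_path <- file.path(out_dir, paste0(preset$name, "_rates.csv"))
    write_rate_csv(data, rate_path, seed = seed, config = config)
    truth_path <- file.path(out_dir, paste0(preset$name, "_truth.yaml"))
    write_config(params_to_config(preset$true_params), truth_path)
    manifest$paths <- list(rates = rate_path, truth = truth_path)
    manifest$truth <- params_to_config(preset$true_params)
    manifest$design <- list(s_grid = design$s_grid,
                            x_levels = design$x_levels,
                            noise = design$noise,
                            replicates = design$replicates)
  } else {
    for (i in seq_along(preset$conditions)) {
      label <- names(preset$conditions)[i]
      spec <- preset$conditions[[i]]
      spec$seed <- seed + i - 1L
      gen <- generate_toy_trajectory(spec, dir = out_dir,
                                     prefix = paste0(preset$name, "_", label))
      manifest$paths[[label]] <- list(topology = gen$topology,
                                      trajectory = gen$trajectory,
                                      labels = gen$labels_path)
      manifest$truth[[label]] <- list(
        n_frames = spec$n_frames,
        productive_probability = spec$productive_probability,
        selective_probability = spec$selective_probability,
        contact_probs = as.list(spec$contact_probs))
    }
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  write_config(manifest, manifest_path)
  wf_log(config, 1, "wrote manifest to ", manifest_path)
  invisible(manifest)
}
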