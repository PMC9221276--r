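# Seeded generators for kinetic datasets, titration curves and toy
# coordinate trajectories.  These stand in for the unreleased experimental
# and simulation data: every generator is bit-reproducible under a fixed
# seed and carries its ground truth alongside the data.

#' Design of a synthetic rate-measurement experiment
#'
#' @param s_grid Substrate concentrations (uM, non-empty).  The default is
#'   12 log-spaced points over 0.5-100 uM, bracketing both stepwise
#'   dissociation constants of midazolam.
#' @param x_levels Effector concentrations (uM, non-empty; 0 = no
#'   effector).
#' @param noise Noise model: `"none"`, `"additive"` (Gaussian with
#'   standard deviation `sd`) or `"proportional"` (Gaussian with
#'   coefficient of variation `cv`).
#' @param sd,cv Noise parameters (`>= 0`) for the respective models.
#' @param replicates Number of replicate measurements per design point.
#' @param seed Integer seed.
#' @return A `rate_design` object.
#' @export
rate_design <- function(s_grid = exp(seq(log(0.5), log(100), length.out = 12)),
                        x_levels = 0,
                        noise = c("none", "additive", "proportional"),
                        sd = 0, cv = 0, replicates = 1, seed = 1) {
  noise <- match.arg(noise)
  if (length(s_grid) == 0 || any(!is.finite(s_grid)) || any(s_grid < 0))
    stop_input("s_grid must be non-empty, finite and >= 0")
  if (length(x_levels) == 0 || any(!is.finite(x_levels)) || any(x_levels < 0))
    stop_input("x_levels must be non-empty, finite and >= 0")
  if (sd < 0 || cv < 0) stop_config("noise parameters must be >= 0")
  if (noise == "additive" && sd == 0 || noise == "proportional" && cv == 0)
    stop_config("noise model selected but its parameter is zero")
  if (replicates < 1 || replicates != round(replicates))
    stop_input("replicates must be a positive integer")
  structure(list(s_grid = as.numeric(s_grid), x_levels = as.numeric(x_levels),
                 noise = noise, sd = sd, cv = cv,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "rate_design")
}

#' Generate a synthetic rate dataset from known model parameters
#'
#' Evaluates [predict_rates()] on the full design and adds the specified
#' measurement noise (negative noisy rates are truncated at zero).  The
#' generating parameters and design are attached as attributes `truth` and
#' `design`, so refitting can be checked against ground truth.
#'
#' @param true_params An [occupancy_params()] object: the generating truth.
#' @param design A [rate_design()] object.
#' @param effector Label for the effector identity.
#' @return Data frame `(s_um, x_um, v1oh, v4oh[, sd][, replicate])` with
#'   attributes `truth`, `design` and `effector`.
#' @export
generate_rate_dataset <- function(true_params, design, effector = "effector") {
  validate_occupancy_params(true_params)
  if (!inherits(design, "rate_design"))
    stop_input("design must be a rate_design object")
  grid <- expand.grid(s_um = design$s_grid, x_um = design$x_levels,
                      replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  pred <- predict_rates(true_params, grid$s_um, grid$x_um)
  v1 <- pred$v_1oh
  v4 <- pred$v_4oh
  set.seed(design$seed)
  if (design$noise == "additive") {
    v1 <- pmax(0, v1 + stats::rnorm(length(v1), 0, design$sd))
    v4 <- pmax(0, v4 + stats::rnorm(length(v4), 0, design$sd))
  } else if (design$noise == "proportional") {
    v1 <- pmax(0, v1 * (1 + design$cv * stats::rnorm(length(v1))))
    v4 <- pmax(0, v4 * (1 + design$cv * stats::rnorm(length(v4))))
  }
  out <- data.frame(s_um = grid$s_um, x_um = grid$x_um,
                    v1oh = v1, v4oh = v4, replicate = grid$replicate)
  if (design$noise == "additive") out$sd <- design$sd
  attr(out, "truth") <- true_params
  attr(out, "design") <- design
  attr(out, "effector") <- effector
  out
}

#' Generate a synthetic spin-shift titration curve
#'
#' Langmuir responses with optional additive Gaussian noise; noisy
#' responses are clipped to the physical range `[0, 1]`.
#'
#' @param ks,bmax Generating Langmuir parameters (see
#'   [langmuir_response()]).
#' @param grid Ligand concentrations (uM, `>= 0`).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame `(ligand_um, response)` with attribute `truth`.
#' @export
generate_titration <- function(ks, bmax, grid, noise_sd = 0, seed = 1) {
  if (length(grid) == 0 || any(!is.finite(grid)) || any(grid < 0))
    stop_input("concentration grid must be non-empty, finite and >= 0")
  y <- langmuir_response(ks, bmax, grid)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- pmin(1, pmax(0, y + stats::rnorm(length(y), 0, noise_sd)))
  }
  out <- data.frame(ligand_um = as.numeric(grid), response = y)
  attr(out, "truth") <- c(ks = ks, bmax = bmax)
  out
}

# default per-residue contact probabilities for the toy system; residue
# numbers follow CYP3A4 (B-C loop: 106, 108; F-F' loop: 213-221; I helix
# neighbourhood: 304, 309)
.default_contact_probs <- c(
  "106" = 0.60, "108" = 0.50, "213" = 0.40, "214" = 0.20, "215" = 0.60,
  "216" = 0.30, "217" = 0.50, "218" = 0.55, "219" = 0.30, "220" = 0.50,
  "221" = 0.35, "304" = 0.40, "309" = 0.50)

#' Specification of a synthetic toy trajectory
#'
#' Defines the statistical structure of a generated coordinate ensemble:
#' the fraction of productive frames, the fraction of selective frames
#' among them, truncated-normal distance distributions on each side of the
#' classification thresholds, and per-residue contact probabilities.
#' Distances are sampled at least `margin` Angstrom clear of the
#' thresholds, so generated labels round-trip exactly through
#' [scan_trajectory()].
#'
#' @param n_frames Number of frames (`>= 1`).
#' @param productive_probability Probability a frame is productive.
#' @param selective_probability Probability a productive frame is
#'   selective.
#' @param contact_probs Named numeric vector: per-residue contact
#'   probability, names are residue numbers.
#' @param d_c1_in,d_c1_out Mean/sd (Angstrom) of the C1 virtual-oxygen
#'   distance inside (productive) and outside the productive cutoff.
#' @param d_c4_near,d_c4_far Mean/sd of the C4 distance below (non-
#'   selective) and above (selective) the selective cutoff.
#' @param thresholds A [classification_thresholds()] object.
#' @param margin Minimal clearance of sampled distances from the
#'   thresholds (Angstrom).
#' @param seed Integer seed.
#' @return A `trajectory_spec` object.
#' @export
trajectory_spec <- function(n_frames = 1000,
                            productive_probability = 0.52,
                            selective_probability = 0.8,
                            contact_probs = .default_contact_probs,
                            d_c1_in = c(mean = 3.8, sd = 0.3),
                            d_c1_out = c(mean = 5.2, sd = 0.3),
                            d_c4_near = c(mean = 4.8, sd = 0.3),
                            d_c4_far = c(mean = 6.3, sd = 0.3),
                            thresholds = classification_thresholds(),
                            margin = 0.05, seed = 1) {
  if (n_frames < 1 || n_frames != round(n_frames))
    stop_input("n_frames must be a positive integer")
  for (p in c(productive_probability, selective_probability, contact_probs)) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop_input("probabilities must lie in [0, 1]")
  }
  if (is.null(names(contact_probs)) || any(is.na(as.integer(names(contact_probs)))))
    stop_input("contact_probs must be named by integer residue numbers")
  if (margin <= 0) stop_input("margin must be > 0")
  structure(list(n_frames = as.integer(n_frames),
                 productive_probability = productive_probability,
                 selective_probability = selective_probability,
                 contact_probs = contact_probs,
                 d_c1_in = d_c1_in, d_c1_out = d_c1_out,
                 d_c4_near = d_c4_near, d_c4_far = d_c4_far,
                 thresholds = thresholds, margin = margin,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

# inverse-CDF sampler for a truncated normal
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# unit vector at angle theta from u, in the plane spanned by u and a
# random perpendicular direction
rotate_from <- function(u, theta) {
  repeat {
    w <- rand_unit()
    e <- c(u[2] * w[3] - u[3] * w[2],
           u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
    ne <- sqrt(sum(e^2))
    if (ne > 1e-6) break
  }
  e <- e / ne
  u * cos(theta) + e * sin(theta)
}

#' Standard atom selections for the toy trajectory system
#'
#' @return Named list of selection strings understood by
#'   [select_atoms()], matching the atoms written by
#'   [generate_toy_trajectory()].
#' @export
toy_selections <- function() {
  list(c1 = "resname MDZ and name C1",
       c4 = "resname MDZ and name C4",
       fe = "resname HEM and name FE",
       axial_s = "resname CYS and name SG",
       pyrrole_n = "resname HEM and name N1 N2 N3 N4")
}

#' Generate a toy trajectory with known frame labels
#'
#' Writes a deliberately minimal coordinate ensemble: a rigid idealised
#' heme (Fe, four pyrrole nitrogens, axial cysteine sulfur), the two
#' substrate carbons C1/C4, and one pseudo-atom per watched residue.  Per
#' frame, productive/selective labels are drawn from the specified
#' probabilities and the carbons are placed at distances sampled from the
#' corresponding truncated-normal component relative to the analytically
#' known virtual oxygen; residue pseudo-atoms are placed inside or outside
#' the contact cutoff according to sampled contact indicators.  The
#' resulting ground-truth label table is returned (and written) alongside.
#'
#' @param spec A [trajectory_spec()] object.
#' @param dir Optional output directory; when given, a single-model
#'   topology PDB, a multi-model trajectory PDB and a label CSV are
#'   written.
#' @param prefix File-name prefix for written outputs.
#' @return List with elements `traj` (a [cyp_trajectory()]), `labels`
#'   (data frame `frame, productive, selective, contact_<residue>...`),
#'   `selections` (see [toy_selections()]) and, if `dir` was given,
#'   `topology`, `trajectory` and `labels_path`.
#' @export
generate_toy_trajectory <- function(spec, dir = NULL, prefix = "toy") {
  if (!inherits(spec, "trajectory_spec"))
    stop_input("spec must be a trajectory_spec object")
  th <- spec$thresholds
  m <- spec$margin
  rids <- as.integer(names(spec$contact_probs))

  atoms <- data.frame(
    name = c("FE", "N1", "N2", "N3", "N4", "SG", "C1", "C4",
             rep("CA", length(rids))),
    resname = c(rep("HEM", 5), "CYS", "MDZ", "MDZ", rep("ALA", length(rids))),
    resid = c(rep(508L, 5), 442L, 601L, 601L, rids),
    chain = "A",
    element = c("FE", rep("N", 4), "S", "C", "C", rep("C", length(rids))),
    stringsAsFactors = FALSE)
  n_at <- nrow(atoms)

  heme_xyz <- rbind(c(0, 0, 0),
                    c(2.05, 0, 0), c(-2.05, 0, 0),
                    c(0, 2.05, 0), c(0, -2.05, 0),
                    c(0, 0, -2.3))
  o_virt <- c(0, 0, 1.65)
  lig_sep <- 2.8  # target C1-C4 through-space separation

  set.seed(spec$seed)
  nf <- spec$n_frames
  productive <- stats::runif(nf) < spec$productive_probability
  selective <- rep(NA, nf)
  selective[productive] <- stats::runif(sum(productive)) <
    spec$selective_probability
  contacts <- matrix(FALSE, nf, length(rids),
                     dimnames = list(NULL, paste0("contact_", rids)))

  xyz <- matrix(NA_real_, nf, 3 * n_at)
  for (f in seq_len(nf)) {
    if (productive[f]) {
      d1 <- rtnorm(1, spec$d_c1_in["mean"], spec$d_c1_in["sd"],
                   lo = 0.5, hi = th$productive_cutoff - m)
      d4 <- if (isTRUE(selective[f])) {
        rtnorm(1, spec$d_c4_far["mean"], spec$d_c4_far["sd"],
               lo = th$selective_cutoff + m, hi = 12)
      } else {
        rtnorm(1, spec$d_c4_near["mean"], spec$d_c4_near["sd"],
               lo = 1.5, hi = th$selective_cutoff - m)
      }
    } else {
      d1 <- rtnorm(1, spec$d_c1_out["mean"], spec$d_c1_out["sd"],
                   lo = th$productive_cutoff + m, hi = 12)
      d4 <- rtnorm(1, 5.5, 0.6, lo = 1.5, hi = 12)
    }
    u <- rand_unit()
    c1 <- o_virt + d1 * u
    cos_t <- (d1^2 + d4^2 - lig_sep^2) / (2 * d1 * d4)
    cos_t <- min(1, max(-1, cos_t))
    c4 <- o_virt + d4 * rotate_from(u, acos(cos_t))

    co <- rbind(heme_xyz, c1, c4)
    mid <- (c1 + c4) / 2
    for (r in seq_along(rids)) {
      hit <- stats::runif(1) < spec$contact_probs[r]
      contacts[f, r] <- hit
      pos <- if (hit) {
        c1 + stats::runif(1, 2.0, th$contact_cutoff - 0.1) * rand_unit()
      } else {
        # relative to the C1/C4 midpoint so both carbons stay outside
        # the cutoff by construction
        mid + stats::runif(1, th$contact_cutoff + lig_sep / 2 + 0.2,
                           th$contact_cutoff + lig_sep / 2 + 4) * rand_unit()
      }
      co <- rbind(co, pos)
    }
    xyz[f, ] <- as.numeric(t(co))
  }

  traj <- cyp_trajectory(atoms, xyz)
  labels <- data.frame(frame = seq_len(nf) - 1L,
                       productive = productive, selective = selective)
  labels <- cbind(labels, as.data.frame(contacts))

  out <- list(traj = traj, labels = labels, selections = toy_selections(),
              spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop_io(paste("cannot create output directory:", dir))
    top <- file.path(dir, paste0(prefix, "_top.pdb"))
    trj <- file.path(dir, paste0(prefix, "_traj.pdb"))
    lab <- file.path(dir, paste0(prefix, "_labels.csv"))
    write_multimodel_pdb(cyp_trajectory(atoms, xyz[1, , drop = FALSE]), top)
    write_multimodel_pdb(traj, trj)
    utils::write.csv(labels, lab, row.names = FALSE)
    out$topology <- top
    out$trajectory <- trj
    out$labels_path <- lab
  }
  out
}

# minimal multi-MODEL PDB writer for the toy system (text format, readable
# by any PDB parser)
write_multimodel_pdb <- function(traj, path) {
  atoms <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(atoms)),
      ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
      atoms$resname, atoms$chain, atoms$resid,
      co[, 1], co[, 2], co[, 3], 1, 0, atoms$element)
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Named scenario presets mirroring the published experimental designs
#'
#' Bundles of generating parameters and designs for the effector panels:
#'
#' * `pgs_15um`: progesterone at a single 15 uM level, the reference
#'   allosteric 4OH-favoring effector;
#' * `steroid_20_50um`: the steroid panel design (effector at 20 and
#'   50 uM);
#' * `medroxyprogesterone_2_8um`: the tight-binding steroid, probed at 2
#'   and 8 uM;
#' * `anf_gefitinib_opposite`: an effector shifting the SOM in the
#'   opposite direction (`f4oh_sx` below the homotropic `f4oh_ss`);
#' * `schisandrin_weak`: a weak steroid-like effector probed at 0.3-1.3
#'   times its Ks;
#' * `pgs_trajectory_pair`: two [trajectory_spec()]s emulating the
#'   simulation comparison (effector condition: lower selective fraction,
#'   major contact losses at residues 106, 108, 215, 218, 220, minor
#'   losses at 217 and 309, a major gain at 214 and a minor gain at 304).
#'
#' @param name Optional preset name; omit to get the full named list.
#' @return A preset (list) or the named list of all presets.
#' @export
scenario_presets <- function(name = NULL) {
  mdz <- function(...) occupancy_params(kd_prod_s = 5.1, kd_allo_s = 14.7,
                                        f4oh_s = 0, f4oh_ss = 0.35, ...)
  pgs_contacts <- .default_contact_probs
  pgs_contacts[] <- c(0.25, 0.20, 0.38, 0.45, 0.25, 0.28, 0.35, 0.20,
                      0.28, 0.20, 0.33, 0.52, 0.40)
  presets <- list(
    pgs_15um = list(
      kind = "kinetics", effector = "progesterone",
      true_params = mdz(kd_allo_x = 5, f4oh_sx = 0.35),
      design = rate_design(x_levels = c(0, 15), seed = 11)),
    steroid_20_50um = list(
      kind = "kinetics", effector = "steroid",
      true_params = mdz(kd_allo_x = 20, f4oh_sx = 0.35),
      design = rate_design(x_levels = c(0, 20, 50), seed = 12)),
    medroxyprogesterone_2_8um = list(
      kind = "kinetics", effector = "medroxyprogesterone",
      true_params = mdz(kd_allo_x = 2, f4oh_sx = 0.35),
      design = rate_design(x_levels = c(0, 2, 8), seed = 13)),
    anf_gefitinib_opposite = list(
      kind = "kinetics", effector = "anf_gefitinib",
      true_params = mdz(kd_allo_x = 8, f4oh_sx = 0),
      design = rate_design(x_levels = c(0, 5, 15), seed = 14)),
    schisandrin_weak = list(
      kind = "kinetics", effector = "schisandrin",
      true_params = mdz(kd_allo_x = 10, f4oh_sx = 0.2),
      design = rate_design(x_levels = c(0, 3, 13), seed = 15)),
    pgs_trajectory_pair = list(
      kind = "trajectory",
      conditions = list(
        no_pgs = trajectory_spec(n_frames = 1000,
                                 productive_probability = 0.52,
                                 selective_probability = 0.8,
                                 contact_probs = .default_contact_probs,
                                 seed = 101),
        with_pgs = trajectory_spec(n_frames = 1000,
                                   productive_probability = 0.52,
                                   selective_probability = 0.6,
                                   contact_probs = pgs_contacts,
                                   seed = 102))))
  for (nm in names(presets)) presets[[nm]]$name <- nm
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop_lookup(paste0("unknown preset ", sQuote(name), "; available: ",
                       paste(names(presets), collapse = ", ")))
  presets[[name]]
}
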