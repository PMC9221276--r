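# Serialisation of scenario presets to flat YAML-ready lists and back.
# Presets survive a write/read round trip unchanged, so fixtures can be
# regenerated from their manifest alone.

#' Serialise a scenario preset to a plain config list
#'
#' @param preset A preset from [scenario_presets()].
#' @return A named list of plain vectors/lists, safe to pass to
#'   [write_config()].
#' @export
preset_to_config <- function(preset) {
  if (!is.list(preset) || is.null(preset$kind))
    stop_input("preset must be a scenario_presets() bundle")
  if (preset$kind == "kinetics") {
    list(name = preset$name, kind = "kinetics", effector = preset$effector,
         true_params = params_to_config(preset$true_params),
         design = unclass(preset$design))
  } else {
    list(name = preset$name, kind = "trajectory",
         conditions = lapply(preset$conditions, function(spec) {
           list(n_frames = spec$n_frames,
                productive_probability = spec$productive_probability,
                selective_probability = spec$selective_probability,
                contact_probs = as.list(spec$contact_probs),
                d_c1_in = as.list(spec$d_c1_in),
                d_c1_out = as.list(spec$d_c1_out),
                d_c4_near = as.list(spec$d_c4_near),
                d_c4_far = as.list(spec$d_c4_far),
                thresholds = unclass(spec$thresholds),
                margin = spec$margin,
                seed = spec$seed)
         }))
  }
}

#' Rebuild a scenario preset from its config list
#'
#' @param config List produced by [preset_to_config()] (possibly after a
#'   YAML round trip).
#' @return A preset in the same form as [scenario_presets()] returns.
#' @export
config_to_preset <- function(config) {
  if (!is.list(config) || is.null(config$kind))
    stop_config("preset config must be a list with a 'kind' field")
  if (config$kind == "kinetics") {
    d <- config$design
    preset <- list(kind = "kinetics", effector = config$effector,
                   true_params = config_to_params(config$true_params),
                   design = rate_design(s_grid = unlist(d$s_grid),
                                        x_levels = unlist(d$x_levels),
                                        noise = d$noise, sd = d$sd, cv = d$cv,
                                        replicates = d$replicates,
                                        seed = d$seed),
                   name = config$name)
  } else if (config$kind == "trajectory") {
    conds <- lapply(config$conditions, function(cc) {
      th <- cc$thresholds
      trajectory_spec(
        n_frames = cc$n_frames,
        productive_probability = cc$productive_probability,
        selective_probability = cc$selective_probability,
        contact_probs = unlist(cc$contact_probs),
        d_c1_in = unlist(cc$d_c1_in), d_c1_out = unlist(cc$d_c1_out),
        d_c4_near = unlist(cc$d_c4_near), d_c4_far = unlist(cc$d_c4_far),
        thresholds = classification_thresholds(th$productive_cutoff,
                                               th$selective_cutoff,
                                               th$contact_cutoff),
        margin = cc$margin, seed = cc$seed)
    })
    preset <- list(kind = "trajectory", conditions = conds,
                   name = config$name)
  } else {
    stop_config(paste("unknown preset kind:", config$kind))
  }
  preset
}
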