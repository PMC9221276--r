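# Weighted nonlinear least-squares machinery for the occupancy model and
# the Langmuir titration analysis.

# Free parameters are optimised on an unconstrained scale: log for
# dissociation constants and turnover numbers, logit for the f4oh
# regioselectivity fractions.  This enforces positivity/[0,1] bounds
# without constrained optimisation.
.par_fields <- c("kd_prod_s", "kd_allo_s", "kd_allo_x", "kd_prod_x",
                 "kcat_s", "kcat_ss", "kcat_sx",
                 "f4oh_s", "f4oh_ss", "f4oh_sx")
.logit_fields <- c("f4oh_s", "f4oh_ss", "f4oh_sx")

.to_unconstrained <- function(value, field) {
  if (field %in% .logit_fields) {
    stats::qlogis(min(max(value, 1e-6), 1 - 1e-6))
  } else {
    log(value)
  }
}

.from_unconstrained <- function(theta, field) {
  unname(if (field %in% .logit_fields) stats::plogis(theta) else exp(theta))
}

.se_unconstrained_to_natural <- function(se, theta, field) {
  # delta method for the inverse transform
  if (field %in% .logit_fields) {
    p <- stats::plogis(theta)
    se * p * (1 - p)
  } else {
    se * exp(theta)
  }
}

validate_rate_dataset <- function(data, n_free = 0) {
  if (!is.data.frame(data)) stop_input("rate data must be a data frame")
  need <- c("s_um", "x_um", "v1oh", "v4oh")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    stop_input(paste("rate data is missing columns:",
                     paste(missing_cols, collapse = ", ")))
  if (any(!is.finite(data$s_um)) || any(data$s_um < 0) ||
      any(!is.finite(data$x_um)) || any(data$x_um < 0))
    stop_input("concentrations must be finite and >= 0")
  if (length(unique(data$s_um)) < 4)
    stop_input("rate data needs at least 4 distinct substrate concentrations")
  if (2L * nrow(data) < n_free)
    stop_input("fewer observations than free parameters")
  invisible(data)
}

#' Fit the two-site occupancy model to rate data
#'
#' Weighted nonlinear least squares on the 1-OH and 4-OH rates jointly,
#' minimising `sum(((v1oh - v1hat)^2 + (v4oh - v4hat)^2) / sd^2)` over the
#' dataset.  Dissociation constants and turnovers are log-parameterised and
#' regioselectivity fractions logit-parameterised, so all estimates respect
#' their bounds.  The optimiser (Levenberg-Marquardt, [minpack.lm::nls.lm])
#' is restarted from `n_starts` seeded perturbations of the initial values;
#' the best optimum wins, ties broken by the smaller parameter norm.
#'
#' A free parameter on which the data carry no information (for instance
#' `kd_allo_x` when every row has `x_um = 0`) is reported with its
#' identifiability flag lowered and an `NA` standard error, never silently
#' returned as a meaningful estimate.
#'
#' @param data Data frame with columns `s_um`, `x_um`, `v1oh`, `v4oh` and
#'   optionally `sd` (per-row noise standard deviation; defaults to 1,
#'   i.e. unweighted).
#' @param init An [occupancy_params()] object of starting values; fields
#'   not listed in `free` are held fixed at these values.
#' @param free Character vector naming the fields of `init` to estimate.
#' @param n_starts Number of multi-starts (the first uses `init` exactly).
#' @param seed Integer seed controlling the multi-start perturbations.
#' @param perturb_sd Standard deviation of the Gaussian perturbations
#'   applied to the unconstrained starting values.
#' @return An `occupancy_fit` object: fitted `params`, per-parameter
#'   `estimates`, `se`, `identifiable` flags, residual sum of squares
#'   `rss`, `converged` flag and bookkeeping fields.
#' @examples
#' truth <- occupancy_params(kd_prod_s = 5.1, kd_allo_s = 14.7)
#' d <- generate_rate_dataset(truth, rate_design(s_grid = c(0.5, 1, 2, 5, 10,
#'   20, 50, 100), x_levels = 0))
#' fit <- fit_rate_data(d, init = occupancy_params(kd_prod_s = 2,
#'   kd_allo_s = 30), free = c("kd_prod_s", "kd_allo_s"))
#' fit$estimates
#' @export
fit_rate_data <- function(data, init, free = c("kd_prod_s", "kd_allo_s"),
                          n_starts = 10, seed = 1, perturb_sd = 0.5) {
  validate_occupancy_params(init)
  free <- unique(free)
  bad <- setdiff(free, .par_fields)
  if (length(bad) > 0)
    stop_input(paste("unknown free parameters:", paste(bad, collapse = ", ")))
  if (length(free) == 0) stop_input("at least one parameter must be free")
  validate_rate_dataset(data, n_free = length(free))
  for (f in free) {
    if (!(f %in% .logit_fields) && !is.finite(init[[f]]))
      stop_input(sprintf("cannot free %s from a disabled (Inf) initial value", f))
  }
  sd <- if ("sd" %in% names(data)) ifelse(is.finite(data$sd) & data$sd > 0,
                                          data$sd, 1) else rep(1, nrow(data))

  theta0 <- vapply(free, function(f) .to_unconstrained(init[[f]], f), 0)

  make_params <- function(theta) {
    p <- unclass(init)
    for (i in seq_along(free)) p[[free[i]]] <- .from_unconstrained(theta[i], free[i])
    structure(p, class = "occupancy_params")
  }
  resid_fn <- function(theta) {
    p <- make_params(theta)
    pred <- predict_rates(p, data$s_um, data$x_um)
    c((data$v1oh - pred$v_1oh) / sd, (data$v4oh - pred$v_4oh) / sd)
  }

  best <- NULL
  for (k in seq_len(n_starts)) {
    start <- theta0
    if (k > 1) {
      set.seed(seed * 1000L + k)
      start <- theta0 + stats::rnorm(length(theta0), 0, perturb_sd)
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) {
        wf_debug("optimisation start failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    cand <- list(theta = res$par, rss = res$deviance,
                 converged = res$info %in% 1:4, info = res$info)
    if (is.null(best) ||
        cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 &&
         sum(cand$theta^2) < sum(best$theta^2))) {
      best <- cand
    }
  }
  if (is.null(best))
    stop_convergence("all optimisation starts failed")

  theta <- best$theta
  r0 <- resid_fn(theta)

  # numeric Jacobian (central differences) on the unconstrained scale
  jac <- matrix(0, length(r0), length(theta))
  h <- 1e-6
  for (i in seq_along(theta)) {
    tp <- tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    jac[, i] <- (resid_fn(tp) - resid_fn(tm)) / (2 * h)
  }
  colnorm <- sqrt(colSums(jac^2))
  identifiable <- colnorm > 1e-8
  names(identifiable) <- free

  se <- rep(NA_real_, length(free))
  names(se) <- free
  dof <- length(r0) - sum(identifiable)
  if (any(identifiable) && dof > 0) {
    ji <- jac[, identifiable, drop = FALSE]
    sigma2 <- best$rss / dof
    cv <- tryCatch(solve(crossprod(ji)) * sigma2, error = function(e) NULL)
    if (!is.null(cv)) {
      se_t <- sqrt(pmax(diag(cv), 0))
      idx <- which(identifiable)
      for (j in seq_along(idx)) {
        f <- free[idx[j]]
        se[f] <- .se_unconstrained_to_natural(se_t[j], theta[idx[j]], f)
      }
    }
  }

  estimates <- vapply(seq_along(free),
                      function(i) .from_unconstrained(theta[i], free[i]), 0)
  names(estimates) <- free

  structure(list(params = make_params(theta),
                 estimates = estimates,
                 se = se,
                 identifiable = identifiable,
                 rss = best$rss,
                 converged = best$converged,
                 free = free,
                 n_obs = nrow(data),
                 n_starts = n_starts,
                 seed = seed,
                 data = data),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("Occupancy model fit (", x$n_obs, " rows, ", x$n_starts, " starts)\n",
      sep = "")
  cat("  converged:", x$converged, "  RSS:", format(x$rss, digits = 6), "\n")
  tab <- data.frame(estimate = x$estimates, se = x$se,
                    identifiable = x$identifiable)
  print(tab, digits = 4)
  if (any(!x$identifiable))
    cat("  warning: flagged parameters are unconstrained by these data\n")
  invisible(x)
}

#' Non-cooperative Langmuir binding isotherm
#'
#' Fractional response (e.g. low-to-high spin shift of the heme iron) as a
#' function of ligand concentration: `bmax * l / (ks + l)`.
#'
#' @param ks Apparent dissociation constant (uM, `> 0`).
#' @param bmax Maximal fractional response (in `[0, 1]`).
#' @param l Ligand concentration(s) (uM, `>= 0`).
#' @return Fractional response, same length as `l`.
#' @examples
#' langmuir_response(ks = 10, bmax = 0.7, l = c(0, 10, 30))
#' @export
langmuir_response <- function(ks, bmax, l) {
  if (!is.numeric(ks) || length(ks) != 1L || !is.finite(ks) || ks <= 0)
    stop_input("ks must be a single number > 0")
  if (!is.numeric(bmax) || length(bmax) != 1L || is.na(bmax) ||
      bmax < 0 || bmax > 1)
    stop_input("bmax must lie in [0, 1]")
  if (!is.numeric(l) || length(l) == 0L || any(!is.finite(l)) || any(l < 0))
    stop_input("ligand concentrations must be finite and >= 0")
  bmax * l / (ks + l)
}

#' Fit a Langmuir isotherm to a titration curve
#'
#' Least-squares fit of [langmuir_response()] to fractional spin-shift
#' data, returning the apparent dissociation constant and amplitude with
#' standard errors from the covariance of the fit.
#'
#' @param curve Data frame with columns `ligand_um` and `response`
#'   (fractional, in `[0, 1]`), at least 4 concentration points.
#' @return A `titration_fit` object with elements `ks`, `bmax`, `se`
#'   (named vector), `rss` and the underlying `nls` fit.
#' @examples
#' tc <- generate_titration(ks = 10, bmax = 0.7,
#'                          grid = c(1, 2, 5, 10, 20, 50, 100))
#' fit_titration(tc)
#' @export
fit_titration <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("ligand_um", "response") %in% names(curve)))
    stop_input("titration curve must have columns ligand_um and response")
  if (nrow(curve) < 4)
    stop_input("titration fit needs at least 4 concentration points")
  if (any(!is.finite(curve$ligand_um)) || any(curve$ligand_um < 0))
    stop_input("ligand concentrations must be finite and >= 0")
  if (any(curve$response < -1e-9) || any(curve$response > 1 + 1e-9))
    stop_input("responses must lie in [0, 1]")
  if (diff(range(curve$response)) < 1e-9)
    stop_identifiability("flat titration response: no binding signal to fit")

  l <- curve$ligand_um
  y <- curve$response
  bmax0 <- max(y)
  ks0 <- l[which.min(abs(y - bmax0 / 2))]
  if (!is.finite(ks0) || ks0 <= 0) ks0 <- stats::median(l[l > 0])

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bmax * l / (ks + l),
                      start = list(ks = ks0, bmax = min(max(bmax0, 1e-3), 1)),
                      lower = c(ks = 1e-9, bmax = 0),
                      upper = c(ks = Inf, bmax = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_convergence(paste("titration fit failed:",
                                               conditionMessage(e))))
  co <- summary(fit)$coefficients
  est <- stats::coef(fit)
  if (est[["ks"]] <= 0) stop_identifiability("fitted ks is not positive")
  structure(list(ks = est[["ks"]], bmax = est[["bmax"]],
                 se = c(ks = unname(co["ks", "Std. Error"]),
                        bmax = unname(co["bmax", "Std. Error"])),
                 rss = sum(stats::resid(fit)^2),
                 fit = fit),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("Langmuir titration fit\n")
  cat(sprintf("  Ks   = %.4g +/- %.2g uM\n", x$ks, x$se[["ks"]]))
  cat(sprintf("  Bmax = %.4g +/- %.2g\n", x$bmax, x$se[["bmax"]]))
  invisible(x)
}

#' Classify the interaction mode of an effector
#'
#' Compares observed rates in the presence of an effector against the
#' baseline (effector-free) occupancy model fitted to the same substrate,
#' at matched substrate concentrations.  The median relative shift of the
#' SOM ratio and of the total hydroxylation rate decide the verdict:
#'
#' * SOM ratio down beyond `threshold_som` -> `"allosteric-4OH-favoring"`
#'   (progesterone/steroid-like: the effector unlocks C4 hydroxylation);
#' * SOM ratio up beyond `threshold_som` -> `"allosteric-4OH-suppressing"`
#'   (alpha-naphthoflavone/gefitinib-like);
#' * total rate down beyond `threshold_rate` with the SOM unchanged ->
#'   `"competitive-inhibition"` (the effector displaces the substrate from
#'   the productive site without touching regioselectivity);
#' * both a SOM shift and a rate loss -> `"mixed"`;
#' * neither -> `"no-effect"`.
#'
#' A baseline with no 4-OH product at all (undefined SOM) that acquires a
#' finite SOM under the effector counts as a maximal SOM decrease.
#'
#' @param fit_base An `occupancy_fit` from [fit_rate_data()] on the
#'   effector-free (`x_um = 0`) rows.
#' @param data_with_x Rate data frame containing rows with `x_um > 0` at
#'   substrate concentrations also present in the baseline fit's data.
#' @param threshold_som,threshold_rate Relative-shift thresholds
#'   (fractions; defaults 0.2).
#' @return An `effector_mode` object with the verdict in `$mode` plus the
#'   median shifts used to reach it.
#' @export
classify_effector_mode <- function(fit_base, data_with_x,
                                   threshold_som = 0.2,
                                   threshold_rate = 0.2) {
  if (!inherits(fit_base, "occupancy_fit"))
    stop_input("fit_base must be an occupancy_fit from fit_rate_data()")
  validate_rate_dataset(data_with_x)
  dx <- data_with_x[data_with_x$x_um > 0, , drop = FALSE]
  if (nrow(dx) == 0) stop_input("data_with_x has no rows with x_um > 0")
  matched <- vapply(dx$s_um, function(s)
    any(abs(fit_base$data$s_um - s) <= 1e-8 * max(1, s)), TRUE)
  if (!any(matched))
    stop_input("no substrate concentrations matched between baseline fit and effector data")
  dx <- dx[matched, , drop = FALSE]

  base <- predict_rates(fit_base$params, dx$s_um, 0)
  som_obs <- ifelse(dx$v4oh > 0, dx$v1oh / dx$v4oh, NA_real_)
  som_base <- base$som_ratio

  som_shift <- rep(NA_real_, nrow(dx))
  both <- is.finite(som_obs) & is.finite(som_base)
  som_shift[both] <- (som_obs[both] - som_base[both]) / som_base[both]
  # baseline made no 4OH but effector does: SOM fell from "infinite"
  som_shift[!is.finite(som_base) & is.finite(som_obs)] <- -1
  # effector abolished the 4OH product: SOM rose without bound
  som_shift[is.finite(som_base) & !is.finite(som_obs)] <- Inf

  vt_obs <- dx$v1oh + dx$v4oh
  vt_base <- base$v_1oh + base$v_4oh
  rate_shift <- (vt_obs - vt_base) / vt_base

  med_som <- stats::median(som_shift, na.rm = TRUE)
  med_rate <- stats::median(rate_shift, na.rm = TRUE)

  som_down <- is.finite(med_som) && med_som <= -threshold_som
  som_up <- !is.na(med_som) && med_som >= threshold_som
  rate_down <- is.finite(med_rate) && med_rate <= -threshold_rate

  mode <- if ((som_down || som_up) && rate_down) {
    "mixed"
  } else if (som_down) {
    "allosteric-4OH-favoring"
  } else if (som_up) {
    "allosteric-4OH-suppressing"
  } else if (rate_down) {
    "competitive-inhibition"
  } else {
    "no-effect"
  }
  structure(list(mode = mode,
                 som_shift = med_som,
                 rate_shift = med_rate,
                 n_matched = nrow(dx),
                 threshold_som = threshold_som,
                 threshold_rate = threshold_rate),
            class = "effector_mode")
}

#' @export
print.effector_mode <- function(x, ...) {
  cat("Effector mode:", x$mode, "\n")
  cat(sprintf("  median SOM shift : %+.3g (threshold %.2g)\n",
              x$som_shift, x$threshold_som))
  cat(sprintf("  median rate shift: %+.3g (threshold %.2g)\n",
              x$rate_shift, x$threshold_rate))
  cat("  matched rows     :", x$n_matched, "\n")
  invisible(x)
}
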