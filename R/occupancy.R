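#' Parameters of the two-site occupancy model
#'
#' CYP3A4 is modelled with two ligand sites: the productive position inside
#' the substrate-binding pocket and the peripheral allosteric site between
#' the F-F' and G-G' loops and the membrane lipid head groups.  Binding is
#' treated as rapid-equilibrium and stepwise: a ligand can occupy the
#' allosteric site only when the productive site is already occupied, so the
#' homotropic limit reduces to the classical two-step scheme with stepwise
#' dissociation constants `kd_prod_s` and `kd_allo_s`.
#'
#' Each catalytically productive state (substrate at the productive site)
#' carries its own turnover number and its own regioselectivity, expressed
#' as the fraction of total product hydroxylated at C4.  The singly-bound
#' state makes 1-OH product only (`f4oh_s = 0` by default); occupation of
#' the allosteric site by a second substrate or by an effector unlocks
#' 4-OH formation.
#'
#' @param kd_prod_s Stepwise dissociation constant of the substrate at the
#'   productive site (uM).  Default 5.1 uM, the value resolved for
#'   midazolam in CYP3A4 nanodiscs.
#' @param kd_allo_s Stepwise dissociation constant of the substrate at the
#'   allosteric site (uM).  Default 14.7 uM.
#' @param kd_allo_x Dissociation constant of the effector at the allosteric
#'   site (uM).  `Inf` (the `"disabled"` sentinel) means no effector
#'   binding at the allosteric site is modelled.
#' @param kd_prod_x Dissociation constant of the effector at the productive
#'   site (uM).  `Inf` (the `"nobind"` sentinel) switches the competitive
#'   binding mode off.
#' @param kcat_s,kcat_ss,kcat_sx Turnover numbers (min^-1 per enzyme) of the
#'   three productive states: substrate alone, substrate at both sites, and
#'   substrate at the productive site with effector at the allosteric site.
#' @param f4oh_s,f4oh_ss,f4oh_sx Fraction of total product that is 4-OH in
#'   each productive state (dimensionless, in `[0, 1]`).
#' @return An object of class `occupancy_params` (a named list).
#' @examples
#' p <- occupancy_params()
#' compute_occupancy(p, s_conc = 5.1, x_conc = 0)
#' @seealso [compute_occupancy()], [predict_rates()], [som_curve()]
#' @export
occupancy_params <- function(kd_prod_s = 5.1, kd_allo_s = 14.7,
                             kd_allo_x = Inf, kd_prod_x = Inf,
                             kcat_s = 1, kcat_ss = kcat_s, kcat_sx = kcat_s,
                             f4oh_s = 0, f4oh_ss = 0.35, f4oh_sx = 0.35) {
  p <- list(kd_prod_s = kd_prod_s, kd_allo_s = kd_allo_s,
            kd_allo_x = kd_allo_x, kd_prod_x = kd_prod_x,
            kcat_s = kcat_s, kcat_ss = kcat_ss, kcat_sx = kcat_sx,
            f4oh_s = f4oh_s, f4oh_ss = f4oh_ss, f4oh_sx = f4oh_sx)
  validate_occupancy_params(p)
  structure(p, class = "occupancy_params")
}

validate_occupancy_params <- function(p) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && !is.na(v)
  for (nm in c("kd_prod_s", "kd_allo_s", "kd_allo_x", "kd_prod_x")) {
    if (!num1(p[[nm]]) || p[[nm]] <= 0)
      stop_input(sprintf("%s must be a single positive number (Inf = disabled/nobind sentinel)", nm))
  }
  if (!is.finite(p$kd_prod_s) || !is.finite(p$kd_allo_s))
    stop_config("substrate dissociation constants must be finite: the model needs at least the homotropic binding pathway enabled")
  for (nm in c("kcat_s", "kcat_ss", "kcat_sx")) {
    if (!num1(p[[nm]]) || !is.finite(p[[nm]]) || p[[nm]] < 0)
      stop_input(sprintf("%s must be a single finite number >= 0", nm))
  }
  for (nm in c("f4oh_s", "f4oh_ss", "f4oh_sx")) {
    if (!num1(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop_input(sprintf("%s must lie in [0, 1]", nm))
  }
  invisible(p)
}

#' @export
print.occupancy_params <- function(x, ...) {
  fmt_kd <- function(v, sentinel) if (is.finite(v)) sprintf("%.4g uM", v) else sentinel
  cat("Two-site occupancy model parameters\n")
  cat("  Kd substrate, productive site :", fmt_kd(x$kd_prod_s, "-"), "\n")
  cat("  Kd substrate, allosteric site :", fmt_kd(x$kd_allo_s, "-"), "\n")
  cat("  Kd effector,  allosteric site :", fmt_kd(x$kd_allo_x, "disabled"), "\n")
  cat("  Kd effector,  productive site :", fmt_kd(x$kd_prod_x, "nobind"), "\n")
  cat(sprintf("  kcat (S / SS / SX)            : %.4g / %.4g / %.4g min^-1\n",
              x$kcat_s, x$kcat_ss, x$kcat_sx))
  cat(sprintf("  f4OH (S / SS / SX)            : %.3g / %.3g / %.3g\n",
              x$f4oh_s, x$f4oh_ss, x$f4oh_sx))
  invisible(x)
}

# Occupancy-state labels: rows = productive site, cols = allosteric site.
.occ_states <- c("empty", "S", "X")

#' Equilibrium occupancy of the 3 x 3 two-site state grid
#'
#' Computes the equilibrium fraction of enzyme in each of the nine
#' occupancy states (productive site empty/substrate/effector crossed with
#' allosteric site empty/substrate/effector) from the rapid-equilibrium
#' partition function.  State weights are products of `[ligand]/Kd` terms
#' over occupied sites; states with the allosteric site occupied but the
#' productive site empty have zero weight (stepwise binding), as do states
#' requiring a disabled binding mode (`Kd = Inf`).
#'
#' In the homotropic limit (no effector) the partition function reduces to
#' `Z = 1 + s/K1 + s^2/(K1*K2)` with `K1 = kd_prod_s`, `K2 = kd_allo_s`.
#'
#' @param params An [occupancy_params()] object.
#' @param s_conc Substrate concentration (uM, scalar `>= 0`).
#' @param x_conc Effector concentration (uM, scalar `>= 0`).
#' @return A `state_occupancy` object: a 3 x 3 numeric matrix of fractions
#'   (rows: productive site `empty`/`S`/`X`; columns: allosteric site),
#'   summing to 1.
#' @examples
#' p <- occupancy_params(kd_prod_s = 5.1, kd_allo_s = 14.7)
#' occ <- compute_occupancy(p, s_conc = 5.1, x_conc = 0)
#' sum(occ["S", ])  # probability the productive site holds substrate
#' @export
compute_occupancy <- function(params, s_conc, x_conc = 0) {
  validate_occupancy_params(params)
  if (!is.numeric(s_conc) || length(s_conc) != 1L || is.na(s_conc) || s_conc < 0)
    stop_input("s_conc must be a single number >= 0")
  if (!is.numeric(x_conc) || length(x_conc) != 1L || is.na(x_conc) || x_conc < 0)
    stop_input("x_conc must be a single number >= 0")

  # site weights; Inf Kd (sentinel) gives weight 0 for any finite concentration
  wp <- c(1, s_conc / params$kd_prod_s,
          if (is.finite(params$kd_prod_x)) x_conc / params$kd_prod_x else 0)
  wa <- c(1, s_conc / params$kd_allo_s,
          if (is.finite(params$kd_allo_x)) x_conc / params$kd_allo_x else 0)
  names(wp) <- names(wa) <- .occ_states

  w <- outer(wp, wa)
  # stepwise scheme: allosteric site is only populated once the productive
  # site is occupied
  w["empty", c("S", "X")] <- 0
  z <- sum(w)
  frac <- w / z
  dimnames(frac) <- list(productive = .occ_states, allosteric = .occ_states)
  structure(frac, class = c("state_occupancy", "matrix"))
}

#' @export
print.state_occupancy <- function(x, digits = 4, ...) {
  cat("Equilibrium state occupancy (rows: productive site; cols: allosteric site)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Predict 1-OH and 4-OH formation rates and the SOM ratio
#'
#' Turnover only happens in states with substrate at the productive site:
#' `(S, empty)`, `(S, S)` and `(S, X)`.  Each contributes
#' `kcat_state * fraction` to the total rate and splits it between the C1
#' (1-OH) and C4 (4-OH) products according to its `f4oh`.  The
#' site-of-metabolism (SOM) ratio is `v_1oh / v_4oh`; when no 4-OH product
#' is formed the ratio is reported as `NA` (the "undefined" sentinel), never
#' as `Inf`, so result tables stay serialisable.
#'
#' @inheritParams compute_occupancy
#' @param s_conc,x_conc Substrate and effector concentrations (uM); vectors
#'   are recycled to common length.
#' @return A data frame with columns `s_um`, `x_um`, `v_1oh`, `v_4oh`
#'   (min^-1 per enzyme) and `som_ratio`.
#' @examples
#' p <- occupancy_params()
#' predict_rates(p, s_conc = c(1, 10, 100), x_conc = 0)
#' @export
predict_rates <- function(params, s_conc, x_conc = 0) {
  if (length(s_conc) == 0L || length(x_conc) == 0L)
    stop_input("s_conc and x_conc must be non-empty")
  n <- max(length(s_conc), length(x_conc))
  s <- rep_len(s_conc, n)
  x <- rep_len(x_conc, n)
  v1 <- v4 <- numeric(n)
  for (i in seq_len(n)) {
    occ <- compute_occupancy(params, s[i], x[i])
    vs  <- params$kcat_s  * occ["S", "empty"]
    vss <- params$kcat_ss * occ["S", "S"]
    vsx <- params$kcat_sx * occ["S", "X"]
    v4[i] <- vs * params$f4oh_s + vss * params$f4oh_ss + vsx * params$f4oh_sx
    v1[i] <- vs * (1 - params$f4oh_s) + vss * (1 - params$f4oh_ss) +
      vsx * (1 - params$f4oh_sx)
  }
  som <- ifelse(v4 > 0, v1 / v4, NA_real_)
  data.frame(s_um = s, x_um = x, v_1oh = v1, v_4oh = v4, som_ratio = som)
}

#' SOM ratio and rate curves over a substrate/effector grid
#'
#' Evaluates [predict_rates()] on the Cartesian product of a substrate
#' concentration grid and a set of effector levels, producing the tables
#' behind the classical SOM-versus-substrate plots: one curve per effector
#' level, with the heterotropic perturbation largest at low substrate and
#' shrinking as the substrate outcompetes the effector at the allosteric
#' site.
#'
#' @inheritParams compute_occupancy
#' @param s_grid Non-empty vector of substrate concentrations (uM).
#' @param x_levels Non-empty vector of effector concentrations (uM).
#' @return A data frame `(s_um, x_um, v_1oh, v_4oh, som_ratio)` with one
#'   row per `(s, x)` pair; undefined SOM ratios are `NA`.
#' @examples
#' p <- occupancy_params(kd_allo_x = 5, f4oh_sx = 0.35)
#' curves <- som_curve(p, s_grid = c(1, 2, 5, 10, 50), x_levels = c(0, 15))
#' @export
som_curve <- function(params, s_grid, x_levels = 0) {
  if (length(s_grid) == 0L) stop_input("s_grid must be non-empty")
  if (length(x_levels) == 0L) stop_input("x_levels must be non-empty")
  grid <- expand.grid(s_um = s_grid, x_um = x_levels,
                      KEEP.OUT.ATTRS = FALSE)
  predict_rates(params, grid$s_um, grid$x_um)
}
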