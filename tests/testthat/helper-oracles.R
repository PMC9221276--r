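# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals: the occupancy oracle enumerates
# the 9-state grid row by row, the stepwise oracle evaluates the
# closed-form two-step partition function, and distances are recomputed
# with explicit arithmetic.

# brute-force enumeration of the 3 x 3 occupancy grid
oracle_occupancy <- function(params, s, x) {
  states <- expand.grid(prod = c("empty", "S", "X"),
                        allo = c("empty", "S", "X"),
                        stringsAsFactors = FALSE)
  w <- numeric(nrow(states))
  for (i in seq_len(nrow(states))) {
    wi <- switch(states$prod[i],
                 empty = 1,
                 S = s / params$kd_prod_s,
                 X = if (is.finite(params$kd_prod_x)) x / params$kd_prod_x else 0)
    wi <- wi * switch(states$allo[i],
                      empty = 1,
                      S = s / params$kd_allo_s,
                      X = if (is.finite(params$kd_allo_x)) x / params$kd_allo_x else 0)
    if (states$prod[i] == "empty" && states$allo[i] != "empty") wi <- 0
    w[i] <- wi
  }
  states$frac <- w / sum(w)
  states
}

# occupancy-weighted rates from the enumeration oracle
oracle_rates <- function(params, s, x) {
  st <- oracle_occupancy(params, s, x)
  v1 <- v4 <- 0
  for (i in seq_len(nrow(st))) {
    if (st$prod[i] != "S") next
    kc <- switch(st$allo[i], empty = params$kcat_s, S = params$kcat_ss,
                 X = params$kcat_sx)
    f4 <- switch(st$allo[i], empty = params$f4oh_s, S = params$f4oh_ss,
                 X = params$f4oh_sx)
    v1 <- v1 + kc * st$frac[i] * (1 - f4)
    v4 <- v4 + kc * st$frac[i] * f4
  }
  c(v1 = v1, v4 = v4)
}

# closed-form two-step stepwise binding model (homotropic limit)
oracle_stepwise <- function(k1, k2, s) {
  z <- 1 + s / k1 + s^2 / (k1 * k2)
  c(empty = 1 / z, single = (s / k1) / z, double = (s^2 / (k1 * k2)) / z)
}

# uniformly random proper rotation matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# idealised planar heme used throughout the geometry tests
ideal_heme <- function() {
  heme_geometry(fe = c(0, 0, 0),
                pyrrole_n = rbind(c(2, 0, 0), c(-2, 0, 0),
                                  c(0, 2, 0), c(0, -2, 0)),
                axial_s = c(0, 0, -2.3))
}

# default midazolam parameterisation used in many tests
mdz_params <- function(...) {
  occupancy_params(kd_prod_s = 5.1, kd_allo_s = 14.7,
                   f4oh_s = 0, f4oh_ss = 0.35, ...)
}
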