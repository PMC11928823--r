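# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately written as naive element-by-element arithmetic so
# they stay independent of the vectorized implementation they check.

default_geometry <- function() {
  specimen_geometry(width = 5e-3, thickness = 126e-6, gauge_length = 5e-3)
}

default_cal <- function() {
  afm_calibration(kn = 0.22, alpha = 50e-9, kt = 4e-10, delta = 1e-3,
                  t_cant = 4e-6, d_tip = 10e-6)
}

# Naive Prony sum: scalar loop over elements and times.
oracle_prony <- function(E, tau, t) {
  out <- numeric(length(t))
  for (k in seq_along(t)) {
    s <- 0
    for (i in seq_along(E)) s <- s + E[i] * exp(-t[k] / tau[i])
    out[k] <- s
  }
  out
}

# Closed-form relaxation percentage of a Maxwell solid over `horizon`.
oracle_relax_pct <- function(E, tau, horizon = 200) {
  w <- E / sum(E)
  100 * (1 - sum(w * exp(-horizon / tau)))
}

# Coarse grid-search fit of a two-element Prony series: exhaustive over
# ordered (tau1, tau2) pairs on a log grid with a linear solve for E.
oracle_grid_fit2 <- function(t, y, tau_grid = exp(seq(log(1), log(1e4), length.out = 60))) {
  best <- NULL
  for (i in seq_along(tau_grid)) {
    for (j in seq_along(tau_grid)) {
      if (j <= i) next
      X <- cbind(exp(-t / tau_grid[i]), exp(-t / tau_grid[j]))
      co <- stats::lm.fit(X, y)$coefficients
      if (any(!is.finite(co)) || any(co <= 0)) next
      rss <- sum((y - X %*% co)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(tau = c(tau_grid[i], tau_grid[j]), E = co, rss = rss)
      }
    }
  }
  best
}

# Numerical convolution of the constant-rate ramp response of a Maxwell
# solid: sigma(t) = integral_0^t sum_i E_i exp(-(t-s)/tau_i) * rate ds,
# trapezoid rule on a fine grid.
oracle_ramp_stress <- function(E, tau, rate, t_eval, n_sub = 4000) {
  vapply(t_eval, function(tt) {
    if (tt == 0) return(0)
    s <- seq(0, tt, length.out = n_sub)
    relax <- oracle_prony(E, tau, tt - s)
    sum((relax[-1] + relax[-n_sub]) / 2 * diff(s)) * rate
  }, numeric(1))
}

paper_like_model <- function() {
  maxwell_model(E = c(1e6, 1e6, 1e6, 7e6), tau = c(0.5, 20, 300, 4000))
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
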