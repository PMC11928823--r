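# Generalized Maxwell (Prony series) model: evaluation, constrained
# multi-start nonlinear least-squares fitting of the hold segment of a
# relaxation trace, and chi-square-drop selection of the number of elements.
#
# The model has no equilibrium spring: stress(t) = sum_i E_i exp(-t / tau_i).
# A slowest element with tau far beyond the observation window plays the
# quasi-equilibrium role, so no separate equilibrium spring is fitted.

#' Construct a generalized Maxwell model
#'
#' An ordered set of spring-dashpot elements `(E_i, tau_i)`. Elements are
#' stored sorted by ascending relaxation time; viscosities `eta_i = E_i tau_i`
#' and relative importances `RI_i = 100 E_i / sum(E)` are derived, never
#' stored.
#'
#' @param E Element stiffnesses, Pa (> 0).
#' @param tau Element relaxation times, s (> 0).
#' @return A `maxwell_model` tibble with columns `E`, `tau`.
#' @examples
#' maxwell_model(E = c(1e6, 1e6, 1e6, 7e6), tau = c(0.5, 20, 300, 4000))
#' @export
maxwell_model <- function(E, tau) {
  if (length(E) != length(tau) || length(E) < 1L) {
    stop_contract("E and tau must have equal length >= 1")
  }
  if (!all(is.finite(E)) || !all(is.finite(tau)) || any(E <= 0) || any(tau <= 0)) {
    stop_contract("all E and tau must be finite and > 0")
  }
  ord <- order(tau)
  out <- tibble(E = as.numeric(E)[ord], tau = as.numeric(tau)[ord])
  structure(out, class = c("maxwell_model", class(out)))
}

#' Evaluate the Maxwell relaxation stress
#'
#' `sum_i E_i exp(-t / tau_i)`; at `t = 0` this is `sum(E)`.
#'
#' @param model A [maxwell_model()].
#' @param t Times in seconds (>= 0).
#' @return Stress (Pa) at each time.
#' @export
maxwell_stress <- function(model, t) {
  stopifnot(inherits(model, "maxwell_model"))
  if (any(t < 0)) stop_contract("t must be >= 0")
  prony_eval(model$E, model$tau, t)
}

# Vectorized Prony evaluation without constructing a model object.
prony_eval <- function(E, tau, t) {
  drop(exp(-outer(t, 1 / tau)) %*% E)
}

#' Relative importance of each element
#'
#' `RI_i = 100 E_i / sum(E)`, the element's share of the instantaneous
#' stiffness. Sums to 100 by construction.
#'
#' @param model A [maxwell_model()].
#' @return Percentages, one per element.
#' @export
relative_importance <- function(model) {
  stopifnot(inherits(model, "maxwell_model"))
  100 * model$E / sum(model$E)
}

#' Element viscosities
#'
#' `eta_i = E_i tau_i` (the dashpot constant of each element).
#'
#' @param model A [maxwell_model()].
#' @return Viscosities in Pa s.
#' @export
viscosity <- function(model) {
  stopifnot(inherits(model, "maxwell_model"))
  model$E * model$tau
}

#' @export
print.maxwell_model <- function(x, ...) {
  cat(sprintf("<maxwell_model> %d element(s)\n", nrow(x)))
  df <- data.frame(E = x$E, tau = x$tau, eta = viscosity(x),
                   RI = relative_importance(x))
  print(df, row.names = TRUE)
  invisible(x)
}

# ---- Fitting ---------------------------------------------------------------

# Residual vector for nls.lm. par = c(log E, log tau); pearson weighting puts
# sqrt(model) in the denominator so the SSR minimized by LM equals the
# Pearson chi2 = sum (obs - fit)^2 / fit.
maxwell_residual <- function(par, t, y, weighting, floor_y) {
  n <- length(par) / 2L
  E <- exp(par[1:n]); tau <- exp(par[(n + 1L):(2L * n)])
  s <- prony_eval(E, tau, t)
  if (weighting == "pearson") {
    (y - s) / sqrt(pmax(s, floor_y))
  } else {
    y - s
  }
}

maxwell_jacobian <- function(par, t, y, weighting, floor_y) {
  n <- length(par) / 2L
  E <- exp(par[1:n]); tau <- exp(par[(n + 1L):(2L * n)])
  X <- exp(-outer(t, 1 / tau))                     # n_obs x n
  s <- drop(X %*% E)
  dE <- sweep(X, 2L, E, `*`)                        # ds/dlogE_i
  dTau <- dE * outer(t, 1 / tau)                    # ds/dlogtau_i
  ds <- cbind(dE, dTau)
  if (weighting == "pearson") {
    sf <- pmax(s, floor_y)
    w <- ifelse(s > floor_y,
                1 / sqrt(sf) + (y - s) / (2 * sf^1.5),
                1 / sqrt(sf))
    -ds * w
  } else {
    -ds
  }
}

fit_chi2 <- function(E, tau, t, y, weighting, floor_y) {
  s <- prony_eval(E, tau, t)
  if (weighting == "pearson") sum((y - s)^2 / pmax(s, floor_y)) else sum((y - s)^2)
}

# Linear solve for E given tau (clamped positive); used to build starts.
solve_E_given_tau <- function(tau, t, y) {
  X <- exp(-outer(t, 1 / tau))
  co <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
  if (is.null(co) || any(!is.finite(co))) co <- rep(max(y) / length(tau), length(tau))
  pmax(co, 1e-6 * max(y))
}

#' Fit a generalized Maxwell model of fixed order to a relaxation trace
#'
#' Constrained nonlinear least squares on the hold segment (time re-origined
#' to the start of the hold), minimizing the Pearson-style
#' `chi2 = sum (obs - fit)^2 / fit` (or the plain residual sum of squares with
#' `weighting = "rss"`). Positivity of every `E_i` and `tau_i` is enforced by
#' optimizing their logarithms. Because multi-exponential fitting is
#' ill-conditioned, the optimizer is multi-started: relaxation times are
#' initialized log-spaced over `[dt, 100 T_hold]` and perturbed per restart by
#' the seeded generator, with stiffnesses started from a linear solve given
#' the trial times. The best restart (lowest chi2, earliest index on ties)
#' is returned.
#'
#' @param trace A [relaxation_trace()].
#' @param n Number of Maxwell elements (>= 1).
#' @param restarts Number of random restarts (default 8).
#' @param seed Integer seed controlling the restart perturbations; mandatory
#'   so fits are reproducible.
#' @param weighting `"pearson"` (default) or `"rss"`.
#' @param as_modulus Report stiffnesses as moduli `E_i / hold_strain` instead
#'   of raw stress amplitudes. Relaxation times and relative importances are
#'   invariant to this rescaling.
#' @param init Optional `maxwell_model` used as a warm start (padded with a
#'   near-zero element when it has `n - 1` elements); used by [select_order()]
#'   to guarantee chi2 nesting.
#' @return A `maxwell_fit` object; see [tidy.maxwell_fit()] /
#'   [glance.maxwell_fit()]. Never throws on non-convergence: the best-effort
#'   parameters are returned with `converged = FALSE`.
#' @export
fit_maxwell <- function(trace, n, restarts = 8, seed = 1L,
                        weighting = c("pearson", "rss"),
                        as_modulus = FALSE, init = NULL) {
  stopifnot(inherits(trace, "relaxation_trace"))
  weighting <- match.arg(weighting)
  check_number(n, "n", positive = TRUE)
  check_number(seed, "seed")
  n <- as.integer(n)
  i0 <- trace_t0(trace)
  t <- trace$time[i0:nrow(trace)] - trace$time[i0]
  y <- trace$stress[i0:nrow(trace)]
  if (length(y) < 4L * n) {
    stop_data(sprintf("hold segment has %d samples; need >= %d for n = %d",
                      length(y), 4L * n, n))
  }
  dt <- min(diff(t))
  t_hold <- max(t)
  floor_y <- 1e-12 * max(abs(y))

  # Trial relaxation times: log-spaced over the resolvable window, jittered
  # per restart. Restart 0 is unjittered; an optional warm start is appended.
  base_log_tau <- seq(log(dt), log(100 * t_hold), length.out = n + 2L)[2:(n + 1L)]
  if (n == 1L) base_log_tau <- log(sqrt(dt * 100 * t_hold))
  starts <- withr::with_seed(as.integer(seed), {
    c(list(base_log_tau),
      lapply(seq_len(max(restarts - 1L, 0L)), function(i) {
        base_log_tau + rnorm(n, 0, 0.6)
      }))
  })
  starts <- lapply(starts, function(lt) {
    tau <- sort(exp(lt))
    E <- solve_E_given_tau(tau, t, y)
    c(log(E), log(tau))
  })
  if (!is.null(init)) {
    stopifnot(inherits(init, "maxwell_model"))
    E0 <- init$E; tau0 <- init$tau
    if (length(E0) == n - 1L) {
      # pad with a negligible element in the largest log-gap of the grid
      grid <- sort(c(log(dt), log(tau0), log(100 * t_hold)))
      gaps <- diff(grid)
      gi <- which.max(gaps)
      tau_new <- exp(grid[gi] + gaps[gi] / 2)
      E0 <- c(E0, 1e-9 * sum(E0)); tau0 <- c(tau0, tau_new)
    }
    if (length(E0) == n) starts <- c(starts, list(c(log(E0), log(tau0))))
  }

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-13, ptol = 1e-13)
  for (k in seq_along(starts)) {
    par0 <- starts[[k]]
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par0, fn = maxwell_residual,
                           jac = maxwell_jacobian,
                           t = t, y = y, weighting = weighting,
                           floor_y = floor_y, control = ctrl)
      ),
      error = function(e) NULL
    )
    cand <- if (!is.null(fit)) {
      list(par = fit$par, info = fit$info)
    } else {
      list(par = par0, info = 0L)           # keep the start as a fallback
    }
    cand$chi2 <- fit_chi2(exp(cand$par[1:n]), exp(cand$par[(n + 1L):(2L * n)]),
                          t, y, weighting, floor_y)
    if (!is.finite(cand$chi2)) next
    if (is.null(best) || cand$chi2 < best$chi2) best <- cand
  }

  if (is.null(best)) {                       # all starts degenerate: best effort
    best <- list(par = starts[[1]], info = 0L,
                 chi2 = fit_chi2(exp(starts[[1]][1:n]),
                                 exp(starts[[1]][(n + 1L):(2L * n)]),
                                 t, y, weighting, floor_y))
  }
  # clamp away under/overflow of the log-parameterization on degenerate data
  # (e.g. an element driven to zero amplitude); the fit is best-effort there
  E_hat <- pmin(pmax(exp(best$par[1:n]), 1e-300), 1e300)
  tau_hat <- pmin(pmax(exp(best$par[(n + 1L):(2L * n)]), 1e-300), 1e300)
  model <- maxwell_model(E = if (as_modulus) E_hat / trace_hold_strain(trace) else E_hat,
                         tau = tau_hat)
  fitted <- prony_eval(E_hat, tau_hat, t)
  structure(
    list(
      model = model,
      chi2 = best$chi2,
      chi2_path = setNames(best$chi2, as.character(n)),
      selected_n = n,
      converged = best$info %in% 1:3,
      n_restarts_used = length(starts),
      weighting = weighting,
      as_modulus = as_modulus,
      hold_strain = trace_hold_strain(trace),
      n_obs = length(y),
      data = tibble(time = t, stress = y, fitted = fitted)
    ),
    class = "maxwell_fit"
  )
}

#' Select the number of Maxwell elements by the drop in chi-square
#'
#' Fits models of increasing order and selects the smallest `n` for which an
#' additional element no longer buys at least `drop_threshold` relative
#' improvement: the first `n` with
#' `(chi2_n - chi2_{n+1}) / chi2_n < drop_threshold`. Each order is
#' warm-started from the previous solution (padded with a near-zero element),
#' which guarantees the chi2 path is non-increasing; fitting stops as soon as
#' the criterion is met.
#'
#' @inheritParams fit_maxwell
#' @param n_max Largest order considered (default 6).
#' @param drop_threshold Relative chi2 improvement below which an extra
#'   element is judged unnecessary (default 0.05).
#' @return The `maxwell_fit` of the selected order, with `chi2_path` holding
#'   the chi2 of every order fitted and `selected_n` the chosen order.
#' @export
select_order <- function(trace, n_max = 6, drop_threshold = 0.05,
                         restarts = 8, seed = 1L,
                         weighting = c("pearson", "rss"), as_modulus = FALSE) {
  weighting <- match.arg(weighting)
  check_number(n_max, "n_max", positive = TRUE)
  if (n_max < 2) stop_contract("n_max must be >= 2")
  check_number(drop_threshold, "drop_threshold", nonneg = TRUE)
  fits <- vector("list", n_max)
  chi2_path <- numeric(0)
  selected <- n_max
  for (n in seq_len(n_max)) {
    init <- if (n > 1L) fits[[n - 1L]]$model else NULL
    fits[[n]] <- fit_maxwell(trace, n = n, restarts = restarts,
                             seed = as.integer(seed) + n, weighting = weighting,
                             as_modulus = as_modulus, init = init)
    # guard against float dust: nesting is guaranteed by the warm start
    if (n > 1L && fits[[n]]$chi2 > chi2_path[n - 1L]) {
      fits[[n]]$chi2 <- chi2_path[n - 1L]
    }
    chi2_path[n] <- fits[[n]]$chi2
    if (n > 1L) {
      drop_rel <- (chi2_path[n - 1L] - chi2_path[n]) / chi2_path[n - 1L]
      if (drop_rel < drop_threshold) {
        selected <- n - 1L
        break
      }
    }
  }
  out <- fits[[selected]]
  out$chi2_path <- setNames(chi2_path, as.character(seq_along(chi2_path)))
  out$selected_n <- selected
  out$drop_threshold <- drop_threshold
  out
}

#' @export
print.maxwell_fit <- function(x, ...) {
  cat(sprintf("<maxwell_fit> n = %d element(s), chi2 = %.6g (%s)%s\n",
              x$selected_n, x$chi2, x$weighting,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$model)
  if (length(x$chi2_path) > 1L) {
    cat("chi2 path:", paste(sprintf("%s: %.4g", names(x$chi2_path), x$chi2_path),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a Maxwell model or fit into one row per element
#'
#' @param x A `maxwell_model` or `maxwell_fit`.
#' @param ... Unused.
#' @return A tibble with columns `element`, `E`, `tau`, `eta`, `RI`.
#' @export
tidy.maxwell_model <- function(x, ...) {
  tibble(element = seq_len(nrow(x)), E = x$E, tau = x$tau,
         eta = viscosity(x), RI = relative_importance(x))
}

#' @rdname tidy.maxwell_model
#' @export
tidy.maxwell_fit <- function(x, ...) tidy(x$model)

#' One-row summary of a Maxwell fit
#'
#' @param x A `maxwell_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `chi2`, `converged`, `n_restarts_used`,
#'   `weighting`, `n_obs`, `hold_strain`.
#' @export
glance.maxwell_fit <- function(x, ...) {
  tibble(n = x$selected_n, chi2 = x$chi2, converged = x$converged,
         n_restarts_used = x$n_restarts_used, weighting = x$weighting,
         n_obs = x$n_obs, hold_strain = x$hold_strain)
}
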