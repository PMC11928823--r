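# AFM nano-mechanics: photodiode-to-force calibration, friction-loop
# processing to a coefficient of friction, and Hertzian sphere-on-flat
# modulus fitting of force-distance curves.

#' Normal force from the photodiode normal deflection
#'
#' `Fn = dVn * alpha * kn`: the deflection sensitivity converts volts to
#' cantilever deflection, the spring constant converts deflection to force.
#'
#' @param dVn Normal photodiode voltage change, V (vectorized).
#' @param cal An [afm_calibration()].
#' @return Force in newtons.
#' @examples
#' cal <- afm_calibration(kn = 0.25, alpha = 50e-9, kt = 4e-10, delta = 1e-3,
#'                        t_cant = 4e-6, d_tip = 10e-6)
#' normal_force(2, cal) # 25 nN
#' @export
normal_force <- function(dVn, cal) {
  stopifnot(inherits(cal, "afm_calibration"))
  dVn * cal$alpha * cal$kn
}

#' Friction force from a friction-loop width
#'
#' `Ff = dVl * kt * delta / (2 (d + t/2))`: the detector sensitivity converts
#' the lateral voltage to a torsion angle, the torsional stiffness to a
#' torque, and the moment arm (tip height plus half the cantilever thickness)
#' to a lateral force. The factor 2 is because `dVl` is the trace-minus-
#' retrace loop width, twice the friction signal.
#'
#' @param dVl Lateral voltage loop width, V (vectorized).
#' @param cal An [afm_calibration()].
#' @return Friction force in newtons.
#' @export
friction_force <- function(dVl, cal) {
  stopifnot(inherits(cal, "afm_calibration"))
  arm <- cal$d_tip + cal$t_cant / 2
  if (arm <= 0) stop_calibration("moment arm d + t/2 must be > 0")
  dVl * cal$kt * cal$delta / (2 * arm)
}

#' Width of a friction loop
#'
#' Mean of (trace - retrace) over the central 80% of scan positions; the
#' outer 10% on each side is excluded because scan-turnaround artifacts live
#' there.
#'
#' @param loop A [friction_loop()].
#' @return Loop width in volts (the `dVl` fed to [friction_force()]).
#' @export
loop_width <- function(loop) {
  stopifnot(inherits(loop, "friction_loop"))
  p <- loop$position
  lo <- min(p) + 0.1 * diff(range(p))
  hi <- max(p) - 0.1 * diff(range(p))
  sel <- p >= lo & p <= hi
  if (sum(sel) < 4L) stop_data("fewer than 4 positions in the central 80% of the scan")
  mean(loop$v_trace[sel] - loop$v_retrace[sel])
}

#' Coefficient of friction from a load sweep of friction loops
#'
#' At each normal force the loop widths are averaged and converted to a
#' friction force; the coefficient of friction is the OLS slope of friction
#' force against normal force. The intercept is kept free and reported as an
#' adhesion offset (tissue in buffer shows adhesion hysteresis), and per-load
#' friction/normal ratios are reported as diagnostics.
#'
#' @param loops A list of [friction_loop()] objects covering >= 3 distinct
#'   normal forces.
#' @param cal An [afm_calibration()].
#' @return A `friction_result`: see [tidy.friction_result()] /
#'   [glance.friction_result()]. Fields: `loads` (N), `mean_friction` (N),
#'   `cof`, `adhesion_offset` (N), `fit_r2`, `ratios`.
#' @export
friction_coefficient <- function(loops, cal) {
  stopifnot(inherits(cal, "afm_calibration"))
  if (!is.list(loops) || !all(vapply(loops, inherits, logical(1), "friction_loop"))) {
    stop_contract("loops must be a list of friction_loop objects")
  }
  fn <- vapply(loops, loop_normal_force, numeric(1))
  width <- vapply(loops, loop_width, numeric(1))
  per_load <- dplyr::summarise(
    dplyr::group_by(tibble(fn = fn, width = width), .data$fn),
    width = mean(.data$width), n_loops = dplyr::n(), .groups = "drop"
  )
  per_load <- dplyr::arrange(per_load, .data$fn)
  if (nrow(per_load) < 3L) {
    stop_data(sprintf("need >= 3 distinct normal forces, got %d", nrow(per_load)))
  }
  ff <- friction_force(per_load$width, cal)
  fit <- lm(ff ~ fn, data = tibble(ff = ff, fn = per_load$fn))
  cof <- unname(coef(fit)[2])
  if (cof < 0) warn("negative coefficient of friction", class = "tissuemech_cof_warning")
  structure(
    list(
      loads = per_load$fn,
      mean_friction = ff,
      n_loops = per_load$n_loops,
      cof = cof,
      adhesion_offset = unname(coef(fit)[1]),
      fit_r2 = r_squared(fit, ff),
      ratios = ff / per_load$fn
    ),
    class = "friction_result"
  )
}

#' @export
print.friction_result <- function(x, ...) {
  cat(sprintf("<friction_result> COF = %.4g, adhesion = %.3g nN, R2 = %.4f (%d loads)\n",
              x$cof, x$adhesion_offset * 1e9, x$fit_r2, length(x$loads)))
  invisible(x)
}

#' Per-load table of a friction result
#' @param x A `friction_result`.
#' @param ... Unused.
#' @return A tibble with `load`, `friction`, `n_loops`, `ratio`.
#' @export
tidy.friction_result <- function(x, ...) {
  tibble(load = x$loads, friction = x$mean_friction,
         n_loops = x$n_loops, ratio = x$ratios)
}

#' @rdname tidy.friction_result
#' @export
glance.friction_result <- function(x, ...) {
  tibble(cof = x$cof, adhesion_offset = x$adhesion_offset,
         fit_r2 = x$fit_r2, n_loads = length(x$loads))
}

# ---- Hertzian contact ------------------------------------------------------

hertz_prefactor <- function(E, cal) {
  (4 / 3) * (E / (1 - cal$poisson^2)) * sqrt(cal$roc)
}

#' Hertzian sphere-on-flat contact force
#'
#' `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` for a rigid sphere of
#' radius `R` indenting an elastic half-space by `delta`. Valid for small
#' indentations; a warning is raised above `0.3 R`.
#'
#' @param E Sample Young's modulus, Pa.
#' @param cal An [afm_calibration()] providing `roc` and `poisson`.
#' @param indentation Indentation depths, m (>= 0).
#' @return Force in newtons.
#' @export
hertz_force <- function(E, cal, indentation) {
  stopifnot(inherits(cal, "afm_calibration"))
  check_number(E, "E", positive = TRUE)
  if (any(indentation < 0)) stop_contract("indentation must be >= 0")
  if (any(indentation > 0.3 * cal$roc)) {
    warn("indentation exceeds 0.3 R; the small-strain Hertz assumption is strained",
         class = "tissuemech_hertz_warning")
  }
  hertz_prefactor(E, cal) * indentation^1.5
}

#' Fit the Hertz model to a force-distance curve
#'
#' The approach curve is baseline-corrected (mean force over the first 25% of
#' samples, assumed pre-contact), then the modulus and the contact point are
#' fitted jointly by least squares of `F = k(E) max(z - z0, 0)^(3/2)` over the
#' samples with baseline-corrected force at or below the trigger. Joint
#' fitting is used because kPa-soft samples show no sharp contact kink.
#'
#' @param curve A data frame with columns `position` (piezo position, m,
#'   increasing toward the sample) and `force` (N), as from
#'   [read_force_curve()] or [gen_hertz_curve()].
#' @param cal An [afm_calibration()].
#' @param trigger Trigger force in newtons; the fit uses samples up to this
#'   force (default 5e-9, a 5 nN instrument trigger).
#' @return A `hertz_fit`: `E` (Pa), `contact_point` (m), `trigger`,
#'   `residual_rms` (N), `converged`, plus the fitted curve in `data`.
#' @examples
#' cal <- afm_calibration(kn = 0.22, alpha = 50e-9, kt = 4e-10, delta = 1e-3,
#'                        t_cant = 4e-6, d_tip = 10e-6)
#' curve <- gen_hertz_curve(E = 1e3, cal = cal, contact_point = 1e-6)
#' fit_hertz(curve, cal)
#' @export
fit_hertz <- function(curve, cal, trigger = 5e-9) {
  stopifnot(inherits(cal, "afm_calibration"))
  check_number(trigger, "trigger", positive = TRUE)
  if (!all(c("position", "force") %in% names(curve))) {
    stop_contract("curve must have columns 'position' and 'force'")
  }
  z <- as.numeric(curve$position)
  f <- as.numeric(curve$force)
  ord <- order(z)
  z <- z[ord]; f <- f[ord]
  n <- length(z)
  if (n < 10L) stop_data("need >= 10 samples in the force curve")
  baseline <- mean(f[seq_len(max(2L, floor(0.25 * n)))])
  f <- f - baseline
  if (max(f) < trigger * (1 - 1e-9)) {
    stop_data(sprintf("curve never reaches the %.3g N trigger (max %.3g N)",
                      trigger, max(f)))
  }
  sel <- f <= trigger * (1 + 1e-9)
  zf <- z[sel]; ff <- f[sel]

  # starting values: contact where force first exceeds 10% of trigger;
  # modulus from the deepest selected point
  i_rise <- which(ff > 0.1 * trigger)
  z0_start <- if (length(i_rise) > 0) zf[i_rise[1]] else stats::median(zf)
  depth <- max(max(zf) - z0_start, 1e-9)
  E_start <- max(trigger / ((4 / 3) / (1 - cal$poisson^2) * sqrt(cal$roc) * depth^1.5),
                 1e-3)
  z_scale <- max(diff(range(zf)), 1e-9)

  resid_fn <- function(par) {
    E <- exp(par[1]); z0 <- par[2] * z_scale
    ff - hertz_prefactor(E, cal) * pmax(zf - z0, 0)^1.5
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(log(E_start), z0_start / z_scale), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 300,
                                                            ftol = 1e-15,
                                                            ptol = 1e-15)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    par <- c(log(E_start), z0_start / z_scale); converged <- FALSE
  } else {
    par <- fit$par; converged <- fit$info %in% 1:3
  }
  E_hat <- exp(par[1]); z0_hat <- par[2] * z_scale
  fitted <- hertz_prefactor(E_hat, cal) * pmax(zf - z0_hat, 0)^1.5
  structure(
    list(E = E_hat, contact_point = z0_hat, trigger = trigger,
         residual_rms = sqrt(mean((ff - fitted)^2)),
         converged = converged, baseline = baseline,
         data = tibble(position = zf, force = ff, fitted = fitted)),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.4g kPa, contact point = %.4g um, RMS = %.3g nN%s\n",
              x$E / 1e3, x$contact_point * 1e6, x$residual_rms * 1e9,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' One-row summary of a Hertz fit
#' @param x A `hertz_fit`.
#' @param ... Unused.
#' @return A tibble with `E`, `contact_point`, `trigger`, `residual_rms`,
#'   `converged`.
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(E = x$E, contact_point = x$contact_point, trigger = x$trigger,
         residual_rms = x$residual_rms, converged = x$converged)
}
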