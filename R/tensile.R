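# Tensile curve processing: preload zero-referencing, stress-strain
# conversion (engineering and true), failure detection, Young's modulus over
# a window of the failure strain, and the stress-relaxation percentage.

#' Zero-reference a tensile record at its preload
#'
#' The first sample whose force reaches the preload becomes the origin: its
#' displacement is subtracted from the displacement array and earlier samples
#' are dropped. The force offset is deliberately not subtracted -- the
#' preloaded state is the mechanical reference, not an artefact.
#'
#' @param rec A [tensile_record()].
#' @return The zero-referenced `tensile_record`.
#' @export
zero_reference <- function(rec) {
  stopifnot(inherits(rec, "tensile_record"))
  preload <- record_preload(rec)
  i0 <- which(rec$force >= preload)[1]
  if (is.na(i0)) stop_data("preload not reached: max force below preload")
  keep <- i0:nrow(rec)
  out <- tibble(time = rec$time[keep], force = rec$force[keep],
                displacement = rec$displacement[keep] - rec$displacement[i0])
  structure(out, geometry = record_geometry(rec), preload = preload,
            zeroed = TRUE, class = class(rec))
}

#' Convert a zero-referenced record to an engineering stress-strain curve
#'
#' stress = force / (width x thickness), strain = displacement / gauge length.
#'
#' @param rec A zero-referenced [tensile_record()] (see [zero_reference()]).
#' @return A [stress_strain()] curve with convention `"engineering"`.
#' @export
to_engineering <- function(rec) {
  stopifnot(inherits(rec, "tensile_record"))
  if (!isTRUE(attr(rec, "zeroed", exact = TRUE))) {
    stop_contract("record must be zero-referenced first (see zero_reference())")
  }
  geom <- record_geometry(rec)
  area <- cross_section(geom)
  stress_strain(strain = rec$displacement / geom$gauge_length,
                stress = rec$force / area,
                convention = "engineering")
}

#' Convert an engineering curve to true stress and strain
#'
#' sigma_true = sigma_eng (1 + eps_eng); eps_true = log(1 + eps_eng). Valid
#' while deformation is uniform (up to the brittle failure point for these
#' near-linear curves).
#'
#' @param ss An engineering-convention [stress_strain()] curve.
#' @return The curve in the `"true"` convention.
#' @export
to_true <- function(ss) {
  stopifnot(inherits(ss, "stress_strain"))
  if (identical(convention(ss), "true")) {
    stop_contract("curve is already in the true convention; refusing to convert twice")
  }
  if (any(ss$strain <= -1)) stop_data("engineering strain must be > -1 everywhere")
  stress_strain(strain = log1p(ss$strain),
                stress = ss$stress * (1 + ss$strain),
                convention = "true")
}

#' Locate the failure point of a stress-strain curve
#'
#' Brittle failure: the failure point is the global stress maximum (ties break
#' to the smallest index). If the curve never drops by more than 5% of its
#' peak after the maximum, the curve looks like a truncated ramp rather than a
#' rupture and the result is flagged.
#'
#' @param ss A [stress_strain()] curve with >= 10 samples.
#' @return A one-row tibble: `failure_stress` (Pa), `failure_strain`, `index`,
#'   and `no_post_failure_drop` (logical flag).
#' @export
detect_failure <- function(ss) {
  stopifnot(inherits(ss, "stress_strain"))
  if (nrow(ss) < 10L) stop_data("need >= 10 samples to locate failure")
  if (diff(range(ss$stress)) == 0) stop_data("stress is constant; no failure point")
  idx <- which.max(ss$stress)
  peak <- ss$stress[idx]
  post_min <- min(ss$stress[idx:nrow(ss)])
  flag <- (peak - post_min) <= 0.05 * peak
  if (flag) {
    warn("no post-failure drop: curve may be a truncated ramp, failure point is the last maximum",
         class = "tissuemech_no_drop_warning")
  }
  tibble(failure_stress = peak, failure_strain = ss$strain[idx],
         index = idx, no_post_failure_drop = flag)
}

#' Young's modulus from the linear region of a stress-strain curve
#'
#' Ordinary least-squares slope of stress vs strain over the samples whose
#' strain lies between `window[1]` and `window[2]` of the failure strain
#' (default 40%--60%, the central linear region of a near-linear brittle
#' curve).
#'
#' @param ss A [stress_strain()] curve.
#' @param window Fractions of the failure strain bounding the fit window,
#'   default `c(0.40, 0.60)`.
#' @return A one-row `tensile_summary` tibble: `youngs_modulus` (Pa),
#'   `failure_stress` (Pa), `failure_strain`, `fit_window_lo`/`_hi` (strain),
#'   `fit_r2`, `n_window`, `convention`.
#' @examples
#' geom <- specimen_geometry(5e-3, 126e-6, 5e-3)
#' rec <- gen_tensile(E = 3.5e6, failure_stress = 0.63e6, geometry = geom)
#' youngs_modulus(to_engineering(zero_reference(rec)))
#' @export
youngs_modulus <- function(ss, window = c(0.40, 0.60)) {
  stopifnot(inherits(ss, "stress_strain"))
  if (length(window) != 2L || !all(is.finite(window))) {
    stop_contract("window must be two finite fractions")
  }
  if (window[1] <= 0 || window[2] <= window[1] || window[2] > 1) {
    stop_contract("window must satisfy 0 < lo < hi <= 1")
  }
  fail <- suppressWarnings(detect_failure(ss))
  lo <- window[1] * fail$failure_strain
  hi <- window[2] * fail$failure_strain
  sel <- which(ss$strain >= lo & ss$strain <= hi)
  if (length(sel) < 3L) {
    stop_data(sprintf(
      "only %d samples inside the fit window [%.3g, %.3g]; sample the curve more densely",
      length(sel), lo, hi))
  }
  fit <- lm(stress ~ strain, data = ss[sel, ])
  slope <- unname(coef(fit)[2])
  r2 <- r_squared(fit, ss$stress[sel])
  out <- tibble(
    youngs_modulus = slope,
    failure_stress = fail$failure_stress,
    failure_strain = fail$failure_strain,
    fit_window_lo = lo, fit_window_hi = hi,
    fit_r2 = r2, n_window = length(sel),
    convention = convention(ss)
  )
  class(out) <- c("tensile_summary", class(out))
  out
}

#' Stress relaxation percentage over a fixed horizon
#'
#' 100 (sigma(t0) - sigma(t0 + horizon)) / sigma(t0), with t0 the start of the
#' hold. The stress at t0 + horizon is read at the nearest sample, by linear
#' interpolation when the horizon falls between two samples.
#'
#' @param trace A [relaxation_trace()].
#' @param horizon Relaxation horizon in seconds (default 200).
#' @return The relaxation percentage (scalar).
#' @examples
#' m <- maxwell_model(E = c(0.5e6, 0.5e6), tau = c(10, 1000))
#' tr <- gen_relaxation(m, hold_strain = 0.1, sample_hz = 10)
#' relaxation_percent(tr) # 100 * (1 - 0.5 exp(-20) - 0.5 exp(-0.2))
#' @export
relaxation_percent <- function(trace, horizon = 200) {
  stopifnot(inherits(trace, "relaxation_trace"))
  check_number(horizon, "horizon", positive = TRUE)
  i0 <- trace_t0(trace)
  s0 <- trace$stress[i0]
  if (!is.finite(s0) || s0 <= 0) stop_data("stress at t0 must be > 0")
  t_target <- trace$time[i0] + horizon
  tmax <- trace$time[nrow(trace)]
  if (t_target > tmax + 1e-9) {
    stop_data(sprintf("trace ends at %.3g s, before t0 + %.3g s", tmax, horizon))
  }
  s_h <- approx(trace$time, trace$stress, xout = min(t_target, tmax))$y
  100 * (s0 - s_h) / s0
}
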