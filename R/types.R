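# Domain types shared across the pipeline. All are plain tibbles or lists with
# a class tag; arrays are treated as immutable after construction and derived
# quantities are always recomputed, never cached.

#' Specimen geometry for a tensile test
#'
#' Dog-bone specimen dimensions used to convert force to engineering stress
#' (force / cross-section) and crosshead displacement to engineering strain
#' (displacement / gauge length).
#'
#' @param width Specimen width in metres.
#' @param thickness Specimen thickness in metres.
#' @param gauge_length Free (gauge) length in metres.
#' @return A `specimen_geometry` object.
#' @examples
#' specimen_geometry(width = 5e-3, thickness = 126e-6, gauge_length = 5e-3)
#' @export
specimen_geometry <- function(width, thickness, gauge_length) {
  check_number(width, "width", positive = TRUE)
  check_number(thickness, "thickness", positive = TRUE)
  check_number(gauge_length, "gauge_length", positive = TRUE)
  structure(
    list(width = width, thickness = thickness, gauge_length = gauge_length),
    class = "specimen_geometry"
  )
}

#' Cross-sectional area of a specimen
#'
#' @param geometry A [specimen_geometry()].
#' @return Area in square metres.
#' @export
cross_section <- function(geometry) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  area <- geometry$width * geometry$thickness
  if (!is.finite(area) || area <= 0) stop_geometry("cross-section must be > 0")
  area
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf(
    "<specimen_geometry> width %.3g mm x thickness %.3g mm, gauge %.3g mm\n",
    x$width * 1e3, x$thickness * 1e3, x$gauge_length * 1e3
  ))
  invisible(x)
}

#' Raw tensile test record
#'
#' A time-resolved force/displacement record in SI units, together with the
#' specimen geometry and the preload used as the reference state (40 mN by
#' default, matching a soft-tissue tensile protocol).
#'
#' @param time Time in seconds, strictly increasing.
#' @param force Force in newtons.
#' @param displacement Crosshead displacement in metres.
#' @param geometry A [specimen_geometry()].
#' @param preload Reference preload in newtons (default 0.040).
#' @return A `tensile_record`: a tibble with columns `time`, `force`,
#'   `displacement` and attributes `geometry`, `preload`, `zeroed`.
#' @export
tensile_record <- function(time, force, displacement, geometry, preload = 0.040) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  check_number(preload, "preload", nonneg = TRUE)
  n <- length(time)
  if (n < 3L || length(force) != n || length(displacement) != n) {
    stop_data("time, force and displacement must have equal length >= 3")
  }
  bad <- which(diff(time) < 0)
  if (length(bad) > 0L) {
    stop_data(sprintf("time must be non-decreasing; first violation at index %d", bad[1] + 1L))
  }
  out <- tibble(time = as.numeric(time), force = as.numeric(force),
                displacement = as.numeric(displacement))
  structure(out,
            geometry = geometry, preload = preload, zeroed = FALSE,
            class = c("tensile_record", class(out)))
}

record_geometry <- function(rec) attr(rec, "geometry", exact = TRUE)
record_preload <- function(rec) attr(rec, "preload", exact = TRUE)

#' Stress-strain curve
#'
#' @param strain Dimensionless strain, zero-referenced (`strain[1] == 0`).
#' @param stress Stress in pascals.
#' @param convention `"engineering"` or `"true"`. Conventions are tagged and
#'   never mixed; [to_true()] refuses an already-true curve.
#' @return A `stress_strain` tibble with a `convention` attribute.
#' @export
stress_strain <- function(strain, stress, convention = c("engineering", "true")) {
  convention <- match.arg(convention)
  if (length(strain) != length(stress)) stop_data("strain and stress must have equal length")
  if (length(strain) > 0 && abs(strain[1]) > 1e-12) {
    stop_data("strain must be zero-referenced: strain[1] == 0")
  }
  out <- tibble(strain = as.numeric(strain), stress = as.numeric(stress))
  structure(out, convention = convention,
            class = c("stress_strain", class(out)))
}

#' Convention of a stress-strain curve
#' @param ss A [stress_strain()] curve.
#' @return `"engineering"` or `"true"`.
#' @export
convention <- function(ss) attr(ss, "convention", exact = TRUE)

#' Ramp-and-hold stress relaxation trace
#'
#' Strain ramps to `hold_strain` and is then held constant; `t0_index` marks
#' the first sample of the hold, the reference time for both the relaxation
#' percentage and the Maxwell fit.
#'
#' @param time Time in seconds, strictly increasing.
#' @param stress Stress in pascals.
#' @param strain Dimensionless strain.
#' @param hold_strain The nominal constant strain of the hold (> 0).
#' @param t0_index Integer index of the first hold sample. If `NULL`, detected
#'   as the first sample whose strain is within `tol` (relative) of
#'   `hold_strain`.
#' @param tol Relative tolerance used both to detect `t0_index` and to check
#'   that the hold strain is constant (default 0.005).
#' @return A `relaxation_trace` tibble with attributes `hold_strain`,
#'   `t0_index`.
#' @export
relaxation_trace <- function(time, stress, strain, hold_strain,
                             t0_index = NULL, tol = 0.005) {
  check_number(hold_strain, "hold_strain", positive = TRUE)
  n <- length(time)
  if (length(stress) != n || length(strain) != n) {
    stop_data("time, stress and strain must have equal length")
  }
  if (any(diff(time) <= 0)) stop_data("time must be strictly increasing")
  if (is.null(t0_index)) {
    hit <- which(abs(strain - hold_strain) <= tol * hold_strain)
    if (length(hit) == 0L) stop_data("no sample reaches hold_strain within tolerance")
    t0_index <- hit[1]
  }
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > n) stop_contract("t0_index out of range")
  hold <- strain[t0_index:n]
  if (any(abs(hold - hold_strain) > tol * hold_strain)) {
    stop_data("strain is not constant over the hold segment within tolerance")
  }
  out <- tibble(time = as.numeric(time), stress = as.numeric(stress),
                strain = as.numeric(strain))
  structure(out, hold_strain = hold_strain, t0_index = t0_index,
            class = c("relaxation_trace", class(out)))
}

trace_t0 <- function(trace) attr(trace, "t0_index", exact = TRUE)
trace_hold_strain <- function(trace) attr(trace, "hold_strain", exact = TRUE)

#' AFM probe and sample calibration constants
#'
#' Constants shared by the photodiode force conversions and the Hertz fit:
#' the normal spring constant `kn` and deflection sensitivity `alpha` convert
#' normal photodiode voltage to force; the torsional stiffness `kt`, detector
#' sensitivity `delta` (rad/V) and the moment arm built from tip height
#' `d_tip` and cantilever thickness `t_cant` convert a friction-loop width to
#' lateral force; `roc` and `poisson` parameterize the Hertzian contact model.
#'
#' @param kn Normal spring constant, N/m.
#' @param alpha Deflection sensitivity, m/V.
#' @param kt Torsional stiffness, N m/rad.
#' @param delta Torsional detector sensitivity, rad/V.
#' @param t_cant Cantilever thickness, m.
#' @param d_tip Tip height, m (no default: probe-specific).
#' @param roc Probe radius of curvature, m (default 10.25 um, a colloidal
#'   sphere probe).
#' @param poisson Sample Poisson ratio, in (0, 0.5] (default 0.45, nearly
#'   incompressible hydrated tissue).
#' @return An `afm_calibration` object.
#' @examples
#' afm_calibration(kn = 0.25, alpha = 50e-9, kt = 4e-10, delta = 1e-3,
#'                 t_cant = 4e-6, d_tip = 10e-6)
#' @export
afm_calibration <- function(kn, alpha, kt, delta, t_cant, d_tip,
                            roc = 10.25e-6, poisson = 0.45) {
  for (nm in c("kn", "alpha", "kt", "delta", "t_cant", "d_tip", "roc")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  check_number(poisson, "poisson")
  if (poisson <= 0 || poisson > 0.5) stop_calibration("poisson must be in (0, 0.5]")
  structure(
    list(kn = kn, alpha = alpha, kt = kt, delta = delta,
         t_cant = t_cant, d_tip = d_tip, roc = roc, poisson = poisson),
    class = "afm_calibration"
  )
}

#' @export
print.afm_calibration <- function(x, ...) {
  cat(sprintf(
    paste0("<afm_calibration> kn %.3g N/m, alpha %.3g nm/V, kt %.3g Nm/rad,\n",
           "  delta %.3g rad/V, t %.3g um, d %.3g um, ROC %.3g um, nu %.2f\n"),
    x$kn, x$alpha * 1e9, x$kt, x$delta, x$t_cant * 1e6, x$d_tip * 1e6,
    x$roc * 1e6, x$poisson
  ))
  invisible(x)
}

#' A single lateral-force (friction) loop
#'
#' Trace and retrace lateral photodiode voltages over one scan line at a fixed
#' applied normal force. The trace-minus-retrace width is proportional to
#' twice the friction force.
#'
#' @param position Scan position, m.
#' @param v_trace,v_retrace Lateral voltages for the two scan directions, V.
#' @param normal_force Applied normal force, N (>= 0).
#' @return A `friction_loop` tibble with a `normal_force` attribute.
#' @export
friction_loop <- function(position, v_trace, v_retrace, normal_force) {
  check_number(normal_force, "normal_force", nonneg = TRUE)
  n <- length(position)
  if (length(v_trace) != n || length(v_retrace) != n) {
    stop_data("trace and retrace must have the same length as position")
  }
  out <- tibble(position = as.numeric(position), v_trace = as.numeric(v_trace),
                v_retrace = as.numeric(v_retrace))
  structure(out, normal_force = normal_force,
            class = c("friction_loop", class(out)))
}

loop_normal_force <- function(loop) attr(loop, "normal_force", exact = TRUE)

#' Noise specification for the synthetic generators
#'
#' @param kind `"multiplicative_gaussian"` (signal x (1 + e), e ~ N(0, sd);
#'   the default for load-cell signals, whose noise scales with the signal) or
#'   `"additive_gaussian"` (signal + e; photodiode-style noise).
#' @param sd Noise level. For multiplicative noise this is always a fraction
#'   of the signal. For additive noise it is an absolute value in signal
#'   units, or a fraction of the peak absolute signal when `relative = TRUE`.
#' @param seed Integer seed; recorded in the provenance of everything the
#'   generators produce.
#' @param relative For additive noise, interpret `sd` as a fraction of the
#'   peak absolute signal.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(kind = c("multiplicative_gaussian", "additive_gaussian"),
                       sd = 0, seed = 1L, relative = FALSE) {
  kind <- match.arg(kind)
  check_number(sd, "sd", nonneg = TRUE)
  check_number(seed, "seed")
  structure(list(kind = kind, sd = sd, seed = as.integer(seed),
                 relative = isTRUE(relative)),
            class = "noise_spec")
}

# Apply a noise spec to a signal. Callers wrap this in withr::with_seed so a
# generator is a pure function of (parameters, seed).
apply_noise <- function(signal, noise) {
  if (is.null(noise) || noise$sd == 0) return(signal)
  n <- length(signal)
  if (noise$kind == "multiplicative_gaussian") {
    signal * (1 + rnorm(n, 0, noise$sd))
  } else {
    sd_abs <- if (noise$relative) noise$sd * max(abs(signal)) else noise$sd
    signal + rnorm(n, 0, sd_abs)
  }
}
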