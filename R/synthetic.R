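# Seeded generators for every input type the pipeline consumes, built from
# known ground truth so each analysis stage can be tested by parameter
# recovery. Every generator is a pure function of (parameters, seed):
# identical calls give bit-identical output.

#' Generate a ramp-and-hold relaxation trace from a Maxwell model
#'
#' Strain ramps at `ramp_rate` to `hold_strain`, then holds for `duration`
#' seconds. The hold stress is the idealized step response
#' `hold_strain * maxwell_stress(model, t - t0)`, so closed-form expressions
#' for the relaxation percentage hold exactly on the hold segment. The ramp
#' stress uses the analytic constant-rate response of each element,
#' `E_i tau_i rate (1 - exp(-t/tau_i))` (a quasi-static approximation; the
#' two conventions differ slightly at the junction for elements with tau
#' comparable to the ramp time, which the hold-only analysis never sees).
#'
#' @param model A [maxwell_model()] whose stiffnesses are moduli (Pa).
#' @param hold_strain Constant strain of the hold (e.g. 0.05, 0.10, 0.15).
#' @param ramp_rate Strain rate of the ramp, 1/s (default 0.34).
#' @param duration Hold duration, s (default 200).
#' @param sample_hz Sampling rate, Hz.
#' @param noise A [noise_spec()] applied to the stress channel.
#' @return A [relaxation_trace()] with `t0_index` set exactly; the noise seed
#'   is attached as attribute `seed`.
#' @export
gen_relaxation <- function(model, hold_strain, ramp_rate = 0.34,
                           duration = 200, sample_hz = 10,
                           noise = noise_spec(sd = 0)) {
  stopifnot(inherits(model, "maxwell_model"))
  check_number(hold_strain, "hold_strain", positive = TRUE)
  check_number(ramp_rate, "ramp_rate", positive = TRUE)
  check_number(duration, "duration", positive = TRUE)
  check_number(sample_hz, "sample_hz", positive = TRUE)
  if (sample_hz * duration < 20) stop_contract("need sample_hz * duration >= 20")
  dt <- 1 / sample_hz
  t0 <- hold_strain / ramp_rate
  k <- floor(t0 / dt + 1e-9)
  ramp_t <- (0:k) * dt
  ramp_t <- ramp_t[ramp_t < t0 - 1e-12 * max(t0, 1)]
  hold_t <- t0 + (0:round(duration * sample_hz)) * dt

  ramp_strain <- ramp_rate * ramp_t
  ramp_stress <- ramp_rate * drop(
    (1 - exp(-outer(ramp_t, 1 / model$tau))) %*% (model$E * model$tau)
  )
  hold_stress <- hold_strain * maxwell_stress(model, hold_t - t0)

  stress <- c(ramp_stress, hold_stress)
  stress <- withr::with_seed(noise$seed, apply_noise(stress, noise))
  out <- relaxation_trace(
    time = c(ramp_t, hold_t),
    stress = stress,
    strain = c(ramp_strain, rep(hold_strain, length(hold_t))),
    hold_strain = hold_strain,
    t0_index = length(ramp_t) + 1L
  )
  attr(out, "seed") <- noise$seed
  out
}

#' Generate a brittle linear tensile record
#'
#' Stress rises linearly with total strain at slope `E` up to
#' `failure_stress`, then collapses over 3 samples to 5% of the peak.
#' Stress and strain are converted back to force and displacement via the
#' geometry, and time via the strain rate, so the record looks like a raw
#' instrument export; the early part of the ramp (forces below the preload)
#' is what [zero_reference()] later discards.
#'
#' @param E Young's modulus, Pa.
#' @param failure_stress Peak stress, Pa (must exceed the preload stress
#'   `preload / cross-section`).
#' @param sample_n Number of samples on the loading ramp (default 500).
#' @param noise A [noise_spec()] applied to the force channel.
#' @param geometry A [specimen_geometry()].
#' @param preload Preload in newtons (default 0.040), recorded on the output.
#' @param strain_rate Strain rate, 1/s (default 0.34), used for the time axis.
#' @return A [tensile_record()]; the noise seed is attached as attribute
#'   `seed`.
#' @export
gen_tensile <- function(E, failure_stress, sample_n = 500,
                        noise = noise_spec(sd = 0), geometry,
                        preload = 0.040, strain_rate = 0.34) {
  check_number(E, "E", positive = TRUE)
  check_number(failure_stress, "failure_stress", positive = TRUE)
  stopifnot(inherits(geometry, "specimen_geometry"))
  area <- cross_section(geometry)
  sigma_preload <- preload / area
  if (failure_stress <= sigma_preload) {
    stop_contract("failure_stress must exceed the preload stress preload/area")
  }
  eps_f <- failure_stress / E
  strain <- seq(0, eps_f, length.out = sample_n)
  stress <- E * strain
  # brittle collapse: 3 samples down to 5% of the peak
  d_eps <- eps_f / (sample_n - 1)
  strain <- c(strain, eps_f + d_eps * (1:3))
  stress <- c(stress, seq(failure_stress, 0.05 * failure_stress,
                          length.out = 4)[2:4])
  force <- stress * area
  force <- withr::with_seed(noise$seed, apply_noise(force, noise))
  out <- tensile_record(
    time = strain / strain_rate,
    force = force,
    displacement = strain * geometry$gauge_length,
    geometry = geometry,
    preload = preload
  )
  attr(out, "seed") <- noise$seed
  out
}

#' Generate a Hertzian force-distance curve
#'
#' Flat zero baseline before the contact point, Hertz sphere-on-flat force
#' beyond it, truncated exactly where the force reaches the trigger.
#'
#' @param E Sample Young's modulus, Pa.
#' @param cal An [afm_calibration()] (radius of curvature, Poisson ratio).
#' @param contact_point Piezo position of contact, m.
#' @param z_start Start of the piezo sweep, m; must precede the contact
#'   point. The default (`NULL`) starts half a maximum indentation depth
#'   before contact, so a third of the sweep is baseline.
#' @param n_samples Number of samples (default 400).
#' @param trigger Trigger force, N (default 5e-9).
#' @param noise A [noise_spec()] applied to the force channel (additive, for
#'   photodiode-style noise, is the physically sensible kind here).
#' @return A tibble with columns `position` (m) and `force` (N); the noise
#'   seed is attached as attribute `seed`.
#' @export
gen_hertz_curve <- function(E, cal, contact_point, z_start = NULL,
                            n_samples = 400, trigger = 5e-9,
                            noise = noise_spec("additive_gaussian", sd = 0)) {
  stopifnot(inherits(cal, "afm_calibration"))
  check_number(E, "E", positive = TRUE)
  check_number(contact_point, "contact_point")
  k <- hertz_prefactor(E, cal)
  depth_max <- (trigger / k)^(2 / 3)
  if (is.null(z_start)) z_start <- contact_point - depth_max / 2
  if (z_start >= contact_point) stop_contract("z_start must precede contact_point")
  position <- seq(z_start, contact_point + depth_max, length.out = n_samples)
  force <- k * pmax(position - contact_point, 0)^1.5
  force <- withr::with_seed(noise$seed, apply_noise(force, noise))
  out <- tibble(position = position, force = force)
  attr(out, "seed") <- noise$seed
  out
}

#' Generate friction loops with load-proportional friction
#'
#' Loop widths are constructed by inverting the lateral-force calibration so
#' that processing them recovers `Ff = cof * Fn + adhesion` exactly in the
#' noiseless limit. Optional turnaround artifacts (large spikes in the outer
#' 10% of the scan) exercise the central-80% width rule.
#'
#' @param cof Ground-truth coefficient of friction (>= 0).
#' @param adhesion Adhesion offset, N (friction force at zero load).
#' @param loads Normal forces, N (one sweep; >= 3 distinct values for the
#'   downstream regression).
#' @param loops_per_load Loops recorded per load (default 16).
#' @param cal An [afm_calibration()].
#' @param noise A [noise_spec()] applied per point to both voltage channels.
#' @param n_points Scan positions per loop (default 128).
#' @param scan_size Scan length, m (default 5e-6).
#' @param artifacts Inject turnaround spikes in the outer 10% of positions.
#' @return A list of [friction_loop()] objects (`loops_per_load` per load);
#'   the noise seed is attached as attribute `seed`.
#' @export
gen_friction_loops <- function(cof, adhesion = 0, loads, loops_per_load = 16,
                               cal, noise = noise_spec("additive_gaussian", sd = 0),
                               n_points = 128, scan_size = 5e-6,
                               artifacts = FALSE) {
  stopifnot(inherits(cal, "afm_calibration"))
  check_number(cof, "cof", nonneg = TRUE)
  check_number(adhesion, "adhesion")
  position <- seq(0, scan_size, length.out = n_points)
  outer10 <- position < 0.1 * scan_size | position > 0.9 * scan_size
  arm <- cal$d_tip + cal$t_cant / 2
  loops <- withr::with_seed(noise$seed, {
    purrr::map(loads, function(fn) {
      ff <- cof * fn + adhesion
      width <- ff * 2 * arm / (cal$kt * cal$delta)
      purrr::map(seq_len(loops_per_load), function(i) {
        v_trace <- apply_noise(rep(width / 2, n_points), noise)
        v_retrace <- apply_noise(rep(-width / 2, n_points), noise)
        if (artifacts) {
          spike <- max(5 * abs(width), 0.1)
          v_trace[outer10] <- v_trace[outer10] + spike
          v_retrace[outer10] <- v_retrace[outer10] - spike
        }
        friction_loop(position, v_trace, v_retrace, normal_force = fn)
      })
    })
  })
  out <- purrr::flatten(loops)
  attr(out, "seed") <- noise$seed
  out
}
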