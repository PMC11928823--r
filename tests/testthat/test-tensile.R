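# Tensile curve processing: zero-referencing, conventions, failure point,
# Young's modulus, relaxation percentage.

test_that("zero_reference anchors at the first sample reaching the preload", {
  geom <- default_geometry()
  force <- seq(0, 1, length.out = 101)
  rec <- tensile_record(time = seq(0, 10, length.out = 101), force = force,
                        displacement = seq(0, 1e-3, length.out = 101),
                        geometry = geom, preload = 0.04)
  z <- zero_reference(rec)
  expect_true(z$force[1] >= 0.04)
  expect_equal(z$displacement[1], 0)
  # force is NOT offset: the preload state is the reference
  expect_equal(z$force[1], force[which(force >= 0.04)[1]])
  expect_equal(nrow(z), 101 - which(force >= 0.04)[1] + 1)

  # preload 0: nothing dropped, displacement re-zeroed at the first sample
  rec0 <- tensile_record(rec$time, rec$force, rec$displacement + 5e-4,
                         geometry = geom, preload = 0)
  z0 <- zero_reference(rec0)
  expect_equal(nrow(z0), nrow(rec0))
  expect_equal(z0$displacement[1], 0)

  # preload never reached
  rec_low <- tensile_record(rec$time, rec$force * 1e-3, rec$displacement,
                            geometry = geom, preload = 0.04)
  expect_error(zero_reference(rec_low), "preload not reached",
               class = "tissuemech_data_error")
})

test_that("to_engineering divides by cross-section and gauge length", {
  geom <- default_geometry() # 5 mm x 0.126 mm, gauge 5 mm
  rec <- tensile_record(time = 0:3, force = c(0.04, 0.2, 0.35, 0.5),
                        displacement = c(0, 2e-4, 3.5e-4, 5e-4),
                        geometry = geom, preload = 0.04)
  ss <- to_engineering(zero_reference(rec))
  expect_equal(convention(ss), "engineering")
  # 0.5 N over 5 mm x 0.126 mm: 793650.79... Pa (hand arithmetic)
  expect_equal(ss$stress[4], 0.5 / (5e-3 * 126e-6), tolerance = 1e-12)
  # 0.5 mm over a 5 mm gauge
  expect_equal(ss$strain[4], 0.10, tolerance = 1e-12)
  # refuses non-zero-referenced input
  expect_error(to_engineering(rec), class = "tissuemech_contract_error")
})

test_that("to_true applies the uniform-deformation conversion once", {
  ss <- stress_strain(strain = c(0, 0.10, 0.25),
                      stress = c(0, 1.0e6, 0.63e6))
  tt <- to_true(ss)
  expect_equal(convention(tt), "true")
  expect_equal(tt$strain, c(0, log(1.10), log(1.25)), tolerance = 1e-12)
  expect_equal(tt$stress, c(0, 1.10e6, 0.7875e6), tolerance = 1e-12)
  # 0.09531, 0.22314: frozen from log1p
  expect_equal(tt$strain[2], 0.0953102, tolerance = 1e-6)
  expect_equal(tt$strain[3], 0.2231436, tolerance = 1e-6)
  expect_error(to_true(tt), class = "tissuemech_contract_error")
})

test_that("true conversion shrinks strain and inflates stress, preserving length", {
  for (seed in 1:5) {
    eps <- withr::with_seed(seed, sort(c(0, runif(30, 0.001, 0.3))))
    ss <- stress_strain(eps, 3.5e6 * eps)
    tt <- to_true(ss)
    expect_equal(nrow(tt), nrow(ss))
    pos <- ss$strain > 0
    expect_true(all(tt$strain[pos] < ss$strain[pos]))
    expect_true(all(tt$stress[pos] > ss$stress[pos]))
  }
})

test_that("detect_failure finds the global stress maximum with first-index ties", {
  # triangle rising to (0.17, 0.63 MPa) then collapsing
  eps <- c(seq(0, 0.17, length.out = 50), seq(0.175, 0.2, length.out = 6))
  sig <- c(seq(0, 0.63e6, length.out = 50), seq(0.2e6, 0.05e6, length.out = 6))
  fail <- detect_failure(stress_strain(eps, sig))
  expect_equal(fail$failure_stress, 0.63e6)
  expect_equal(fail$failure_strain, 0.17)
  expect_false(fail$no_post_failure_drop)

  # strictly increasing: last point, with the truncated-ramp flag
  eps2 <- seq(0, 0.1, length.out = 20)
  expect_warning(
    fail2 <- detect_failure(stress_strain(eps2, 1e6 * eps2)),
    class = "tissuemech_no_drop_warning"
  )
  expect_equal(fail2$index, 20L)
  expect_true(fail2$no_post_failure_drop)

  # two equal maxima: earlier index wins
  sig3 <- c(seq(0, 1e6, length.out = 10), 0.5e6, 1e6, 0.1e6)
  eps3 <- seq(0, 0.13, length.out = 13)
  fail3 <- detect_failure(stress_strain(eps3, sig3))
  expect_equal(fail3$index, 10L)
})

test_that("youngs_modulus recovers an exact linear slope for any valid window", {
  eps <- seq(0, 0.18, length.out = 400)
  sig <- 3.5e6 * eps
  # brittle cutoff after the peak
  ss <- stress_strain(c(eps, 0.181, 0.182), c(sig, 0.1e6, 0.03e6))
  for (w in list(c(0.4, 0.6), c(0.2, 0.8), c(0.45, 0.55))) {
    summ <- youngs_modulus(ss, window = w)
    expect_equal(summ$youngs_modulus, 3.5e6, tolerance = 1e-12)
    expect_equal(summ$fit_r2, 1, tolerance = 1e-12)
  }
  summ <- youngs_modulus(ss)
  expect_equal(summ$failure_stress, 3.5e6 * 0.18)
  expect_equal(summ$fit_window_lo, 0.4 * 0.18)
  expect_equal(summ$fit_window_hi, 0.6 * 0.18)

  expect_error(youngs_modulus(ss, window = c(0.6, 0.4)),
               class = "tissuemech_contract_error")
  # too-sparse curve inside the window
  sparse <- stress_strain(seq(0, 0.2, length.out = 11),
                          c(seq(0, 1e6, length.out = 10), 0.1e6))
  expect_error(youngs_modulus(sparse, window = c(0.49, 0.51)),
               class = "tissuemech_data_error")
})

test_that("relaxation_percent matches closed forms and is scale-invariant", {
  # constant stress: 0%
  tr_const <- relaxation_trace(time = seq(0, 250, by = 1),
                               stress = rep(2e5, 251),
                               strain = rep(0.1, 251),
                               hold_strain = 0.1, t0_index = 1L)
  expect_equal(relaxation_percent(tr_const), 0)

  # single element, tau = 100 s, horizon 200 s: 100 (1 - e^-2)
  m1 <- maxwell_model(E = 1e6, tau = 100)
  tr1 <- gen_relaxation(m1, hold_strain = 0.1, sample_hz = 5)
  expect_equal(relaxation_percent(tr1), 100 * (1 - exp(-2)), tolerance = 1e-9)
  expect_equal(relaxation_percent(tr1), 86.46647, tolerance = 1e-5)

  # two elements, closed form 100 (1 - 0.5 e^-20 - 0.5 e^-0.2) = 59.06...
  m2 <- maxwell_model(E = c(0.5e6, 0.5e6), tau = c(10, 1000))
  tr2 <- gen_relaxation(m2, hold_strain = 0.1, sample_hz = 5)
  expect_equal(relaxation_percent(tr2),
               100 * (1 - 0.5 * exp(-20) - 0.5 * exp(-0.2)), tolerance = 1e-9)

  # invariant under uniform stress rescaling
  tr2b <- relaxation_trace(tr2$time, tr2$stress * 7.3, tr2$strain,
                           hold_strain = 0.1, t0_index = attr(tr2, "t0_index"))
  expect_equal(relaxation_percent(tr2b), relaxation_percent(tr2), tolerance = 1e-12)

  # horizon beyond the trace
  expect_error(relaxation_percent(tr2, horizon = 1e4),
               class = "tissuemech_data_error")
})
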