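# Generalized Maxwell model: evaluation, derived quantities, fitting, and
# chi2-drop order selection.

test_that("maxwell_stress matches a naive element-by-element sum", {
  m <- maxwell_model(E = 1e6, tau = 1)
  expect_equal(maxwell_stress(m, 0), 1e6)
  expect_equal(maxwell_stress(m, 1), 1e6 * exp(-1), tolerance = 1e-12)

  m4 <- paper_like_model()
  t <- c(0, 0.5, 20, 200, 1000)
  expect_equal(maxwell_stress(m4, t),
               oracle_prony(m4$E, m4$tau, t), tolerance = 1e-12)
  # t = 200 s: dominated by the slow element, 7 e^-0.05 + e^-2/3 + ... MPa
  expect_equal(maxwell_stress(m4, 200) / 1e6,
               7 * exp(-200 / 4000) + exp(-200 / 300) + exp(-200 / 20) + exp(-400),
               tolerance = 1e-12)
  expect_error(maxwell_stress(m4, c(1, -1)), class = "tissuemech_contract_error")
})

test_that("relative importance and viscosity are elementwise and sum correctly", {
  m <- maxwell_model(E = c(1e6, 1e6, 1e6, 7e6), tau = c(0.5, 20, 300, 4000))
  expect_equal(relative_importance(m), c(10, 10, 10, 70))
  expect_equal(sum(relative_importance(m)), 100, tolerance = 1e-9)
  expect_equal(relative_importance(maxwell_model(1e5, 3)), 100)
  expect_equal(relative_importance(maxwell_model(c(2e6, 2e6), c(1, 10))), c(50, 50))

  expect_equal(viscosity(maxwell_model(2e6, 50)), 1e8)
  expect_equal(viscosity(maxwell_model(1, 1)), 1)
  expect_equal(viscosity(maxwell_model(c(1e6, 7e6), c(0.5, 4000))),
               c(0.5e6, 28000e6))
})

test_that("maxwell_stress is invariant to element order", {
  t <- seq(0, 300, by = 7)
  a <- maxwell_model(E = c(3e5, 1e6, 5e5), tau = c(2, 900, 40))
  b <- maxwell_model(E = c(1e6, 5e5, 3e5), tau = c(900, 40, 2))
  expect_equal(maxwell_stress(a, t), maxwell_stress(b, t), tolerance = 1e-14)
})

test_that("model construction enforces positivity and tau ordering", {
  m <- maxwell_model(E = c(1, 2), tau = c(100, 1))
  expect_equal(m$tau, c(1, 100))
  expect_equal(m$E, c(2, 1))
  expect_error(maxwell_model(E = c(1, -1), tau = c(1, 2)),
               class = "tissuemech_contract_error")
  expect_error(maxwell_model(E = 1, tau = 0), class = "tissuemech_contract_error")
})

test_that("fit_maxwell recovers noiseless in-class parameters", {
  # single element
  tr1 <- gen_relaxation(maxwell_model(E = 1e6, tau = 50), hold_strain = 0.1,
                        sample_hz = 5)
  f1 <- fit_maxwell(tr1, n = 1, seed = 3)
  # fitted amplitudes are stress (hold_strain * E); report as modulus too
  expect_equal(f1$model$E, 0.1 * 1e6, tolerance = 1e-6)
  expect_equal(f1$model$tau, 50, tolerance = 1e-6)
  f1m <- fit_maxwell(tr1, n = 1, seed = 3, as_modulus = TRUE)
  expect_equal(f1m$model$E, 1e6, tolerance = 1e-6)
  expect_true(f1$converged)

  # two elements, checked against an independent grid-search oracle
  m2 <- maxwell_model(E = c(0.5e6, 0.5e6), tau = c(10, 1000))
  tr2 <- gen_relaxation(m2, hold_strain = 0.1, sample_hz = 5)
  f2 <- fit_maxwell(tr2, n = 2, seed = 3)
  expect_equal(f2$model$tau, c(10, 1000), tolerance = 0.01)
  i0 <- attr(tr2, "t0_index")
  t <- tr2$time[i0:nrow(tr2)] - tr2$time[i0]
  grid <- oracle_grid_fit2(t, tr2$stress[i0:nrow(tr2)])
  # oracle resolution is one log-grid step (~17%); the fit must sit at the
  # oracle's optimum within that resolution
  expect_equal(log(f2$model$tau), log(grid$tau), tolerance = 0.2)

  # nesting: n = 3 on a two-element trace fits at least as well
  f3 <- fit_maxwell(tr2, n = 3, seed = 3, init = f2$model)
  expect_lte(f3$chi2, f2$chi2 * (1 + 1e-9))
})

test_that("fit_maxwell validates inputs and never throws on hard data", {
  tr <- gen_relaxation(maxwell_model(1e6, 50), hold_strain = 0.1, sample_hz = 0.1)
  # 21 hold samples cannot support n = 6 (needs 24)
  expect_error(fit_maxwell(tr, n = 6, seed = 1), class = "tissuemech_data_error")
  # pure-noise stress still returns a best-effort fit object
  tr_noise <- relaxation_trace(time = 0:40,
                               stress = abs(withr::with_seed(1, rnorm(41, 1, 0.1))),
                               strain = rep(0.1, 41), hold_strain = 0.1,
                               t0_index = 1L)
  f <- fit_maxwell(tr_noise, n = 2, seed = 1, restarts = 2)
  expect_s3_class(f$model, "maxwell_model")
  expect_true(is.finite(f$chi2))
})

test_that("fits are deterministic in the seed", {
  tr <- gen_relaxation(paper_like_model(), hold_strain = 0.1, sample_hz = 2,
                       noise = noise_spec("multiplicative_gaussian", 0.01, seed = 5))
  f_a <- fit_maxwell(tr, n = 2, seed = 11)
  f_b <- fit_maxwell(tr, n = 2, seed = 11)
  expect_identical(f_a$model$tau, f_b$model$tau)
  expect_identical(f_a$chi2, f_b$chi2)
})

test_that("select_order picks 1 element for single-element data and obeys limits", {
  tr <- gen_relaxation(maxwell_model(E = 1e6, tau = 50), hold_strain = 0.1,
                       sample_hz = 2,
                       noise = noise_spec("multiplicative_gaussian", 0.005, seed = 2))
  sel <- select_order(tr, n_max = 3, restarts = 4, seed = 2)
  expect_equal(sel$selected_n, 1L)
  expect_equal(sel$chi2, unname(sel$chi2_path[sel$selected_n]))

  # drop_threshold = 1 selects 1 always
  tr4 <- gen_relaxation(paper_like_model(), hold_strain = 0.1, sample_hz = 2,
                        noise = noise_spec("multiplicative_gaussian", 0.01, seed = 3))
  sel1 <- select_order(tr4, drop_threshold = 1.0, restarts = 2, seed = 3)
  expect_equal(sel1$selected_n, 1L)

  expect_error(select_order(tr, n_max = 1, seed = 1),
               class = "tissuemech_contract_error")
})

test_that("chi2 path is non-increasing (nesting with warm starts)", {
  for (seed in c(4, 9)) {
    tr <- gen_relaxation(paper_like_model(), hold_strain = 0.1, sample_hz = 2,
                         noise = noise_spec("multiplicative_gaussian", 0.01,
                                            seed = seed))
    sel <- select_order(tr, n_max = 4, drop_threshold = 0, restarts = 3,
                        seed = seed)
    expect_true(all(diff(sel$chi2_path) <= 1e-12 * sel$chi2_path[-length(sel$chi2_path)]))
  }
})

test_that("tidy and glance expose per-element and per-fit summaries", {
  tr <- gen_relaxation(maxwell_model(E = 1e6, tau = 50), hold_strain = 0.1,
                       sample_hz = 2)
  f <- fit_maxwell(tr, n = 1, seed = 1, restarts = 2)
  td <- tidy(f)
  expect_named(td, c("element", "E", "tau", "eta", "RI"))
  expect_equal(td$eta, td$E * td$tau)
  gl <- glance(f)
  expect_equal(gl$n, 1L)
  expect_true(gl$converged)
})
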