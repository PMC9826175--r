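test_that("evaporation rate matches hand arithmetic and scales linearly", {
  expect_equal(evaporation_rate(100, 0.87, 0.10, 1), 100 / 1.87 * 0.1,
               tolerance = 1e-12)
  expect_equal(evaporation_rate(100, 0.87, 0, 1), 0)
  expect_equal(evaporation_rate(100, 0.87, 0.10, 0.5),
               2 * evaporation_rate(100, 0.87, 0.10, 1))
  expect_error(evaporation_rate(100, 0.87, -0.01, 1), "re-wetting")
  expect_error(evaporation_rate(100, 0.87, 0.1, 0), "dt")
})

test_that("efficiency definition, proportionality and unphysical flag", {
  m_w <- 5.348
  Qst <- 46100
  # exact balance gives unit efficiency
  q_in <- m_w * Qst / 0.018 / 1000
  expect_equal(drying_efficiency(m_w, Qst, q_in), 1, tolerance = 1e-12)
  eta <- drying_efficiency(m_w, Qst, 33000)
  expect_equal(eta, 0.415, tolerance = 0.002)
  expect_equal(drying_efficiency(m_w, Qst, 66000), eta / 2, tolerance = 1e-12)
  expect_equal(suppressWarnings(drying_efficiency(2 * m_w, Qst, 33000)),
               2 * eta, tolerance = 1e-12)
  expect_warning(drying_efficiency(m_w, Qst, 1000), "unphysical")
  expect_error(drying_efficiency(-1, Qst, 33000), "> 0")
  # as-printed literature form differs by Ww^2
  expect_equal(drying_efficiency(m_w, Qst, 33000, as_printed = TRUE),
               eta * 0.018^2, tolerance = 1e-12)
})

test_that("profile reproduces the drying curve's analytic differences", {
  run <- simulate_drying_run(W_ini = 100, X_ini = 0.87, X_eq = 0.05, k = 0.3,
                             temp_c = 45, Q_in_rate = 33000, n_points = 9)
  prof <- efficiency_profile(run, cp_spec)
  expect_equal(nrow(prof), 8)
  # closed-form interval losses of the exponential decay
  t <- run$time_h
  dx_expected <- (0.87 - 0.05) * (exp(-0.3 * t[-length(t)]) - exp(-0.3 * t[-1]))
  expect_equal(prof$m_w, 100 / 1.87 * dx_expected, tolerance = 1e-10)
  expect_true(all(diff(prof$m_w) < 0))
  expect_true(all(diff(prof$eta) < 0))
  # single-interval run equals the scalar efficiency
  run2 <- drying_run(c(0, 1), c(0.87, 0.77), W_ini = 100, X_ini = 0.87,
                     temp_c = 45, Q_in_rate = 33000)
  prof2 <- efficiency_profile(run2, cp_spec)
  expect_equal(prof2$eta,
               drying_efficiency(evaporation_rate(100, 0.87, 0.10, 1),
                                 total_isosteric_heat(cp_spec, 0.82, 45),
                                 33000))
})

test_that("a run generated at constant efficiency recovers it to 1e-9", {
  # constant-rate drying with a flat isotherm (qst = 0) keeps Qst constant
  flat <- sorption_spec("halsey", 5.5667, 0, 2.0859)
  x <- seq(0.8, 0.2, by = -0.1)
  run <- drying_run(seq_along(x) - 1, x, W_ini = 50, X_ini = 0.8,
                    temp_c = 45, Q_in_rate = 20000)
  prof <- efficiency_profile(run, flat)
  eta_expected <- drying_efficiency(50 / 1.8 * 0.1, latent_heat_water(45),
                                    20000)
  expect_equal(prof$eta, rep(eta_expected, nrow(prof)), tolerance = 1e-9)
})

test_that("drying-run construction enforces physical validity", {
  expect_error(drying_run(c(0, 1), c(0.5, 0.6), 100, 0.5, 45, 1000),
               "non-increasing")
  expect_error(drying_run(c(1, 0), c(0.6, 0.5), 100, 0.6, 45, 1000),
               "increasing")
  expect_error(simulate_drying_run(100, 0.5, 0.6, 0.3, 45, 1000),
               "below X_ini")
  # zero decay constant: constant moisture, zero evaporation everywhere
  run0 <- simulate_drying_run(100, 0.5, 0.05, 0, 45, 1000, n_points = 5)
  prof0 <- efficiency_profile(run0, cp_spec)
  expect_equal(prof0$m_w, rep(0, 4))
  expect_equal(prof0$eta, rep(0, 4))
})
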