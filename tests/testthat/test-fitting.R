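test_that("goodness-of-fit indices match hand arithmetic and are order-invariant", {
  obs <- c(0.2, 0.4, 0.6, 0.8)
  pred <- c(0.22, 0.38, 0.63, 0.77)
  g <- goodness_of_fit(obs, pred, n_params = 3)
  # MRPE = 25*(0.02/0.2 + 0.02/0.4 + 0.03/0.6 + 0.03/0.8)
  expect_equal(g$mrpe, 5.9375, tolerance = 1e-12)
  expect_equal(g$see, sqrt((4e-4 + 4e-4 + 9e-4 + 9e-4) / 1),
               tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  expect_equal(goodness_of_fit(obs[perm], pred[perm], 3), g)
  gp <- goodness_of_fit(obs, obs, 3)
  expect_equal(gp$r2, 1)
  expect_equal(gp$mrpe, 0)
  expect_equal(gp$see, 0)
  expect_error(goodness_of_fit(c(0, 0.4, 0.5, 0.6), pred, 3), "zero")
})

test_that("noise-free data from every family is recovered to 1e-6 relative", {
  design_base <- study_design(noise_sd = 0, product_shift = 0, seed = 1)
  for (f in names(all_specs)) {
    truth <- all_specs[[f]]
    d <- simulate_isotherms(study_design(truth = truth, noise_sd = 0,
                                         product_shift = 0, seed = 1))
    ft <- fit_sorption(d, f)
    est <- unlist(ft$spec[c("p1", "p2", "p3")])
    tru <- unlist(truth[c("p1", "p2", "p3")])
    expect_equal(unname(est), unname(tru), tolerance = 1e-6, info = f)
    expect_equal(ft$r2, 1, tolerance = 1e-9, info = f)
    expect_lt(ft$mrpe, 1e-5)
    expect_lt(ft$see, 1e-7)
    expect_true(ft$converged)
  }
})

test_that("noisy Chung-Pfost fit recovers truth within 2 standard errors", {
  d <- simulate_isotherms(study_design(noise_sd = 0, product_shift = 0,
                                       seed = 3))
  # Gaussian noise on the ERH response, matching the regression scale
  set.seed(3)
  d$erh <- pmin(pmax(d$erh + rnorm(nrow(d), 0, 0.01), 1e-3), 0.999)
  ft <- fit_sorption(d, "chung_pfost")
  est <- unlist(ft$spec[c("p1", "p2", "p3")])
  tru <- c(533.4351, 15.6235, 38.9053)
  expect_true(all(abs(est - tru) < 2 * ft$stderr))
  # stderr magnitudes comparable to pooled-fit reference (order of magnitude)
  expect_gt(ft$stderr[["p1"]], 2)
  expect_lt(ft$stderr[["p1"]], 300)
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- simulate_isotherms(study_design(truth = oswin_spec, noise_sd = 0,
                                       product_shift = 0, seed = 1))
  ft <- fit_sorption(d, "oswin")
  td <- tidy(ft)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$term, c("p1", "p2", "p3"))
  gl <- glance(ft)
  expect_equal(gl$nobs, nrow(d))
  expect_true(gl$converged)
  expect_equal(predict(ft, tibble::tibble(emc = 0.5 * (0.1783 - 0.0008338 * 25) * 2,
                                          temp_c = 25)),
               0.5, tolerance = 1e-6)
})

test_that("residual normality screen behaves under null and alternative", {
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    residual_normality(rnorm(100))$normal
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  set.seed(11)
  skewed <- rexp(100)
  expect_false(residual_normality(skewed)$normal)
  out <- residual_normality(c(-1, 0, 1))
  expect_true(is.finite(out$statistic))
  expect_error(residual_normality(rep(0.2, 10)), "constant")
})

test_that("model comparison ranks the generating family first on its own data", {
  d <- simulate_isotherms(study_design(truth = oswin_spec, noise_sd = 0,
                                       product_shift = 0, seed = 2))
  cm <- compare_sorption_models(d)
  expect_equal(cm$family[1], "oswin")
  expect_equal(cm$see[1], 0, tolerance = 1e-8)
  # derived sanity band under default study conditions: truth family under
  # 15% MRPE, every family under 20%
  d2 <- simulate_isotherms(study_design(seed = 5))
  cm2 <- compare_sorption_models(d2)
  expect_true(all(cm2$mrpe < 20))
  expect_lt(cm2$mrpe[cm2$family == "chung_pfost"], 15)
  expect_equal(cm2$good_fit, cm2$mrpe < 10)
})

test_that("fitting preconditions are enforced", {
  d <- simulate_isotherms(study_design(seed = 1))
  one_t <- d[d$temp_c == 45, ]
  expect_error(fit_sorption(one_t, "oswin"), "2 distinct temperatures")
  few_h <- d[d$erh > 0.5, ]
  expect_error(fit_sorption(few_h[few_h$erh %in% unique(few_h$erh)[1:2], ],
                            "oswin"), "3 distinct ERH")
})
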