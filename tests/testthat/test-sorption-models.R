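test_that("predict_erh reproduces hand-evaluated closed forms", {
  expect_equal(predict_erh(cp_spec, 0.10, 25), 0.1737833, tolerance = 1e-6)
  expect_equal(predict_erh(oswin_spec, 0.10, 25), 0.1960147, tolerance = 1e-6)
  expect_equal(predict_erh(halsey_spec, 0.10, 25), 0.2096275, tolerance = 1e-6)
  # large moisture: Chung-Pfost exponent vanishes, ERH -> 1
  expect_equal(predict_erh(cp_spec, 5, 25), 1, tolerance = 1e-6)
  # Oswin at ERH = 0.5, the inverse gives M = p1 + p2*T exactly
  expect_equal(predict_emc(oswin_spec, 0.5, 25), 0.1783 - 0.0008338 * 25,
               tolerance = 1e-12)
})

test_that("predictions stay strictly inside (0, 1) and increase with emc", {
  for (f in names(all_specs)) {
    spec <- all_specs[[f]]
    for (t in std_temps) {
      erh <- predict_erh(spec, emc_grid_std, t)
      expect_true(all(erh > 0 & erh < 1), info = f)
      expect_true(all(diff(erh) > 0),
                  info = paste(f, "monotone in emc at", t))
    }
  }
})

test_that("closed-form inversion round-trips to 1e-10 relative", {
  grid <- expand.grid(emc = emc_grid_std, temp_c = std_temps)
  for (f in names(all_specs)) {
    spec <- all_specs[[f]]
    erh <- predict_erh(spec, grid$emc, grid$temp_c)
    back <- predict_emc(spec, erh, grid$temp_c)
    expect_equal(back, grid$emc, tolerance = 1e-10, info = f)
    fwd <- predict_erh(spec, predict_emc(spec, 0.174, 25), 25)
    expect_equal(fwd, 0.174, tolerance = 1e-10, info = f)
  }
  # frozen: inverting the first predict_erh example recovers M = 0.10
  expect_equal(predict_emc(cp_spec, 0.1737833, 25), 0.10, tolerance = 1e-5)
})

test_that("analytic d ln(ERH)/dT matches hand values and finite differences", {
  expect_equal(dlnerh_dtemp(cp_spec, 0.10, 25), 0.02738343, tolerance = 1e-6)
  expect_equal(dlnerh_dtemp(halsey_spec, 0.10, 25), 0.01984277,
               tolerance = 1e-6)
  grid <- expand.grid(emc = emc_grid_std, temp_c = std_temps)
  for (f in names(all_specs)) {
    spec <- all_specs[[f]]
    ana <- dlnerh_dtemp(spec, grid$emc, grid$temp_c)
    num <- num_dlnerh(spec, grid$emc, grid$temp_c)
    expect_equal(ana, num, tolerance = 1e-6, info = f)
  }
  # temperature-independent isotherm has zero derivative
  flat <- sorption_spec("halsey", 5.5667, 0, 2.0859)
  expect_equal(dlnerh_dtemp(flat, 0.10, 25), 0)
})

test_that("net isosteric heat is positive, decreasing in moisture, zero for flat isotherms", {
  q25 <- net_isosteric_heat(cp_spec, 0.25, 25)
  expect_equal(q25, 1942.62, tolerance = 1e-4)
  for (f in names(all_specs)) {
    spec <- all_specs[[f]]
    q <- outer(emc_grid_std, std_temps,
               function(m, t) net_isosteric_heat(spec, m, t))
    expect_true(all(q > 0), info = f)
  }
  # Chung-Pfost: strictly decreasing in emc at every temperature
  for (t in std_temps) {
    q <- net_isosteric_heat(cp_spec, emc_grid_std, t)
    expect_true(all(diff(q) < 0))
  }
  flat <- sorption_spec("halsey", 5.5667, 0, 2.0859)
  expect_equal(net_isosteric_heat(flat, emc_grid_std, 25),
               rep(0, length(emc_grid_std)))
})

test_that("parameter-domain violations raise errors, never NaN", {
  bad_cp <- sorption_spec("chung_pfost", 533, 15.6, -30)
  expect_error(predict_erh(bad_cp, 0.1, 25), "invalid")
  bad_oswin <- sorption_spec("oswin", 0.01, -0.01, 3)
  expect_error(predict_erh(bad_oswin, 0.1, 25), "invalid")
  expect_error(predict_erh(cp_spec, -0.1, 25), "emc")
  expect_error(predict_emc(cp_spec, 1.2, 25), "erh")
  expect_error(sorption_spec("gab", 1, 2, 3))
})
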