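test_that("typical-mother exposure chain reproduces the closed-form numbers", {
  p <- ref_params()
  conc_ave <- avg_plasma_conc(p, q24())
  expect_equal(conc_ave, 1000 * 300 / (19.4 * 24), tolerance = 1e-10)
  expect_equal(conc_ave, 644.33, tolerance = 1e-4)
  ## same daily dose, same clearance: identical average concentration
  expect_equal(avg_plasma_conc(p, q12()), conc_ave)
  ## quadrature route agrees with the closed form
  expect_equal(avg_plasma_conc(p, q24(), method = "quadrature"), conc_ave,
               tolerance = 1e-6)
  conc_milk <- avg_milk_conc(conc_ave, 1.77)
  expect_equal(conc_milk, 1140.4, tolerance = 1e-4)
  expect_equal(avg_milk_conc(conc_ave, 1), conc_ave)
  expect_equal(avg_milk_conc(conc_ave, 0), 0)
  dose_inf <- infant_daily_dose(conc_milk)
  expect_equal(dose_inf, 171.07, tolerance = 1e-4)
  expect_equal(infant_daily_dose(0), 0)
  ## algebraic collapse: 0.15 * rcb * dose / (CL * 24) * 1000
  expect_equal(dose_inf, 0.15 * 1.77 * 300 / (19.4 * 24) * 1000,
               tolerance = 1e-12)
})

test_that("relative infant dose arithmetic", {
  expect_equal(relative_infant_dose(1000 * 2, 300, 150), 100)  # equal mg/kg
  expect_equal(relative_infant_dose(171.07, 300, 64),
               100 * 0.17107 / (300 / 64), tolerance = 1e-6)
  expect_equal(relative_infant_dose(171.07, 300, 64), 3.65,
               tolerance = 0.002)
  expect_error(relative_infant_dose(171, 300, 0), "weight")
})

test_that("infant clearance allometry and maturation", {
  expect_equal(infant_clearance(7, 1e6), 12.7, tolerance = 1e-8)
  expect_equal(infant_clearance(7, 0.25), 6.35)   # half-maximal at TM50
  expect_equal(infant_clearance(3.6, 13 / 365.25), 0.416, tolerance = 1e-3)
  ## monotone increasing in both weight and age
  wt <- seq(2, 10, by = 0.5)
  expect_true(all(diff(infant_clearance(wt, 0.2)) > 0))
  age <- seq(0.02, 2, by = 0.05)
  expect_true(all(diff(infant_clearance(5, age)) > 0))
})

test_that("infant steady-state concentration scales as dose over clearance", {
  expect_equal(infant_css(0, 4.26), 0)
  expect_equal(infant_css(179.3 * 5.17, 4.26), 9.07, tolerance = 1e-3)
  expect_equal(infant_css(927, 2 * 4.26), infant_css(927, 4.26) / 2)
  expect_equal(infant_css(2 * 927, 4.26), 2 * infant_css(927, 4.26))
  expect_error(infant_css(100, 0), "positive")
})

test_that("per-pair exposure report covers every mother-visit with EBE-based values", {
  ## noise-free single-subject study: EBEs are ~0, so the report must
  ## reproduce the typical-value arithmetic
  model0 <- pop_model(lamivudine_params(), diag(1e-8, 3),
                      c(plasma = 1e-6, milk = 1e-6))
  tab <- simulate_study(small_design(n = 3L), model0, seed = 9)
  fit <- fit_nlme(tab, model0, se = FALSE, control = fast_control)
  rep <- infant_exposure(fit)
  expect_equal(nrow(rep), 6L)    # 3 mothers x 2 visits
  expect_equal(rep$conc_milk, rep$conc_ave * coef(fit)[["rcb"]] *
                 exp(fit$ebe[as.character(rep$ID), "rcb"]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rep$dose_infant, rep$conc_milk * 0.15, tolerance = 1e-10)
  expect_true(all(rep$rid_pct > 0))
  expect_equal(rep$css,
               rep$dose_infant * tab$IWT[match(paste(rep$ID, rep$VISIT),
                                               paste(tab$ID, tab$VISIT))] /
                 (rep$cl_infant * 24), tolerance = 1e-10)
})
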