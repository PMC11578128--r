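## One small fitted study shared across the diagnostics tests.
diag_tab <- small_study(seed = 55, n = 10L)
diag_fit <- suppressWarnings(fit_nlme(diag_tab, se = FALSE,
                                      control = fast_control))

test_that("with no random effects CWRES reduces to the weighted residual", {
  fit0 <- diag_fit
  fit0$omega <- diag(1e-14, 3)
  fit0$ebe[] <- 0
  r <- cwres(fit0)
  tab <- fit0$data
  used <- tab$MATRIX %in% c("plasma", "milk") & tab$MDV == 0 & tab$BLQ == 0
  f <- predict(fit0, type = "population")[used]
  sdf <- sqrt(fit0$sigma2)[ifelse(r$MATRIX == "plasma", "plasma", "milk")]
  expected <- (r$obs - f) / (sdf * f)
  expect_equal(r$cwres, expected, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("CWRES from a correctly specified fit look standard normal", {
  r <- cwres(diag_fit)
  expect_true(all(is.finite(r$cwres[!r$flagged])))
  expect_lt(abs(mean(r$cwres, na.rm = TRUE)), 0.25)
  expect_gt(sd(r$cwres, na.rm = TRUE), 0.7)
  expect_lt(sd(r$cwres, na.rm = TRUE), 1.3)
})

test_that("forcing a wrong equilibration rate leaves a CWRES-vs-time pattern in milk", {
  ## with kcb forced fast, milk is modelled in phase with plasma: the
  ## delayed true profile leaves a systematic (non-monotone) time pattern
  ## in the milk residuals, detected as a rank ANOVA across sampling times
  tab <- small_study(seed = 77, n = 12L)
  bad <- suppressWarnings(
    fit_nlme(tab, fixed = list(kcb = 10), se = FALSE,
             control = fast_control))
  r <- cwres(bad)
  milk <- r[r$MATRIX == "milk" & !r$flagged, ]
  p_bad <- kruskal.test(milk$cwres, factor(milk$TIME))$p.value
  expect_lt(p_bad, 1e-4)
  spread_bad <- diff(range(tapply(milk$cwres, milk$TIME, mean)))
  expect_gt(spread_bad, 1)
  good <- suppressWarnings(
    fit_nlme(tab, se = FALSE, control = fast_control))
  rg <- cwres(good)
  milk_g <- rg[rg$MATRIX == "milk" & !rg$flagged, ]
  spread_good <- diff(range(tapply(milk_g$cwres, milk_g$TIME, mean)))
  expect_lt(spread_good, spread_bad)
})

test_that("prediction correction is the identity when predictions are flat", {
  v <- pc_vpc(diag_fit, n_sim = 200, seed = 1)
  ## within each bin x matrix the correction factors multiply to bin-median
  ## over record prediction; records at a common design point get factor 1
  pred <- predict(diag_fit, type = "population")
  tab <- diag_fit$data
  keep <- which(tab$MATRIX %in% c("plasma", "milk") & tab$BLQ == 0)
  ## the [3, 6) h bin contains a single design time (4 h) shared by every
  ## subject, and population predictions ignore the random effects, so all
  ## predictions in the bin coincide and the correction is the identity
  one_bin <- keep[tab$MATRIX[keep] == "plasma" & tab$TIME[keep] == 4]
  pcf <- v$correction$factor[match(one_bin, v$correction$row)]
  expect_equal(pcf, rep(1, length(pcf)))
})

test_that("VPC output respects percentile ordering and band coverage structure", {
  v <- pc_vpc(diag_fit, n_sim = 200, seed = 2)
  tab <- v$table
  expect_true(all(c("plasma", "milk") %in% tab$matrix))
  for (mx in unique(tab$matrix)) {
    for (b in unique(tab$bin[tab$matrix == mx])) {
      q <- tab[tab$matrix == mx & tab$bin == b, ]
      q <- q[order(q$prob), ]
      expect_true(all(diff(q$observed) >= 0))
      expect_true(all(q$lower <= q$upper))
    }
  }
  expect_error(pc_vpc(diag_fit, n_sim = 50), "at least 200")
})

test_that("simulate() reproduces the observed design and responds to the seed", {
  sims <- simulate(diag_fit, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(diag_fit$data))
  expect_equal(sims[[1]]$TIME, diag_fit$data$TIME)
  expect_false(identical(sims[[1]]$DV, sims[[2]]$DV))
  again <- simulate(diag_fit, nsim = 2, seed = 9)
  expect_identical(sims[[1]]$DV, again[[1]]$DV)
})
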