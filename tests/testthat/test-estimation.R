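test_that("joint -2LL matches an independent scalar implementation", {
  set.seed(13)
  tab <- small_study(seed = 21, n = 3L)
  model <- ref_model()
  for (k in 1:6) {
    eta <- drop(draw_etas(1, model$omega))
    id <- sample(unique(tab$ID), 1)
    sub <- tab[tab$ID == id, ]
    expect_equal(
      individual_joint_neg2ll(sub, model$theta, model$omega, model$sigma2,
                              eta),
      naive_joint_neg2ll(sub, model$theta, model$omega, model$sigma2, eta),
      tolerance = 1e-10)
  }
})

test_that("joint -2LL reduces to the hand-computed Gaussian for one record", {
  tab <- data.frame(ID = 1, VISIT = 1, MATRIX = "plasma", TIME = 2,
                    DV = 700, BLQ = 0L, MDV = 0L, DOSE = 300, TAU = 24,
                    GROUP = "morning", WT = 64, AGE = 30, BMI = 24.8,
                    CRCL = 134.6, VDAY = 13, IWT = 3.6)
  model <- ref_model()
  f <- plasma_conc(model$theta, q24(), 2) / 1000
  sdf <- sqrt(model$sigma2[["plasma"]]) * f
  by_hand <- log(2 * pi) + 2 * log(sdf) + ((0.7 - f) / sdf)^2 +
    3 * log(2 * pi) + determinant(model$omega)$modulus[1]
  expect_equal(
    individual_joint_neg2ll(tab, model$theta, model$omega, model$sigma2,
                            c(0, 0, 0)),
    as.numeric(by_hand), tolerance = 1e-12)
})

test_that("with huge residual variance the observations stop informing the mode", {
  ## under proportional error the eta-dependent log-variance term survives
  ## the sigma -> infinity limit, but the residual quadratic vanishes: the
  ## conditional mode becomes independent of the observed concentrations
  model <- ref_model()
  big_sig <- c(plasma = 1e10, milk = 1e10)
  mode_for <- function(tab) optimize(function(e1)
    individual_joint_neg2ll(tab, model$theta, model$omega, big_sig,
                            c(e1, 0, 0)), c(-1, 1))$minimum
  tab1 <- small_study(seed = 4, n = 1L)
  tab2 <- tab1
  tab2$DV[tab2$MATRIX != "infant"] <- tab2$DV[tab2$MATRIX != "infant"] * 5
  expect_equal(mode_for(tab1), mode_for(tab2), tolerance = 1e-6)
  ## and the residual quadratic itself is negligible at the mode
  p <- individual_params(model$theta, c(mode_for(tab1), 0, 0))
  m <- tab1[tab1$MATRIX == "plasma", ]
  f <- plasma_conc(p, q24(), m$TIME)
  expect_lt(sum(((m$DV - f) / (sqrt(big_sig[["plasma"]]) * f))^2), 1e-4)
})

test_that("zero IIV collapses the marginal onto the fixed-effect likelihood", {
  tab <- small_study(seed = 5, n = 4L)
  model <- ref_model()
  ofv0 <- marginal_neg2ll(tab, model$theta, diag(0, 3), model$sigma2)
  by_hand <- sum(vapply(unique(tab$ID), function(id) {
    sub <- tab[tab$ID == id, ]
    naive_joint_neg2ll(sub, model$theta, diag(1, 3), model$sigma2,
                       c(0, 0, 0)) - 3 * log(2 * pi)
  }, numeric(1)))
  expect_equal(ofv0, as.numeric(by_hand), tolerance = 1e-10)
})

test_that("Laplace agrees with adaptive Gauss-Hermite quadrature on 1-eta problems", {
  ## one subject, IIV on CL only; the quadrature oracle is built from the
  ## scalar likelihood with 32-node Gauss-Hermite centred at the mode
  model <- ref_model()
  for (s in c(2, 7)) {
    tab <- small_study(seed = s, n = 1L)
    for (w in c(0.15, 0.4)) {
      omega1 <- diag(c(w^2, 1e-12, 1e-12))
      neg2ll_1d <- function(e1)
        vapply(e1, function(e) {
          p <- individual_params(model$theta, c(e, 0, 0))
          m <- tab[tab$MATRIX %in% c("plasma", "milk") & tab$BLQ == 0, ]
          f <- ifelse(m$MATRIX == "plasma",
                      plasma_conc(p, q24(), m$TIME),
                      milk_conc(p, q24(), m$TIME)) / 1000
          sdf <- pmax(sqrt(model$sigma2[ifelse(m$MATRIX == "plasma",
                                               "plasma", "milk")]) * f,
                      1e-6)
          sum(log(2 * pi) + 2 * log(sdf) + ((m$DV / 1000 - f) / sdf)^2) +
            log(2 * pi) + log(w^2) + e^2 / w^2
        }, numeric(1))
      mode <- optimize(neg2ll_1d, c(-2, 2))$minimum
      h <- 1e-4
      curv <- (neg2ll_1d(mode + h) + neg2ll_1d(mode - h) -
                 2 * neg2ll_1d(mode)) / h^2   # d2(-2LL)/de2
      s_ad <- sqrt(2 / curv)
      gh <- pracma::gaussHermite(32)
      vals <- neg2ll_1d(mode + sqrt(2) * s_ad * gh$x)
      integral <- sum(gh$w * exp(-vals / 2 + gh$x^2)) * sqrt(2) * s_ad /
        sqrt(pi) * sqrt(pi)   # sum w_i f(x_i) e^{x_i^2} * sqrt(2) s
      ofv_quad <- -2 * log(sum(gh$w * exp(-vals / 2 + gh$x^2)) *
                             sqrt(2) * s_ad)
      ofv_laplace <- marginal_neg2ll(tab, model$theta, omega1,
                                     model$sigma2)
      expect_equal(ofv_laplace, ofv_quad, tolerance = 0.1 / abs(ofv_quad))
    }
  }
})

test_that("the marginal likelihood is curved around the generating clearance", {
  tab <- simulate_study(seed = 12)
  model <- ref_model()
  perturb <- function(fac) {
    th <- unclass(model$theta)
    structural_params(th[["ka"]], th[["cl"]] * fac, th[["vc"]],
                      th[["kcb"]], th[["rcb"]])
  }
  ofv_true <- marginal_neg2ll(tab, model$theta, model$omega, model$sigma2)
  expect_lt(ofv_true, marginal_neg2ll(tab, perturb(1.5), model$omega,
                                      model$sigma2))
  expect_lt(ofv_true, marginal_neg2ll(tab, perturb(0.5), model$omega,
                                      model$sigma2))
})

test_that("likelihood-ratio test calibration and nesting guard", {
  r <- lrt(103.84, 100, df = 1)
  expect_equal(r$p_value, pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$p_value, 0.05, tolerance = 0.002)
  expect_true(r$significant)
  expect_equal(lrt(100, 100)$p_value, 1)
  expect_equal(lrt(106.63, 100)$p_value, 0.01, tolerance = 0.005)
  expect_warning(r2 <- lrt(100, 103), "nesting")
  expect_equal(r2$p_value, 1)
})

test_that("bootstrap over identical cloned subjects returns the point estimates", {
  one <- small_study(seed = 30, n = 1L)
  clones <- do.call(rbind, lapply(1:4, function(i) {
    d <- one; d$ID <- i; d
  }))
  ctrl <- list(rel.tol = 1e-5, iter.max = 40L)
  fit <- suppressWarnings(fit_nlme(clones, se = FALSE, control = ctrl))
  b <- suppressWarnings(bootstrap_ci(clones, n_resamples = 3L, seed = 1,
                                     control = ctrl))
  expect_equal(b$n_failed, 0L)
  med <- b$table$median
  names(med) <- b$table$parameter
  expect_equal(med[c("cl", "vc", "rcb")],
               coef(fit)[c("cl", "vc", "rcb")], tolerance = 1e-6)
})

test_that("covariate effects enter the model as specified multipliers", {
  tab <- small_study(seed = 40, n = 4L)
  ce <- covariate_effect("cl", "CRCL", "power")
  ## a power effect with coefficient 0 leaves the likelihood unchanged
  f0 <- suppressWarnings(fit_nlme(tab, se = FALSE,
                                  control = list(iter.max = 1L)))
  f1 <- suppressWarnings(fit_nlme(tab, covariates = list(ce), se = FALSE,
                                  control = list(iter.max = 1L)))
  expect_lte(f1$ofv, f0$ofv + 1e-6)
  expect_error(fit_nlme(tab, covariates = list(
    covariate_effect("cl", "NOPE")), se = FALSE), "NOPE")
  x <- c(80, 120, 160)
  expect_equal(lactpk:::.cov_multiplier("power", 0.75, x, 120),
               (x / 120)^0.75)
  expect_equal(lactpk:::.cov_multiplier("linear", 0.01, x, 120),
               1 + 0.01 * (x - 120))
  expect_equal(lactpk:::.cov_multiplier("exponential", 0.01, x, 120),
               exp(0.01 * (x - 120)))
})
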