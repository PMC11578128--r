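test_that("no dose gives zero concentration everywhere", {
  reg0 <- dose_regimen(0, 24)
  t <- c(0, 1, 7.3, 23)
  expect_equal(plasma_conc(ref_params(), reg0, t), rep(0, 4))
  expect_equal(milk_conc(ref_params(), reg0, t), rep(0, 4))
})

test_that("invalid structural parameters are rejected", {
  expect_error(structural_params(-1, 19.4, 184, 0.245, 1.77), "positive")
  expect_error(structural_params(1.87, 19.4, 184, 0.245, Inf), "finite")
  expect_error(dose_regimen(300, 0), "tau")
})

test_that("steady-state mean plasma concentration equals Dose/(CL tau)", {
  ## identity AUC(0-tau, ss) = Dose/CL, independent of Ka and Vc
  for (reg in list(q24(), q12())) {
    for (p in list(ref_params(),
                   structural_params(0.6, 19.4, 90, 0.245, 1.77))) {
      auc <- integrate(function(t) plasma_conc(p, reg, t), 0, reg$tau,
                       rel.tol = 1e-10)$value
      expect_equal(auc / reg$tau, 1000 * reg$dose / (p[["cl"]] * reg$tau),
                   tolerance = 1e-8)
    }
  }
})

test_that("single-dose plasma tmax matches the analytic formula", {
  p <- ref_params()
  reg <- dose_regimen(300, 24, ss = FALSE, n_doses = 1)
  ke <- p[["cl"]] / p[["vc"]]
  tmax_analytic <- log(p[["ka"]] / ke) / (p[["ka"]] - ke)
  grid <- seq(0, 12, by = 1e-3)
  tmax_grid <- grid[which.max(plasma_conc(p, reg, grid))]
  expect_equal(tmax_grid, tmax_analytic, tolerance = 1e-3)
  expect_equal(tmax_analytic, 1.6296, tolerance = 1e-4)
})

test_that("steady-state milk:plasma AUC ratio equals rcb for any kcb", {
  for (kcb in c(0.02, 0.245, 3, 50)) {
    p <- structural_params(1.87, 19.4, 184, kcb, 1.77)
    for (reg in list(q24(), q12())) {
      aucp <- integrate(function(t) plasma_conc(p, reg, t), 0, reg$tau,
                        rel.tol = 1e-10)$value
      aucm <- integrate(function(t) milk_conc(p, reg, t), 0, reg$tau,
                        rel.tol = 1e-10)$value
      expect_equal(aucm / aucp, 1.77, tolerance = 1e-6)
    }
  }
})

test_that("instant equilibration collapses milk onto rcb * plasma", {
  p <- structural_params(1.87, 19.4, 184, 1e6, 1.77)
  t <- seq(0.5, 23.5, by = 0.5)
  expect_equal(milk_conc(p, q24(), t), 1.77 * plasma_conc(p, q24(), t),
               tolerance = 1e-3)
})

test_that("closed forms agree with the ODE oracle on random draws", {
  set.seed(42)
  ref <- unclass(ref_params())
  t <- seq(0.25, 23.75, by = 0.75)
  for (k in 1:8) {
    f <- 10^runif(5, -1, 1)
    p <- structural_params(ref[["ka"]] * f[1], ref[["cl"]] * f[2],
                           ref[["vc"]] * f[3], ref[["kcb"]] * f[4],
                           ref[["rcb"]] * f[5])
    reg <- dose_regimen(300, 24, ss = FALSE, n_doses = 1)
    ode <- integrate_odes(p, reg, t)
    expect_equal(plasma_conc(p, reg, t), ode$plasma, tolerance = 1e-6)
    expect_equal(milk_conc(p, reg, t), ode$milk, tolerance = 1e-6)
  }
})

test_that("rate coincidences (ka=ke, kcb=ke, kcb=ka) stay finite and accurate", {
  t <- seq(0.5, 23, by = 0.5)
  reg <- dose_regimen(300, 24, ss = FALSE, n_doses = 1)
  ke <- 19.4 / 184
  cases <- list(structural_params(ke, 19.4, 184, 0.245, 1.77),
                structural_params(1.87, 19.4, 184, ke, 1.77),
                structural_params(1.87, 19.4, 184, 1.87, 1.77),
                structural_params(ke, 19.4, 184, ke, 1.77))
  for (p in cases) {
    ode <- integrate_odes(p, reg, t)
    expect_true(all(is.finite(plasma_conc(p, reg, t))))
    expect_equal(plasma_conc(p, reg, t), ode$plasma, tolerance = 1e-4)
    expect_equal(milk_conc(p, reg, t), ode$milk, tolerance = 1e-4)
  }
})

test_that("ODE system respects initial conditions and mass balance", {
  p <- ref_params()
  reg <- dose_regimen(300, 24, ss = FALSE, n_doses = 1)
  sol0 <- integrate_odes(p, reg, 0)
  expect_equal(sol0$plasma, 0)
  expect_equal(sol0$milk, 0)
  ## with elimination off, depot + central mass is conserved
  rhs <- function(t, y, parms)
    list(c(-p[["ka"]] * y[1], p[["ka"]] * y[1]))
  sol <- deSolve::lsoda(c(300, 0), times = seq(0, 48, 4), func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(rowSums(sol[, 2:3]), rep(300, nrow(sol)), tolerance = 1e-7)
})

test_that("long dose train converges to the steady-state closed form", {
  p <- ref_params()
  t_last <- 19 * 24 + seq(0.5, 23.5, 0.5)
  ode <- integrate_odes(p, dose_regimen(300, 24, ss = FALSE, n_doses = 20),
                        t_last)
  cp <- plasma_conc(p, q24(), seq(0.5, 23.5, 0.5))
  cm <- milk_conc(p, q24(), seq(0.5, 23.5, 0.5))
  expect_lt(max(abs(cp - ode$plasma) / ode$plasma), 1e-3)
  expect_lt(max(abs(cm - ode$milk) / ode$milk), 1e-3)
})

test_that("milk peaks later than plasma for finite kcb", {
  grid <- seq(0, 24, by = 0.01)
  for (kcb in c(0.05, 0.245, 1, 5)) {
    p <- structural_params(1.87, 19.4, 184, kcb, 1.77)
    reg <- dose_regimen(300, 24, ss = FALSE, n_doses = 1)
    tmax_p <- grid[which.max(plasma_conc(p, reg, grid))]
    tmax_m <- grid[which.max(milk_conc(p, reg, grid))]
    expect_gt(tmax_m, tmax_p)
  }
})

test_that("milk concentration is strictly increasing in rcb", {
  t <- c(0.5, 2, 6, 12, 20)
  rcbs <- c(0.5, 1, 1.77, 2.5)
  profiles <- sapply(rcbs, function(r) {
    p <- structural_params(1.87, 19.4, 184, 0.245, r)
    milk_conc(p, q24(), t)
  })
  for (i in seq_along(t))
    expect_true(all(diff(profiles[i, ]) > 0))
})

test_that("individual parameters follow the exponential IIV model", {
  th <- ref_params()
  expect_equal(unclass(individual_params(th, c(0, 0, 0))), unclass(th))
  p2 <- individual_params(th, c(log(2), 0, 0))
  expect_equal(p2[["cl"]], 38.8)
  expect_equal(p2[["ka"]], th[["ka"]])   # no IIV on absorption
  set.seed(7)
  etas <- draw_etas(1e5, iiv_matrix(20.9, 76.4, 15.9, 0.42))
  cl_draws <- 19.4 * exp(etas[, 1])
  ## CV% convention is 100*sqrt(omega^2): first-order accurate for the
  ## lognormal sample CV
  expect_equal(sd(cl_draws) / mean(cl_draws), 0.209, tolerance = 0.015)
})

test_that("proportional residual error has the right scale and truncation", {
  expect_equal(apply_residual_error(c(10, 20), "plasma",
                                    c(plasma = 0, milk = 0)),
               c(10, 20), ignore_attr = TRUE)
  expect_equal(as.numeric(apply_residual_error(0, "milk",
                                               c(plasma = 0.1, milk = 0.1))),
               0)
  expect_error(apply_residual_error(1, "serum", c(plasma = 1, milk = 1)),
               "matrix")
  set.seed(11)
  sig <- c(plasma = (38.3 / 100)^2, milk = 1)
  obs <- apply_residual_error(rep(100, 1e5), "plasma", sig)
  expect_equal(sd(obs) / mean(obs), 0.383, tolerance = 0.01)
  big <- apply_residual_error(rep(1, 1e4), "milk", sig)
  expect_true(any(attr(big, "truncated")))
  expect_true(all(big >= 0))
})
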