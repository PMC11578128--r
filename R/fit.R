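## Nonlinear mixed-effects estimation for the lactation model.
##
## The marginal likelihood is approximated by Laplace's method at each
## subject's conditional mode (FOCE-style linearisation available as an
## option).  All record-level quantities are computed vectorised across the
## whole dataset; the inner eta-optimisation is a damped Newton iteration
## run for all subjects simultaneously with finite-difference derivatives.
## Internal unit system: mg, L, h, mg/L (ng/mL only at the I/O boundary).

#' Parameter-covariate effect term
#'
#' Describes one candidate covariate relationship for the stepwise
#' covariate search or for direct inclusion in a fit.  The covariate is
#' centered on its dataset median (computed across subjects at fit time).
#'
#' @param param structural parameter carrying the effect: `"cl"`, `"vc"`
#'   or `"rcb"` (the parameters with inter-individual variability).
#' @param covariate column name in the observation table (`"WT"`, `"AGE"`,
#'   `"BMI"`, `"CRCL"`, `"VDAY"`).
#' @param form functional form: `"linear"` (`1 + b*(x - c)`), `"power"`
#'   (`(x/c)^b`) or `"exponential"` (`exp(b*(x - c))`).
#' @return An object of class `"covariate_effect"`.
#' @export
covariate_effect <- function(param = c("cl", "vc", "rcb"), covariate,
                             form = c("power", "linear", "exponential")) {
  param <- match.arg(param)
  form <- match.arg(form)
  stopifnot(is.character(covariate), length(covariate) == 1L)
  structure(list(param = param, covariate = covariate, form = form,
                 center = NA_real_, coef = NA_real_),
            class = "covariate_effect")
}

.cov_multiplier <- function(form, coef, x, center) {
  switch(form,
         linear = pmax(1 + coef * (x - center), 1e-6),
         power = (x / center)^coef,
         exponential = exp(coef * (x - center)))
}

## ---- data preparation -----------------------------------------------------

## Flatten an observation table into record-level vectors for the maternal
## likelihood.  BLQ handling: "M1" drops flagged records; "M3" keeps them
## as censored with an upper bound at the matrix LLOQ.
.prep_nlme <- function(table, blq = c("M1", "M3"),
                       lloq = c(plasma = 5, milk = 16.6)) {
  blq <- match.arg(blq)
  m <- table[table$MATRIX %in% c("plasma", "milk") & table$MDV == 0, ,
             drop = FALSE]
  if (blq == "M1") m <- m[m$BLQ == 0, , drop = FALSE]
  if (nrow(m) == 0L) stop("no usable observations", call. = FALSE)
  ids <- sort(unique(m$ID))
  if (any(!ids %in% m$ID[m$BLQ == 0]))
    stop("every subject needs at least one non-BLQ observation",
         call. = FALSE)
  sid <- match(m$ID, ids)
  mat <- ifelse(m$MATRIX == "plasma", 1L, 2L)
  covcols <- intersect(c("WT", "AGE", "BMI", "CRCL", "VDAY"), names(m))
  covmed <- lapply(covcols, function(cc) {
    per_sub <- tapply(m[[cc]], m$ID, function(x) x[1])
    stats::median(per_sub)
  })
  names(covmed) <- covcols
  list(n = length(ids), ids = ids, sid = sid,
       time = m$TIME, ts = m$TIME %% m$TAU, tau = m$TAU, dose = m$DOSE,
       y = m$DV / 1000, mat = mat, blq = m$BLQ,
       upper = unname(lloq[c("plasma", "milk")][mat]) / 1000,
       covs = m[covcols], cov_medians = covmed,
       nobs = as.vector(table(sid)), blq_mode = blq)
}

## ---- vectorised structural predictions ------------------------------------

## Steady-state closed-form concentrations (mg/L) for every record given
## record-level parameter vectors; rate coincidences nudged apart as in the
## scalar closed form.
.pred_rec <- function(prep, ka, cl, vc, kcb, rcb) {
  eps <- 1e-8
  ke <- cl / vc
  bad <- which(abs(ka - ke) < eps * pmax(ka, ke))   # NA-safe: which() drops NA
  if (length(bad)) ka[bad] <- ke[bad] * (1 + eps)
  b <- prep$dose * ka / (vc * (ka - ke))
  ts <- prep$ts; tau <- prep$tau
  e_ke <- exp(-ke * ts) / (1 - exp(-ke * tau))
  e_ka <- exp(-ka * ts) / (1 - exp(-ka * tau))
  f <- b * (e_ke - e_ka)
  im <- prep$mat == 2L
  if (any(im)) {
    kcbm <- kcb[im]; kem <- ke[im]; kam <- ka[im]
    bad <- which(abs(kcbm - kem) < eps * pmax(kcbm, kem))
    if (length(bad)) kcbm[bad] <- kem[bad] * (1 + eps)
    bad <- which(abs(kcbm - kam) < eps * pmax(kcbm, kam))
    if (length(bad)) kcbm[bad] <- kam[bad] * (1 + 2 * eps)
    e_kcb <- exp(-kcbm * ts[im]) / (1 - exp(-kcbm * tau[im]))
    fco <- kcbm * rcb[im] * b[im]
    f[im] <- fco * (e_ke[im] / (kcbm - kem) - e_ka[im] / (kcbm - kam) +
                      e_kcb * (1 / (kcbm - kam) - 1 / (kcbm - kem)))
  }
  pmax(f, 0)
}

## Record-level base parameters (typical value x covariate multipliers),
## before random effects.
.base_params <- function(prep, theta, cov_effects) {
  n <- length(prep$y)
  base <- list(ka = rep(theta[["ka"]], n), cl = rep(theta[["cl"]], n),
               vc = rep(theta[["vc"]], n), kcb = rep(theta[["kcb"]], n),
               rcb = rep(theta[["rcb"]], n))
  for (ce in cov_effects) {
    x <- prep$covs[[ce$covariate]]
    base[[ce$param]] <- base[[ce$param]] *
      .cov_multiplier(ce$form, ce$coef, x, ce$center)
  }
  base
}

## Per-subject joint -2*log-likelihood (data + prior) at random-effect
## matrix E (n x 3, columns CL/Vc/Rcb).  Proportional error with
## interaction; residual SD floored at 1e-6 mg/L.  Returns the per-subject
## vector.
.g_subjects <- function(prep, base, sig_sd, oinv, ldet_o, E) {
  f <- .pred_rec(prep,
                 base$ka,
                 base$cl * exp(E[prep$sid, 1L]),
                 base$vc * exp(E[prep$sid, 2L]),
                 base$kcb,
                 base$rcb * exp(E[prep$sid, 3L]))
  sdf <- pmax(sig_sd[prep$mat] * f, 1e-6)
  term <- log(2 * pi) + 2 * log(sdf) + ((prep$y - f) / sdf)^2
  term[!is.finite(term)] <- 1e10       # degenerate point: reject, not crash
  if (prep$blq_mode == "M3" && any(prep$blq == 1L)) {
    i <- prep$blq == 1L
    term[i] <- -2 * stats::pnorm((prep$upper[i] - f[i]) / sdf[i],
                                 log.p = TRUE)
  }
  data_term <- as.vector(rowsum(term, prep$sid))
  quad <- rowSums((E %*% oinv) * E)
  data_term + 3 * log(2 * pi) + ldet_o + quad
}

## Damped Newton iteration over the per-subject modes, all subjects at
## once; gradients and Hessians by central finite differences of the joint
## -2LL (perturbing one eta column for every subject simultaneously).
.inner_modes <- function(prep, base, sig_sd, omega, E0,
                         tol = 2e-6, max_iter = 50L) {
  omega <- omega + diag(1e-10, 3)   # keep the prior proper if IIV collapses
  oinv <- solve(omega)
  ldet_o <- determinant(omega, logarithm = TRUE)$modulus[1]
  g_fun <- function(E) .g_subjects(prep, base, sig_sd, oinv, ldet_o, E)
  n <- prep$n
  h <- 1e-4
  E <- E0
  g <- g_fun(E)

  fd_grad <- function(E, g) {
    gp <- gm <- vector("list", 3L)
    for (j in 1:3) {
      Ej <- E; Ej[, j] <- E[, j] + h; gp[[j]] <- g_fun(Ej)
      Ej[, j] <- E[, j] - h; gm[[j]] <- g_fun(Ej)
    }
    list(grad = cbind((gp[[1]] - gm[[1]]) / (2 * h),
                      (gp[[2]] - gm[[2]]) / (2 * h),
                      (gp[[3]] - gm[[3]]) / (2 * h)),
         diag2 = cbind((gp[[1]] + gm[[1]] - 2 * g) / h^2,
                       (gp[[2]] + gm[[2]] - 2 * g) / h^2,
                       (gp[[3]] + gm[[3]] - 2 * g) / h^2))
  }
  fd_hess <- function(E, d) {
    H <- array(0, c(3, 3, n))
    for (j in 1:3) H[j, j, ] <- d$diag2[, j]
    for (jk in list(c(1, 2), c(1, 3), c(2, 3))) {
      j <- jk[1]; k <- jk[2]
      Ej <- E; Ej[, j] <- Ej[, j] + h; Ej[, k] <- Ej[, k] + h
      gpp <- g_fun(Ej)
      Ej[, k] <- Ej[, k] - 2 * h
      gpm <- g_fun(Ej)
      Ej[, j] <- Ej[, j] - 2 * h
      gmm <- g_fun(Ej)
      Ej[, k] <- Ej[, k] + 2 * h
      gmp <- g_fun(Ej)
      H[j, k, ] <- H[k, j, ] <- (gpp - gpm - gmp + gmm) / (4 * h^2)
    }
    H
  }

  H <- NULL
  grad_norm <- Inf
  for (iter in seq_len(max_iter)) {
    d <- fd_grad(E, g)
    gn <- sqrt(rowSums(d$grad^2))
    grad_norm <- max(gn)
    active <- gn > tol
    if (!any(active)) break
    ## the Hessian is reused across iterations (chord Newton); refreshed
    ## periodically and recomputed exactly at the final mode below
    if (is.null(H) || iter %% 4L == 1L) H <- fd_hess(E, d)
    step <- matrix(0, n, 3L)
    for (i in which(active)) {
      Hi <- H[, , i]
      if (any(!is.finite(Hi)) || any(!is.finite(d$grad[i, ]))) next
      ridge <- 0
      repeat {
        ch <- tryCatch(chol(Hi + diag(ridge, 3)), error = function(e) NULL)
        if (!is.null(ch)) break
        ridge <- max(ridge * 10, 1e-4)
      }
      step[i, ] <- backsolve(ch, forwardsolve(t(ch), d$grad[i, ]))
    }
    lam <- rep(1, n)
    gnew <- g
    for (half in 1:12) {
      ## clamp: |eta| beyond 15 is numerically degenerate (exp under/
      ## overflow) and far outside any plausible random effect
      Enew <- pmin(pmax(E - lam * step, -15), 15)
      gnew <- g_fun(Enew)
      worse <- (active & (gnew > g + 1e-12)) | !is.finite(gnew)
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
    }
    keep <- active & is.finite(gnew) & gnew <= g
    if (!any(keep)) break
    E[keep, ] <- Enew[keep, ]
    g <- g_fun(E)
  }
  d <- fd_grad(E, g)
  H <- fd_hess(E, d)
  list(E = E, g = g, H = H, grad_norm = max(sqrt(rowSums(d$grad^2))))
}

## Laplace objective: sum_i [ g_i(mode) - 3*log(2*pi) + log det(H_i/2) ].
## Includes the full Gaussian constants, so only OFV differences are
## comparable across models (standard convention).
.ofv_laplace <- function(modes) {
  ld <- vapply(seq_len(dim(modes$H)[3]), function(i) {
    Hi <- modes$H[, , i] / 2
    d <- det(Hi)
    if (is.finite(d) && d > 0) return(log(d))
    ## non-PD curvature at the reported mode (flat or unconverged inner
    ## direction): floor the eigenvalues so the objective stays finite and
    ## the outer optimiser can move away
    if (any(!is.finite(Hi))) return(NA_real_)
    ev <- eigen(Hi, symmetric = TRUE, only.values = TRUE)$values
    sum(log(pmax(ev, 1e-6)))
  }, numeric(1))
  if (anyNA(ld)) return(NA_real_)
  sum(modes$g - 3 * log(2 * pi) + ld)
}

## FOCE-style linearised marginal: y ~ N(f(mode) + G (eta - mode),
## R(mode)), marginalised over eta ~ N(0, Omega).  G by forward
## differences.  Also the work-horse for CWRES.
.foce_parts <- function(prep, base, sig_sd, omega, E) {
  h <- 1e-5
  f0 <- .pred_rec(prep, base$ka, base$cl * exp(E[prep$sid, 1L]),
                  base$vc * exp(E[prep$sid, 2L]), base$kcb,
                  base$rcb * exp(E[prep$sid, 3L]))
  G <- matrix(0, length(f0), 3L)
  for (j in 1:3) {
    Ej <- E; Ej[, j] <- E[, j] + h
    fj <- .pred_rec(prep, base$ka, base$cl * exp(Ej[prep$sid, 1L]),
                    base$vc * exp(Ej[prep$sid, 2L]), base$kcb,
                    base$rcb * exp(Ej[prep$sid, 3L]))
    G[, j] <- (fj - f0) / h
  }
  sdf <- pmax(sig_sd[prep$mat] * f0, 1e-6)
  list(f = f0, G = G, sdf = sdf)
}

.ofv_foce <- function(prep, base, sig_sd, omega, E) {
  parts <- .foce_parts(prep, base, sig_sd, omega, E)
  total <- 0
  for (i in seq_len(prep$n)) {
    idx <- which(prep$sid == i)
    Gi <- parts$G[idx, , drop = FALSE]
    Vi <- Gi %*% omega %*% t(Gi) + diag(parts$sdf[idx]^2,
                                        length(idx))
    mi <- parts$f[idx] - as.vector(Gi %*% E[i, ])
    r <- prep$y[idx] - mi
    ch <- tryCatch(chol(Vi), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    z <- forwardsolve(t(ch), r)
    total <- total + length(idx) * log(2 * pi) +
      2 * sum(log(diag(ch))) + sum(z^2)
  }
  total
}

## ---- parameter transforms -------------------------------------------------

## Unconstrained parameterisation: log fixed effects; log-Cholesky of the
## CL-Vc IIV block; log SD for the Rcb IIV and the two proportional error
## components; covariate coefficients untransformed.
.make_parmap <- function(init, cov_effects, fixed) {
  theta_names <- c("ka", "cl", "vc", "kcb", "rcb")
  fixed_omega <- fixed$omega
  fixed_sigma <- fixed$sigma
  fixed <- fixed[setdiff(names(fixed), c("omega", "sigma"))]
  bad <- setdiff(names(fixed), theta_names)
  if (length(bad))
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  est_theta <- setdiff(theta_names, names(fixed))
  labels <- paste0("log_", est_theta)
  if (is.null(fixed_omega))
    labels <- c(labels, "lchol_11", "lchol_21", "lchol_22", "log_sd_rcb")
  if (is.null(fixed_sigma))
    labels <- c(labels, "log_sig_plasma", "log_sig_milk")
  if (length(cov_effects))
    labels <- c(labels, vapply(cov_effects, function(ce)
      paste0("beta_", ce$param, "_", tolower(ce$covariate)), character(1)))
  list(theta_names = theta_names, est_theta = est_theta, fixed = fixed,
       fixed_omega = fixed_omega, fixed_sigma = fixed_sigma,
       n_cov = length(cov_effects), labels = labels)
}

.model2par <- function(model, parmap, cov_coefs = NULL) {
  th <- unclass(model$theta)
  par <- log(th[parmap$est_theta])
  if (is.null(parmap$fixed_omega)) {
    om2 <- model$omega[1:2, 1:2]
    L <- t(chol(om2 + diag(1e-10, 2)))
    par <- c(par, log(L[1, 1]), L[2, 1], log(L[2, 2]),
             0.5 * log(max(model$omega[3, 3], 1e-10)))
  }
  if (is.null(parmap$fixed_sigma))
    par <- c(par, 0.5 * log(pmax(model$sigma2, 1e-10)))
  if (parmap$n_cov)
    par <- c(par, if (is.null(cov_coefs)) rep(0, parmap$n_cov)
             else cov_coefs)
  names(par) <- parmap$labels
  par
}

.par2model <- function(par, parmap) {
  k <- length(parmap$est_theta)
  th <- numeric(5); names(th) <- parmap$theta_names
  th[parmap$est_theta] <- exp(par[seq_len(k)])
  for (nm in names(parmap$fixed)) th[nm] <- parmap$fixed[[nm]]
  pos <- k
  if (is.null(parmap$fixed_omega)) {
    L <- matrix(c(exp(par[pos + 1]), par[pos + 2], 0,
                  exp(par[pos + 3])), 2, 2)
    omega <- matrix(0, 3, 3)
    omega[1:2, 1:2] <- L %*% t(L)
    omega[3, 3] <- exp(2 * par[pos + 4])
    pos <- pos + 4
  } else omega <- parmap$fixed_omega
  if (is.null(parmap$fixed_sigma)) {
    sig_sd <- exp(par[pos + 1:2])
    pos <- pos + 2
  } else sig_sd <- sqrt(parmap$fixed_sigma[c("plasma", "milk")])
  cov_coefs <- if (parmap$n_cov)
    par[pos + seq_len(parmap$n_cov)] else numeric(0)
  list(theta = th, omega = omega, sig_sd = sig_sd, cov_coefs = cov_coefs)
}

## ---- exported likelihood primitives ---------------------------------------

#' Per-subject joint -2 log-likelihood
#'
#' The conditional data likelihood (proportional Gaussian error with
#' interaction: residual SD scales with the eta-dependent prediction,
#' floored at 1e-6 mg/L) plus the random-effect prior, on the closed-form
#' steady-state predictions.  This is the integrand whose mode and
#' curvature define the Laplace marginal likelihood.
#'
#' @param table observation table rows for a single subject.
#' @param theta a [structural_params()] object.
#' @param omega 3x3 IIV covariance (CL, Vc, Rcb).
#' @param sigma2 named proportional error variances `c(plasma =, milk =)`.
#' @param eta numeric vector of length 3.
#' @param blq BLQ mode, `"M1"` (exclude) or `"M3"` (censored normal).
#' @return The joint -2 log-likelihood (full constants included).
#' @export
individual_joint_neg2ll <- function(table, theta, omega, sigma2, eta,
                                    blq = "M1") {
  stopifnot(length(unique(table$ID)) == 1L)
  prep <- .prep_nlme(table, blq = blq)
  base <- .base_params(prep, unclass(theta), list())
  oinv <- solve(omega)
  ldet <- determinant(omega, logarithm = TRUE)$modulus[1]
  .g_subjects(prep, base, sqrt(sigma2[c("plasma", "milk")]), oinv, ldet,
              matrix(eta, 1L, 3L))[1]
}

#' Approximate marginal -2 log-likelihood (OFV)
#'
#' Sums the per-subject Laplace approximations at the conditional modes
#' (or the FOCE-style linearised marginal).  Includes the full Gaussian
#' normalising constants, so absolute values follow that convention and
#' only differences between nested models are meaningful.  When `omega` is
#' numerically zero the random effects are degenerate at zero and the
#' fixed-effect -2LL is returned exactly.
#'
#' @param table an observation table (maternal records are used).
#' @param theta a [structural_params()] object.
#' @param omega 3x3 IIV covariance.
#' @param sigma2 named proportional error variances.
#' @param method `"laplace"` or `"foce"`.
#' @param blq `"M1"` or `"M3"`.
#' @return The OFV (scalar).
#' @export
marginal_neg2ll <- function(table, theta, omega, sigma2,
                            method = c("laplace", "foce"), blq = "M1") {
  method <- match.arg(method)
  prep <- .prep_nlme(table, blq = blq)
  base <- .base_params(prep, unclass(theta), list())
  sig_sd <- sqrt(sigma2[c("plasma", "milk")])
  if (max(diag(omega)) < 1e-12) {
    oinv <- diag(3); E0 <- matrix(0, prep$n, 3L)
    g <- .g_subjects(prep, base, sig_sd, oinv, 0, E0)
    quad_const <- 3 * log(2 * pi)     # strip the degenerate prior term
    return(sum(g - quad_const))
  }
  modes <- .inner_modes(prep, base, sig_sd, omega,
                        matrix(0, prep$n, 3L))
  if (method == "laplace") .ofv_laplace(modes)
  else .ofv_foce(prep, base, sig_sd, omega, modes$E)
}

## ---- the fitting function -------------------------------------------------

#' Fit the lactation population model by Laplace NLME
#'
#' Maximises the approximate marginal likelihood of the plasma-milk
#' effect-compartment model over fixed effects, IIV covariance (CL-Vc
#' block plus an independent Rcb variance) and matrix-specific proportional
#' residual error variances.  Positivity and positive-definiteness are
#' enforced by log and log-Cholesky transforms, so the outer optimisation
#' ([stats::nlminb()]) is unconstrained.  Standard errors come from the
#' central finite-difference Hessian of the objective; empirical Bayes
#' estimates (conditional modes) and eta-shrinkage are computed at the
#' optimum.
#'
#' @param data an observation table, e.g. from [simulate_study()] or
#'   [read_pk_dataset()].
#' @param init a [pop_model()] with initial values; defaults to the
#'   published parameter set.
#' @param covariates optional list of [covariate_effect()] terms to include
#'   (coefficients are estimated).
#' @param method likelihood approximation, `"laplace"` (default) or
#'   `"foce"` (linearised).
#' @param blq BLQ handling in the maternal likelihood: `"M1"` excludes
#'   flagged records, `"M3"` adds a censored-normal contribution.
#' @param fixed named list of parameters to fix (excluded from
#'   estimation): structural parameters by name (e.g. `list(ka = 1.87)`),
#'   and/or `omega =` a full 3x3 IIV covariance, `sigma =` a named vector
#'   of residual variances.
#' @param se compute standard errors (`TRUE`/`FALSE`); skipping them saves
#'   the Hessian evaluation.
#' @param control list overriding [stats::nlminb()] control values.
#' @return An object of class `"lactpk_fit"`; see [summary.lactpk_fit()].
#' @examples
#' \donttest{
#' tab <- simulate_study(seed = 1)
#' fit <- fit_nlme(tab, se = FALSE)
#' coef(fit)
#' }
#' @export
fit_nlme <- function(data, init = lamivudine_model(), covariates = NULL,
                     method = c("laplace", "foce"), blq = c("M1", "M3"),
                     fixed = list(), se = TRUE, control = list()) {
  method <- match.arg(method)
  blq <- match.arg(blq)
  stopifnot(inherits(init, "pop_model"))
  if (!is.null(covariates)) {
    if (inherits(covariates, "covariate_effect"))
      covariates <- list(covariates)
    stopifnot(all(vapply(covariates, inherits, TRUE, "covariate_effect")))
  } else covariates <- list()
  prep <- .prep_nlme(data, blq = blq)
  if (length(unique(prep$mat)) < 2L &&
      !all(c("kcb", "rcb") %in% names(fixed)))
    warning("only one observation matrix present; kcb and rcb are not ",
            "identifiable", call. = FALSE)
  for (i in seq_along(covariates)) {
    cc <- covariates[[i]]$covariate
    if (!cc %in% names(prep$covs))
      stop("covariate column not in data: ", cc, call. = FALSE)
    covariates[[i]]$center <- prep$cov_medians[[cc]]
  }
  parmap <- .make_parmap(init, covariates, fixed)
  par0 <- .model2par(init, parmap)
  ctrl <- utils::modifyList(list(rel.tol = 1e-8, iter.max = 500L,
                                 eval.max = 2000L), control)

  state <- new.env(parent = emptyenv())
  state$E <- matrix(0, prep$n, 3L)
  ofv_at <- function(par, E0) {
    m <- .par2model(par, parmap)
    ce <- covariates
    for (i in seq_along(ce)) ce[[i]]$coef <- m$cov_coefs[i]
    base <- .base_params(prep, m$theta, ce)
    modes <- .inner_modes(prep, base, m$sig_sd, m$omega, E0)
    ofv <- if (method == "laplace") .ofv_laplace(modes)
           else .ofv_foce(prep, base, m$sig_sd, m$omega, modes$E)
    list(ofv = if (is.finite(ofv)) ofv else 1e10, E = modes$E)
  }
  objective <- function(par) {
    r <- ofv_at(par, state$E)
    if (r$ofv < 1e10) state$E <- r$E
    r$ofv
  }
  ## Central-difference gradient with the inner warm start frozen, so the
  ## finite differences see a deterministic objective.
  gradient <- function(par, h = 1e-5) {
    E0 <- state$E
    vapply(seq_along(par), function(j) {
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      (ofv_at(pp, E0)$ofv - ofv_at(pm, E0)$ofv) / (2 * h)
    }, numeric(1))
  }

  box <- 12
  opt <- stats::nlminb(par0, objective, gradient = gradient,
                       control = ctrl, lower = -box, upper = box)
  ## restart from the endpoint while the gradient is visibly nonzero:
  ## nlminb occasionally quits early on this likelihood surface
  for (restart in 1:2) {
    grad_opt <- gradient(opt$par)
    if (max(abs(grad_opt)) < 0.05) break
    opt2 <- stats::nlminb(opt$par, objective, gradient = gradient,
                          control = ctrl, lower = -box, upper = box)
    if (opt2$objective >= opt$objective - 1e-8) {
      opt <- if (opt2$objective < opt$objective) opt2 else opt
      break
    }
    opt <- opt2
  }
  ofv <- objective(opt$par)            # refresh modes at the optimum
  grad_opt <- gradient(opt$par)
  ## nlminb's "false convergence" is routinely reported on flat, noisy
  ## likelihood surfaces; a small gradient on the transformed scale is the
  ## operative optimality check
  if (opt$convergence != 0 && max(abs(grad_opt)) < 0.05) {
    opt$convergence <- 0L
    opt$message <- paste0("converged (max |gradient| = ",
                          signif(max(abs(grad_opt)), 3), ")")
  }
  m <- .par2model(opt$par, parmap)
  ce <- covariates
  for (i in seq_along(ce)) ce[[i]]$coef <- m$cov_coefs[i]

  ebe <- state$E
  rownames(ebe) <- prep$ids
  colnames(ebe) <- c("cl", "vc", "rcb")
  om_sd <- sqrt(diag(m$omega))
  shrink <- 1 - apply(ebe, 2, stats::sd) / pmax(om_sd, 1e-12)

  vc_mat <- NULL; se_nat <- NULL
  hess_status <- "not computed"
  if (se) {
    hess <- stats::optimHess(opt$par, objective, gradient,
                             control = list(ndeps = rep(1e-4,
                                                        length(opt$par))))
    vc_try <- tryCatch(solve(0.5 * hess), error = function(e) NULL)
    if (is.null(vc_try) ||
        any(eigen(vc_try, symmetric = TRUE,
                  only.values = TRUE)$values <= 0)) {
      hess_status <- "Hessian not positive definite; SEs withheld"
    } else {
      vc_mat <- vc_try
      dimnames(vc_mat) <- list(parmap$labels, parmap$labels)
      hess_status <- "ok"
      J <- .natural_jacobian(opt$par, parmap)
      cov_nat <- J %*% vc_mat %*% t(J)
      se_nat <- sqrt(pmax(diag(cov_nat), 0))
      names(se_nat) <- rownames(J)
    }
  }

  theta_hat <- structural_params(ka = m$theta[["ka"]], cl = m$theta[["cl"]],
                                 vc = m$theta[["vc"]],
                                 kcb = m$theta[["kcb"]],
                                 rcb = m$theta[["rcb"]])
  fit <- structure(list(
    theta = theta_hat, omega = m$omega,
    sigma2 = c(plasma = unname(m$sig_sd[1])^2,
               milk = unname(m$sig_sd[2])^2),
    covariates = ce,
    coefficients = .natural_coefs(m),
    ofv = ofv, par = opt$par, parmap = parmap, vcov = vc_mat,
    se = se_nat, hess_status = hess_status,
    ebe = ebe, shrinkage = shrink,
    convergence = opt$convergence, message = opt$message,
    iterations = opt$iterations, grad_norm = max(abs(grad_opt)),
    method = method, blq = blq, n_subjects = prep$n,
    n_obs = length(prep$y), data = data, prep = prep,
    call = match.call()), class = "lactpk_fit")
  if (ofv >= 1e9)
    warning("fit failed: objective non-finite at the returned point",
            call. = FALSE)
  else if (opt$convergence != 0)
    warning("optimiser did not report clean convergence: ", opt$message,
            call. = FALSE)
  fit
}

## Natural-scale reporting vector: fixed effects, IIV CVs (CV% =
## 100*sqrt(omega^2)), the CL-Vc association (both 100*sqrt(|cov|) and the
## correlation), residual error CVs, covariate coefficients.
.natural_coefs <- function(m) {
  om <- m$omega
  c(ka = m$theta[["ka"]], cl = m$theta[["cl"]], vc = m$theta[["vc"]],
    kcb = m$theta[["kcb"]], rcb = m$theta[["rcb"]],
    iiv_cl_cv = 100 * sqrt(om[1, 1]), iiv_vc_cv = 100 * sqrt(om[2, 2]),
    iiv_cl_vc_cv = 100 * sqrt(abs(om[1, 2])),
    corr_cl_vc = om[1, 2] / sqrt(max(om[1, 1] * om[2, 2], 1e-300)),
    iiv_rcb_cv = 100 * sqrt(om[3, 3]),
    sigma_plasma_cv = 100 * unname(m$sig_sd[1]),
    sigma_milk_cv = 100 * unname(m$sig_sd[2]),
    if (length(m$cov_coefs)) stats::setNames(m$cov_coefs,
      paste0("beta", seq_along(m$cov_coefs))))
}

.natural_jacobian <- function(par, parmap, h = 1e-6) {
  f <- function(p) .natural_coefs(.par2model(p, parmap))
  f0 <- f(par)
  J <- matrix(0, length(f0), length(par),
              dimnames = list(names(f0), parmap$labels))
  for (j in seq_along(par)) {
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (f(pp) - f(pm)) / (2 * h)
  }
  J
}
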