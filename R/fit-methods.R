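## S3 methods for "lactpk_fit" objects.

#' @export
print.lactpk_fit <- function(x, ...) {
  cat("Lactation population PK model (", x$method,
      " approximation, BLQ mode ", x$blq, ")\n", sep = "")
  cat(sprintf("%d subjects, %d maternal observations; OFV = %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  th <- unclass(x$theta)
  cat(sprintf("  Ka %.3g 1/h  CL/F %.3g L/h  Vc/F %.3g L  Kcb %.3g 1/h  Rcb %.3g\n",
              th[["ka"]], th[["cl"]], th[["vc"]], th[["kcb"]], th[["rcb"]]))
  if (x$convergence != 0)
    cat("  note: optimiser status ", x$convergence, " (", x$message, ")\n",
        sep = "")
  invisible(x)
}

#' Summary of a fitted lactation model
#'
#' Tabulates the estimates in the conventional reporting layout: fixed
#' effects in natural units, inter-individual variability as CV%
#' (100*sqrt(omega^2)), the CL-Vc association both as 100*sqrt(|cov|) and
#' as a correlation, residual proportional error as CV%, with relative
#' standard errors (100*SE/estimate) when available, plus eta-shrinkage.
#'
#' @param object a [fit_nlme()] result.
#' @param ... unused.
#' @return An object of class `"summary.lactpk_fit"`.
#' @export
summary.lactpk_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  rse <- if (!is.null(se)) 100 * se[names(est)] / abs(est) else NULL
  structure(list(est = est, se = se, rse = rse,
                 shrinkage = object$shrinkage, ofv = object$ofv,
                 n_subjects = object$n_subjects, n_obs = object$n_obs,
                 method = object$method, hess_status = object$hess_status,
                 convergence = object$convergence),
            class = "summary.lactpk_fit")
}

#' @export
print.summary.lactpk_fit <- function(x, digits = 3, ...) {
  cat(sprintf("OFV %.3f on %d subjects / %d observations (%s)\n\n",
              x$ofv, x$n_subjects, x$n_obs, x$method))
  tab <- data.frame(Estimate = signif(x$est, digits))
  if (!is.null(x$rse)) tab$`RSE%` <- signif(x$rse, digits)
  print(tab)
  cat("\neta-shrinkage (%):",
      paste(sprintf("%s %.1f", names(x$shrinkage), 100 * x$shrinkage),
            collapse = ", "), "\n")
  if (x$hess_status != "ok" && x$hess_status != "not computed")
    cat("standard errors:", x$hess_status, "\n")
  invisible(x)
}

#' @export
coef.lactpk_fit <- function(object, ...) object$coefficients

#' @export
vcov.lactpk_fit <- function(object, ...) object$vcov

#' @export
logLik.lactpk_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$par),
            nobs = object$n_obs, class = "logLik")
}

#' Empirical Bayes estimates of the random effects
#'
#' @param fit a [fit_nlme()] result.
#' @return Matrix of conditional modes (subjects x eta for CL, Vc, Rcb).
#' @export
ebe <- function(fit) {
  stopifnot(inherits(fit, "lactpk_fit"))
  fit$ebe
}

#' Predicted concentrations from a fitted model
#'
#' @param object a [fit_nlme()] result.
#' @param newdata optional observation table; defaults to the fitted data.
#'   Individual predictions for subjects absent from the fit use eta = 0.
#' @param type `"individual"` (empirical-Bayes parameters) or
#'   `"population"` (typical parameters, eta = 0).
#' @param ... unused.
#' @return Numeric vector (ng/mL) aligned with the maternal observation
#'   rows of `newdata`; rows of other matrices get `NA`.
#' @export
predict.lactpk_fit <- function(object, newdata = NULL,
                               type = c("individual", "population"), ...) {
  type <- match.arg(type)
  tab <- if (is.null(newdata)) object$data else newdata
  keep <- tab$MATRIX %in% c("plasma", "milk")
  out <- rep(NA_real_, nrow(tab))
  m <- tab[keep, , drop = FALSE]
  sid <- match(m$ID, rownames(object$ebe))
  E <- if (type == "individual") {
    Em <- object$ebe[ifelse(is.na(sid), 1L, sid), , drop = FALSE]
    Em[is.na(sid), ] <- 0
    Em
  } else matrix(0, nrow(m), 3L)
  prep <- list(dose = m$DOSE, tau = m$TAU, ts = m$TIME %% m$TAU,
               mat = ifelse(m$MATRIX == "plasma", 1L, 2L),
               sid = seq_len(nrow(m)),
               covs = m[intersect(c("WT", "AGE", "BMI", "CRCL", "VDAY"),
                                  names(m))],
               y = numeric(nrow(m)))
  base <- .base_params(prep, unclass(object$theta), object$covariates)
  f <- .pred_rec(prep, base$ka, base$cl * exp(E[, 1L]),
                 base$vc * exp(E[, 2L]), base$kcb,
                 base$rcb * exp(E[, 3L]))
  out[keep] <- 1000 * f
  out
}

#' Simulate replicate studies from a fitted model
#'
#' Simulates `nsim` datasets at the observed design (same subjects, times,
#' matrices and covariates): fresh random effects from the estimated IIV
#' covariance, population predictions, proportional residual error.
#' Infant rows are carried through unchanged.
#'
#' @param object a [fit_nlme()] result.
#' @param nsim number of replicate datasets.
#' @param seed integer seed or `NULL`.
#' @param ... unused.
#' @return A list of observation tables.
#' @export
simulate.lactpk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  .with_seed(seed, {
    tab <- object$data
    keep <- tab$MATRIX %in% c("plasma", "milk")
    m <- tab[keep, , drop = FALSE]
    ids <- sort(unique(m$ID))
    sid <- match(m$ID, ids)
    prep <- list(dose = m$DOSE, tau = m$TAU, ts = m$TIME %% m$TAU,
                 mat = ifelse(m$MATRIX == "plasma", 1L, 2L), sid = sid,
                 covs = m[intersect(c("WT", "AGE", "BMI", "CRCL", "VDAY"),
                                    names(m))],
                 y = numeric(nrow(m)))
    base <- .base_params(prep, unclass(object$theta), object$covariates)
    sig_sd <- sqrt(object$sigma2)
    lapply(seq_len(nsim), function(k) {
      E <- draw_etas(length(ids), object$omega)
      f <- 1000 * .pred_rec(prep, base$ka, base$cl * exp(E[sid, 1L]),
                            base$vc * exp(E[sid, 2L]), base$kcb,
                            base$rcb * exp(E[sid, 3L]))
      dv <- f * (1 + stats::rnorm(length(f), 0,
                                  sig_sd[prep$mat]))
      sim <- tab
      sim$DV[keep] <- pmax(dv, 0)
      sim$BLQ <- 0L
      sim
    })
  })
}

#' Residuals of a fitted lactation model
#'
#' @param object a [fit_nlme()] result.
#' @param type `"cwres"` for conditional weighted residuals (see
#'   [cwres()]), `"iwres"` for individual weighted residuals
#'   `(y - f_i) / (sigma * f_i)` at the empirical-Bayes parameters.
#' @param ... unused.
#' @return Numeric vector aligned with the maternal observation records
#'   used in the fit.
#' @export
residuals.lactpk_fit <- function(object, type = c("cwres", "iwres"), ...) {
  type <- match.arg(type)
  if (type == "cwres") return(cwres(object)$cwres)
  prep <- object$prep
  base <- .base_params(prep, unclass(object$theta), object$covariates)
  E <- object$ebe
  f <- .pred_rec(prep, base$ka, base$cl * exp(E[prep$sid, 1L]),
                 base$vc * exp(E[prep$sid, 2L]), base$kcb,
                 base$rcb * exp(E[prep$sid, 3L]))
  sdf <- pmax(sqrt(object$sigma2)[prep$mat] * f, 1e-6)
  (prep$y - f) / sdf
}

#' Basic goodness-of-fit plot
#'
#' Observed versus individual- and population-predicted concentrations on
#' log-log axes, by matrix.
#'
#' @param x a [fit_nlme()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lactpk_fit <- function(x, ...) {
  tab <- x$data
  keep <- tab$MATRIX %in% c("plasma", "milk") & tab$MDV == 0 & tab$BLQ == 0
  obs <- tab$DV[keep]
  ipred <- predict(x)[keep]
  ppred <- predict(x, type = "population")[keep]
  col <- ifelse(tab$MATRIX[keep] == "plasma", "firebrick", "steelblue")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (p in list(list(v = ipred, lab = "Individual predicted (ng/mL)"),
                 list(v = ppred, lab = "Population predicted (ng/mL)"))) {
    graphics::plot(p$v, obs, log = "xy", col = col, pch = 16, cex = 0.7,
                   xlab = p$lab, ylab = "Observed (ng/mL)", ...)
    graphics::abline(0, 1)
  }
  invisible(x)
}
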