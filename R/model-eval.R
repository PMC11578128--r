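#' Likelihood-ratio test between nested models
#'
#' Differences in the objective function value (-2 log-likelihood) between
#' nested models are chi-square distributed under the null; a drop of 3.84
#' for one additional parameter corresponds to p = 0.05.
#'
#' @param ofv_reduced OFV of the smaller (reduced) model.
#' @param ofv_full OFV of the larger (full) model.
#' @param df additional parameters in the full model.
#' @param alpha significance level for the flag.
#' @return A list with `delta_ofv`, `df`, `p_value` and `significant`.
#' @examples
#' lrt(103.84, 100, df = 1)   # p = 0.05, on the boundary
#' @export
lrt <- function(ofv_reduced, ofv_full, df = 1L, alpha = 0.05) {
  stopifnot(df >= 1)
  delta <- ofv_reduced - ofv_full
  if (delta < 0) {
    warning("full model has higher OFV than the reduced model; ",
            "check nesting", call. = FALSE)
    delta_p <- 1
  } else delta_p <- stats::pchisq(delta, df, lower.tail = FALSE)
  ## the conventional OFV-drop thresholds (3.84, 6.63) are rounded critical
  ## values; a drop meeting the printed threshold counts as significant
  list(delta_ofv = delta, df = df, p_value = delta_p,
       significant = delta_p <= alpha + 1e-4)
}

#' Stepwise covariate modelling
#'
#' Greedy forward inclusion followed by backward elimination over a set of
#' candidate parameter-covariate effects.  A candidate enters when it drops
#' the OFV by at least `forward_dofv` (3.84, i.e. p < 0.05 at one degree of
#' freedom; the boundary counts as passing) against the current model, the
#' best candidate first; retained effects must each survive backward
#' deletion at `backward_dofv` (6.63, p < 0.01).  Covariates are centered
#' on the dataset median.
#'
#' @param data observation table.
#' @param init initial [pop_model()].
#' @param candidates list of [covariate_effect()] objects; default is the
#'   screened set: weight, age, creatinine clearance and BMI on clearance,
#'   weight and BMI on volume, visit day on the milk ratio.
#' @param forward_dofv,backward_dofv OFV-drop thresholds.
#' @param ... further arguments to [fit_nlme()] (e.g. `control`).
#' @return A list with the selected `fit`, the selected `effects`, the
#'   base-model fit and a `trace` data.frame of every step.
#' @export
scm <- function(data, init = lamivudine_model(),
                candidates = scm_candidates(),
                forward_dofv = 3.84, backward_dofv = 6.63, ...) {
  stopifnot(all(vapply(candidates, inherits, TRUE, "covariate_effect")))
  base_fit <- fit_nlme(data, init, se = FALSE, ...)
  ## candidate fits start from the current estimates (standard SCM
  ## practice), which cuts their optimisation cost substantially
  init_from <- function(fit)
    pop_model(fit$theta, fit$omega, fit$sigma2)
  trace <- list()
  note <- function(phase, ce, dofv, action)
    data.frame(phase = phase,
               effect = paste0(ce$covariate, "->", toupper(ce$param),
                               " (", ce$form, ")"),
               delta_ofv = dofv, action = action)
  selected <- list()
  current_fit <- base_fit
  pool <- candidates
  repeat {                                # forward inclusion
    if (!length(pool)) break
    dofvs <- rep(NA_real_, length(pool))
    fits <- vector("list", length(pool))
    for (j in seq_along(pool)) {
      fj <- tryCatch(
        fit_nlme(data, init_from(current_fit),
                 covariates = c(selected, pool[j]), se = FALSE, ...),
        error = function(e) NULL)
      fits[j] <- list(fj)               # keep NULLs as placeholders
      dofvs[j] <- if (is.null(fj) || !is.finite(fj$ofv)) -Inf
                  else current_fit$ofv - fj$ofv
    }
    best <- which.max(dofvs)
    if (dofvs[best] >= forward_dofv) {
      trace[[length(trace) + 1L]] <-
        note("forward", pool[[best]], dofvs[best], "included")
      selected <- c(selected, pool[best])
      current_fit <- fits[[best]]
      pool <- pool[-best]
    } else {
      for (j in seq_along(pool))
        trace[[length(trace) + 1L]] <-
          note("forward", pool[[j]], dofvs[j], "not included")
      break
    }
  }
  repeat {                                # backward elimination
    if (!length(selected)) break
    dofvs <- rep(NA_real_, length(selected))
    fits <- vector("list", length(selected))
    for (j in seq_along(selected)) {
      fj <- tryCatch(
        fit_nlme(data, init_from(current_fit), covariates = selected[-j],
                 se = FALSE, ...),
        error = function(e) NULL)
      fits[j] <- list(fj)
      dofvs[j] <- if (is.null(fj) || !is.finite(fj$ofv)) Inf
                  else fj$ofv - current_fit$ofv
    }
    weakest <- which.min(dofvs)
    if (dofvs[weakest] < backward_dofv) {
      trace[[length(trace) + 1L]] <-
        note("backward", selected[[weakest]], dofvs[weakest], "removed")
      current_fit <- fits[[weakest]]
      selected <- selected[-weakest]
    } else {
      for (j in seq_along(selected))
        trace[[length(trace) + 1L]] <-
          note("backward", selected[[j]], dofvs[j], "retained")
      break
    }
  }
  list(fit = current_fit, effects = selected, base_fit = base_fit,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(phase = character(), effect = character(),
                               delta_ofv = numeric(), action = character()))
}

#' Default covariate candidate set
#'
#' The relationships screened in the analysis: maternal weight, age,
#' creatinine clearance and BMI on clearance; weight and BMI on volume;
#' postpartum day of sampling on the milk-to-plasma ratio.
#'
#' @param form functional form used for every candidate.
#' @return A list of [covariate_effect()] objects.
#' @export
scm_candidates <- function(form = "power") {
  c(lapply(c("WT", "AGE", "CRCL", "BMI"), function(cc)
      covariate_effect("cl", cc, form)),
    lapply(c("WT", "BMI"), function(cc) covariate_effect("vc", cc, form)),
    list(covariate_effect("rcb", "VDAY", form)))
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples subjects (all their records together) with replacement,
#' refits the model on each resampled dataset, and reports per-parameter
#' medians and percentile confidence intervals.  Failed fits are excluded
#' and counted; more than 20% failures flags the result.
#'
#' @param data observation table.
#' @param init initial [pop_model()].
#' @param n_resamples number of bootstrap datasets (1000 for a full
#'   analysis; reduce for exploratory runs).
#' @param seed integer seed.
#' @param level confidence level for the percentile interval.
#' @param ... further arguments to [fit_nlme()].
#' @return An object of class `"lactpk_boot"`: a list with the `table` of
#'   median and CI per parameter, the matrix of `estimates`, `n_failed`,
#'   and a `status` string.
#' @export
bootstrap_ci <- function(data, init = lamivudine_model(),
                         n_resamples = 1000L, seed = NULL, level = 0.95,
                         ...) {
  .with_seed(seed, {
    ids <- unique(data$ID)
    est <- list()
    n_failed <- 0L
    for (b in seq_len(n_resamples)) {
      take <- sample(ids, length(ids), replace = TRUE)
      pieces <- lapply(seq_along(take), function(j) {
        d <- data[data$ID == take[j], , drop = FALSE]
        d$ID <- j                       # resampled clones get fresh IDs
        d
      })
      bd <- do.call(rbind, pieces)
      fit <- tryCatch(suppressWarnings(fit_nlme(bd, init, se = FALSE, ...)),
                      error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$ofv)) n_failed <- n_failed + 1L
      else est[[length(est) + 1L]] <- coef(fit)
    }
    if (!length(est)) stop("all bootstrap fits failed", call. = FALSE)
    em <- do.call(rbind, est)
    a <- (1 - level) / 2
    tab <- data.frame(
      parameter = colnames(em),
      median = apply(em, 2, stats::median),
      lower = apply(em, 2, stats::quantile, probs = a),
      upper = apply(em, 2, stats::quantile, probs = 1 - a),
      row.names = NULL)
    status <- if (n_failed > 0.2 * n_resamples)
      sprintf("warning: %d/%d fits failed", n_failed, n_resamples)
    else "ok"
    structure(list(table = tab, estimates = em, n_failed = n_failed,
                   n_resamples = n_resamples, level = level,
                   status = status),
              class = "lactpk_boot")
  })
}

#' @export
print.lactpk_boot <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap: %d resamples, %d failed (%s)\n",
              x$n_resamples, x$n_failed, x$status))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab)
  invisible(x)
}
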