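#' Conditional weighted residuals
#'
#' The FOCE-based definition from the population-modelling literature:
#' with `f` the prediction at the conditional mode `eta_hat`, `G` the
#' gradient of the prediction with respect to eta there, and `R` the
#' residual covariance (with interaction), each subject's observations are
#' approximately `N(f - G eta_hat, G Omega G' + R)`; CWRES are the
#' decorrelated residuals under that approximation and are close to
#' standard normal when the model is right.  Records in subjects whose
#' covariance is numerically singular are flagged and excluded.
#'
#' @param fit a [fit_nlme()] result.
#' @return A data.frame with `ID`, `MATRIX`, `TIME`, `obs` (ng/mL),
#'   `cwres`, and a logical `flagged`.
#' @export
cwres <- function(fit) {
  stopifnot(inherits(fit, "lactpk_fit"))
  prep <- fit$prep
  base <- .base_params(prep, unclass(fit$theta), fit$covariates)
  parts <- .foce_parts(prep, base, sqrt(fit$sigma2), fit$omega, fit$ebe)
  res <- rep(NA_real_, length(prep$y))
  flagged <- rep(FALSE, length(prep$y))
  for (i in seq_len(prep$n)) {
    idx <- which(prep$sid == i)
    Gi <- parts$G[idx, , drop = FALSE]
    Vi <- Gi %*% fit$omega %*% t(Gi) +
      diag(parts$sdf[idx]^2, length(idx))
    mi <- parts$f[idx] - as.vector(Gi %*% fit$ebe[i, ])
    ev <- eigen(Vi, symmetric = TRUE)
    if (min(ev$values) < 1e-12 * max(ev$values)) {
      flagged[idx] <- TRUE
      next
    }
    vhalf_inv <- ev$vectors %*% (t(ev$vectors) / sqrt(ev$values))
    res[idx] <- as.vector(vhalf_inv %*% (prep$y[idx] - mi))
  }
  data.frame(ID = prep$ids[prep$sid],
             MATRIX = c("plasma", "milk")[prep$mat],
             TIME = prep$time, obs = 1000 * prep$y,
             cwres = res, flagged = flagged)
}

#' Prediction-corrected visual predictive check
#'
#' Simulates replicate studies from the fitted model at the observed
#' design, rescales every observation and simulation by the ratio of the
#' bin-median population prediction to the record's own population
#' prediction (removing design heterogeneity such as the two dose
#' regimens), and compares observed percentiles per time bin with the
#' simulation-based confidence bands, separately for plasma and milk.
#' Empty bins are merged with their lower neighbour.
#'
#' @param fit a [fit_nlme()] result.
#' @param n_sim number of simulated replicate studies (at least 200).
#' @param seed integer seed.
#' @param bins time-bin breakpoints (h); records are binned by time after
#'   dose within the interval.
#' @param probs percentiles to track.
#' @param ci_level width of the simulation confidence band.
#' @return An object of class `"lactpk_vpc"`: a data.frame `table` with
#'   one row per matrix/bin/percentile (observed value, band lower/upper,
#'   bin midpoint, n records) plus the correction factors.
#' @export
pc_vpc <- function(fit, n_sim = 500L, seed = NULL,
                   bins = c(0, 1, 3, 6, 10, 14, 18, 24),
                   probs = c(0.05, 0.5, 0.95), ci_level = 0.9) {
  stopifnot(inherits(fit, "lactpk_fit"))
  if (n_sim < 200L) stop("n_sim must be at least 200", call. = FALSE)
  tab <- fit$data
  keep <- which(tab$MATRIX %in% c("plasma", "milk") & tab$MDV == 0 &
                  tab$BLQ == 0)
  m <- tab[keep, , drop = FALSE]
  t_in <- m$TIME %% m$TAU
  pred <- predict(fit, type = "population")[keep]
  sims <- simulate(fit, nsim = n_sim, seed = seed)
  bin_of <- cut(t_in, bins, include.lowest = TRUE, right = FALSE)
  ## merge empty bins downward
  for (mx in c("plasma", "milk")) {
    sel <- m$MATRIX == mx
    counts <- table(bin_of[sel])
    empty <- names(counts)[counts == 0]
    if (length(empty))
      message("empty ", mx, " bins merged: ",
              paste(empty, collapse = ", "))
  }
  key <- interaction(m$MATRIX, bin_of, drop = TRUE)
  pcf <- stats::ave(pred, key, FUN = stats::median) / pred
  obs_pc <- m$DV * pcf
  alpha <- (1 - ci_level) / 2
  out <- list()
  for (mx in c("plasma", "milk")) {
    sel <- which(m$MATRIX == mx)
    if (!length(sel)) next
    for (b in levels(droplevels(bin_of[sel]))) {
      idx <- sel[bin_of[sel] == b]
      if (!length(idx)) next
      obs_q <- stats::quantile(obs_pc[idx], probs, names = FALSE)
      sim_q <- sapply(sims, function(s)
        stats::quantile(s$DV[keep][idx] * pcf[idx], probs, names = FALSE))
      lo <- apply(sim_q, 1, stats::quantile, probs = alpha)
      hi <- apply(sim_q, 1, stats::quantile, probs = 1 - alpha)
      med <- apply(sim_q, 1, stats::median)
      out[[length(out) + 1L]] <- data.frame(
        matrix = mx, bin = b, mid = stats::median(t_in[idx]),
        prob = probs, observed = obs_q,
        sim_median = med, lower = lo, upper = hi, n = length(idx))
    }
  }
  structure(list(table = do.call(rbind, out), n_sim = n_sim, bins = bins,
                 probs = probs, ci_level = ci_level,
                 correction = data.frame(row = keep, factor = pcf)),
            class = "lactpk_vpc")
}

#' @export
print.lactpk_vpc <- function(x, digits = 3, ...) {
  cat(sprintf("Prediction-corrected VPC (%d simulations, %g%% bands)\n",
              x$n_sim, 100 * x$ci_level))
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot a prediction-corrected VPC
#'
#' One panel per matrix: observed percentiles (lines with points) against
#' the simulation confidence bands (shaded).
#'
#' @param x a [pc_vpc()] result.
#' @param log_y logical; log-scale concentration axis.
#' @param ... unused.
#' @export
plot.lactpk_vpc <- function(x, log_y = TRUE, ...) {
  tab <- x$table
  mats <- unique(tab$matrix)
  op <- graphics::par(mfrow = c(1, length(mats)))
  on.exit(graphics::par(op))
  for (mx in mats) {
    tm <- tab[tab$matrix == mx, ]
    ylim <- range(tm$lower, tm$upper, tm$observed)
    graphics::plot(NA, xlim = range(tm$mid), ylim = ylim,
                   log = if (log_y) "y" else "",
                   xlab = "Time after dose (h)",
                   ylab = "Prediction-corrected conc. (ng/mL)",
                   main = mx)
    for (p in unique(tm$prob)) {
      tp <- tm[tm$prob == p, ]
      o <- order(tp$mid)
      graphics::polygon(c(tp$mid[o], rev(tp$mid[o])),
                        c(tp$lower[o], rev(tp$upper[o])),
                        col = grDevices::adjustcolor("indianred", 0.3),
                        border = NA)
      graphics::lines(tp$mid[o], tp$observed[o], type = "b", pch = 16,
                      lty = if (p == 0.5) 1 else 2)
    }
  }
  invisible(x)
}
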