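#' Study design of the paired plasma-milk-infant PK study
#'
#' Describes the sampling design of the lactation study the synthetic
#' generator emulates: 35 mothers (10 on 150 mg q12h, 25 on 300 mg q24h),
#' two postpartum visits each, a morning-dosing group sampled densely over
#' 0-8 h (plasma 0, 1, 2, 4, 8 h; milk 0, 2, 4, 8 h) and an evening-dosing
#' group sampled at 12, 16, 20 h in both matrices, infant spot samples, and
#' matrix-specific quantification limits.
#'
#' @param n_q12 number of mothers on 150 mg every 12 h.
#' @param n_q24 number of mothers on 300 mg every 24 h.
#' @param n_morning number of morning-dosing (densely sampled) mothers;
#'   the 12-hourly mothers are allocated to the morning group first.
#' @param times_plasma_morning,times_milk_morning,times_infant_morning
#'   sampling times (h after dose) for the morning group.
#' @param times_plasma_evening,times_milk_evening,times_infant_evening
#'   sampling times (h after self-reported dose) for the evening group.
#' @param visit1_window,visit2_window postpartum-day `c(min, median, max)`
#'   for the two visits.
#' @param lloq_plasma,lloq_milk,lloq_infant lower limits of quantification
#'   (ng/mL).
#' @param missingness probability that any scheduled sample is lost.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(n_q12 = 10L, n_q24 = 25L, n_morning = 14L,
                         times_plasma_morning = c(0, 1, 2, 4, 8),
                         times_milk_morning = c(0, 2, 4, 8),
                         times_infant_morning = c(0, 4, 6),
                         times_plasma_evening = c(12, 16, 20),
                         times_milk_evening = c(12, 16, 20),
                         times_infant_evening = c(12, 18),
                         visit1_window = c(7, 13, 43),
                         visit2_window = c(36, 73.5, 84),
                         lloq_plasma = 5, lloq_milk = 16.6, lloq_infant = 5,
                         missingness = 0.07) {
  d <- list(n_q12 = as.integer(n_q12), n_q24 = as.integer(n_q24),
            n_morning = as.integer(n_morning),
            times_plasma_morning = times_plasma_morning,
            times_milk_morning = times_milk_morning,
            times_infant_morning = times_infant_morning,
            times_plasma_evening = times_plasma_evening,
            times_milk_evening = times_milk_evening,
            times_infant_evening = times_infant_evening,
            visit1_window = visit1_window, visit2_window = visit2_window,
            lloq_plasma = lloq_plasma, lloq_milk = lloq_milk,
            lloq_infant = lloq_infant, missingness = missingness)
  if (d$n_q12 < 0 || d$n_q24 < 0 || d$n_q12 + d$n_q24 < 1)
    stop("need at least one mother", call. = FALSE)
  if (d$n_morning < 0 || d$n_morning > d$n_q12 + d$n_q24)
    stop("n_morning must be between 0 and the total number of mothers",
         call. = FALSE)
  if (any(c(lloq_plasma, lloq_milk, lloq_infant) < 0))
    stop("LLOQs must be nonnegative", call. = FALSE)
  if (missingness < 0 || missingness >= 1)
    stop("missingness must be in [0, 1)", call. = FALSE)
  class(d) <- "study_design"
  d
}

## Published cohort characteristics, median (min, max):
## maternal weight 64.0 (50.0, 89.0) kg, age 30 (19, 40) yr,
## BMI 24.8 (20.0, 30.5) kg/m2, creatinine clearance 134.6 (89.2, 184.7)
## mL/min, infant weight 3.60 (2.40, 5.58) kg at visit 1 and
## 5.17 (3.90, 7.13) kg at visit 2.
.covariate_table <- function() {
  list(WT   = c(50.0, 64.0, 89.0),
       AGE  = c(19, 30, 40),
       BMI  = c(20.0, 24.8, 30.5),
       CRCL = c(89.2, 134.6, 184.7),
       IWT1 = c(2.40, 3.60, 5.58),
       IWT2 = c(3.90, 5.17, 7.13))
}

## Median-anchored bounded draw: a 50/50 mixture of Beta(2,2) scaled onto
## [lo, med] and [med, hi].  The sample median equals the published median
## exactly and all draws stay inside the published range; a plain symmetric
## Beta over the range cannot do both because the ranges are skewed.
.rmedrange <- function(n, lo, med, hi) {
  b <- stats::rbeta(n, 2, 2)
  upper <- stats::runif(n) < 0.5
  ifelse(upper, med + (hi - med) * b, lo + (med - lo) * b)
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  expr
}

#' Draw subject-level covariates for a synthetic study
#'
#' Maternal weight, age, BMI and creatinine clearance, postpartum visit
#' days, and infant weights are drawn from median-anchored bounded
#' distributions matching the published cohort medians and ranges
#' (independently per covariate; the true joint distribution is unknown).
#' Infant weight at visit 2 is constrained to be at least the visit-1
#' weight; infant age equals the postpartum day of the visit.
#'
#' @param design a [study_design()].
#' @param n number of mothers (defaults to the design total).
#' @param seed integer seed for reproducibility, or `NULL` to use the
#'   current RNG state.
#' @return A data.frame with one row per mother: `ID`, `DOSE`, `TAU`,
#'   `GROUP`, `WT`, `AGE`, `BMI`, `CRCL`, `VDAY1`, `VDAY2`, `IWT1`, `IWT2`.
#' @export
generate_covariates <- function(design = study_design(), n = NULL,
                                seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  .with_seed(seed, {
    if (is.null(n)) n <- design$n_q12 + design$n_q24
    n <- as.integer(n)
    frac_q12 <- design$n_q12 / (design$n_q12 + design$n_q24)
    n_q12 <- if (n == design$n_q12 + design$n_q24) design$n_q12
             else round(frac_q12 * n)
    tab <- .covariate_table()
    draw <- function(key) .rmedrange(n, tab[[key]][1], tab[[key]][2],
                                     tab[[key]][3])
    iwt1 <- draw("IWT1"); iwt2 <- pmax(draw("IWT2"), iwt1)
    n_total <- design$n_q12 + design$n_q24
    n_morning <- if (n == n_total) design$n_morning
                 else min(n, round(design$n_morning * n / n_total))
    data.frame(
      ID = seq_len(n),
      DOSE = c(rep(150, n_q12), rep(300, n - n_q12)),
      TAU = c(rep(12, n_q12), rep(24, n - n_q12)),
      GROUP = ifelse(seq_len(n) <= n_morning, "morning", "evening"),
      WT = draw("WT"), AGE = draw("AGE"), BMI = draw("BMI"),
      CRCL = draw("CRCL"),
      VDAY1 = round(.rmedrange(n, design$visit1_window[1],
                               design$visit1_window[2],
                               design$visit1_window[3])),
      VDAY2 = round(.rmedrange(n, design$visit2_window[1],
                               design$visit2_window[2],
                               design$visit2_window[3])),
      IWT1 = iwt1, IWT2 = iwt2)
  })
}

#' Simulate a synthetic mother-infant PK study
#'
#' Draws per-mother random effects from the population model, evaluates the
#' steady-state plasma and milk profiles at each mother's sampling schedule
#' for both visits, applies proportional residual error, generates infant
#' spot concentrations from the infant-exposure forward model (steady-state
#' concentration with 30% proportional noise, reflecting the near-constant
#' observed infant profiles), removes samples at the design missingness
#' rate, and censors below the matrix LLOQs.
#'
#' @param design a [study_design()].
#' @param model a [pop_model()]; defaults to the published parameter set.
#' @param seed integer seed; identical seeds give identical tables.
#' @param covariates optional pre-drawn covariate table from
#'   [generate_covariates()].
#' @param infant_cv proportional error CV on infant concentrations.
#' @return An observation table (data.frame) with columns `ID`, `VISIT`,
#'   `MATRIX`, `TIME`, `DV` (ng/mL), `BLQ`, `MDV`, `DOSE`, `TAU`, `GROUP`,
#'   `WT`, `AGE`, `BMI`, `CRCL`, `VDAY`, `IWT`.  The true per-subject
#'   random effects are attached as attribute `"eta"`.
#' @export
simulate_study <- function(design = study_design(),
                           model = lamivudine_model(), seed = NULL,
                           covariates = NULL, infant_cv = 0.30) {
  stopifnot(inherits(design, "study_design"), inherits(model, "pop_model"))
  .with_seed(seed, {
    cov <- if (is.null(covariates)) generate_covariates(design)
           else covariates
    n <- nrow(cov)
    eta <- draw_etas(n, model$omega)
    rows <- vector("list", n * 2L)
    k <- 0L
    for (i in seq_len(n)) {
      p_i <- individual_params(model$theta, eta[i, ])
      reg <- dose_regimen(cov$DOSE[i], cov$TAU[i])
      morning <- cov$GROUP[i] == "morning"
      t_p <- if (morning) design$times_plasma_morning
             else design$times_plasma_evening
      t_m <- if (morning) design$times_milk_morning
             else design$times_milk_evening
      t_i <- if (morning) design$times_infant_morning
             else design$times_infant_evening
      for (v in 1:2) {
        iwt <- if (v == 1) cov$IWT1[i] else cov$IWT2[i]
        vday <- if (v == 1) cov$VDAY1[i] else cov$VDAY2[i]
        pred_p <- plasma_conc(p_i, reg, t_p)
        pred_m <- milk_conc(p_i, reg, t_m)
        css <- .infant_css_forward(p_i, cov$DOSE[i] * 24 / cov$TAU[i],
                                   iwt, vday)
        obs_p <- apply_residual_error(pred_p, "plasma", model$sigma2)
        obs_m <- apply_residual_error(pred_m, "milk", model$sigma2)
        obs_i <- pmax(css * (1 + stats::rnorm(length(t_i), 0, infant_cv)), 0)
        k <- k + 1L
        rows[[k]] <- data.frame(
          ID = cov$ID[i], VISIT = v,
          MATRIX = rep(c("plasma", "milk", "infant"),
                       c(length(t_p), length(t_m), length(t_i))),
          TIME = c(t_p, t_m, t_i),
          DV = c(obs_p, obs_m, obs_i),
          BLQ = 0L, MDV = 0L,
          DOSE = cov$DOSE[i], TAU = cov$TAU[i], GROUP = cov$GROUP[i],
          WT = cov$WT[i], AGE = cov$AGE[i], BMI = cov$BMI[i],
          CRCL = cov$CRCL[i], VDAY = vday, IWT = iwt)
      }
    }
    tab <- do.call(rbind, rows[seq_len(k)])
    if (design$missingness > 0)
      tab <- tab[stats::runif(nrow(tab)) >= design$missingness, ,
                 drop = FALSE]
    rownames(tab) <- NULL
    tab <- censor_blq(tab, design$lloq_plasma, design$lloq_milk,
                      design$lloq_infant)
    attr(tab, "eta") <- eta
    attr(tab, "design") <- design
    tab
  })
}

## Forward model for the infant spot concentration: average maternal plasma
## concentration over 24 h -> milk concentration -> daily infant dose ->
## steady-state infant concentration via the allometric-maturation
## clearance.  daily_dose in mg/day, iwt kg, vday days postpartum.
.infant_css_forward <- function(params, daily_dose, iwt, vday) {
  conc_ave <- daily_dose / (params[["cl"]] * 24)          # mg/L
  dose_inf <- params[["rcb"]] * conc_ave * 0.15 * 1000    # ug/kg/day
  cl_inf <- infant_clearance(iwt, vday / 365.25)
  dose_inf * iwt / (cl_inf * 24)                          # ug/L = ng/mL
}

#' Draw random effects from an IIV covariance matrix
#'
#' @param n number of subjects.
#' @param omega covariance matrix of the log-scale random effects.
#' @return An `n` x `ncol(omega)` matrix of draws.
#' @export
draw_etas <- function(n, omega) {
  ev <- eigen(omega, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- matrix(stats::rnorm(n * ncol(omega)), n)
  z %*% rt
}

#' Censor observations below the limit of quantification
#'
#' Records strictly below their matrix LLOQ are flagged `BLQ = 1` and their
#' reported value is set to LLOQ/2, the convention used for numeric
#' summaries of censored records.  A record exactly at the LLOQ is not
#' censored.  The likelihood treats flagged records according to the fit's
#' BLQ mode (excluded under M1, censored-normal contribution under M3).
#'
#' @param table an observation table.
#' @param lloq_plasma,lloq_milk,lloq_infant limits (ng/mL); 0 disables
#'   censoring for that matrix.
#' @return The table with `BLQ` and `DV` updated.
#' @export
censor_blq <- function(table, lloq_plasma = 5, lloq_milk = 16.6,
                       lloq_infant = 5) {
  if (any(c(lloq_plasma, lloq_milk, lloq_infant) < 0))
    stop("LLOQs must be nonnegative", call. = FALSE)
  lloq <- c(plasma = lloq_plasma, milk = lloq_milk,
            infant = lloq_infant)[table$MATRIX]
  hit <- !is.na(table$DV) & table$DV < lloq & lloq > 0
  table$BLQ <- as.integer(hit)
  table$DV[hit] <- lloq[hit] / 2
  table
}
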