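#' Average steady-state plasma concentration over 24 h
#'
#' The 24-h AUC at steady state equals (daily dose)/CL regardless of the
#' dosing interval, so the average concentration is
#' `daily_dose / (CL * 24)`; for a 12-hourly regimen the 24-h window spans
#' two doses.  A quadrature route over the closed-form profile is available
#' as a cross-check.
#'
#' @param params a [structural_params()] object (individual or typical).
#' @param regimen a [dose_regimen()] object (steady state assumed).
#' @param method `"closed"` (default) or `"quadrature"`.
#' @return Average plasma concentration, ng/mL.
#' @examples
#' avg_plasma_conc(lamivudine_params(), dose_regimen(300, 24))  # 644.3
#' @export
avg_plasma_conc <- function(params, regimen,
                            method = c("closed", "quadrature")) {
  stopifnot(inherits(params, "structural_params"),
            inherits(regimen, "dose_regimen"))
  method <- match.arg(method)
  daily_dose <- regimen$dose * 24 / regimen$tau
  if (method == "closed")
    return(1000 * daily_dose / (params[["cl"]] * 24))
  stats::integrate(function(t) plasma_conc(params, regimen, t), 0, 24,
                   rel.tol = 1e-9, subdivisions = 400L)$value / 24
}

#' Average breast-milk concentration
#'
#' `ConcMilk = Rcb * ConcAve`: the milk accumulation ratio times the
#' average maternal plasma concentration.
#'
#' @param conc_ave average maternal plasma concentration (ng/mL).
#' @param rcb milk accumulation (milk-to-plasma) ratio.
#' @return Average milk concentration, ng/mL.
#' @export
avg_milk_conc <- function(conc_ave, rcb) {
  stopifnot(all(conc_ave >= 0), all(rcb >= 0))
  rcb * conc_ave
}

#' Daily infant dose through breast milk
#'
#' `Dose_infant = ConcMilk * VolMilk` with the conventional estimated milk
#' intake of 0.15 L/kg/day.
#'
#' @param conc_milk average milk concentration (ng/mL).
#' @param vol_milk daily milk intake, L/kg/day.
#' @return Infant dose, ug/kg/day.
#' @export
infant_daily_dose <- function(conc_milk, vol_milk = 0.15) {
  stopifnot(all(conc_milk >= 0), all(vol_milk >= 0))
  (conc_milk / 1000) * vol_milk * 1000   # ng/mL -> mg/L; mg -> ug
}

#' Relative infant dose
#'
#' The infant's weight-normalised daily dose through milk as a percentage
#' of the mother's weight-normalised daily dose.  Values below 10% are the
#' conventional safety reference in lactation pharmacology.
#'
#' @param dose_infant infant dose, ug/kg/day.
#' @param maternal_daily_dose maternal dose, mg/day.
#' @param maternal_wt maternal weight, kg.
#' @return Relative infant dose, percent.
#' @export
relative_infant_dose <- function(dose_infant, maternal_daily_dose,
                                 maternal_wt) {
  if (any(maternal_wt <= 0))
    stop("maternal weight must be positive", call. = FALSE)
  100 * (dose_infant / 1000) / (maternal_daily_dose / maternal_wt)
}

#' Infant apparent clearance by allometry and maturation
#'
#' Paediatric apparent oral clearance:
#' `12.7 * (WT/7)^0.75 * Age^1.47 / (0.25^1.47 + Age^1.47)` L/h, an
#' allometric three-quarter power of weight around the 7-kg reference,
#' multiplied by a sigmoidal maturation function of postnatal age with
#' half-maturation at 0.25 years.
#'
#' @param wt infant weight, kg.
#' @param age infant age, years.
#' @return Apparent clearance, L/h.
#' @examples
#' infant_clearance(7, 1e6)   # 12.7: matured, reference weight
#' infant_clearance(7, 0.25)  # 6.35: half-maximal maturation
#' @export
infant_clearance <- function(wt, age) {
  if (any(wt <= 0)) stop("infant weight must be positive", call. = FALSE)
  if (any(age < 0)) stop("infant age must be nonnegative", call. = FALSE)
  12.7 * (wt / 7)^0.75 * age^1.47 / (0.25^1.47 + age^1.47)
}

#' Infant steady-state concentration
#'
#' `Css = Dose_infant / (CL_infant * tau)` with a 24-h interval: the total
#' daily infant dose in ug/day divided by the daily clearance volume gives
#' ug/L, numerically equal to ng/mL.
#'
#' @param dose_infant_total total infant dose, ug/day.
#' @param cl_infant infant apparent clearance, L/h.
#' @param tau averaging interval, h.
#' @return Steady-state infant concentration, ng/mL.
#' @export
infant_css <- function(dose_infant_total, cl_infant, tau = 24) {
  stopifnot(all(dose_infant_total >= 0))
  if (any(cl_infant <= 0))
    stop("infant clearance must be positive", call. = FALSE)
  dose_infant_total / (cl_infant * tau)
}

#' Per-pair infant exposure from a fitted model
#'
#' Runs the full infant-exposure chain for every mother-infant pair and
#' visit in a fitted study: empirical-Bayes individual parameters give the
#' average plasma and milk concentrations, the daily infant dose, the
#' relative infant dose, the allometric-maturation infant clearance and the
#' predicted steady-state infant concentration, plus the dose as a
#' percentage of the recommended therapeutic infant dose.
#'
#' @param fit a fitted model from [fit_nlme()].
#' @param vol_milk daily milk intake, L/kg/day.
#' @param recommended_dose reference infant treatment dose, mg/kg/day
#'   (8 = 4 mg/kg twice daily, the recommendation for infants of 4 weeks
#'   to 3 months; use 4 for younger infants).
#' @return A data.frame with one row per mother-visit: `ID`, `VISIT`,
#'   `conc_ave`, `conc_milk` (ng/mL), `dose_infant` (ug/kg/day), `rid_pct`,
#'   `pct_recommended`, `cl_infant` (L/h), `css` (ng/mL), and the observed
#'   median infant concentration for that visit when present (`obs_infant`,
#'   BLQ records imputed at LLOQ/2).
#' @export
infant_exposure <- function(fit, vol_milk = 0.15, recommended_dose = 8) {
  stopifnot(inherits(fit, "lactpk_fit"))
  tab <- fit$data
  ebe <- fit$ebe
  ids <- rownames(ebe)
  out <- list()
  for (id in ids) {
    sub <- tab[tab$ID == as.numeric(id), , drop = FALSE]
    p_i <- individual_params(fit$theta, ebe[id, ])
    for (v in sort(unique(sub$VISIT))) {
      sv <- sub[sub$VISIT == v, , drop = FALSE]
      reg <- dose_regimen(sv$DOSE[1], sv$TAU[1])
      conc_ave <- avg_plasma_conc(p_i, reg)
      conc_milk <- avg_milk_conc(conc_ave, p_i[["rcb"]])
      dose_inf <- infant_daily_dose(conc_milk, vol_milk)
      rid <- relative_infant_dose(dose_inf, sv$DOSE[1] * 24 / sv$TAU[1],
                                  sv$WT[1])
      iwt <- sv$IWT[1]
      cl_inf <- if (is.na(iwt)) NA_real_
                else infant_clearance(iwt, sv$VDAY[1] / 365.25)
      css <- if (is.na(iwt)) NA_real_
             else infant_css(dose_inf * iwt, cl_inf)
      inf_obs <- sv$DV[sv$MATRIX == "infant"]
      out[[length(out) + 1L]] <- data.frame(
        ID = as.numeric(id), VISIT = v,
        conc_ave = conc_ave, conc_milk = conc_milk,
        dose_infant = dose_inf, rid_pct = rid,
        pct_recommended = 100 * (dose_inf / 1000) / recommended_dose,
        cl_infant = cl_inf, css = css,
        obs_infant = if (length(inf_obs)) stats::median(inf_obs)
                     else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
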