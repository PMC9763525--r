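# Prediction of Lu-177 tumour absorbed doses from a single Ga-68 PET
# measurement, using grade-specific population effective half-lives and
# local energy deposition.

#' Prediction configuration
#'
#' @param t_eff_grade1,t_eff_grade2 Population effective half-lives in
#'   hours for grade-1 and grade-2 tumours (defaults 103 and 81).
#' @param energy_per_decay_kev Mean electron energy per decay (keV).
#' @param density Tissue density (g/mL).
#' @return An object of class `prediction_config`.
#' @export
prediction_config <- function(t_eff_grade1 = 103, t_eff_grade2 = 81,
                              energy_per_decay_kev = 147.9, density = 1.04) {
  stopifnot(t_eff_grade1 > 0, t_eff_grade2 > 0,
            energy_per_decay_kev > 0, density > 0)
  structure(list(t_eff_grade1 = t_eff_grade1, t_eff_grade2 = t_eff_grade2,
                 energy_per_decay_kev = energy_per_decay_kev,
                 density = density),
            class = "prediction_config")
}

#' Back-propagate a Ga-68 concentration to the time of injection
#'
#' The measured concentration, already decay-corrected for the physical
#' decay of Ga-68, is further corrected for biological clearance over the
#' scan delay.  In mode `"effective"` the biological rate is
#' `lambda_bio = lambda_eff - lambda_phys(Lu-177)`, i.e. the clearance
#' component of the population effective half-life that the prediction
#' model assumes; mode `"none"` applies no further correction.  Either
#' way the correction over ~1 h is below 1%.
#'
#' @param ac68_decay_corrected Physically decay-corrected concentration
#'   (Bq/mL).
#' @param t_image Scan time post injection in hours.
#' @param t_eff Effective Lu-177 half-life in hours.
#' @param mode `"effective"` (default) or `"none"`.
#' @param half_life_177lu_d Physical Lu-177 half-life in days.
#' @return Concentration at t = 0 (Bq/mL), with attribute `mode`.
#' @export
backpropagate_to_t0 <- function(ac68_decay_corrected, t_image, t_eff,
                                mode = c("effective", "none"),
                                half_life_177lu_d = HALF_LIFE_LU177_D) {
  mode <- match.arg(mode)
  stopifnot(t_image >= 0, t_eff > 0)
  if (mode == "none") {
    out <- ac68_decay_corrected
  } else {
    lambda_bio <- log(2) / t_eff - log(2) / (half_life_177lu_d * 24)
    if (lambda_bio <= 0)
      stop("effective half-life exceeds the physical Lu-177 half-life; ",
           "biological rate would be <= 0")
    out <- ac68_decay_corrected * exp(lambda_bio * t_image)
  }
  attr(out, "mode") <- mode
  out
}

#' Predict the Lu-177 tumour absorbed dose from Ga-68 uptake
#'
#' The Ga-68 AC/IA at t = 0 is assumed to equal the Lu-177 AC/IA at
#' t = 0 (shared ligand); scaling by the injected Lu-177 activity gives
#' the initial Lu-177 concentration, which decays with the grade-specific
#' population effective half-life.  Local energy deposition and analytic
#' integration of the mono-exponential give the absorbed dose.
#'
#' @param ac68_per_ia_t0 Ga-68 AC/IA back-propagated to t = 0 (1/mL).
#' @param injected_activity_177 Injected Lu-177 activity (Bq).
#' @param grade Tumour grade, 1 or 2.
#' @param cfg A [prediction_config()].
#' @param tumour_id Identifier carried through.
#' @return List of class `predicted_dose` with `tumour_id`,
#'   `ac68_per_ia_t0`, `predicted_ac177_t0` (Bq/mL),
#'   `predicted_ad_per_ia` (Gy/GBq), `grade_used`, `t_eff_used`.
#' @export
predict_dose <- function(ac68_per_ia_t0, injected_activity_177, grade,
                         cfg = prediction_config(), tumour_id = NA_character_) {
  if (!grade %in% c(1, 2)) stop("unknown grade: ", grade)
  stopifnot(ac68_per_ia_t0 >= 0, injected_activity_177 > 0)
  t_eff <- if (grade == 1) cfg$t_eff_grade1 else cfg$t_eff_grade2
  lambda_h <- log(2) / t_eff
  a0 <- ac68_per_ia_t0 * injected_activity_177
  ad <- dose_rate_local(a0, cfg$energy_per_decay_kev, cfg$density) / lambda_h
  structure(list(tumour_id = tumour_id,
                 ac68_per_ia_t0 = ac68_per_ia_t0,
                 predicted_ac177_t0 = a0,
                 predicted_ad_per_ia = ad / (injected_activity_177 / 1e9),
                 grade_used = as.integer(grade),
                 t_eff_used = t_eff),
            class = "predicted_dose")
}

#' @export
print.predicted_dose <- function(x, ...) {
  cat("<predicted_dose> grade ", x$grade_used, ": AD/IA = ",
      signif(x$predicted_ad_per_ia, 5), " Gy/GBq\n", sep = "")
  invisible(x)
}

#' Pair predicted and measured doses for agreement analysis
#'
#' @param predicted data.frame with `tumour_id`, `patient_id`,
#'   `predicted_ad_per_ia`.
#' @param measured data.frame with `tumour_id`, `ad_per_ia` (> 0).
#' @return data.frame with per-tumour `ratio` (predicted/measured) and
#'   `log_ratio`, plus attribute `patient_means`: per-patient means of the
#'   predicted and measured tumour doses (for the patient-level
#'   agreement analysis).
#' @export
prediction_error_table <- function(predicted, measured) {
  miss <- setdiff(predicted$tumour_id, measured$tumour_id)
  miss2 <- setdiff(measured$tumour_id, predicted$tumour_id)
  if (length(miss) || length(miss2))
    stop("unmatched tumour ids: ",
         paste(c(miss, miss2), collapse = ", "))
  m <- merge(predicted, measured[, c("tumour_id", "ad_per_ia")],
             by = "tumour_id")
  if (any(m$ad_per_ia <= 0)) stop("measured doses must be > 0")
  m$ratio <- m$predicted_ad_per_ia / m$ad_per_ia
  m$log_ratio <- log(m$ratio)
  pm <- do.call(rbind, lapply(split(m, m$patient_id), function(d)
    data.frame(patient_id = d$patient_id[1],
               n_tumours = nrow(d),
               mean_predicted = mean(d$predicted_ad_per_ia),
               mean_measured = mean(d$ad_per_ia))))
  rownames(pm) <- NULL
  attr(m, "patient_means") <- pm
  m
}

#' Ga-68-based dose prediction for a synthetic cohort
#'
#' @param cohort A `cohort`.
#' @param quantified Output of [quantify_cohort()].
#' @param cfg A [prediction_config()].
#' @param mode Back-propagation mode, see [backpropagate_to_t0()].
#' @return data.frame with one row per tumour: grade, `ac68_per_ia_t0`,
#'   `predicted_ad_per_ia`, and the generator truth dose.
#' @export
predict_cohort <- function(cohort, quantified, cfg = prediction_config(),
                           mode = "effective") {
  q <- quantified[quantified$kind == "tumour", ]
  rows <- lapply(cohort, function(p) {
    qi <- q[q$patient_id == p$patient_id, ]
    if (nrow(qi) == 0) return(NULL)
    t_eff <- if (p$grade == 1) cfg$t_eff_grade1 else cfg$t_eff_grade2
    ac0 <- backpropagate_to_t0(qi$ac68_corrected,
                               p$ga_scan_time_min / 60, t_eff, mode = mode)
    ac0_per_ia <- ac_per_ia(as.numeric(ac0), p$injected_activity_68)
    pd <- lapply(seq_len(nrow(qi)), function(i)
      predict_dose(ac0_per_ia[i], p$injected_activity_177, p$grade, cfg,
                   qi$region_id[i]))
    tr <- p$truth[match(qi$region_id, p$truth$region_id), ]
    data.frame(patient_id = p$patient_id,
               tumour_id = qi$region_id,
               grade = p$grade,
               ac68_per_ia_t0 = ac0_per_ia,
               predicted_ad_per_ia = vapply(pd, `[[`, numeric(1),
                                            "predicted_ad_per_ia"),
               truth_ad_per_ia = tr$ad_per_ia)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
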