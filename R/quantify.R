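# Image and region quantification: VOI statistics, decay correction,
# AC/IA, SUV, scanner calibration, and partial-volume correction for
# tumours (PET and SPECT) and organs.

#' Calibration configuration for quantification
#'
#' @param suv_factor_68ga Scanner SUV bias for Ga-68 PET; measured VOI
#'   concentrations are divided by this factor (default 0.94).
#' @param rc_organ_spect RC applied to kidney and spleen SPECT values
#'   (default 0.85); liver parenchyma uses 1.
#' @param half_life_68ga_min Physical half-life of Ga-68 in minutes.
#' @param half_life_177lu_d Physical half-life of Lu-177 in days.
#' @param tissue_density Soft-tissue density in g/mL (default 1.04).
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(suv_factor_68ga = 0.94,
                               rc_organ_spect = 0.85,
                               half_life_68ga_min = HALF_LIFE_GA68_MIN,
                               half_life_177lu_d = HALF_LIFE_LU177_D,
                               tissue_density = 1.04) {
  stopifnot(suv_factor_68ga > 0, rc_organ_spect > 0, rc_organ_spect <= 1.05,
            half_life_68ga_min > 0, half_life_177lu_d > 0, tissue_density > 0)
  structure(list(suv_factor_68ga = suv_factor_68ga,
                 rc_organ_spect = rc_organ_spect,
                 half_life_68ga_min = half_life_68ga_min,
                 half_life_177lu_d = half_life_177lu_d,
                 tissue_density = tissue_density),
            class = "calibration_config")
}

#' VOI statistics
#'
#' @param image A `voxel_image`.
#' @param mask A `label_mask` aligned with `image`.
#' @param label Region label.
#' @return List with `mean`, `max`, `total` (Bq, value x voxel volume) and
#'   `volume` (mL).
#' @export
voi_stats <- function(image, mask, label) {
  stopifnot(inherits(image, "voxel_image"), inherits(mask, "label_mask"))
  if (!identical(dim(image$values), dim(mask$labels)))
    stop("image and mask must share a grid")
  idx <- region_indices(mask, label)
  vals <- image$values[idx]
  vv <- voxel_volume_ml(image)
  list(mean = mean(vals), max = max(vals),
       total = sum(vals) * vv, volume = length(vals) * vv)
}

#' Decay-correct a measured value back to time zero
#'
#' @param value Measured value(s).
#' @param t_elapsed Time since administration (same unit as `half_life`).
#' @param half_life Physical half-life (> 0).
#' @return `value * 2^(t_elapsed / half_life)`.
#' @export
decay_correct <- function(value, t_elapsed, half_life) {
  if (half_life <= 0) stop("'half_life' must be > 0")
  value * 2^(t_elapsed / half_life)
}

#' Activity concentration per injected activity
#'
#' @param ac_corrected_t0 Decay-corrected activity concentration (Bq/mL).
#' @param injected_activity Injected activity (Bq, > 0).
#' @return AC/IA in 1/mL.
#' @export
ac_per_ia <- function(ac_corrected_t0, injected_activity) {
  if (any(injected_activity <= 0)) stop("'injected_activity' must be > 0")
  ac_corrected_t0 / injected_activity
}

#' Standardized uptake value
#'
#' SUV = activity concentration x body weight / injected activity, with
#' the weight in grams so the result carries units g/mL.  Per clinical
#' practice the concentration is not partial-volume corrected and is
#' decay-corrected to the injection time; `mode = "max"` uses the maximum
#' voxel value of the VOI instead of the mean.
#'
#' @param ac Activity concentration (Bq/mL), mean or max per `mode`.
#' @param injected_activity Injected activity (Bq).
#' @param weight Body weight in kg (> 0).
#' @param mode `"mean"` or `"max"` (label only; supply the matching `ac`).
#' @return SUV in g/mL.
#' @export
suv <- function(ac, injected_activity, weight, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (any(weight <= 0)) stop("'weight' must be > 0")
  if (any(injected_activity <= 0)) stop("'injected_activity' must be > 0")
  ac * (weight * 1000) / injected_activity
}

#' Apply the Ga-68 scanner SUV calibration
#'
#' Divides measured PET activity concentrations by the scanner bias
#' factor (default 0.94).
#'
#' @param ac Measured concentration(s) (Bq/mL).
#' @param cal A [calibration_config()].
#' @return Calibrated concentration(s).
#' @export
apply_suv_calibration <- function(ac, cal = calibration_config()) {
  ac / cal$suv_factor_68ga
}

#' Estimate the local background concentration around a region
#'
#' Mean concentration within a morphological shell between the `inner`
#' and `outer` Chebyshev dilations of the region, excluding every other
#' labelled region (so a neighbouring lesion does not contaminate the
#' estimate).
#'
#' @param image A `voxel_image`.
#' @param mask A `label_mask`.
#' @param label Region label.
#' @param shell_voxels `c(inner, outer)` dilation radii in voxels.
#' @return Background concentration (Bq/mL).
#' @export
estimate_background <- function(image, mask, label, shell_voxels = c(2L, 4L)) {
  stopifnot(inherits(image, "voxel_image"), inherits(mask, "label_mask"))
  bin <- mask$labels == label
  if (!any(bin)) stop("empty region")
  inner <- dilate_mask(bin, shell_voxels[1])
  outer <- dilate_mask(inner, shell_voxels[2] - shell_voxels[1])
  shell <- outer & !inner & mask$labels == 0L
  if (!any(shell)) stop("empty background shell after exclusions")
  mean(image$values[shell])
}

#' Partial-volume correction of a PET tumour value
#'
#' Solves the coupled system linking the corrected concentration, the
#' background-to-object ratio and the physical volume by fixed-point
#' iteration:
#' `eta = background / corrected`; `Vp = volume_map(Vs, eta)`;
#' `corrected = apparent / R(Vp, eta)`.
#'
#' @param ac_apparent Measured (calibrated) tumour concentration (Bq/mL).
#' @param v_segmented Segmented volume (mL).
#' @param background_ac Local background concentration (Bq/mL).
#' @param rc_params Fitted [rc_params()] (with `f`).
#' @param vol_params Fitted volume map (or identity,
#'   `list(a0=0, a1=1, a2=0, a3=0)`).
#' @param tol Relative convergence tolerance.
#' @param max_iter Maximum iterations.
#' @param start Starting value for the corrected concentration.
#' @return List with `v_physical`, `ac_corrected`, `eta_hat`,
#'   `iterations`, `converged`, `flagged` (TRUE when the background
#'   reaches the object level and eta was clamped at 1).
#' @export
pvc_tumour_pet <- function(ac_apparent, v_segmented, background_ac,
                           rc_params, vol_params = list(a0 = 0, a1 = 1, a2 = 0, a3 = 0),
                           tol = 1e-6, max_iter = 100, start = ac_apparent) {
  stopifnot(ac_apparent > 0, v_segmented > 0, background_ac >= 0)
  corrected <- start
  trajectory <- numeric(0)
  flagged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- if (corrected > 0) background_ac / corrected else 1
    if (eta >= 1) { eta <- 1; flagged <- TRUE }
    vp <- apply_volume_map(v_segmented, eta, vol_params)
    corrected_new <- ac_apparent / rc_full(vp, eta, rc_params)
    trajectory <- c(trajectory, corrected_new)
    if (abs(corrected_new - corrected) <= tol * abs(corrected)) {
      corrected <- corrected_new
      if (flagged)
        warning("background >= object concentration; eta clamped at 1")
      return(list(v_physical = vp, ac_corrected = corrected, eta_hat = eta,
                  iterations = it, converged = TRUE, flagged = flagged))
    }
    corrected <- corrected_new
  }
  stop("PVC fixed point did not converge in ", max_iter,
       " iterations; trajectory tail: ",
       paste(signif(utils::tail(trajectory, 5), 6), collapse = ", "))
}

#' Partial-volume correction of a SPECT tumour value
#'
#' Spill-out-only correction: `corrected = apparent / R0(Vs)` with the
#' volume-only recovery model calibrated on cold-background spheres.
#'
#' @param ac_apparent Measured concentration (Bq/mL).
#' @param v_segmented_spect Segmented SPECT volume (mL).
#' @param rc_params_spect Fitted [rc_params()] (volume-only; `f` unused).
#' @param floor_ml Smallest admissible volume.
#' @return Corrected concentration (Bq/mL).
#' @export
pvc_tumour_spect <- function(ac_apparent, v_segmented_spect, rc_params_spect,
                             floor_ml = 0.1) {
  if (any(v_segmented_spect < floor_ml))
    stop("volume below floor of ", floor_ml, " mL")
  ac_apparent / rc_volume(v_segmented_spect, rc_params_spect)
}

#' Partial-volume correction of an organ value
#'
#' @param ac_apparent Measured concentration (Bq/mL).
#' @param rc Recovery coefficient in (0, 1].
#' @return `ac_apparent / rc`.
#' @export
pvc_organ <- function(ac_apparent, rc) {
  if (any(rc <= 0) || any(rc > 1)) stop("'rc' must be in (0, 1]")
  ac_apparent / rc
}

#' Quantify a synthetic cohort
#'
#' Applies the full quantification chain to every region of a generated
#' cohort: scanner calibration, PET tumour PVC (fixed point), SPECT
#' tumour PVC (volume-only), organ RCs, AC/IA normalisation and SUVs.
#'
#' @param cohort A `cohort` from [make_cohort()].
#' @param rc_pet,rc_spect Recovery parameters to invert the partial-volume
#'   effect (defaults: the generating parameters recorded in the cohort
#'   spec).
#' @param vol_map Volume map applied to PET volumes (default identity).
#' @param cal A [calibration_config()].
#' @return data.frame, one row per region measurement, with corrected
#'   concentrations, AC/IA for both tracers, SUVs, and ground truth.
#' @export
quantify_cohort <- function(cohort,
                            rc_pet = attr(cohort, "spec")$rc_pet,
                            rc_spect = attr(cohort, "spec")$rc_spect,
                            vol_map = list(a0 = 0, a1 = 1, a2 = 0, a3 = 0),
                            cal = calibration_config(
                              suv_factor_68ga = attr(cohort, "spec")$suv_factor_68ga,
                              rc_organ_spect = attr(cohort, "spec")$organ_rc_spect),
                            pvc_tol = 1e-9) {
  rows <- lapply(cohort, function(p) {
    tm <- p$tumours
    n_t <- nrow(tm)
    ac68_cal <- apply_suv_calibration(tm$ac68_apparent, cal)
    bg_cal <- apply_suv_calibration(tm$background68, cal)
    pvc <- lapply(seq_len(n_t), function(i)
      pvc_tumour_pet(ac68_cal[i], tm$volume_pet[i], bg_cal[i], rc_pet, vol_map,
                     tol = pvc_tol))
    ac68_corr <- vapply(pvc, `[[`, numeric(1), "ac_corrected")
    eta_hat <- vapply(pvc, `[[`, numeric(1), "eta_hat")
    vp_hat <- vapply(pvc, `[[`, numeric(1), "v_physical")
    ac177_corr <- pvc_tumour_spect(tm$ac177_spect_apparent, tm$volume_spect,
                                   rc_spect)
    tum <- data.frame(
      patient_id = p$patient_id, region_id = tm$tumour_id, kind = "tumour",
      grade = p$grade, weight = p$weight,
      volume_pet = vp_hat, volume_spect = tm$volume_spect,
      eta_hat = eta_hat,
      ac68_corrected = ac68_corr,
      ac68_per_ia = ac_per_ia(ac68_corr, p$injected_activity_68),
      suv_mean = suv(ac68_cal, p$injected_activity_68, p$weight),
      ac177_corrected = ac177_corr,
      ac177_per_ia = ac_per_ia(
        decay_correct(ac177_corr, p$spect_time_h,
                      cal$half_life_177lu_d * 24),
        p$injected_activity_177))

    og <- p$organs
    ac177_og <- pvc_organ(og$ac177_spect_apparent,
                          ifelse(og$organ == "liver", 1, cal$rc_organ_spect))
    ac68_og <- apply_suv_calibration(og$ac68_apparent, cal)  # organ PET RC ~ 1 here
    org <- data.frame(
      patient_id = p$patient_id, region_id = og$organ, kind = "organ",
      grade = p$grade, weight = p$weight,
      volume_pet = NA_real_, volume_spect = NA_real_, eta_hat = NA_real_,
      ac68_corrected = ac68_og,
      ac68_per_ia = ac_per_ia(ac68_og, p$injected_activity_68),
      suv_mean = suv(ac68_og, p$injected_activity_68, p$weight),
      ac177_corrected = ac177_og,
      ac177_per_ia = ac_per_ia(
        decay_correct(ac177_og, p$spect_time_h, cal$half_life_177lu_d * 24),
        p$injected_activity_177))
    rbind(tum, org)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
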