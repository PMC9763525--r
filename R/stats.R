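# Statistical battery: Pearson, weighted inter-patient and
# repeated-measures intra-patient correlations, leave-one-out stability
# intervals, log-ratio Bland-Altman agreement, and the tumour-volume
# filter.

new_cor_result <- function(r, p, slope, intercept, n_effective, df,
                           method, loo_interval = NULL) {
  structure(list(r = r, p = p, slope = slope, intercept = intercept,
                 n_effective = n_effective, df = df, method = method,
                 loo_interval = loo_interval),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3g, p = %.3g (n = %d)\n",
              x$method, x$r, x$p, x$n_effective))
  if (!is.na(x$slope))
    cat(sprintf("  slope k = %.3g%s\n", x$slope,
                if (!is.na(x$intercept))
                  sprintf(", intercept m = %.3g", x$intercept) else ""))
  if (!is.null(x$loo_interval))
    cat(sprintf("  leave-one-out interval: (%.3g, %.3g)\n",
                x$loo_interval[1], x$loo_interval[2]))
  invisible(x)
}

p_from_t <- function(r, df) {
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

#' Pearson correlation with regression coefficients
#'
#' Product-moment correlation with a two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom, plus the OLS slope and
#' intercept of `y` on `x`.
#'
#' @param x,y Numeric vectors (n >= 3, finite).
#' @return A `cor_result`.
#' @export
cor_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  sx <- x - mean(x); sy <- y - mean(y)
  vx <- sum(sx^2); vy <- sum(sy^2)
  if (vx == 0 || vy == 0) stop("zero variance")
  r <- sum(sx * sy) / sqrt(vx * vy)
  k <- sum(sx * sy) / vx
  m <- mean(y) - k * mean(x)
  new_cor_result(r, p_from_t(r, n - 2), k, m, n, n - 2, "Pearson")
}

#' Weighted Pearson correlation
#'
#' Correlation of weighted covariances about weighted means; with integer
#' weights it equals the unweighted correlation on the correspondingly
#' replicated data.  The p-value uses a t-approximation with
#' (number of points - 2) degrees of freedom; slope and intercept come
#' from weighted least squares.
#'
#' @param x,y Numeric vectors.
#' @param w Positive weights (e.g. number of tumours per patient).
#' @return A `cor_result`.
#' @export
cor_weighted <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(w) == length(x),
            length(x) >= 3, all(w > 0),
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  W <- sum(w)
  mx <- sum(w * x) / W; my <- sum(w * y) / W
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2)
  cyy <- sum(w * (y - my)^2)
  if (cxx == 0 || cyy == 0) stop("zero variance")
  r <- cxy / sqrt(cxx * cyy)
  k <- cxy / cxx
  m <- my - k * mx
  new_cor_result(r, p_from_t(r, n - 2), k, m, n, n - 2, "weighted Pearson")
}

#' Repeated-measures correlation
#'
#' Within-subject correlation under a common slope with subject-specific
#' intercepts (the analysis-of-covariance construction): both variables
#' are centred within subject; `r` is the sign of the common slope times
#' the square root of the variance the common slope explains over
#' explained-plus-residual; degrees of freedom are
#' `N - n_subjects - 1`.  Subjects with a single observation cannot
#' inform the slope and are dropped with a warning.
#'
#' @param subject_ids Subject identifier per observation.
#' @param x,y Numeric vectors.
#' @return A `cor_result` (intercept is `NA`; only the common slope is
#'   reported).
#' @export
cor_rm <- function(subject_ids, x, y) {
  stopifnot(length(x) == length(y), length(subject_ids) == length(x))
  keep <- stats::ave(seq_along(x), subject_ids, FUN = length) > 1
  if (!all(keep)) {
    warning(sum(!keep), " singleton subject(s) dropped")
    subject_ids <- subject_ids[keep]; x <- x[keep]; y <- y[keep]
  }
  if (length(x) == 0 || length(unique(subject_ids)) < 2)
    stop("need >= 2 subjects with >= 2 observations each")
  xc <- x - stats::ave(x, subject_ids)
  yc <- y - stats::ave(y, subject_ids)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("zero within-subject variance in x")
  slope <- sum(xc * yc) / sxx
  ss_exp <- slope^2 * sxx
  ss_res <- sum((yc - slope * xc)^2)
  r <- sign(slope) * sqrt(ss_exp / (ss_exp + ss_res))
  n <- length(x); n_sub <- length(unique(subject_ids))
  df <- n - n_sub - 1
  new_cor_result(r, p_from_t(r, df), slope, NA_real_, n, df,
                 "repeated-measures")
}

#' Leave-one-out interval of a correlation coefficient
#'
#' Recomputes a correlation once per analysis unit (patient, point, ...),
#' each time omitting that unit, and returns the range of `r`.
#'
#' @param data A data.frame.
#' @param corr_fn Function `data -> cor_result` (or anything with `$r`).
#' @param unit_col Column defining the unit to omit (default: each row).
#' @return `c(r_min, r_max)`; degenerate subsets are skipped with a
#'   warning.
#' @export
loo_interval <- function(data, corr_fn, unit_col = NULL) {
  units <- if (is.null(unit_col)) seq_len(nrow(data))
           else unique(data[[unit_col]])
  if (length(units) < 4) stop("need >= 4 units for a leave-one-out interval")
  rs <- vapply(units, function(u) {
    sub <- if (is.null(unit_col)) data[-u, , drop = FALSE]
           else data[data[[unit_col]] != u, , drop = FALSE]
    tryCatch(corr_fn(sub)$r,
             error = function(e) {
               warning("leave-one-out subset for unit '", u,
                       "' degenerate: ", conditionMessage(e))
               NA_real_
             })
  }, numeric(1))
  range(rs, na.rm = TRUE)
}

#' Log-ratio Bland-Altman agreement
#'
#' Deviations are analysed as `d = ln(pred / meas)` so that positive and
#' negative relative deviations are symmetric.  The mean and the
#' normal-based 95% coverage interval `mean +/- 1.96 sd` (sd with n - 1
#' denominator) are computed on the log scale and back-transformed to
#' percent relative deviations, `(exp(d) - 1) * 100`.
#'
#' @param pred,meas Positive values (predicted and measured doses).
#' @param level `"tumour"` (per pair) or `"patient"` (per-patient means of
#'   the tumour doses are formed first; requires `patient_id`).
#' @param patient_id Patient identifier per pair (for `level = "patient"`).
#' @param coverage Coverage probability of the interval.
#' @return List of class `agreement_result`: `mean_deviation_pct`,
#'   `ci_low_pct`, `ci_high_pct`, `n`, `level`, and the log-scale
#'   statistics `log_mean`, `log_sd`.
#' @export
log_ratio_bland_altman <- function(pred, meas, level = c("tumour", "patient"),
                                   patient_id = NULL, coverage = 0.95) {
  level <- match.arg(level)
  if (any(pred <= 0) || any(meas <= 0)) stop("values must be > 0")
  if (level == "patient") {
    if (is.null(patient_id)) stop("'patient_id' required for patient level")
    pred <- tapply(pred, patient_id, mean)
    meas <- tapply(meas, patient_id, mean)
  }
  d <- log(pred / meas)
  n <- length(d)
  m <- mean(d)
  s <- if (n > 1) stats::sd(d) else 0
  z <- stats::qnorm(1 - (1 - coverage) / 2)
  back <- function(x) (exp(x) - 1) * 100
  structure(list(mean_deviation_pct = back(m),
                 ci_low_pct = back(m - z * s),
                 ci_high_pct = back(m + z * s),
                 n = n, level = level,
                 log_mean = m, log_sd = s, z = z),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (log-ratio, %s level, n = %d):\n  mean %+.3g%%, 95%% coverage interval (%+.3g%%, %+.3g%%)\n",
    x$level, x$n, x$mean_deviation_pct, x$ci_low_pct, x$ci_high_pct))
  invisible(x)
}

#' Filter tumours by PET volume
#'
#' Tumours at or below the cutoff (strictly `volume > cutoff` is kept) are
#' excluded, as are records with missing volume.
#'
#' @param records data.frame with a `volume_pet` column (mL).
#' @param volume_cutoff_ml Cutoff volume (default 5 mL).
#' @return List with `kept`, `excluded` (with an `exclusion_reason`
#'   column), `n_kept`, `n_excluded`.
#' @export
filter_tumours <- function(records, volume_cutoff_ml = 5) {
  if (is.null(records$volume_pet)) stop("'records' needs a 'volume_pet' column")
  v <- records$volume_pet
  missing_v <- is.na(v)
  keep <- !missing_v & v > volume_cutoff_ml
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded))
    excluded$exclusion_reason <- ifelse(is.na(excluded$volume_pet),
                                        "missing volume",
                                        paste0("volume <= ", volume_cutoff_ml, " mL"))
  list(kept = records[keep, , drop = FALSE], excluded = excluded,
       n_kept = sum(keep), n_excluded = sum(!keep))
}

#' Average left and right kidney values
#'
#' @param left,right Values for the two kidneys; if one is `NA` the other
#'   passes through and the result is flagged.
#' @return Mean value, with attribute `single_kidney` when only one was
#'   present.
#' @export
kidney_average <- function(left, right) {
  if (is.na(left) && is.na(right)) stop("both kidney values missing")
  if (is.na(left) || is.na(right)) {
    out <- if (is.na(left)) right else left
    attr(out, "single_kidney") <- TRUE
    return(out)
  }
  (left + right) / 2
}

#' Correlation tables for a quantified, dosed cohort
#'
#' Reproduces the layout of the study's result tables: organ Pearson
#' correlations (kidneys averaged left/right) of Lu-177 AD/IA and AC/IA
#' against Ga-68 AC/IA with leave-one-out intervals over patients, and
#' tumour inter-patient (weighted) and intra-patient (repeated-measures)
#' correlations after the 5 mL PET-volume filter.
#'
#' @param quantified Output of [quantify_cohort()].
#' @param doses Output of [hybrid_dose_cohort()].
#' @param volume_cutoff_ml Tumour PET-volume cutoff in mL.
#' @return List with `organ` and `tumour` data.frames of correlation
#'   results, and the `filter` counts.
#' @export
cohort_correlations <- function(quantified, doses, volume_cutoff_ml = 5) {
  q <- merge(quantified, doses[, c("patient_id", "region_id", "ad_per_ia")],
             by = c("patient_id", "region_id"))

  org <- q[q$kind == "organ", ]
  org$organ <- sub("kidney_(left|right)", "kidney", org$region_id)
  organ_rows <- do.call(rbind, lapply(split(org, org$organ), function(d) {
    agg <- do.call(rbind, lapply(split(d, d$patient_id), function(pp)
      data.frame(patient_id = pp$patient_id[1],
                 ac68_per_ia = mean(pp$ac68_per_ia),
                 ac177_per_ia = mean(pp$ac177_per_ia),
                 ad_per_ia = mean(pp$ad_per_ia))))
    res_ad <- cor_pearson(agg$ac68_per_ia, agg$ad_per_ia)
    res_ac <- cor_pearson(agg$ac68_per_ia, agg$ac177_per_ia)
    loo_ad <- if (nrow(agg) >= 4)
      loo_interval(agg, function(s) cor_pearson(s$ac68_per_ia, s$ad_per_ia))
    else c(NA_real_, NA_real_)
    data.frame(organ = d$organ[1],
               r_ad = res_ad$r, p_ad = res_ad$p,
               k_ad = res_ad$slope, m_ad = res_ad$intercept,
               loo_ad_min = loo_ad[1], loo_ad_max = loo_ad[2],
               r_ac = res_ac$r, p_ac = res_ac$p)
  }))
  rownames(organ_rows) <- NULL

  tum <- q[q$kind == "tumour", ]
  filt <- filter_tumours(tum, volume_cutoff_ml)
  tum <- filt$kept
  pm <- do.call(rbind, lapply(split(tum, tum$patient_id), function(d)
    data.frame(patient_id = d$patient_id[1], n_tumours = nrow(d),
               ac68_per_ia = mean(d$ac68_per_ia),
               ad_per_ia = mean(d$ad_per_ia),
               ac177_per_ia = mean(d$ac177_per_ia))))
  inter_ad <- cor_weighted(pm$ac68_per_ia, pm$ad_per_ia, pm$n_tumours)
  if (nrow(pm) >= 4)
    inter_ad$loo_interval <- loo_interval(
      pm, function(s) cor_weighted(s$ac68_per_ia, s$ad_per_ia, s$n_tumours))
  intra_ad <- cor_rm(tum$patient_id, tum$ac68_per_ia, tum$ad_per_ia)
  inter_ac <- cor_weighted(pm$ac68_per_ia, pm$ac177_per_ia, pm$n_tumours)
  intra_ac <- cor_rm(tum$patient_id, tum$ac68_per_ia, tum$ac177_per_ia)
  tumour_rows <- data.frame(
    outcome = c("ad_per_ia", "ac177_per_ia"),
    r_inter = c(inter_ad$r, inter_ac$r),
    p_inter = c(inter_ad$p, inter_ac$p),
    k_inter = c(inter_ad$slope, inter_ac$slope),
    m_inter = c(inter_ad$intercept, inter_ac$intercept),
    r_intra = c(intra_ad$r, intra_ac$r),
    p_intra = c(intra_ad$p, intra_ac$p),
    k_intra = c(intra_ad$slope, intra_ac$slope))

  list(organ = organ_rows, tumour = tumour_rows,
       inter_patient = list(ad = inter_ad, ac = inter_ac),
       intra_patient = list(ad = intra_ad, ac = intra_ac),
       filter = list(n_kept = filt$n_kept, n_excluded = filt$n_excluded))
}
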