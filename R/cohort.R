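# Synthetic patient cohort with known kinetics and ground-truth absorbed
# doses.  Emulates an 18-patient neuroendocrine-tumour therapy cohort:
# a Ga-68 PET snapshot about an hour after injection, four planar Lu-177
# scans over a week, and one quantitative SPECT near 22 h, with
# mono-exponential tumour kinetics whose population effective half-lives
# are grade-specific (103 h grade 1, 81 h grade 2).

#' Specification of a synthetic patient cohort
#'
#' Region kinetics are mono-exponential: the activity concentration per
#' injected activity is `c0 * exp(-lambda_eff * t)` with
#' `lambda_eff = ln 2 / t_eff`.  The Ga-68 uptake is assumed identical to
#' the Lu-177 uptake per injected activity (shared ligand), so the Ga-68
#' snapshot is the same `c0` propagated over the scan delay by the
#' biological clearance component only (physical decay of the respective
#' nuclide is removed by decay correction).
#'
#' Forward-modelled measurement biases (inverted later by the
#' quantification stage): PET tumour values are multiplied by the
#' background-aware recovery coefficient and the scanner SUV bias factor;
#' SPECT tumour values by the volume-only recovery coefficient; organ
#' SPECT values by a fixed organ RC.
#'
#' @param n_patients Number of patients.
#' @param tumours_per_patient Integer range `c(min, max)`; counts drawn
#'   uniformly.
#' @param tumour_volume_range Volume range in mL; volumes drawn
#'   log-uniformly.
#' @param grade_mix Fraction of grade-1 patients.
#' @param half_life_means Population effective half-lives in hours,
#'   `c(grade1, grade2)`.
#' @param half_life_cv Inter-subject coefficient of variation of the
#'   effective half-life.
#' @param uptake_meanlog,uptake_sdlog Log-normal parameters of the tumour
#'   AC/IA at t = 0 (1/mL).
#' @param organ_kinetics data.frame with columns `organ`, `c0` (AC/IA at
#'   t = 0, 1/mL) and `t_eff_h`.
#' @param eta_range Range of the PET tumour background-to-object ratio.
#' @param ga_scan_time_min Ga-68 PET time post injection (minutes).
#' @param planar_times_h Planar imaging times (hours p.i.).
#' @param spect_time_h SPECT imaging time (hours p.i.).
#' @param injected_activity_68,injected_activity_177 Injected activities (Bq).
#' @param weight_range Body-weight range (kg).
#' @param noise_cv Multiplicative log-normal noise CV applied to every
#'   region-level measurement; 0 gives exact model evaluations.
#' @param uptake_bend Factor (<= 1) applied to the first planar sample;
#'   values below 1 put the first point under the back-extrapolated
#'   exponential, exercising the non-trivial early curve segments.
#' @param rc_pet,rc_spect [rc_params()] used to forward-model partial
#'   volume losses.
#' @param suv_factor_68ga Scanner SUV bias applied to PET concentrations.
#' @param organ_rc_spect RC applied to kidney/spleen SPECT values.
#' @param seed Integer seed; all draws come from one generator.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 18,
                        tumours_per_patient = c(1, 8),
                        tumour_volume_range = c(0.8, 80),
                        grade_mix = 0.5,
                        half_life_means = c(grade1 = 103, grade2 = 81),
                        half_life_cv = 0.15,
                        uptake_meanlog = log(2e-4),
                        uptake_sdlog = 0.7,
                        organ_kinetics = data.frame(
                          organ = c("kidney_left", "kidney_right", "spleen", "liver"),
                          c0 = c(3e-5, 3e-5, 4e-5, 1.5e-5),
                          t_eff_h = c(50, 50, 70, 65)),
                        eta_range = c(0.05, 0.4),
                        ga_scan_time_min = 64,
                        planar_times_h = c(1, 24, 96, 168),
                        spect_time_h = 21.9,
                        injected_activity_68 = 0.17e9,
                        injected_activity_177 = 7.45e9,
                        weight_range = c(55, 95),
                        noise_cv = 0.05,
                        uptake_bend = 1,
                        rc_pet = rc_params(1.7, 1.4, 0.55),
                        rc_spect = rc_params(2.2, 1.1),
                        suv_factor_68ga = 0.94,
                        organ_rc_spect = 0.85,
                        seed = 1L) {
  stopifnot(n_patients >= 1,
            all(planar_times_h > 0), spect_time_h > 0, ga_scan_time_min > 0,
            all(half_life_means > 0), grade_mix >= 0, grade_mix <= 1,
            injected_activity_68 > 0, injected_activity_177 > 0,
            noise_cv >= 0, uptake_bend > 0, uptake_bend <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

draw_half_life <- function(mean_h, cv) {
  if (cv == 0) return(mean_h)
  s2 <- log(1 + cv^2)
  stats::rlnorm(1, meanlog = log(mean_h) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic patient cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of `patient_record` objects (class `cohort`).  Each
#'   record has `patient_id`, `grade`, `weight`, injected activities,
#'   a `tumours` data.frame, an `organs` data.frame, a `planar_series`
#'   data.frame (`region_id`, `time_h`, `signal`), and a `truth` block
#'   with the generating `c0`, `t_eff_h`, and closed-form `ad_per_ia`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  lambda_phys_lu <- log(2) / (HALF_LIFE_LU177_D * 24)  # 1/h
  t_ga_h <- spec$ga_scan_time_min / 60
  noise <- function(n) lognormal_factor(n, spec$noise_cv)

  patients <- lapply(seq_len(spec$n_patients), function(ip) {
    pid <- sprintf("P%02d", ip)
    grade <- if (stats::runif(1) < spec$grade_mix) 1L else 2L
    weight <- stats::runif(1, spec$weight_range[1], spec$weight_range[2])
    hl_mean <- spec$half_life_means[[grade]]

    n_t <- sample(seq(spec$tumours_per_patient[1], spec$tumours_per_patient[2]), 1)
    vol <- exp(stats::runif(n_t, log(spec$tumour_volume_range[1]),
                            log(spec$tumour_volume_range[2])))
    t_eff <- vapply(seq_len(n_t), function(i)
      draw_half_life(hl_mean, spec$half_life_cv), numeric(1))
    c0 <- stats::rlnorm(n_t, spec$uptake_meanlog, spec$uptake_sdlog)
    eta <- stats::runif(n_t, spec$eta_range[1], spec$eta_range[2])
    lambda_eff <- log(2) / t_eff
    lambda_bio <- pmax(lambda_eff - lambda_phys_lu, 0)

    # Ga-68 PET snapshot (decay-corrected to administration)
    ac68_true <- c0 * spec$injected_activity_68 * exp(-lambda_bio * t_ga_h)
    rc68 <- rc_full(vol, eta, spec$rc_pet)
    ac68_apparent <- spec$suv_factor_68ga * rc68 * ac68_true * noise(n_t)
    background68 <- spec$suv_factor_68ga * eta * ac68_true

    # Lu-177 SPECT snapshot (physical concentration at spect_time_h)
    ac177_true <- c0 * spec$injected_activity_177 * exp(-lambda_eff * spec$spect_time_h)
    vol_spect <- vol * noise(n_t)
    ac177_apparent <- rc_volume(vol_spect, spec$rc_spect) * ac177_true * noise(n_t)

    tumours <- data.frame(
      tumour_id = sprintf("%s_T%02d", pid, seq_len(n_t)),
      volume_pet = vol,          # segmentation assumed unbiased here
      volume_spect = vol_spect,
      eta_true = eta,
      ac68_apparent = ac68_apparent,
      background68 = background68,
      ac177_spect_apparent = ac177_apparent)

    organs <- spec$organ_kinetics
    organs$t_eff_h <- vapply(organs$t_eff_h, draw_half_life,
                             numeric(1), cv = spec$half_life_cv)
    organs$c0 <- organs$c0 * lognormal_factor(nrow(organs), 0.3)
    o_lambda <- log(2) / organs$t_eff_h
    o_lambda_bio <- pmax(o_lambda - lambda_phys_lu, 0)
    organs$ac68_apparent <- spec$suv_factor_68ga * organs$c0 *
      spec$injected_activity_68 * exp(-o_lambda_bio * t_ga_h) * noise(nrow(organs))
    organs$rc_spect <- ifelse(organs$organ == "liver", 1, spec$organ_rc_spect)
    organs$ac177_spect_apparent <- organs$rc_spect * organs$c0 *
      spec$injected_activity_177 * exp(-o_lambda * spec$spect_time_h) *
      noise(nrow(organs))

    # planar time series: arbitrary per-region scale, exponential shape
    regions <- data.frame(
      region_id = c(tumours$tumour_id, organs$organ),
      kind = c(rep("tumour", n_t), rep("organ", nrow(organs))),
      c0 = c(c0, organs$c0),
      t_eff_h = c(t_eff, organs$t_eff_h))
    planar <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      scale_i <- stats::rlnorm(1, 0, 0.3)   # planar units are arbitrary
      lam <- log(2) / regions$t_eff_h[i]
      sig <- scale_i * regions$c0[i] * exp(-lam * spec$planar_times_h)
      sig[1] <- sig[1] * spec$uptake_bend
      data.frame(region_id = regions$region_id[i],
                 kind = regions$kind[i],
                 time_h = spec$planar_times_h,
                 signal = sig * noise(length(sig)))
    }))

    truth <- data.frame(
      region_id = regions$region_id,
      kind = regions$kind,
      c0 = regions$c0,
      t_eff_h = regions$t_eff_h,
      ad_per_ia = ad_per_ia_monoexp(regions$c0, regions$t_eff_h))

    structure(list(patient_id = pid, grade = grade, weight = weight,
                   injected_activity_68 = spec$injected_activity_68,
                   injected_activity_177 = spec$injected_activity_177,
                   spect_time_h = spec$spect_time_h,
                   ga_scan_time_min = spec$ga_scan_time_min,
                   tumours = tumours, organs = organs,
                   planar_series = planar, truth = truth),
              class = "patient_record")
  })
  structure(patients, class = "cohort", spec = spec)
}

#' @export
print.cohort <- function(x, ...) {
  nt <- sum(vapply(x, function(p) nrow(p$tumours), integer(1)))
  cat("<cohort> ", length(x), " patients, ", nt, " tumours\n", sep = "")
  invisible(x)
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> ", x$patient_id, " grade ", x$grade, ", ",
      nrow(x$tumours), " tumour(s)\n", sep = "")
  invisible(x)
}

#' Flatten a cohort's tumour truth and measurements to one table
#' @param cohort A `cohort`.
#' @return data.frame, one row per tumour.
#' @export
cohort_tumour_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    tr <- p$truth[p$truth$kind == "tumour", ]
    cbind(patient_id = p$patient_id, grade = p$grade, weight = p$weight,
          p$tumours,
          truth_c0 = tr$c0, truth_t_eff_h = tr$t_eff_h,
          truth_ad_per_ia = tr$ad_per_ia)
  }))
}

#' Synthetic planar ROI pixel patch
#'
#' Fixture generator for the planar region-value rules: a rectangular
#' pixel patch with a given mean signal and multiplicative log-normal
#' spread.
#'
#' @param region_kind `"organ"` or `"tumour"`.
#' @param mean_signal Mean pixel value.
#' @param n_pixels Number of pixels (>= 5 for tumour patches, where the
#'   five-highest-pixel rule applies).
#' @param noise_cv Relative spread; 0 gives a constant patch.
#' @param seed Integer seed.
#' @return A numeric matrix.
#' @export
make_planar_patch <- function(region_kind = c("organ", "tumour"),
                              mean_signal, n_pixels, noise_cv = 0,
                              seed = 1L) {
  region_kind <- match.arg(region_kind)
  if (region_kind == "tumour" && n_pixels < 5)
    stop("tumour patches need >= 5 pixels (five-highest-pixel rule)")
  if (n_pixels < 1) stop("'n_pixels' must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vals <- mean_signal * lognormal_factor(n_pixels, noise_cv)
  nr <- max(1L, floor(sqrt(n_pixels)))
  nc <- ceiling(n_pixels / nr)
  m <- matrix(NA_real_, nr, nc)
  m[seq_len(n_pixels)] <- vals
  m
}
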