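test_that("planar region values follow the organ and tumour rules", {
  expect_equal(planar_region_value(matrix(10, 3, 3), "organ",
                                   thigh_background = 4), 6)
  expect_equal(planar_region_value(1:7, "tumour"), mean(3:7))
  expect_warning(v <- planar_region_value(matrix(2, 2, 2), "organ",
                                          thigh_background = 5), "clipped")
  expect_equal(v, 0)
  expect_error(planar_region_value(1:4, "tumour"), ">= 5 pixels")
})

test_that("organ curve fit is exact on exact mono-exponential samples", {
  t <- c(1, 24, 96, 168)
  y <- 100 * exp(-log(2) / 103 * t)
  fit <- fit_organ_curve(data.frame(time_h = t, signal = y))
  expect_equal(fit$tail_A, 100, tolerance = 1e-6)
  expect_equal(fit$t_eff, 103, tolerance = 1e-6)
  expect_equal(fit$t_eff, log(2) / fit$tail_lambda)
  expect_equal(fit$t_switch, 24)
  # early segment interpolates the first two samples and anchors at origin
  expect_equal(predict(fit, c(0, 1, 24)), c(0, y[1], y[2]), tolerance = 1e-9)
  # rising tail is refused
  expect_error(fit_organ_curve(data.frame(time_h = t, signal = rev(y)),
                               region = "kidney"), "kidney")
})

test_that("noisy organ tail fits recover the decay constant (median over replicates)", {
  t <- c(1, 24, 96, 168)
  lam <- log(2) / 103
  set.seed(404)
  lams <- replicate(300, {
    y <- 100 * exp(-lam * t) * exp(rnorm(4, 0, 0.05))
    fit_organ_curve(data.frame(time_h = t, signal = y))$tail_lambda
  })
  expect_lt(abs(median(lams) / lam - 1), 0.15)
})

test_that("tumour curve uses the quadratic only for genuine uptake shapes", {
  t <- c(1, 24, 96, 168)
  # rising early data (uptake still ongoing at 1 h): quadratic retained
  y_up <- c(5, 95, 95 * exp(-log(2) / 90 * 72), 95 * exp(-log(2) / 90 * 144))
  fit_up <- fit_tumour_curve(data.frame(time_h = t, signal = y_up))
  expect_equal(fit_up$early$type, "quadratic")
  expect_equal(predict(fit_up, c(1, 24)), y_up[1:2], tolerance = 1e-9)
  # samples on a line through the origin: quadratic coefficient ~ 0
  y_lin <- c(4, 96, 96 * exp(-log(2) / 80 * 72), 96 * exp(-log(2) / 80 * 144))
  fit_lin <- fit_tumour_curve(data.frame(time_h = t, signal = y_lin))
  expect_equal(fit_lin$early$type, "quadratic")
  expect_lt(abs(fit_lin$early$c), 1e-12)
  # decaying early data: interpolating parabola overshoots, fall back
  y_dec <- 100 * exp(-log(2) / 103 * t)
  fit_dec <- fit_tumour_curve(data.frame(time_h = t, signal = y_dec))
  expect_equal(fit_dec$early$type, "pwlinear")
  expect_equal(fit_dec$early$fallback, "overshoot")
  expect_equal(fit_dec$t_eff, 103, tolerance = 1e-6)
})

test_that("analytic curve integrals match adaptive quadrature on random curves", {
  set.seed(505)
  for (rep in 1:200) {
    t <- c(1, 24, 96, 168)
    lam <- log(2) / runif(1, 30, 150)
    a <- runif(1, 10, 200)
    bend <- runif(1, 0.3, 1)
    y <- a * exp(-lam * t); y[1] <- y[1] * bend
    fit <- if (rep %% 2) fit_organ_curve(data.frame(time_h = t, signal = y))
           else fit_tumour_curve(data.frame(time_h = t, signal = y))
    analytic <- lutadose:::integrate_tac(fit)
    quad <- integrate(function(tt) predict(fit, tt), 0, fit$t_switch,
                      rel.tol = 1e-11)$value +
      integrate(function(tt) fit$tail_A * exp(-fit$tail_lambda * tt),
                fit$t_switch, Inf, rel.tol = 1e-11)$value
    expect_lt(abs(analytic / quad - 1), 1e-6)
  }
})

test_that("dose rate under local energy deposition matches dimensional analysis", {
  # 1e6 Bq/mL x 147.9 keV = 1e6 * 147.9 * 1.602176634e-16 J/(s mL);
  # divide by 1.04e-3 kg/mL -> Gy/s; x 3600 -> Gy/h
  oracle <- 1e6 * 147.9 * 1.602176634e-16 / 1.04e-3 * 3600
  expect_equal(dose_rate_local(1e6), oracle, tolerance = 1e-12)
  expect_equal(dose_rate_local(0), 0)
  expect_equal(dose_rate_local(2e6), 2 * dose_rate_local(1e6))
})

test_that("rescale-and-integrate reduces to d0/lambda for a pure exponential", {
  lam <- log(2) / 90
  curve <- monoexp_tac(50, lam)
  res <- rescale_and_integrate(curve, dose_rate_at_spect = 0.2, t_spect = 0)
  expect_equal(res$ad_per_ia, 0.2 / lam, tolerance = 1e-12)
  expect_lt(res$quadrature_rel_diff, 1e-6)
  expect_error(rescale_and_integrate(monoexp_tac(1, lam), 0.1, 1e5),
               "not positive")
})

test_that("scale-1 rescaling equals the hand-integrated piecewise curve", {
  t <- c(2, 20, 90, 160)
  y <- c(3, 60, 60 * exp(-log(2) / 70 * 70), 60 * exp(-log(2) / 70 * 140))
  fit <- fit_tumour_curve(data.frame(time_h = t, signal = y))
  stopifnot(fit$early$type == "quadratic")
  cv <- predict(fit, 21)
  res <- rescale_and_integrate(fit, cv, 21)   # scale exactly 1
  b <- fit$early$b; cc <- fit$early$c
  hand <- b * 20^2 / 2 + cc * 20^3 / 3 +
    fit$tail_A * exp(-fit$tail_lambda * 20) / fit$tail_lambda
  expect_equal(res$ad_per_ia, hand, tolerance = 1e-12)
})

test_that("absorbed dose is invariant to the arbitrary planar signal scale", {
  co <- make_cohort(exact_cohort_spec(seed = 41, n_patients = 2))
  q <- quantify_cohort(co)
  d1 <- hybrid_dose_cohort(co, q)
  co2 <- co
  for (i in seq_along(co2))
    co2[[i]]$planar_series$signal <- co2[[i]]$planar_series$signal * 37.5
  d2 <- hybrid_dose_cohort(co2, q)
  expect_equal(d1$ad_per_ia, d2$ad_per_ia, tolerance = 1e-12)
})

test_that("off-schedule SPECT re-timing uses the planar effective half-life", {
  expect_equal(retime_spect(10, 22.3, 22.3, 103), 10)
  expect_equal(retime_spect(10, 125.3, 22.3, 103), 20)
  expect_equal(retime_spect(7, 94.6, 22.3, 103), 7 * 2^(72.3 / 103))
  expect_error(retime_spect(1, 2, 1, 0), "> 0")
})

test_that("noiseless cohort dosimetry reproduces closed-form doses within 2%", {
  co <- make_cohort(exact_cohort_spec(seed = 51, n_patients = 6))
  q <- quantify_cohort(co)
  d <- hybrid_dose_cohort(co, q)
  expect_true(all(d$quadrature_rel_diff < 1e-6))
  expect_lt(max(abs(d$ad_per_ia / d$truth_ad_per_ia - 1)), 0.02)
  # fitted effective half-lives equal the generating ones
  for (p in co) {
    dp <- d[d$patient_id == p$patient_id, ]
    tr <- p$truth[match(dp$region_id, p$truth$region_id), ]
    expect_equal(dp$t_eff_h, tr$t_eff_h, tolerance = 1e-6)
  }
})

test_that("dosimetry is exact when the curve is the mono-exponential itself", {
  # bypass the early-segment approximation entirely
  c0 <- 2e-4; t_eff <- 103; ia <- 7.45e9; t_sp <- 21.9
  lam <- log(2) / t_eff
  curve <- monoexp_tac(c0 * exp(-lam * 0), lam)  # amplitude arbitrary anyway
  ac_sp <- c0 * ia * exp(-lam * t_sp)
  rate <- dose_rate_local(ac_sp) / (ia / 1e9)
  res <- rescale_and_integrate(curve, rate, t_sp)
  expect_equal(res$ad_per_ia, lutadose:::ad_per_ia_monoexp(c0, t_eff),
               tolerance = 1e-9)
})
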