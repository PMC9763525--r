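test_that("Pearson correlation matches cor.test and lm as oracles", {
  set.seed(81)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  res <- cor_pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  cf <- coef(lm(y ~ x))
  expect_equal(res$slope, unname(cf[2]), tolerance = 1e-12)
  expect_equal(res$intercept, unname(cf[1]), tolerance = 1e-12)
  # exact linearity and symmetry
  expect_equal(cor_pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(cor_pearson(y, x)$r, res$r, tolerance = 1e-12)
  expect_error(cor_pearson(x, rep(1, 20)), "zero variance")
})

test_that("weighted correlation with integer weights equals replication", {
  set.seed(82)
  x <- rnorm(8); y <- 0.5 * x + rnorm(8)
  w <- sample(1:4, 8, replace = TRUE)
  res_w <- cor_weighted(x, y, w)
  res_rep <- cor_pearson(rep(x, w), rep(y, w))
  expect_equal(res_w$r, res_rep$r, tolerance = 1e-12)
  expect_equal(res_w$slope, res_rep$slope, tolerance = 1e-12)
  expect_equal(res_w$intercept, res_rep$intercept, tolerance = 1e-12)
  # equal weights reduce to plain Pearson, including the p-value
  res_eq <- cor_weighted(x, y, rep(2, 8))
  res_pl <- cor_pearson(x, y)
  expect_equal(res_eq$r, res_pl$r, tolerance = 1e-12)
  expect_equal(res_eq$p, res_pl$p, tolerance = 1e-12)
  expect_equal(cor_weighted(x, 3 * x - 2, w)$r, 1, tolerance = 1e-12)
  # weighted slope matches weighted least squares
  expect_equal(res_w$slope, unname(coef(lm(y ~ x, weights = w))[2]),
               tolerance = 1e-12)
})

test_that("repeated-measures correlation matches a dummy-variable regression oracle", {
  set.seed(83)
  for (rep in 1:5) {
    sub <- rep(sprintf("S%d", 1:6), times = sample(2:6, 6, replace = TRUE))
    n <- length(sub)
    off <- rnorm(6, sd = 2)
    x <- rnorm(n)
    y <- 0.7 * x + rnorm(n, sd = 0.8) + off[as.integer(factor(sub))]
    res <- cor_rm(sub, x, y)
    # oracle: explicit subject dummies; r^2 from the drop in residual SS
    full <- lm(y ~ x + factor(sub))
    null <- lm(y ~ factor(sub))
    ss_full <- sum(residuals(full)^2)
    ss_null <- sum(residuals(null)^2)
    r_oracle <- sign(coef(full)[["x"]]) * sqrt((ss_null - ss_full) / ss_null)
    expect_equal(res$r, r_oracle, tolerance = 1e-10)
    expect_equal(res$slope, coef(full)[["x"]], tolerance = 1e-10)
    df <- n - 6 - 1
    t_or <- r_oracle * sqrt(df / (1 - r_oracle^2))
    expect_equal(res$p, 2 * pt(-abs(t_or), df), tolerance = 1e-10)
  }
})

test_that("repeated-measures correlation is exact on parallel lines", {
  sub <- rep(c("A", "B"), each = 4)
  x <- c(1, 2, 3, 4, 2, 4, 6, 8)
  y <- 3 * x + ifelse(sub == "A", 10, -5)
  res <- cor_rm(sub, x, y)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$slope, 3, tolerance = 1e-12)
  # per-subject constant shifts leave r unchanged
  y2 <- y + ifelse(sub == "A", 100, -40)
  expect_equal(cor_rm(sub, x, y2)$r, res$r, tolerance = 1e-12)
  # singleton subjects are dropped with a warning
  expect_warning(res2 <- cor_rm(c(sub, "C"), c(x, 9), c(y, 1)), "singleton")
  expect_equal(res2$r, res$r, tolerance = 1e-12)
  expect_error(suppressWarnings(cor_rm(c("A", "B"), 1:2, 1:2)), ">= 2 subjects")
})

test_that("leave-one-out interval recomputes once per unit", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2.0, 4.1, 5.9, 8.05))
  iv <- loo_interval(d, function(s) cor_pearson(s$x, s$y))
  expect_length(iv, 2)
  expect_gt(iv[1], 0.99)
  # perfectly linear data: interval collapses at 1
  dl <- data.frame(x = 1:6, y = 2 * (1:6) + 3)
  expect_equal(loo_interval(dl, function(s) cor_pearson(s$x, s$y)), c(1, 1),
               tolerance = 1e-12)
  # an outlier that drives r: interval must contain the outlier-free r
  do <- data.frame(x = c(1, 1.1, 0.9, 1.05, 0.95, 10),
                   y = c(1.2, 0.8, 1.1, 0.9, 1.0, 10))
  r_all <- cor_pearson(do$x, do$y)$r
  r_wo <- cor_pearson(do$x[-6], do$y[-6])$r
  iv_o <- loo_interval(do, function(s) cor_pearson(s$x, s$y))
  expect_gt(r_all, 0.9)
  expect_true(iv_o[1] <= r_wo && r_wo <= iv_o[2])
  expect_gt(iv_o[2] - iv_o[1], 0.5)
  # grouped units: one recomputation per patient
  dg <- data.frame(pid = rep(1:4, each = 2), x = rnorm(8), y = rnorm(8))
  iv_g <- loo_interval(dg, function(s) cor_pearson(s$x, s$y), unit_col = "pid")
  expect_length(iv_g, 2)
  expect_error(loo_interval(d[1:3, ], function(s) cor_pearson(s$x, s$y)),
               ">= 4")
})

test_that("log-ratio Bland-Altman matches its closed form", {
  # exact agreement
  r0 <- log_ratio_bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$mean_deviation_pct, 0)
  expect_equal(c(r0$ci_low_pct, r0$ci_high_pct), c(0, 0))
  # constant factor 2: +100% with zero-width interval
  r2 <- log_ratio_bland_altman(2 * c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$mean_deviation_pct, 100, tolerance = 1e-12)
  expect_equal(r2$ci_low_pct, 100, tolerance = 1e-12)
  # Monte-Carlo vs closed form at mu = 0.1, sigma = 0.5
  set.seed(84)
  d <- rnorm(1e5, 0.1, 0.5)
  r <- log_ratio_bland_altman(exp(d), rep(1, 1e5))
  expect_lt(abs(r$mean_deviation_pct - (exp(0.1) - 1) * 100), 0.5)
  expect_lt(abs(r$ci_low_pct / ((exp(0.1 - 1.96 * 0.5) - 1) * 100) - 1), 0.05)
  expect_lt(abs(r$ci_high_pct / ((exp(0.1 + 1.96 * 0.5) - 1) * 100) - 1), 0.05)
  # round trip: reported bounds invert to the log-scale statistics
  expect_equal(log(r$mean_deviation_pct / 100 + 1), r$log_mean, tolerance = 1e-12)
  expect_equal(log(r$ci_high_pct / 100 + 1), r$log_mean + r$z * r$log_sd,
               tolerance = 1e-12)
  expect_error(log_ratio_bland_altman(c(1, -1), c(1, 1)), "> 0")
})

test_that("patient-level agreement averages tumour doses per patient first", {
  pid <- c("P1", "P1", "P2", "P2")
  pred <- c(2, 4, 3, 3)
  meas <- c(1, 2, 3, 3)
  r <- log_ratio_bland_altman(pred, meas, "patient", patient_id = pid)
  # patient means: P1 3/1.5 = 2, P2 3/3 = 1
  expect_equal(r$n, 2)
  expect_equal(r$log_mean, mean(c(log(2), 0)), tolerance = 1e-12)
})

test_that("tumour volume filter is strict at the cutoff", {
  rec <- data.frame(tumour_id = 1:4, volume_pet = c(4.9, 5.0, 5.1, NA))
  f <- filter_tumours(rec)
  expect_equal(f$kept$tumour_id, 3L)          # 5.0 excluded: strict >
  expect_equal(f$n_kept, 1)
  expect_equal(f$n_excluded, 3)
  expect_true("missing volume" %in% f$excluded$exclusion_reason)
  expect_equal(filter_tumours(rec[1:3, ], 0)$n_kept, 3)
  # count matches a brute-force count on a generated cohort
  co <- make_cohort(cohort_spec(n_patients = 10, seed = 91))
  tt <- cohort_tumour_table(co)
  f2 <- filter_tumours(tt)
  expect_equal(f2$n_kept, sum(tt$volume_pet > 5))
})

test_that("kidney averaging handles a missing side", {
  expect_equal(kidney_average(2, 4), 3)
  expect_equal(kidney_average(5, 5), 5)
  one <- kidney_average(NA, 7)
  expect_equal(as.numeric(one), 7)
  expect_true(attr(one, "single_kidney"))
  expect_error(kidney_average(NA, NA), "missing")
})
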