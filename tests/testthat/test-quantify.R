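test_that("VOI statistics match a brute-force loop oracle", {
  set.seed(17)
  vals <- array(runif(6 * 5 * 4), c(6, 5, 4))
  labs <- array(0L, c(6, 5, 4))
  labs[2:4, 2:3, 2:3] <- 1L
  labs[6, 5, 4] <- 2L
  img <- voxel_image(vals, 2)
  msk <- label_mask(labs, data.frame(label = 1:2, region = c("a", "b")), 2)
  st <- voi_stats(img, msk, 1L)
  # loop oracle
  tot <- 0; mx <- -Inf; cnt <- 0
  for (i in 1:6) for (j in 1:5) for (k in 1:4) if (labs[i, j, k] == 1L) {
    tot <- tot + vals[i, j, k]; mx <- max(mx, vals[i, j, k]); cnt <- cnt + 1
  }
  vv <- 2^3 / 1000
  expect_equal(st$total, tot * vv)
  expect_equal(st$max, mx)
  expect_equal(st$mean, tot / cnt)
  expect_equal(st$volume, cnt * vv)
  expect_equal(st$mean, st$total / st$volume)  # mean-total identity
  # single voxel region
  st2 <- voi_stats(img, msk, 2L)
  expect_equal(st2$total, vals[6, 5, 4] * vv)
  expect_error(voi_stats(img, msk, 3L), "empty")
})

test_that("decay correction doubles per half-life and round-trips", {
  expect_equal(decay_correct(10, 68, 68), 20)
  expect_equal(decay_correct(10, 0, 68), 10)
  v <- 123.4
  decayed <- v * 2^(-35 / 68)
  expect_equal(decay_correct(decayed, 35, 68), v, tolerance = 1e-12)
  expect_error(decay_correct(1, 1, -2), "> 0")
})

test_that("AC/IA and SUV follow their definitions", {
  expect_equal(ac_per_ia(1000, 1e6), 1e-3)
  expect_equal(ac_per_ia(0, 1e6), 0)
  expect_error(ac_per_ia(1, 0), "> 0")
  expect_equal(suv(5000, 1e8, 80), 4.0)
  # whole-body VOI of a uniform unit-density body holding all activity:
  # concentration = IA / (weight in g / 1 g/mL) => SUV = 1
  ia <- 7.4e9; wt <- 70
  expect_equal(suv(ia / (wt * 1000), ia, wt), 1.0)
  expect_error(suv(1, 1e6, 0), "> 0")
})

test_that("scanner SUV calibration divides by the configured factor", {
  expect_equal(apply_suv_calibration(94, calibration_config()), 100)
  expect_equal(apply_suv_calibration(7, calibration_config(suv_factor_68ga = 1)), 7)
  cal <- calibration_config(suv_factor_68ga = 0.9)
  expect_equal(apply_suv_calibration(9, cal), 10)
})

test_that("background shell estimation excludes other lesions", {
  labs <- array(0L, c(20, 20, 12))
  labs[8:12, 8:12, 5:8] <- 1L
  labs[8:12, 15:17, 5:8] <- 2L        # neighbouring lesion
  vals <- array(0.4, dim(labs))
  vals[labs == 1L] <- 1
  vals[labs == 2L] <- 5               # hot neighbour must not leak in
  img <- voxel_image(vals, 3.65)
  msk <- label_mask(labs, data.frame(label = 1:2, region = c("t1", "t2")), 3.65)
  expect_equal(estimate_background(img, msk, 1L), 0.4, tolerance = 1e-12)
  expect_error(estimate_background(img, msk, 3L), "empty")
})

test_that("background estimate on a blurred phantom is close to truth", {
  ph <- make_sphere_phantom(small_phantom_spec(eta = 0.4))
  img <- blur_and_noise(ph$truth, 6.4)
  bg <- estimate_background(img, ph$mask, 2L)
  expect_lt(abs(bg / (0.4 * 1e5) - 1), 0.05)
})

test_that("PET tumour PVC handles its degenerate regimes", {
  rcp <- rc_params(2, 1.2, 0.6)
  vmap <- list(a0 = 0, a1 = 1, a2 = 0, a3 = 0)
  # zero background: single-step Eq. 2 regime
  r <- pvc_tumour_pet(80, 10, 0, rcp, vmap)
  expect_equal(r$ac_corrected, 80 / rc_volume(10, rcp), tolerance = 1e-9)
  expect_equal(r$eta_hat, 0)
  # uniform field: apparent equals background, corrected = apparent
  expect_warning(u <- pvc_tumour_pet(50, 10, 50, rcp, vmap), "clamped")
  expect_equal(u$eta_hat, 1)
  expect_equal(u$ac_corrected, 50, tolerance = 1e-9)
  expect_lte(u$iterations, 2)
})

test_that("PET tumour PVC converges fast and is start-independent", {
  rcp <- rc_params(2, 1.2, 0.6)
  vmap <- list(a0 = 0.2, a1 = 1.05, a2 = -0.3, a3 = 0.02)
  truth_c <- 1e5
  for (eta in c(0.1, 0.3, 0.6)) {
    vp <- 8
    vs <- (vp - 0.2 + 0.3 * eta) / (1.05 + 0.02 * eta)  # invert the map
    apparent <- rc_full(vp, eta, rcp) * truth_c
    r1 <- pvc_tumour_pet(apparent, vs, eta * truth_c, rcp, vmap)
    expect_lt(r1$iterations, 20)
    expect_lt(abs(r1$ac_corrected / truth_c - 1), 1e-5)
    r2 <- pvc_tumour_pet(apparent, vs, eta * truth_c, rcp, vmap,
                         start = apparent * 10)
    expect_lt(abs(r2$ac_corrected / r1$ac_corrected - 1), 1e-5)
  }
})

test_that("SPECT tumour and organ PVC follow the volume-only model", {
  rcs <- rc_params(2.2, 1.1)
  expect_equal(pvc_tumour_spect(70, 1e6, rcs), 70, tolerance = 1e-5)
  expect_equal(pvc_tumour_spect(70, 2.2, rcs), 140)   # V = alpha halves RC
  expect_error(pvc_tumour_spect(70, 0.01, rcs), "floor")
  expect_equal(pvc_organ(85, 0.85), 100)
  expect_equal(pvc_organ(12, 1), 12)
  expect_error(pvc_organ(1, 1.2), "in \\(0, 1\\]")
})

test_that("end-to-end phantom quantification recovers truth within 5%", {
  cal <- run_calibration(seed = 1)
  for (eta in c(0, 0.4, 0.8)) {
    ph <- make_sphere_phantom(phantom_spec(background_ratio = eta))
    img <- blur_and_noise(ph$truth, 6.4)
    m <- measure_spheres(img, ph$mask, 1e5)
    for (i in which(m$v_physical >= 5)) {
      bg <- estimate_background(img, ph$mask, m$label[i])
      r <- pvc_tumour_pet(m$apparent_concentration[i], m$v_segmented[i], bg,
                          cal$rc_pet, cal$volume_map)
      expect_lt(abs(r$ac_corrected / 1e5 - 1), 0.05)
    }
  }
})

test_that("SUV equals AC/IA without PVC times body weight on cohort records", {
  co <- make_cohort(cohort_spec(n_patients = 3, seed = 21))
  q <- quantify_cohort(co)
  for (p in co) {
    qi <- q[q$patient_id == p$patient_id & q$kind == "tumour", ]
    cal <- calibration_config(suv_factor_68ga = attr(co, "spec")$suv_factor_68ga)
    ac_no_pvc <- apply_suv_calibration(p$tumours$ac68_apparent, cal)
    expect_equal(qi$suv_mean,
                 ac_per_ia(ac_no_pvc, p$injected_activity_68) * p$weight * 1000,
                 tolerance = 1e-12)
  }
})

test_that("cohort quantification inverts the forward-modelled biases", {
  co <- make_cohort(exact_cohort_spec(seed = 31))
  q <- quantify_cohort(co)
  tt <- cohort_tumour_table(co)
  qt <- q[q$kind == "tumour", ]
  expect_equal(qt$region_id, tt$tumour_id)
  # Ga-68: corrected concentration equals c0 * IA68 up to biological decay
  lam_bio <- log(2) / tt$truth_t_eff_h - log(2) / (6.647 * 24)
  expected <- tt$truth_c0 * co[[1]]$injected_activity_68 *
    exp(-lam_bio * co[[1]]$ga_scan_time_min / 60)
  expect_equal(qt$ac68_corrected, expected, tolerance = 1e-6)
  # Lu-177: decay-corrected AC/IA equals c0 * exp(-lambda_bio * t_spect)
  lam_eff <- log(2) / tt$truth_t_eff_h
  lam_phys <- log(2) / (6.647 * 24)
  expect_equal(qt$ac177_per_ia,
               tt$truth_c0 * exp(-(lam_eff - lam_phys) * co[[1]]$spect_time_h),
               tolerance = 1e-6)
})
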