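# Partial-volume recovery models and their calibration.
#
# Two parametric models are used.  The volume-only recovery coefficient
#   R0(Vp) = 1 / (1 + (alpha/Vp)^beta)
# describes spill-out for an object of physical volume Vp in a cold
# background.  The background-aware extension
#   R(Vp, eta) = R0 + (1 - R0) f eta + (1 - R0) (1 - f) eta^2
# adds spill-in from a background at object-to-background concentration
# ratio eta, with f in [0, 1]; R(Vp, 0) = R0(Vp) and R(Vp, 1) = 1.
# A bilinear map  Vp = a0 + a1 Vs + a2 eta + a3 Vs eta  corrects
# segmentation volume bias.

#' Recovery-coefficient parameters
#'
#' @param alpha Volume scale in mL (> 0).
#' @param beta Dimensionless shape exponent (> 0).
#' @param f Background-mixing fraction in `[0, 1]`; may be `NA` when only
#'   cold-background (eta = 0) data were used.
#' @return An object of class `rc_params`.
#' @export
rc_params <- function(alpha, beta, f = NA_real_) {
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (beta <= 0) stop("'beta' must be > 0")
  if (!is.na(f) && (f < 0 || f > 1)) stop("'f' must be in [0, 1]")
  structure(list(alpha = alpha, beta = beta, f = f), class = "rc_params")
}

#' @export
print.rc_params <- function(x, ...) {
  cat("Recovery-coefficient parameters:\n")
  cat(sprintf("  alpha = %.4g mL,  beta = %.4g,  f = %s\n",
              x$alpha, x$beta,
              if (is.na(x$f)) "NA (cold-background fit)" else sprintf("%.4g", x$f)))
  invisible(x)
}

#' Volume-only recovery coefficient
#'
#' @param v_physical Physical object volume(s) in mL (> 0).
#' @param params An [rc_params()] object (or list with `alpha`, `beta`).
#' @return Recovery coefficient(s) in (0, 1), increasing in volume.
#' @export
rc_volume <- function(v_physical, params) {
  if (any(v_physical <= 0)) stop("'v_physical' must be > 0")
  1 / (1 + (params$alpha / v_physical)^params$beta)
}

#' Background-aware recovery coefficient
#'
#' @inheritParams rc_volume
#' @param eta Background-to-object concentration ratio(s), >= 0.
#' @return Recovery coefficient(s); equals [rc_volume()] at `eta = 0` and
#'   is identically 1 at `eta = 1`.
#' @export
rc_full <- function(v_physical, eta, params) {
  if (any(eta < 0)) stop("'eta' must be >= 0")
  f <- params$f
  if (is.na(f)) stop("'params$f' is NA; fit with background data first")
  r0 <- rc_volume(v_physical, params)
  r0 + (1 - r0) * f * eta + (1 - r0) * (1 - f) * eta^2
}

#' Fit the background-aware recovery model to sphere measurements
#'
#' Nonlinear least squares (Levenberg--Marquardt) of observed recovery
#' `apparent / true` concentration against `rc_full(Vp, eta)`.  Bounds are
#' imposed by parameter transformation: log for `alpha` and `beta`,
#' logistic for `f`.  When every measurement has `eta = 0` the mixing
#' fraction is unidentifiable; only (`alpha`, `beta`) are fitted, `f` is
#' `NA` and the fit is flagged.
#'
#' @param measurements A data.frame with columns `v_physical`, `eta`, and
#'   either `recovery` or both `apparent_concentration` and
#'   `true_concentration`.
#' @param init Optional [rc_params()] starting values (default:
#'   `alpha` = median volume, `beta` = 1, `f` = 0.5).
#' @param maxiter Maximum Levenberg--Marquardt iterations.
#' @return An object of class `rc_fit` (also `rc_params`) with elements
#'   `alpha`, `beta`, `f`, `f_identifiable`, `residuals`, `residual_norm`,
#'   `fitted`, `data`, `convergence`.
#' @export
fit_rc <- function(measurements, init = NULL, maxiter = 200) {
  m <- as.data.frame(measurements)
  if (is.null(m$recovery))
    m$recovery <- m$apparent_concentration / m$true_concentration
  if (nrow(m) < 4) stop("need at least 4 measurements")
  if (length(unique(m$v_physical)) < 2)
    stop("need measurements at >= 2 distinct volumes")
  if (any(m$v_physical <= 0) || any(m$eta < 0)) stop("invalid measurements")
  eta_only_zero <- all(m$eta == 0)
  if (is.null(init))
    init <- rc_params(stats::median(m$v_physical), 1, 0.5)

  if (eta_only_zero) {
    par0 <- c(la = log(init$alpha), lb = log(init$beta))
    resid_fn <- function(p)
      m$recovery - rc_volume(m$v_physical, list(alpha = exp(p[1]), beta = exp(p[2])))
  } else {
    f0 <- if (is.na(init$f)) 0.5 else min(max(init$f, 1e-3), 1 - 1e-3)
    par0 <- c(la = log(init$alpha), lb = log(init$beta), g = stats::qlogis(f0))
    resid_fn <- function(p)
      m$recovery - rc_full(m$v_physical, m$eta,
                           list(alpha = exp(p[1]), beta = exp(p[2]),
                                f = stats::plogis(p[3])))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = maxiter))
  if (fit$info == 0 || fit$info == 9)
    stop("recovery fit did not converge (info = ", fit$info,
         "); best residual norm ", signif(sqrt(fit$deviance), 4))
  p <- fit$par
  out <- rc_params(exp(p[["la"]]), exp(p[["lb"]]),
                   if (eta_only_zero) NA_real_ else stats::plogis(p[["g"]]))
  out$f_identifiable <- !eta_only_zero
  if (eta_only_zero)
    warning("all measurements have eta = 0: 'f' is unidentifiable; ",
            "fitted volume-only model")
  out$residuals <- as.numeric(resid_fn(p))
  out$residual_norm <- sqrt(sum(out$residuals^2))
  out$fitted <- m$recovery - out$residuals
  out$data <- m
  out$convergence <- list(info = fit$info, message = fit$message,
                          iterations = fit$niter)
  class(out) <- c("rc_fit", "rc_params")
  out
}

#' @export
print.rc_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  fitted on %d measurements, residual norm %.3g\n",
              nrow(x$data), x$residual_norm))
  if (!x$f_identifiable)
    cat("  note: eta = 0 only; f unidentifiable\n")
  invisible(x)
}

#' @export
coef.rc_fit <- function(object, ...)
  c(alpha = object$alpha, beta = object$beta, f = object$f)

#' Predicted recovery for an `rc_fit`
#' @param object An `rc_fit`.
#' @param newdata data.frame with `v_physical` and `eta` (defaults to the
#'   training data).
#' @param ... unused.
#' @export
predict.rc_fit <- function(object, newdata = object$data, ...) {
  if (object$f_identifiable)
    rc_full(newdata$v_physical, newdata$eta, object)
  else
    rc_volume(newdata$v_physical, object)
}

#' Fit the segmentation volume map
#'
#' Ordinary least squares for `Vp = a0 + a1 Vs + a2 eta + a3 Vs eta`.
#'
#' @param pairs data.frame with columns `v_segmented`, `eta`, `v_physical`.
#' @return An object of class `volume_map` with coefficients `a0..a3` and
#'   the underlying `lm` fit.
#' @export
fit_volume_map <- function(pairs) {
  p <- as.data.frame(pairs)
  if (nrow(p) < 4) stop("need at least 4 design points")
  fit <- stats::lm(v_physical ~ v_segmented * eta, data = p)
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("rank-deficient design: volume-map coefficients not identifiable")
  structure(list(a0 = unname(cf[1]), a1 = unname(cf[2]),
                 a2 = unname(cf[3]), a3 = unname(cf[4]), lm = fit),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("Volume map: Vp = %.4g + %.4g Vs + %.4g eta + %.4g Vs*eta\n",
              x$a0, x$a1, x$a2, x$a3))
  invisible(x)
}

#' @export
coef.volume_map <- function(object, ...)
  c(a0 = object$a0, a1 = object$a1, a2 = object$a2, a3 = object$a3)

#' Apply the segmentation volume map
#'
#' Evaluates the bilinear map; results at or below zero are floored at
#' `floor_ml` with a warning, since the affine form can go non-positive
#' outside its calibration range.
#'
#' @param v_segmented Segmented volume(s) in mL.
#' @param eta Background-to-object concentration ratio(s).
#' @param params A `volume_map` or list with `a0..a3`.
#' @param floor_ml Minimum returned volume (mL).
#' @return Physical volume estimate(s) in mL.
#' @export
apply_volume_map <- function(v_segmented, eta, params, floor_ml = 0.1) {
  v <- params$a0 + params$a1 * v_segmented + params$a2 * eta +
    params$a3 * v_segmented * eta
  if (any(v <= 0)) {
    warning("volume map produced non-positive volume(s); floored at ",
            floor_ml, " mL")
    v <- pmax(v, floor_ml)
  }
  v
}

#' Organ recovery coefficient from a VOI mask
#'
#' The RC of an arbitrarily shaped region is the mean, over the region's
#' voxels, of the binary mask convolved with the Gaussian PSF.
#'
#' @param mask A `label_mask` or a logical/0-1 3-D array.
#' @param psf_fwhm PSF FWHM in mm (>= 0).
#' @param label Region label when `mask` is a `label_mask`.
#' @param voxel_size Required when `mask` is a plain array.
#' @return Scalar RC in (0, 1]; exactly 1 when `psf_fwhm = 0`.
#' @export
organ_rc_from_mask <- function(mask, psf_fwhm, label = NULL, voxel_size = NULL) {
  if (inherits(mask, "label_mask")) {
    if (is.null(label)) label <- mask$legend$label[1]
    bin <- mask$labels == label
    voxel_size <- mask$voxel_size
  } else {
    bin <- mask != 0
    if (is.null(voxel_size)) stop("'voxel_size' required for a plain array mask")
  }
  if (!any(bin)) stop("empty region")
  if (psf_fwhm < 0) stop("'psf_fwhm' must be >= 0")
  if (psf_fwhm == 0) return(1)
  sm <- gaussian_blur_array(array(as.numeric(bin), dim(bin)), psf_fwhm, voxel_size)
  mean(sm[bin])
}

#' Estimate the PSF FWHM by matched filtering
#'
#' Searches `fwhm_grid` for the Gaussian width minimising the squared
#' difference between the blurred truth image and the measured image, then
#' refines the minimum by parabolic interpolation through the three grid
#' points around it.
#'
#' @param measured,truth Aligned `voxel_image`s.
#' @param fwhm_grid Candidate FWHM values in mm (sorted, >= 0).
#' @return Estimated FWHM in mm.
#' @export
estimate_psf_fwhm <- function(measured, truth,
                              fwhm_grid = seq(2, 12, by = 0.5)) {
  stopifnot(inherits(measured, "voxel_image"), inherits(truth, "voxel_image"))
  if (!identical(dim(measured$values), dim(truth$values)))
    stop("images must share a grid")
  fwhm_grid <- sort(fwhm_grid)
  sse <- vapply(fwhm_grid, function(w) {
    sum((gaussian_blur_array(truth$values, w, truth$voxel_size) -
           measured$values)^2)
  }, numeric(1))
  i <- which.min(sse)
  if (i == 1L || i == length(fwhm_grid)) {
    if (i == 1L && fwhm_grid[1] == 0) return(0)
    stop("SSE minimum at grid boundary (", fwhm_grid[i],
         " mm); widen 'fwhm_grid'")
  }
  # parabolic refinement through (i-1, i, i+1)
  x <- fwhm_grid[(i - 1):(i + 1)]; y <- sse[(i - 1):(i + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  if (a <= 0) return(x[2])
  -b / (2 * a)
}

#' Measure spheres in a simulated phantom image
#'
#' Produces the sphere measurement table used for recovery calibration:
#' apparent concentration (mean of the measured image over the sphere
#' mask), observed recovery, and a segmented volume obtained by relative
#' thresholding (voxels above `threshold` of the way from background level
#' to the in-sphere maximum, within a dilated neighbourhood of the sphere).
#'
#' @param measured A blurred/noisy `voxel_image`.
#' @param mask The phantom `label_mask` (legend carries analytic volumes
#'   and eta).
#' @param true_concentration Sphere activity concentration in the truth.
#' @param threshold Relative segmentation threshold in (0, 1).
#' @return data.frame with columns `label`, `v_physical`, `v_segmented`,
#'   `eta`, `apparent_concentration`, `true_concentration`, `recovery`.
#' @export
measure_spheres <- function(measured, mask, true_concentration,
                            threshold = 0.5) {
  stopifnot(inherits(measured, "voxel_image"), inherits(mask, "label_mask"))
  vv <- voxel_volume_ml(mask)
  leg <- mask$legend
  bg_level <- leg$eta[1] * true_concentration
  out <- lapply(seq_len(nrow(leg)), function(i) {
    lab <- leg$label[i]
    idx <- region_indices(mask, lab)
    vals <- measured$values[idx]
    # segmentation neighbourhood: sphere mask dilated by 3 voxels,
    # excluding other spheres
    nb <- dilate_mask(mask$labels == lab, 3L) & (mask$labels %in% c(0L, lab))
    thr <- bg_level + threshold * (max(vals) - bg_level)
    vs <- sum(measured$values[nb] > thr) * vv
    data.frame(label = lab,
               v_physical = leg$volume_ml[i],
               v_segmented = vs,
               eta = leg$eta[i],
               apparent_concentration = mean(vals),
               true_concentration = true_concentration,
               recovery = mean(vals) / true_concentration)
  })
  do.call(rbind, out)
}

# Chebyshev binary dilation by n voxels (26-neighbourhood applied n times).
dilate_mask <- function(bin, n) {
  d <- dim(bin)
  out <- bin
  for (k in seq_len(n)) {
    acc <- out
    for (axis in 1:3) {
      sz <- d[axis]
      shp <- function(a, s) {
        r <- array(FALSE, d)
        if (s > 0) {
          if (axis == 1) r[(1 + s):sz, , ] <- a[1:(sz - s), , ]
          if (axis == 2) r[, (1 + s):sz, ] <- a[, 1:(sz - s), ]
          if (axis == 3) r[, , (1 + s):sz] <- a[, , 1:(sz - s)]
        } else {
          s <- -s
          if (axis == 1) r[1:(sz - s), , ] <- a[(1 + s):sz, , ]
          if (axis == 2) r[, 1:(sz - s), ] <- a[, (1 + s):sz, ]
          if (axis == 3) r[, , 1:(sz - s)] <- a[, , (1 + s):sz]
        }
        r
      }
      acc <- acc | shp(acc, 1L) | shp(acc, -1L)
    }
    out <- acc
  }
  out
}
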