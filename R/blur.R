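# Gaussian point-spread-function machinery shared by the phantom generator,
# the organ recovery calculation, and matched-filter FWHM estimation.

#' Convert a Gaussian FWHM to its standard deviation
#' @param fwhm Full width at half maximum (any length unit).
#' @return Standard deviation in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1-D discrete Gaussian kernel integrated over both the source and the
# target voxel box, so that convolving a voxel-wise constant signal gives
# the voxel average of the continuous convolution (the imaging model:
# a voxel reads out the mean signal over its extent).  Normalised to sum
# 1 so that separable convolution conserves total activity for interior
# objects.  Uses  Int Phi(z) dz = z Phi(z) + phi(z).
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  psi <- function(z) z * stats::pnorm(z) + stats::dnorm(z)
  r <- max(1L, ceiling(4 * sigma_vox + 1))
  x <- seq.int(-r, r)
  k <- sigma_vox * (psi((x + 1) / sigma_vox) - 2 * psi(x / sigma_vox) +
                      psi((x - 1) / sigma_vox))
  k / sum(k)
}

# Convolve a 3-D array along one axis with a symmetric kernel,
# zero padding outside the grid.  Implemented as a sum of shifted
# arrays: cheap for the short kernels used here.
convolve_axis <- function(a, kernel, axis) {
  nk <- length(kernel)
  if (nk == 1L) return(a * kernel)
  r <- (nk - 1L) %/% 2L
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  for (j in seq_len(nk)) {
    s <- j - r - 1L                       # source offset
    if (s >= 0) { dst <- seq_len(n - s); src <- dst + s }
    else        { src <- seq_len(n + s); dst <- src - s }
    if (length(dst) == 0L) next
    w <- kernel[j]
    if (axis == 1L) out[dst, , ] <- out[dst, , ] + w * a[src, , , drop = FALSE]
    else if (axis == 2L) out[, dst, ] <- out[, dst, ] + w * a[, src, , drop = FALSE]
    else out[, , dst] <- out[, , dst] + w * a[, , src, drop = FALSE]
  }
  out
}

# Separable isotropic Gaussian blur of a plain 3-D array.
gaussian_blur_array <- function(values, fwhm_mm, voxel_size) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(values)
  voxel_size <- rep_len(voxel_size, 3L)
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(fwhm_to_sigma(fwhm_mm) / voxel_size[axis])
    values <- convolve_axis(values, k, axis)
  }
  values
}

#' Blur a phantom image with the system PSF and add counting noise
#'
#' Applies an isotropic Gaussian point-spread function of the stated FWHM
#' and, optionally, scaled-Poisson counting noise: voxel values are scaled
#' to expected counts (`noise_scale` counts per voxel at `ref_concentration`),
#' integer counts are drawn, and the result is scaled back to Bq/mL.
#'
#' The blur conserves total activity for objects away from the grid
#' boundary because the discrete kernel is normalised to unit sum.
#'
#' @param truth A `voxel_image` of true activity concentration.
#' @param psf_fwhm PSF full width at half maximum in mm (>= 0).
#' @param noise_scale Expected counts per voxel at `ref_concentration`;
#'   0 disables noise.
#' @param seed Optional integer seed used only for the noise draw.
#' @param ref_concentration Concentration (Bq/mL) mapped to `noise_scale`
#'   counts; defaults to the image maximum.
#' @return A `voxel_image` of the simulated measured concentrations.
#' @export
blur_and_noise <- function(truth, psf_fwhm, noise_scale = 0, seed = NULL,
                           ref_concentration = max(truth$values)) {
  stopifnot(inherits(truth, "voxel_image"))
  if (psf_fwhm < 0) stop("'psf_fwhm' must be >= 0")
  if (noise_scale < 0) stop("'noise_scale' must be >= 0")
  vals <- gaussian_blur_array(truth$values, psf_fwhm, truth$voxel_size)
  if (noise_scale > 0) {
    if (ref_concentration <= 0) stop("'ref_concentration' must be > 0")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    expected <- vals / ref_concentration * noise_scale
    counts <- stats::rpois(length(expected), pmax(expected, 0))
    vals <- array(counts * ref_concentration / noise_scale, dim(vals))
  }
  voxel_image(vals, truth$voxel_size, truth$origin)
}
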