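#' Voxel image of activity concentration
#'
#' A minimal container for a 3-D grid of activity concentration values
#' (Bq/mL) together with the voxel size in mm.  All quantification and
#' phantom routines in the package operate on this class.
#'
#' @param values Numeric 3-D array of activity concentrations (Bq/mL).
#' @param voxel_size Voxel edge length(s) in mm; a scalar (isotropic) or a
#'   length-3 vector.
#' @param origin Position of the first voxel centre in mm (length 3).
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (!all(is.finite(values)))
    stop("'values' must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0))
    stop("'voxel_size' must be positive")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat("<voxel_image> ", paste(dim(x$values), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  value range: [", signif(min(x$values), 5), ", ",
      signif(max(x$values), 5), "] Bq/mL\n", sep = "")
  invisible(x)
}

#' Volume of one voxel in mL
#' @param img A `voxel_image` or `label_mask`.
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(img) prod(img$voxel_size) / 1000

#' Label mask aligned with a voxel image
#'
#' @param labels Integer 3-D array; 0 means unlabelled.
#' @param legend A data.frame with at least columns `label` and `region`;
#'   phantom masks also carry `volume_ml`, the analytic sphere volume.
#' @param voxel_size Voxel size in mm, as for [voxel_image()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, legend, voxel_size) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3-D array")
  storage.mode(labels) <- "integer"
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  structure(list(labels = labels, legend = legend, voxel_size = voxel_size),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", nrow(x$legend), " regions\n", sep = "")
  print(x$legend)
  invisible(x)
}

region_indices <- function(mask, label) {
  idx <- which(mask$labels == label)
  if (length(idx) == 0L) stop("empty region for label ", label)
  idx
}

#' Write / read voxel images as NIfTI-1 volumes
#'
#' Thin wrappers around \pkg{RNifti} preserving the voxel size.
#' @param img A `voxel_image`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_voxel_image` returns a `voxel_image`.
#' @export
write_voxel_image <- function(img, path) {
  nii <- RNifti::asNifti(img$values)
  RNifti::pixdim(nii) <- img$voxel_size
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_voxel_image
#' @export
read_voxel_image <- function(path) {
  nii <- RNifti::readNifti(path)
  voxel_image(array(as.numeric(nii), dim = dim(nii)),
              voxel_size = RNifti::pixdim(nii)[1:3])
}

#' @rdname write_voxel_image
#' @param mask A `label_mask`.
#' @export
write_label_mask <- function(mask, path) {
  nii <- RNifti::asNifti(mask$labels)
  RNifti::pixdim(nii) <- mask$voxel_size
  RNifti::writeNifti(nii, path)
  invisible(path)
}
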