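#' Construct a volume grid
#'
#' A `volume_grid` holds one hemisphere's scalar field (gray-matter density
#' in `[0, 1]`) on a regular 3D lattice together with a boolean mask of
#' in-brain voxels and a hemisphere label. Values outside the mask are
#' forced to zero, mirroring how gray-matter maps are thresholded before
#' analysis.
#'
#' @param values 3D numeric array of densities.
#' @param mask 3D logical array of the same shape; defaults to `values > 0`.
#' @param hemisphere `"LH"` or `"RH"`.
#' @param voxel_size_mm positive scalar edge length of a voxel.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, mask = NULL, hemisphere = c("LH", "RH"),
                        voxel_size_mm = 1.5) {
  hemisphere <- match.arg(hemisphere)
  if (length(dim(values)) != 3L) stop("'values' must be a 3D array")
  if (is.null(mask)) mask <- values > 0
  mask <- array(as.logical(mask), dim(values))
  if (!identical(dim(mask), dim(values))) stop("mask shape mismatch")
  if (!any(mask)) stop("mask is empty")
  if (!all(is.finite(values[mask]))) stop("non-finite values inside mask")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  values[!mask] <- 0
  structure(list(values = values, mask = mask, hemisphere = hemisphere,
                 voxel_size_mm = voxel_size_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s %s, %d/%d voxels in mask, range [%.3f, %.3f]>\n",
              x$hemisphere, paste(dim(x$values), collapse = "x"),
              sum(x$mask), length(x$mask),
              min(x$values[x$mask]), max(x$values[x$mask])))
  invisible(x)
}

#' Pair a subject's left and right hemisphere grids
#'
#' @param subject_id character id.
#' @param lh,rh `volume_grid` objects labelled LH and RH with identical
#'   shapes and voxel sizes.
#' @param covariates named list of per-subject scalars (age, sex, icv,
#'   batch, family_id, session_id -- any subset).
#' @return An object of class `hemisphere_pair`.
#' @export
hemisphere_pair <- function(subject_id, lh, rh, covariates = list()) {
  stopifnot(inherits(lh, "volume_grid"), inherits(rh, "volume_grid"))
  if (lh$hemisphere != "LH" || rh$hemisphere != "RH")
    stop("lh/rh hemisphere labels are wrong")
  if (!identical(dim(lh$values), dim(rh$values)))
    stop("lh and rh grids must share a shape")
  if (lh$voxel_size_mm != rh$voxel_size_mm)
    stop("lh and rh voxel sizes differ")
  structure(list(subject_id = as.character(subject_id), lh = lh, rh = rh,
                 covariates = covariates),
            class = "hemisphere_pair")
}

#' @export
print.hemisphere_pair <- function(x, ...) {
  cat(sprintf("<hemisphere_pair '%s' %s; covariates: %s>\n", x$subject_id,
              paste(dim(x$lh$values), collapse = "x"),
              if (length(x$covariates)) paste(names(x$covariates), collapse = ", ")
              else "none"))
  invisible(x)
}

# Ellipsoidal brain-like mask centred in the grid; semi-axes as a fraction
# of each dimension, leaving a margin for neighborhood analyses.
ellipsoid_mask <- function(dims, semi_frac = 0.40) {
  ctr <- (dims + 1) / 2
  ax <- semi_frac * dims
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  r2 <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2
  array(r2 <= 1, dims)
}

# Isotropic Gaussian smoothing of a 3D array (zero padding at the border).
smooth3d <- function(a, sigma) {
  d <- dim(a)
  array(cpp_gauss_smooth3(as.numeric(a), d[1], d[2], d[3], sigma), d)
}

clip01 <- function(a) {
  a[a < 0] <- 0
  a[a > 1] <- 1
  a
}
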