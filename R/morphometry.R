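#' Construct a deformation field
#'
#' Holds a per-voxel displacement vector field (voxel units, pulling
#' convention: the value at a voxel tells where that voxel's content came
#' from) and its validity mask.
#'
#' @param displacements 4D numeric array `(dims, 3)` of displacement
#'   components along the three grid axes.
#' @param mask 3D logical array; defaults to all `TRUE`.
#' @return A `deformation_field`.
#' @export
deformation_field <- function(displacements, mask = NULL) {
  d <- dim(displacements)
  if (length(d) != 4 || d[4] != 3)
    stop("displacements must be a (d1, d2, d3, 3) array")
  if (any(d[1:3] < 3)) stop("grid must span at least 3 voxels per axis")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask shape mismatch")
  if (!all(is.finite(displacements))) stop("non-finite displacements")
  structure(list(displacements = displacements, mask = mask),
            class = "deformation_field")
}

# Mask-aware partial derivative of a 3D array along one axis: central
# differences where both neighbors are in-mask, one-sided at the mask
# boundary, 0 where no in-mask neighbor exists.
masked_gradient <- function(a, mask, axis) {
  dims <- dim(a)
  shift <- function(x, by) {
    out <- array(0, dims)
    src <- dst <- lapply(dims, seq_len)
    if (by > 0) { dst[[axis]] <- (1 + by):dims[axis]; src[[axis]] <- 1:(dims[axis] - by) }
    else { dst[[axis]] <- 1:(dims[axis] + by); src[[axis]] <- (1 - by):dims[axis] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
  }
  fa <- shift(a, -1)           # value at +1 along axis, aligned to center
  ba <- shift(a, 1)            # value at -1
  fm <- shift(mask, -1) & mask
  bm <- shift(mask, 1) & mask
  g <- array(0, dims)
  both <- fm & bm
  g[both] <- (fa[both] - ba[both]) / 2
  fonly <- fm & !bm
  g[fonly] <- fa[fonly] - a[fonly]
  bonly <- bm & !fm
  g[bonly] <- a[bonly] - ba[bonly]
  g
}

#' Jacobian determinant of a displacement field
#'
#' Computes `det(I + grad(u))` at every in-mask voxel by finite
#' differences (central in the interior, one-sided at the mask boundary):
#' the local volume expansion (> 1) or contraction (< 1) implied by the
#' deformation. Axis-reflecting fields yield negative determinants, which
#' are reported as-is (not clipped); background voxels are 0.
#'
#' @param field a [deformation_field()].
#' @param log_jd return the (signed) natural log of the determinant
#'   instead of the raw value; non-positive determinants yield `NA`.
#' @return 3D numeric array.
#' @export
jacobian_determinant <- function(field, log_jd = FALSE) {
  stopifnot(inherits(field, "deformation_field"))
  u <- field$displacements
  mask <- field$mask
  g <- array(0, c(dim(mask), 3, 3))
  for (comp in 1:3) for (axis in 1:3)
    g[, , , comp, axis] <- masked_gradient(u[, , , comp], mask, axis)
  # det(I + G) expanded for 3x3
  a11 <- 1 + g[, , , 1, 1]; a12 <- g[, , , 1, 2]; a13 <- g[, , , 1, 3]
  a21 <- g[, , , 2, 1]; a22 <- 1 + g[, , , 2, 2]; a23 <- g[, , , 2, 3]
  a31 <- g[, , , 3, 1]; a32 <- g[, , , 3, 2]; a33 <- 1 + g[, , , 3, 3]
  jd <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  jd[!mask] <- 0
  if (log_jd) {
    out <- array(NA_real_, dim(mask))
    pos <- mask & jd > 0
    out[pos] <- log(jd[pos])
    out[!mask] <- 0
    return(out)
  }
  jd
}

#' Regional summary of a Jacobian-determinant map
#'
#' Mean determinant per region of a parcellation; region 0 is the overall
#' in-mask mean. The resulting regional values (or voxelwise maps) feed
#' the same PC loci analysis as the specialization maps.
#'
#' @param jd 3D numeric array from [jacobian_determinant()].
#' @param parcellation a [decile_partition()] result or integer label
#'   array.
#' @param mask 3D logical array of valid voxels.
#' @return data.frame of `region_id`, `mean_value`.
#' @export
jd_summary <- function(jd, parcellation, mask) {
  summarize_map(list(values = jd, mask = mask), parcellation)
}
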