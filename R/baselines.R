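#' Saliency-map configuration
#'
#' @param window_vox sliding-window edge length in voxels (default 5).
#' @param stride_vox window step (default 2); must not exceed the window
#'   so that coverage is total.
#' @param fill_value occlusion fill value (default 0).
#' @return A `saliency_config` list.
#' @export
saliency_config <- function(window_vox = 5, stride_vox = 2, fill_value = 0) {
  if (stride_vox > window_vox) stop("stride must not exceed window")
  if (window_vox < 1 || stride_vox < 1) stop("window and stride must be >= 1")
  structure(list(window_vox = as.integer(window_vox),
                 stride_vox = as.integer(stride_vox),
                 fill_value = fill_value),
            class = "saliency_config")
}

#' Voxelwise asymmetry index
#'
#' The classical lateralization measure `(LH - RH) / (LH + RH)` at
#' corresponding voxels, in `[-1, 1]` for nonnegative inputs; positive
#' values mean leftward asymmetry. Zero-sum voxels are set to 0.
#'
#' @param lh,rh `volume_grid`s of identical shape.
#' @param correspondence `"identity"` when the two hemisphere grids share
#'   a lattice (the synthetic generator's convention), `"mirror"` to pair
#'   each LH voxel with its reflection across the split (x) axis, as for
#'   hemispheres cropped from a whole-brain volume.
#' @return 3D numeric array in the LH frame; voxels where either paired
#'   voxel is outside its mask are 0.
#' @export
asymmetry_index <- function(lh, rh, correspondence = c("identity", "mirror")) {
  correspondence <- match.arg(correspondence)
  if (!identical(dim(lh$values), dim(rh$values))) stop("shape mismatch")
  rv <- rh$values
  rm <- rh$mask
  if (correspondence == "mirror") {
    rv <- flip_x(rv)
    rm <- flip_x(rm)
  }
  both <- lh$mask & rm
  den <- lh$values + rv
  ai <- (lh$values - rv) / ifelse(abs(den) < 1e-12, 1, den)
  ai[abs(den) < 1e-12] <- 0
  ai[!both] <- 0
  ai
}

flip_x <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]

#' Occlusion saliency map of a trained model
#'
#' Slides a cubic window over the source hemisphere; each placement
#' occludes the window (fill value), reconstructs the target, and the
#' change in reconstruction loss relative to the intact source is
#' accumulated into every voxel the window covered. A per-voxel counter
#' tracks occlusions and the map is the accumulated change divided by the
#' counter. Boundary placements are clipped to the grid so coverage is
#' total.
#'
#' @param model trained `ce_model`.
#' @param source,target `volume_grid`s (source feeds the model; loss is
#'   against `target`).
#' @param cfg a [saliency_config()].
#' @param absolute accumulate `|change|` instead of signed change.
#' @param batch_size placements evaluated per forward pass.
#' @return 3D numeric array (saliency per voxel; 0 where never covered).
#' @export
saliency_map <- function(model, source, target, cfg = saliency_config(),
                         absolute = FALSE, batch_size = 32) {
  dims <- dim(source$values)
  if (any(cfg$window_vox > dims)) stop("window larger than grid")
  intact <- reconstruction_loss(target, ce_generate(model, source))
  starts <- lapply(dims, function(d) seq(1L, d, by = cfg$stride_vox))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  acc <- array(0, dims)
  cnt <- array(0L, dims)
  maskvec <- as.numeric(target$mask)
  tvec <- as.numeric(target$values)
  nmask <- sum(target$mask)
  np <- nrow(grid)
  for (b0 in seq(1, np, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1, np)
    xb <- array(0, c(1, prod(dims), length(bi)))
    wins <- vector("list", length(bi))
    for (k in seq_along(bi)) {
      g <- grid[bi[k], ]
      xs <- g$x:min(g$x + cfg$window_vox - 1L, dims[1])
      ys <- g$y:min(g$y + cfg$window_vox - 1L, dims[2])
      zs <- g$z:min(g$z + cfg$window_vox - 1L, dims[3])
      v <- source$values
      v[xs, ys, zs] <- cfg$fill_value
      v[!source$mask] <- 0
      xb[1, , k] <- as.numeric(v)
      wins[[k]] <- list(xs = xs, ys = ys, zs = zs)
    }
    out <- gen_infer_cube(model, xb)
    for (k in seq_along(bi)) {
      rec <- out[1, , k] * maskvec
      loss <- sum((rec - tvec)[maskvec > 0]^2) / nmask
      ch <- loss - intact
      if (absolute) ch <- abs(ch)
      w <- wins[[k]]
      acc[w$xs, w$ys, w$zs] <- acc[w$xs, w$ys, w$zs] + ch
      cnt[w$xs, w$ys, w$zs] <- cnt[w$xs, w$ys, w$zs] + 1L
    }
  }
  out <- array(0, dims)
  covered <- cnt > 0
  out[covered] <- acc[covered] / cnt[covered]
  out
}

# Placement counter alone (used to verify coverage against enumeration).
saliency_counter <- function(dims, cfg) {
  starts <- lapply(dims, function(d) seq(1L, d, by = cfg$stride_vox))
  cnt <- array(0L, dims)
  for (z in starts[[3]]) for (y in starts[[2]]) for (x in starts[[1]]) {
    xs <- x:min(x + cfg$window_vox - 1L, dims[1])
    ys <- y:min(y + cfg$window_vox - 1L, dims[2])
    zs <- z:min(z + cfg$window_vox - 1L, dims[3])
    cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1L
  }
  cnt
}
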