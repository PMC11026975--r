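#' Load a gray-matter density volume from NIfTI
#'
#' Values are clipped to `[0, 1]`; the mask keeps voxels whose density
#' meets the probability threshold, and sub-threshold voxels are zeroed
#' (edge noise removal).
#'
#' @param path NIfTI file.
#' @param gm_threshold probability threshold (default 0.15).
#' @param hemisphere label to attach.
#' @return A `volume_grid`.
#' @export
load_gm_volume <- function(path, gm_threshold = 0.15,
                           hemisphere = c("LH", "RH")) {
  hemisphere <- match.arg(hemisphere)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3) stop("expected a 3D image")
  a <- array(as.numeric(a), dim(a))
  a <- clip01(a)
  mask <- a >= gm_threshold
  if (!any(mask)) stop("empty mask after thresholding")
  a[!mask] <- 0
  vox <- tryCatch(RNifti::pixdim(img)[1], error = function(e) 1.5)
  volume_grid(a, mask, hemisphere, voxel_size_mm = vox)
}

#' Write a volume grid (or plain 3D array) as NIfTI
#'
#' @param x `volume_grid`, `specificity_map`, or 3D array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel size when `x` is a plain array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = 1.5) {
  vals <- if (is.list(x)) x$values else x
  if (is.list(x) && !is.null(x$voxel_size_mm)) voxel_size_mm <- x$voxel_size_mm
  img <- RNifti::asNifti(vals, reference = NULL)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Split a whole-brain volume into hemisphere grids
#'
#' Splits along the first (x) grid axis at the midline plane (voxel
#' centers below the midplane go to the LH; for odd widths the exact
#' midline column joins the LH). Each hemisphere is cropped to its mask
#' bounding box and zero-padded up to a multiple of `pad_multiple` so it
#' can feed the model; crop/pad offsets are recorded so
#' [recompose_hemispheres()] inverts the split exactly.
#'
#' @param whole a `volume_grid` of the whole brain.
#' @param pad_multiple pad each cropped dim up to a multiple of this
#'   (default 16, matching four halvings).
#' @return A `hemisphere_pair` with a `split_info` attribute.
#' @export
split_hemispheres <- function(whole, pad_multiple = 16L) {
  dims <- dim(whole$values)
  nx <- dims[1]
  lx <- seq_len(ceiling(nx / 2))
  rx <- setdiff(seq_len(nx), lx)
  one_side <- function(xs, hemi) {
    v <- whole$values[xs, , , drop = FALSE]
    m <- whole$mask[xs, , , drop = FALSE]
    if (!any(m)) stop(sprintf("%s hemisphere is empty", hemi))
    bb <- apply(which(m, arr.ind = TRUE), 2, range)
    crop_lo <- bb[1, ]; crop_hi <- bb[2, ]
    v <- v[crop_lo[1]:crop_hi[1], crop_lo[2]:crop_hi[2],
           crop_lo[3]:crop_hi[3], drop = FALSE]
    m <- m[crop_lo[1]:crop_hi[1], crop_lo[2]:crop_hi[2],
           crop_lo[3]:crop_hi[3], drop = FALSE]
    cd <- dim(v)
    pd <- as.integer(ceiling(cd / pad_multiple) * pad_multiple)
    pv <- array(0, pd); pm <- array(FALSE, pd)
    pv[seq_len(cd[1]), seq_len(cd[2]), seq_len(cd[3])] <- v
    pm[seq_len(cd[1]), seq_len(cd[2]), seq_len(cd[3])] <- m
    list(grid = volume_grid(pv, pm, hemi, whole$voxel_size_mm),
         info = list(x_range = range(xs), crop_lo = crop_lo,
                     crop_hi = crop_hi, cropped_dims = cd, padded_dims = pd))
  }
  l <- one_side(lx, "LH")
  r <- one_side(rx, "RH")
  pair <- hemisphere_pair("split", l$grid, r$grid)
  attr(pair, "split_info") <- list(whole_dims = dims, lh = l$info, rh = r$info)
  pair
}

#' Recompose a whole-brain volume from a split pair
#'
#' Inverts [split_hemispheres()] using the recorded crop/pad offsets; the
#' round trip reproduces the original volume exactly in-mask.
#'
#' @param pair a `hemisphere_pair` carrying a `split_info` attribute.
#' @return A whole-brain `volume_grid`.
#' @export
recompose_hemispheres <- function(pair) {
  info <- attr(pair, "split_info")
  if (is.null(info)) stop("pair carries no split_info")
  vals <- array(0, info$whole_dims)
  mask <- array(FALSE, info$whole_dims)
  put <- function(grid, side) {
    cd <- side$cropped_dims
    v <- grid$values[seq_len(cd[1]), seq_len(cd[2]), seq_len(cd[3]), drop = FALSE]
    m <- grid$mask[seq_len(cd[1]), seq_len(cd[2]), seq_len(cd[3]), drop = FALSE]
    xs <- side$x_range[1] + side$crop_lo[1] - 1 + seq_len(cd[1]) - 1
    ys <- side$crop_lo[2] + seq_len(cd[2]) - 1
    zs <- side$crop_lo[3] + seq_len(cd[3]) - 1
    vals[xs, ys, zs] <<- v
    mask[xs, ys, zs] <<- m
  }
  put(pair$lh, info$lh)
  put(pair$rh, info$rh)
  volume_grid(vals, mask, "LH", pair$lh$voxel_size_mm)
}

#' Write a synthetic cohort to disk
#'
#' One uncompressed NIfTI per hemisphere per subject, a covariate CSV
#' (subject_id, session_id, age, sex, icv, batch, family_id), and a JSON
#' ground-truth sidecar recording the generator seed, mapping/effect
#' parameters and the planted specific-support voxel indices.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$pairs)) {
    p <- cohort$pairs[[i]]
    ses <- p$covariates$session_id %||% 1L
    write_volume(p$lh, file.path(dir, sprintf("%s_ses%d_lh.nii", p$subject_id, ses)))
    write_volume(p$rh, file.path(dir, sprintf("%s_ses%d_rh.nii", p$subject_id, ses)))
  }
  cov <- cohort$covariates
  cov$session_id <- 1L
  write.csv(cov, file.path(dir, "covariates.csv"), row.names = FALSE)
  gt <- lapply(cohort$truth, function(tr) list(
    subject_id = tr$subject_id, seed = tr$seed,
    effect_params = tr$effect_params,
    mapping_sigmas = c(lh = tr$mapping_params$lh$sigma,
                       rh = tr$mapping_params$rh$sigma),
    specific_support_lh = which(tr$specific_support_lh),
    specific_support_rh = which(tr$specific_support_rh)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  write_volume(array(as.numeric(cohort$mask), dim(cohort$mask)),
               file.path(dir, "mask.nii"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param gm_threshold mask threshold applied on load (the generator's
#'   mask NIfTI, when present, overrides it).
#' @return list with `pairs` and `covariates`.
#' @export
read_cohort <- function(dir, gm_threshold = 1e-6) {
  cov <- read.csv(file.path(dir, "covariates.csv"), stringsAsFactors = FALSE)
  mask <- NULL
  mp <- file.path(dir, "mask.nii")
  if (file.exists(mp)) mask <- as.array(RNifti::readNifti(mp)) > 0.5
  pairs <- lapply(seq_len(nrow(cov)), function(i) {
    sid <- cov$subject_id[i]
    ses <- cov$session_id[i] %||% 1L
    rd <- function(h, label) {
      a <- as.array(RNifti::readNifti(
        file.path(dir, sprintf("%s_ses%d_%s.nii", sid, ses, h))))
      a <- array(as.numeric(a), dim(a))
      m <- if (!is.null(mask)) mask else a >= gm_threshold
      volume_grid(clip01(a), m, label)
    }
    hemisphere_pair(sid, rd("lh", "LH"), rd("rh", "RH"),
                    as.list(cov[i, setdiff(names(cov), "subject_id")]))
  })
  list(pairs = pairs, covariates = cov)
}

#' Save / load a context-encoder checkpoint
#'
#' The checkpoint is an RDS of the full model next to a JSON sidecar
#' recording the configuration, seed and training direction.
#'
#' @param model a `ce_model`.
#' @param path checkpoint path (`.rds`).
#' @return `path` (save) or the restored `ce_model` (load).
#' @export
save_ce_model <- function(model, path) {
  stopifnot(inherits(model, "ce_model"))
  saveRDS(model, path)
  side <- c(unclass(model$config),
            list(seed = model$seed, direction = model$direction))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_ce_model
#' @export
load_ce_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "ce_model"))
  m
}
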