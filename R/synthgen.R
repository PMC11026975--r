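#' Configuration for the synthetic paired-hemisphere generator
#'
#' The generator emulates the assumed composition of the two hemispheres:
#' each subject carries a smooth shared ("homologous") field that is passed
#' through two distinct, cohort-fixed hemisphere mappings, plus independent
#' hemisphere-specific components planted as compact blobs. Optional layers
#' add session noise, family structure, scanner/batch offsets, and age/sex
#' covariate effects, so every downstream statistic has a known ground
#' truth.
#'
#' @param grid_shape integer vector of 3 dims, each >= 16.
#' @param n_subjects number of subjects.
#' @param shared_smoothness_vox Gaussian smoothing width (voxels) of the
#'   shared field.
#' @param specific_amplitude peak amplitude of specific blobs (density units).
#' @param specific_n_blobs number of blobs per hemisphere per subject.
#' @param blob_radius_vox Gaussian radius of a blob (voxels).
#' @param session_noise_sd SD of smooth additive session noise.
#' @param n_sessions default number of sessions emitted by
#'   [generate_sessions()].
#' @param n_families optional number of families; subjects are assigned
#'   round-robin.
#' @param family_share fraction in `[0, 1]` of shared/specific factor
#'   variance common within a family.
#' @param batch_labels optional batch assignment: an integer number of
#'   batches (round-robin) or a length-`n_subjects` vector.
#' @param batch_offsets additive density offset per batch level.
#' @param covariate_effects named list: `age` = additive field shift per
#'   year relative to age 50; `sex` = relative increase of specific
#'   amplitude in males.
#' @param seed integer seed; the full cohort is reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(grid_shape = c(32, 32, 32), n_subjects = 20,
                         shared_smoothness_vox = 9, specific_amplitude = 0.3,
                         specific_n_blobs = 3, blob_radius_vox = 3,
                         session_noise_sd = 0, n_sessions = 1,
                         n_families = NULL, family_share = 0,
                         batch_labels = NULL, batch_offsets = NULL,
                         covariate_effects = list(age = 0.002, sex = 0.1),
                         seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must have 3 dims, each >= 16")
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (shared_smoothness_vox <= 0) stop("shared_smoothness_vox must be positive")
  if (specific_amplitude < 0) stop("specific_amplitude must be nonnegative")
  if (session_noise_sd < 0) stop("session_noise_sd must be nonnegative")
  if (n_sessions < 1) stop("n_sessions must be >= 1")
  if (family_share < 0 || family_share > 1) stop("family_share must be in [0, 1]")
  structure(list(grid_shape = grid_shape, n_subjects = as.integer(n_subjects),
                 shared_smoothness_vox = shared_smoothness_vox,
                 specific_amplitude = specific_amplitude,
                 specific_n_blobs = as.integer(specific_n_blobs),
                 blob_radius_vox = blob_radius_vox,
                 session_noise_sd = session_noise_sd,
                 n_sessions = as.integer(n_sessions),
                 n_families = n_families, family_share = family_share,
                 batch_labels = batch_labels, batch_offsets = batch_offsets,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Gaussian random field standardised in-mask to mean 0, SD 1.
grf <- function(dims, sigma, mask) {
  f <- smooth3d(array(rnorm(prod(dims)), dims), sigma)
  v <- f[mask]
  (f - mean(v)) / sd(v)
}

# Compactly supported positive blob field: Gaussian bumps truncated below
# 25% of peak amplitude, so the planted field is exactly zero outside its
# support and the support is exactly the nonzero set.
blob_field <- function(dims, mask, n_blobs, radius, amplitude) {
  field <- array(0, dims)
  if (n_blobs < 1 || amplitude == 0)
    return(list(field = field, support = field > 0))
  idx <- which(mask)
  centers <- idx[sample.int(length(idx), n_blobs, replace = TRUE)]
  co <- arrayInd(centers, dims)
  ext <- ceiling(2 * radius)
  for (b in seq_len(n_blobs)) {
    lo <- pmax(co[b, ] - ext, 1L)
    hi <- pmin(co[b, ] + ext, dims)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dx2 <- (xs - co[b, 1])^2
    dy2 <- (ys - co[b, 2])^2
    dz2 <- (zs - co[b, 3])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    bump <- amplitude * exp(-r2 / (2 * radius^2))
    bump[bump < 0.25 * amplitude] <- 0
    field[xs, ys, zs] <- pmax(field[xs, ys, zs], bump)
  }
  field[!mask] <- 0
  list(field = field, support = field > 0)
}

# Hemisphere mapping: cohort-fixed extra smoothing plus a fixed smooth
# multiplicative gain field. Smoothing is mask-normalized so the brain
# boundary does not imprint a common attenuation pattern on every subject.
apply_mapping <- function(h, mp) {
  num <- smooth3d(h * mp$mask, mp$sigma)
  den <- smooth3d(mp$mask * 1, mp$sigma)
  out <- h * 0
  inm <- mp$mask & den > 1e-8
  out[inm] <- num[inm] / den[inm]
  mp$gain * out
}

#' Generate a synthetic cohort of paired hemispheres
#'
#' Draws, per subject, a smooth shared field, maps it through the two
#' cohort-fixed hemisphere mappings, adds independent hemisphere-specific
#' blob components and any configured batch/covariate/family/session
#' effects, clips to `[0, 1]` and applies an ellipsoidal mask. The second
#' list returned records the planted ground truth per subject (pre-clip
#' fields, blob supports, mapping and effect parameters) so recovery can be
#' scored exactly.
#'
#' @param config a [synth_config()].
#' @return `list(pairs = <list of hemisphere_pair>, truth = <list of ground
#'   truth records>, mask = <3D logical>, mapping = <mapping parameters>,
#'   covariates = <data.frame>)`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  dims <- config$grid_shape
  n <- config$n_subjects
  mask <- ellipsoid_mask(dims)

  # cohort-fixed hemisphere mappings f1 (LH) and f2 (RH)
  mk_gain <- function() {
    g <- 1 + 0.12 * grf(dims, 6, mask)
    pmin(pmax(g, 0.7), 1.3)
  }
  mapping <- list(lh = list(sigma = 0.8, gain = mk_gain(), mask = mask),
                  rh = list(sigma = 1.6, gain = mk_gain(), mask = mask))

  # covariates
  age <- runif(n, 20, 80)
  sex <- sample(0:1, n, replace = TRUE)
  icv <- runif(n, 1200, 1700)
  batch <- config$batch_labels
  if (is.null(batch)) batch <- rep(1L, n)
  else if (length(batch) == 1L) batch <- rep_len(seq_len(batch), n)
  batch <- as.integer(factor(batch))
  offsets <- config$batch_offsets
  if (is.null(offsets)) offsets <- rep(0, max(batch))
  family_id <- if (!is.null(config$n_families))
    rep_len(seq_len(config$n_families), n) else seq_len(n)

  w <- config$family_share
  fam_shared <- list(); fam_blob_lh <- list(); fam_blob_rh <- list()
  if (w > 0) {
    for (f in unique(family_id)) {
      fam_shared[[f]] <- grf(dims, config$shared_smoothness_vox, mask)
      fam_blob_lh[[f]] <- blob_field(dims, mask, config$specific_n_blobs,
                                     config$blob_radius_vox, 1)
      fam_blob_rh[[f]] <- blob_field(dims, mask, config$specific_n_blobs,
                                     config$blob_radius_vox, 1)
    }
  }

  eff <- config$covariate_effects
  age_slope <- if (!is.null(eff$age)) eff$age else 0
  sex_off <- if (!is.null(eff$sex)) eff$sex else 0

  pairs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    h <- grf(dims, config$shared_smoothness_vox, mask)
    if (w > 0) h <- sqrt(w) * fam_shared[[family_id[i]]] + sqrt(1 - w) * h
    h <- 0.5 + 0.12 * h + age_slope * (age[i] - 50)

    amp <- config$specific_amplitude * (1 + sex_off * sex[i])
    s_lh <- blob_field(dims, mask, config$specific_n_blobs,
                       config$blob_radius_vox, amp)
    s_rh <- blob_field(dims, mask, config$specific_n_blobs,
                       config$blob_radius_vox, amp)
    if (w > 0) {
      s_lh$field <- sqrt(w) * amp * fam_blob_lh[[family_id[i]]]$field +
        sqrt(1 - w) * s_lh$field
      s_lh$support <- s_lh$field > 0
      s_rh$field <- sqrt(w) * amp * fam_blob_rh[[family_id[i]]]$field +
        sqrt(1 - w) * s_rh$field
      s_rh$support <- s_rh$field > 0
    }

    hl <- apply_mapping(h, mapping$lh)
    hr <- apply_mapping(h, mapping$rh)
    off <- offsets[batch[i]]
    clean_lh <- hl + s_lh$field + off
    clean_rh <- hr + s_rh$field + off
    noise_lh <- noise_rh <- 0
    if (config$session_noise_sd > 0) {
      noise_lh <- config$session_noise_sd * grf(dims, 1.5, mask)
      noise_rh <- config$session_noise_sd * grf(dims, 1.5, mask)
    }
    xl <- clip01(clean_lh + noise_lh); xl[!mask] <- 0
    xr <- clip01(clean_rh + noise_rh); xr[!mask] <- 0

    sid <- sprintf("sub%03d", i)
    cov <- list(age = age[i], sex = sex[i], icv = icv[i],
                batch = batch[i], family_id = family_id[i], session_id = 1L)
    pairs[[i]] <- hemisphere_pair(sid,
      volume_grid(xl, mask, "LH"), volume_grid(xr, mask, "RH"), cov)
    truth[[i]] <- list(subject_id = sid, shared_field = h,
                       homologous_lh = hl, homologous_rh = hr,
                       specific_lh = s_lh$field, specific_rh = s_rh$field,
                       specific_support_lh = s_lh$support,
                       specific_support_rh = s_rh$support,
                       clean_lh = clean_lh, clean_rh = clean_rh,
                       mapping_params = mapping,
                       effect_params = list(batch_offset = off,
                                            age_slope = age_slope,
                                            sex_offset = sex_off,
                                            session_noise_sd = config$session_noise_sd),
                       seed = config$seed)
  }
  covdf <- data.frame(subject_id = vapply(pairs, function(p) p$subject_id, ""),
                      age = age, sex = sex, icv = icv, batch = batch,
                      family_id = family_id, stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth, mask = mask, mapping = mapping,
       covariates = covdf)
}

#' Re-noised scan sessions of one synthetic subject
#'
#' Keeps the subject's underlying shared and specific fields fixed and adds
#' fresh smooth session noise per session, emulating a test-retest design.
#'
#' @param pair the subject's [hemisphere_pair()].
#' @param gt the matching ground-truth record from [generate_cohort()].
#' @param n_sessions number of sessions (>= 1).
#' @param noise_sd SD of the smooth additive noise; 0 reproduces the clean
#'   scan.
#' @param seed integer seed.
#' @return list of `hemisphere_pair`, one per session.
#' @export
generate_sessions <- function(pair, gt, n_sessions, noise_sd, seed = 1) {
  if (n_sessions < 1) stop("n_sessions must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  set.seed(seed)
  mask <- pair$lh$mask
  dims <- dim(mask)
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    nl <- nr <- 0
    if (noise_sd > 0) {
      nl <- noise_sd * grf(dims, 1.5, mask)
      nr <- noise_sd * grf(dims, 1.5, mask)
    }
    xl <- clip01(gt$clean_lh + nl); xl[!mask] <- 0
    xr <- clip01(gt$clean_rh + nr); xr[!mask] <- 0
    cov <- pair$covariates
    cov$session_id <- s
    out[[s]] <- hemisphere_pair(pair$subject_id,
      volume_grid(xl, mask, "LH"), volume_grid(xr, mask, "RH"), cov)
  }
  out
}

#' Random contiguous ROI partition of a mask
#'
#' Stand-in for an anatomical atlas on synthetic grids: in-mask voxels are
#' split into `n_rois` spatially contiguous, roughly equal-sized regions by
#' clustering voxel coordinates (Voronoi cells of seeded centroids, which
#' are contiguous on a convex mask).
#'
#' @param mask 3D logical array.
#' @param n_rois number of regions, between 2 and the voxel count.
#' @param seed integer seed.
#' @return 3D integer array; labels 1..n_rois in-mask, 0 outside.
#' @export
make_roi_partition <- function(mask, n_rois, seed = 1) {
  idx <- which(mask)
  if (n_rois < 2 || n_rois > length(idx))
    stop("n_rois must be between 2 and the in-mask voxel count")
  labels <- array(0L, dim(mask))
  if (n_rois == length(idx)) {
    labels[idx] <- seq_along(idx)
    return(labels)
  }
  set.seed(seed)
  co <- arrayInd(idx, dim(mask))
  km <- suppressWarnings(kmeans(co, centers = n_rois, nstart = 3,
                                iter.max = 100))
  labels[idx] <- km$cluster
  labels
}
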