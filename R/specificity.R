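#' Absolute neuroanatomical specificity (ANS) map
#'
#' Voxelwise absolute difference between the actual hemisphere and its
#' cross-hemisphere reconstruction: the amount of hemisphere-specific
#' component at each voxel. The sign of the residual is deliberately
#' discarded.
#'
#' @param actual,recon `volume_grid`s with matching shape and mask.
#' @param subject_id,session_id optional identifiers carried on the map.
#' @return A `specificity_map` (values, mask, metric, hemisphere, ids,
#'   `harmonized = FALSE`).
#' @export
ans_map <- function(actual, recon, subject_id = "", session_id = "") {
  check_same_grid(actual, recon)
  vals <- abs(actual$values - recon$values)
  vals[!actual$mask] <- 0
  new_specificity_map(vals, actual$mask, "ANS", actual$hemisphere,
                      subject_id, session_id)
}

#' Relative neuroanatomical specialization (RNS) map
#'
#' Voxelwise `|actual - recon| / (actual + recon)`: the proportion of
#' specific component. Voxels whose denominator falls below `eps` are set
#' to 0 rather than propagating division-by-zero artifacts.
#'
#' @inheritParams ans_map
#' @param eps denominator guard (default 1e-6 on `[0, 1]` data).
#' @return A `specificity_map`.
#' @export
rns_map <- function(actual, recon, eps = 1e-6, subject_id = "",
                    session_id = "") {
  check_same_grid(actual, recon)
  if (eps < 0) stop("eps must be nonnegative")
  den <- actual$values + recon$values
  vals <- abs(actual$values - recon$values) / ifelse(den < eps, 1, den)
  vals[den < eps] <- 0
  vals[!actual$mask] <- 0
  new_specificity_map(vals, actual$mask, "RNS", actual$hemisphere,
                      subject_id, session_id)
}

new_specificity_map <- function(values, mask, metric, hemisphere,
                                subject_id = "", session_id = "",
                                harmonized = FALSE) {
  structure(list(values = values, mask = mask, metric = metric,
                 hemisphere = hemisphere, subject_id = subject_id,
                 session_id = session_id, harmonized = harmonized),
            class = "specificity_map")
}

#' @export
print.specificity_map <- function(x, ...) {
  cat(sprintf("<specificity_map %s %s%s, %d in-mask voxels, mean %.4f%s>\n",
              x$metric, x$hemisphere,
              if (nzchar(x$subject_id)) paste0(" '", x$subject_id, "'") else "",
              sum(x$mask), mean(x$values[x$mask]),
              if (x$harmonized) ", harmonized" else ""))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) stop("shape mismatch")
  if (!identical(a$mask, b$mask)) stop("mask mismatch")
  invisible(TRUE)
}

#' Decile parcellation of a group-mean specialization map
#'
#' Ranks in-mask voxels of the group-mean map in descending order and
#' splits them into 10 equal parts: part 1 holds the top 10 percent, part
#' 10 the bottom 10 percent. Ties are broken by raster (x, y, z) order so
#' the partition is deterministic; part sizes differ by at most one voxel.
#'
#' @param group_mean_map a `specificity_map` (typically the mean map of
#'   healthy validation subjects).
#' @return list with `part_labels` (3D integer array, 0 = background),
#'   `source_metric`, `reference`.
#' @export
decile_partition <- function(group_mean_map) {
  mask <- group_mean_map$mask
  idx <- which(mask)
  n <- length(idx)
  if (n < 10) stop("mask has fewer than 10 voxels")
  v <- group_mean_map$values[idx]
  ord <- order(-v, seq_along(v))
  sizes <- rep(n %/% 10L, 10L)
  extra <- n %% 10L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- array(0L, dim(mask))
  labels[idx[ord]] <- rep(1:10, times = sizes)
  structure(list(part_labels = labels,
                 source_metric = group_mean_map$metric,
                 reference = "group-mean"),
            class = "decile_parcellation")
}

#' Overall and regional means of a map
#'
#' @param map a `specificity_map` (or any object with `values` and `mask`).
#' @param parcellation optional [decile_partition()] result or a 3D integer
#'   label array; when given, one row per region is appended after the
#'   overall (region 0) row.
#' @return data.frame of `region_id`, `mean_value`.
#' @export
summarize_map <- function(map, parcellation = NULL) {
  mask <- map$mask
  out <- data.frame(region_id = 0L, mean_value = mean(map$values[mask]))
  if (!is.null(parcellation)) {
    labels <- if (inherits(parcellation, "decile_parcellation"))
      parcellation$part_labels else parcellation
    if (!identical(dim(labels), dim(map$values)))
      stop("parcellation not aligned to map")
    ids <- sort(unique(labels[labels > 0]))
    for (id in ids) {
      sel <- labels == id
      if (!any(sel)) stop(sprintf("region %d is empty", id))
      out <- rbind(out, data.frame(region_id = id,
                                   mean_value = mean(map$values[sel])))
    }
  }
  out
}

#' ComBat harmonization of specialization maps across batches
#'
#' Applies parametric empirical-Bayes location/scale harmonization per
#' voxel across scanner/site batches, protecting biological covariates in
#' the design. Voxels with (near-)zero variance across subjects are passed
#' through unchanged.
#'
#' @param maps list of `specificity_map`s on a common grid, one subject
#'   each.
#' @param batch vector of batch labels, length equal to `maps`; at least 2
#'   batches with at least 2 subjects each.
#' @param covariates optional data.frame of per-subject covariates to
#'   protect (numeric or factor columns).
#' @return list of harmonized `specificity_map`s (`harmonized = TRUE`).
#' @export
harmonize_combat <- function(maps, batch, covariates = NULL) {
  if (length(maps) != length(batch)) stop("batch length mismatch")
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("need at least 2 batches")
  if (any(table(batch) < 2)) stop("each batch needs at least 2 subjects")
  mask <- maps[[1]]$mask
  m <- vapply(maps, function(x) x$values[mask], numeric(sum(mask)))
  mod <- NULL
  if (!is.null(covariates) && ncol(covariates) > 0) {
    mod <- model.matrix(~ ., data = as.data.frame(covariates))
    if (qr(mod)$rank < ncol(mod)) stop("rank-deficient covariate design")
  }
  ok <- apply(m, 1, function(r) var(r) > 1e-12)
  harm <- m
  if (any(ok)) {
    harm[ok, ] <- sva::ComBat(dat = m[ok, , drop = FALSE], batch = batch,
                              mod = mod, par.prior = TRUE)
  }
  lapply(seq_along(maps), function(i) {
    vals <- maps[[i]]$values
    vals[mask] <- harm[, i]
    new_specificity_map(vals, mask, maps[[i]]$metric, maps[[i]]$hemisphere,
                        maps[[i]]$subject_id, maps[[i]]$session_id,
                        harmonized = TRUE)
  })
}

#' Pairwise similarity matrix between two sets of maps
#'
#' Entry (i, j) is the Pearson correlation of the vectorized in-mask
#' values of `maps_a[[i]]` and `maps_b[[j]]` -- the fingerprinting
#' similarity used to match reconstructions, sessions, or relatives.
#'
#' @param maps_a,maps_b non-empty lists of grids/maps on a common mask.
#' @param row_ids,col_ids optional label vectors.
#' @return A `similarity_matrix` (values, row_ids, col_ids, stat).
#' @export
pairwise_similarity <- function(maps_a, maps_b, row_ids = NULL,
                                col_ids = NULL) {
  if (!length(maps_a) || !length(maps_b)) stop("empty map list")
  mask <- maps_a[[1]]$mask
  va <- vapply(maps_a, function(x) x$values[mask], numeric(sum(mask)))
  vb <- vapply(maps_b, function(x) x$values[mask], numeric(sum(mask)))
  if (any(apply(va, 2, sd) == 0) || any(apply(vb, 2, sd) == 0))
    stop("zero-variance vector")
  ids <- function(maps, given, prefix) {
    if (!is.null(given)) return(as.character(given))
    got <- vapply(maps, function(x)
      if (!is.null(x$subject_id) && nzchar(x$subject_id)) x$subject_id else "",
      "")
    if (all(nzchar(got)) && !anyDuplicated(got)) got
    else paste0(prefix, seq_along(maps))
  }
  structure(list(values = cor(va, vb),
                 row_ids = ids(maps_a, row_ids, "a"),
                 col_ids = ids(maps_b, col_ids, "b"),
                 stat = "Pearson"),
            class = "similarity_matrix")
}

#' Fingerprint match rate of a similarity matrix
#'
#' Percentage of rows whose maximum falls on the diagonal; ties involving
#' an off-diagonal cell count as non-matches.
#'
#' @param sim a square `similarity_matrix` (or plain square matrix).
#' @return Scalar percent in `[0, 100]`.
#' @export
match_rate <- function(sim) {
  v <- if (inherits(sim, "similarity_matrix")) sim$values else sim
  if (nrow(v) != ncol(v)) stop("similarity matrix must be square")
  hits <- vapply(seq_len(nrow(v)), function(i)
    v[i, i] > max(v[i, -i]), logical(1))
  100 * mean(hits)
}

#' Within- versus between-group similarity test
#'
#' Splits the cells of a similarity matrix into within-group (same
#' subject/family) and between-group cells and compares them with a
#' two-sided two-sample t test. When row and column ids coincide (one set
#' of subjects against itself) only off-diagonal upper-triangle cells are
#' used, so self-similarities of exactly 1 never enter.
#'
#' @param sim a `similarity_matrix`.
#' @param grouping vector of group labels per row (and per column if the
#'   ids coincide); for two-session designs, labels per row/col pair.
#' @param grouping_col optional distinct column grouping.
#' @return list with `t_statistic`, `p_value`, `group_means`
#'   (within/between), and the two cell-value vectors.
#' @export
within_between_test <- function(sim, grouping, grouping_col = NULL) {
  v <- sim$values
  same_sets <- is.null(grouping_col) &&
    identical(sim$row_ids, sim$col_ids)
  gr <- as.character(grouping)
  gc <- as.character(if (is.null(grouping_col)) grouping else grouping_col)
  within <- c(); between <- c()
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    if (same_sets && j <= i) next
    if (gr[i] == gc[j]) within <- c(within, v[i, j])
    else between <- c(between, v[i, j])
  }
  if (!length(within) || !length(between))
    stop("a within/between cell class is empty")
  if (sd(within) < 1e-12 && sd(between) < 1e-12) {
    # degenerate but directionally unambiguous comparison
    d <- mean(within) - mean(between)
    tt <- list(statistic = c(t = sign(d) * Inf),
               p.value = if (d == 0) 1 else 0)
  } else {
    tt <- t.test(within, between, var.equal = FALSE)
  }
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       group_means = c(within = mean(within), between = mean(between)),
       within = within, between = between)
}

#' Ranking AUC of a detection score
#'
#' Probability that a randomly chosen positive voxel outranks a randomly
#' chosen negative one (Wilcoxon form); used to score how well a
#' specialization map detects planted specific-component support.
#'
#' @param scores numeric vector.
#' @param labels logical vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
ranking_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both classes")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
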