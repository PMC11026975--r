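#' Representational dissimilarity matrix from feature vectors
#'
#' Entry (i, j) is the correlation distance `1 - Pearson(row_i, row_j)`
#' between two subjects' feature vectors.
#'
#' @param features subjects x features numeric matrix with at least 2
#'   rows; rows must have nonzero variance.
#' @param ids optional subject labels.
#' @return An `rdm` (square symmetric matrix, zero diagonal,
#'   `kind = "feature"`).
#' @export
rdm_from_features <- function(features, ids = rownames(features)) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 subjects")
  if (any(apply(features, 1, sd) == 0)) stop("constant feature row")
  v <- 1 - cor(t(features))
  diag(v) <- 0
  new_rdm(v, ids %||% paste0("s", seq_len(nrow(features))), "feature")
}

#' Representational dissimilarity matrix from a categorical variable
#'
#' Distance 0 when the labels match, 1 otherwise.
#'
#' @param labels vector of categorical labels (length >= 2).
#' @param ids optional subject labels.
#' @return An `rdm` with `kind = "categorical"`.
#' @export
rdm_from_categories <- function(labels, ids = names(labels)) {
  if (length(labels) < 2) stop("need at least 2 subjects")
  v <- outer(labels, labels, FUN = function(a, b) as.numeric(a != b))
  dimnames(v) <- NULL
  new_rdm(v, ids %||% paste0("s", seq_along(labels)), "categorical")
}

new_rdm <- function(values, ids, kind) {
  structure(list(values = values, ids = as.character(ids), kind = kind),
            class = "rdm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rdm_upper <- function(r) r$values[upper.tri(r$values)]

#' Compare two RDMs by rank correlation with a permutation test
#'
#' Correlates the upper triangles (Spearman for continuous feature RDMs,
#' Kendall recommended against categorical RDMs) and obtains a two-sided
#' permutation p value by jointly relabeling the rows and columns of the
#' second RDM.
#'
#' @param a,b `rdm`s of equal size.
#' @param method `"spearman"` or `"kendall"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `rho` and `p_perm`.
#' @export
compare_rdms <- function(a, b, method = c("spearman", "kendall"),
                         n_perm = 5000, seed = 1) {
  method <- match.arg(method)
  if (!identical(dim(a$values), dim(b$values))) stop("size mismatch")
  va <- rdm_upper(a)
  rho <- cor(va, rdm_upper(b), method = method)
  set.seed(seed)
  n <- nrow(b$values)
  cnt <- 0L
  for (k in seq_len(n_perm)) {
    pm <- sample.int(n)
    vb <- b$values[pm, pm][upper.tri(b$values)]
    if (abs(cor(va, vb, method = method)) >= abs(rho) - 1e-12) cnt <- cnt + 1L
  }
  list(rho = rho, p_perm = (1 + cnt) / (1 + n_perm))
}

#' Steiger's z test for two dependent correlations sharing one variable
#'
#' Compares `r_ab` with `r_ac` given the correlation `r_bc` between the
#' two non-shared variables, using the Fisher-z statistic for dependent
#' correlations (Steiger 1980, Z2*-type with mean-correlation pooling).
#' Negative z means `r_ab < r_ac`.
#'
#' @param r_ab,r_ac the two correlations being compared (share variable a).
#' @param r_bc correlation between b and c.
#' @param n sample size (> 3).
#' @return list with `z` and two-sided normal `p`.
#' @export
steiger_z <- function(r_ab, r_ac, r_bc, n) {
  if (any(abs(c(r_ab, r_ac, r_bc)) >= 1)) stop("correlations must be in (-1, 1)")
  if (n <= 3) stop("n must exceed 3")
  rbar <- (r_ab + r_ac) / 2
  det <- 1 + 2 * r_ab * r_ac * r_bc - r_ab^2 - r_ac^2 - r_bc^2
  if (det <= 0) stop("correlation triple is not positive definite")
  f <- (1 - r_bc) / (2 * (1 - rbar^2))
  if (f > 1) f <- 1
  h <- (1 - f * rbar^2) / (1 - rbar^2)
  z1 <- atanh(r_ab)
  z2 <- atanh(r_ac)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_bc) * h))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Pearson partial correlation
#'
#' Correlation of the least-squares residuals of `x` and `y` after
#' regressing both on an intercept plus the covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates optional matrix/data.frame of covariates (full rank).
#' @return list with `r`, `p` (t test on residual df), `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  k <- 0
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cm <- as.matrix(covariates)
    d <- cbind(1, cm)
    if (qr(d)$rank < ncol(d)) stop("rank-deficient covariate design")
    k <- ncol(cm)
    x <- .lm.fit(d, x)$residuals
    y <- .lm.fit(d, y)$residuals
  }
  # a variable fully explained by the covariates carries no partial signal
  if (sd(x) < 1e-10 || sd(y) < 1e-10)
    return(list(r = 0, p = 1, df = n - 2 - k))
  r <- cor(x, y)
  df <- n - 2 - k
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df), df = df)
}

map_matrix <- function(maps) {
  mask <- maps[[1]]$mask
  t(vapply(maps, function(m) m$values[mask], numeric(sum(mask))))
}

#' Principal-component loci analysis
#'
#' Fits a PCA on a training fraction of subjects' maps, scores the held-out
#' subjects, and partial-correlates each held-out subject's PC score with
#' each voxel of the reference features (the maps themselves by default,
#' or e.g. actual gray-matter density), flagging voxels significant after
#' Benjamini-Hochberg FDR correction. This localizes the loci driving the
#' main inter-individual variation of a specialization map.
#'
#' @param features subjects x voxels matrix (e.g. from a list of maps via
#'   their in-mask values) used to fit the PCs.
#' @param reference_features subjects x voxels matrix whose voxels are
#'   correlated against the PC scores (defaults to `features`).
#' @param covariates data.frame of nuisance covariates (age, sex, icv).
#' @param n_pcs number of components (default 2).
#' @param fdr_q FDR level for the significance flags.
#' @param train_frac fraction of subjects used to fit the transformation;
#'   the rest are scored and correlated.
#' @param seed integer seed for the split.
#' @return list with per-PC voxel correlation vectors `r`, adjusted
#'   p-values `q`, logical `significant` flags, the held-out `scores`, and
#'   the split indices.
#' @export
pc_loci_analysis <- function(features, reference_features = features,
                             covariates = NULL, n_pcs = 2, fdr_q = 0.05,
                             train_frac = 0.8, seed = 1) {
  features <- as.matrix(features)
  s <- nrow(features)
  k <- if (is.null(covariates)) 0 else NCOL(covariates)
  if (n_pcs > s - 1) stop("n_pcs exceeds subjects - 1")
  if (s < n_pcs + k + 2) stop("insufficient subjects")
  set.seed(seed)
  tr <- sort(sample.int(s, max(n_pcs + 1, round(train_frac * s))))
  te <- setdiff(seq_len(s), tr)
  if (length(te) < k + 3) stop("held-out set too small for correlation")
  pca <- prcomp(features[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
  scores <- predict(pca, features[te, , drop = FALSE])[, seq_len(n_pcs), drop = FALSE]
  ref <- as.matrix(reference_features)[te, , drop = FALSE]
  cov_te <- if (k > 0) as.matrix(covariates)[te, , drop = FALSE] else NULL
  res <- lapply(seq_len(n_pcs), function(pc) {
    rp <- apply(ref, 2, function(v) {
      if (sd(v) == 0) return(c(0, 1))
      pcres <- partial_correlation(scores[, pc], v, cov_te)
      c(pcres$r, pcres$p)
    })
    q <- p.adjust(rp[2, ], method = "BH")
    list(r = rp[1, ], q = q, significant = q <= fdr_q)
  })
  names(res) <- paste0("pc", seq_len(n_pcs))
  c(res, list(scores = scores, train_idx = tr, test_idx = te,
              explained_variance = pca$sdev^2 / sum(pca$sdev^2)))
}

#' Left:right PC-ratio regression sweep
#'
#' Keeping the total number of principal components fixed at `n_total_pcs`,
#' concatenates the top `k` LH PCs with the top `N - k` RH PCs for
#' `k = 0..N`, fits ordinary least squares from that basis to each of the
#' regional target values (nuisance covariates are regressed out of both
#' sides first), and records the mean R-squared across regions. The shape
#' of the resulting curve shows which hemisphere's structural pattern
#' carries more information about the targets.
#'
#' @param lh_features,rh_features subjects x voxels matrices.
#' @param targets subjects x regions matrix (e.g. the 10 decile means).
#' @param n_total_pcs total PC count N.
#' @param covariates optional nuisance covariates.
#' @return data.frame with `lh_pcs`, `rh_pcs`, `ratio`, `mean_r2`.
#' @export
fit_pc_regression_sweep <- function(lh_features, rh_features, targets,
                                    n_total_pcs, covariates = NULL) {
  lh <- as.matrix(lh_features)
  rh <- as.matrix(rh_features)
  targets <- as.matrix(targets)
  s <- nrow(lh)
  n <- n_total_pcs
  if (n > min(s - 1, ncol(lh), ncol(rh))) stop("n_total_pcs exceeds rank")
  p_lh <- prcomp(lh, center = TRUE)$x[, seq_len(n), drop = FALSE]
  p_rh <- prcomp(rh, center = TRUE)$x[, seq_len(n), drop = FALSE]
  resid_cov <- function(m) {
    if (is.null(covariates) || NCOL(covariates) == 0) return(scale(m, scale = FALSE))
    d <- cbind(1, as.matrix(covariates))
    m - d %*% qr.coef(qr(d), m)
  }
  p_lh <- resid_cov(p_lh)
  p_rh <- resid_cov(p_rh)
  ty <- resid_cov(targets)
  out <- lapply(0:n, function(k) {
    x <- cbind(p_lh[, seq_len(k), drop = FALSE],
               p_rh[, seq_len(n - k), drop = FALSE])
    qx <- qr(cbind(1, x))
    if (qx$rank < ncol(x) + 1) stop("rank-deficient PC design")
    r2 <- apply(ty, 2, function(yy) {
      fit <- qr.fitted(qx, yy)
      1 - sum((yy - fit)^2) / sum((yy - mean(yy))^2)
    })
    data.frame(lh_pcs = k, rh_pcs = n - k,
               ratio = sprintf("%d:%d", k, n - k), mean_r2 = mean(r2))
  })
  do.call(rbind, out)
}

#' Age-prediction transfer across actual and reconstructed hemispheres
#'
#' Fits a PCA (components explaining `var_explained` of the variance) and
#' a linear age regression on the training subjects' concatenated LH+RH
#' features, then transfers the fitted transformation and coefficients to
#' four test image sets: actual+actual, actual LH + reconstructed RH,
#' reconstructed LH + actual RH, reconstructed+reconstructed. A paired t
#' test compares the predictions from the fully actual and fully
#' reconstructed sets.
#'
#' @param train_lh,train_rh training subjects x voxels matrices.
#' @param train_ages numeric vector.
#' @param test_act_lh,test_act_rh,test_rec_lh,test_rec_rh test matrices.
#' @param var_explained cumulative variance fraction kept (0, 1].
#' @return list with `predictions` (a data.frame, one column per image
#'   set), `n_pcs`, and `paired_test` comparing sets 1 and 4.
#' @export
age_transfer_pipeline <- function(train_lh, train_rh, train_ages,
                                  test_act_lh, test_act_rh,
                                  test_rec_lh, test_rec_rh,
                                  var_explained = 0.5) {
  if (var_explained <= 0 || var_explained > 1)
    stop("var_explained must be in (0, 1]")
  xtr <- cbind(as.matrix(train_lh), as.matrix(train_rh))
  pca <- prcomp(xtr, center = TRUE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  npc <- max(1, which(cum >= var_explained)[1])
  str <- pca$x[, seq_len(npc), drop = FALSE]
  fit <- lm(train_ages ~ str)
  beta <- coef(fit)
  pred <- function(lh, rh) {
    sc <- predict(pca, cbind(as.matrix(lh), as.matrix(rh)))[, seq_len(npc), drop = FALSE]
    drop(beta[1] + sc %*% beta[-1])
  }
  preds <- data.frame(act_act = pred(test_act_lh, test_act_rh),
                      act_rec = pred(test_act_lh, test_rec_rh),
                      rec_act = pred(test_rec_lh, test_act_rh),
                      rec_rec = pred(test_rec_lh, test_rec_rh))
  d <- preds$act_act - preds$rec_rec
  pt <- if (sd(d) < 1e-12) list(statistic = c(t = 0), p.value = 1)
  else t.test(preds$act_act, preds$rec_rec, paired = TRUE)
  list(predictions = preds, n_pcs = npc,
       paired_test = list(t = unname(pt$statistic), p = pt$p.value))
}

#' Multivariate variance-component model
#'
#' Decomposes a subjects x measures phenotype matrix as `Y = E + U` with
#' `vec(E) ~ N(0, Sigma_e (x) F)` and `vec(U) ~ N(0, Sigma_u (x) I)`,
#' where `F` is a subject-similarity kernel built from an anatomical
#' feature. Covariates are regressed out of each measure, measures are
#' rank-based inverse-normal (Blom) quantile normalized, `F` is projected
#' to the nearest positive-semidefinite matrix and rescaled to unit
#' diagonal, and the two covariance components are estimated by
#' expectation-maximization on the matrix-normal likelihood (working in
#' the eigenbasis of `F`, where subjects decouple). The explained-variance
#' fraction is `M = tr(Sigma_e) / (tr(Sigma_e) + tr(Sigma_u))`.
#'
#' @param y subjects x measures numeric matrix (S > H + covariates).
#' @param f subjects x subjects similarity kernel.
#' @param covariates optional data.frame/matrix regressed out per measure.
#' @param jackknife when `TRUE`, additionally refits leaving each subject
#'   out once and returns the S leave-one-out M values.
#' @param max_iter,tol EM iteration cap and relative tolerance.
#' @return A `vc_fit` list: `sigma_e`, `sigma_u`, `m`, `jackknife_m`,
#'   `h`, `s`, `converged`, `identifiable`.
#' @export
fit_variance_components <- function(y, f, covariates = NULL,
                                    jackknife = FALSE, max_iter = 500,
                                    tol = 1e-6) {
  y <- as.matrix(y)
  s <- nrow(y); hh <- ncol(y)
  k <- if (is.null(covariates)) 0 else NCOL(covariates)
  if (s <= hh + k) stop("need more subjects than measures plus covariates")
  if (!isTRUE(all.equal(f, t(f), tolerance = 1e-8))) stop("f must be symmetric")

  prep_y <- function(yy, cov) {
    if (!is.null(cov)) {
      d <- cbind(1, as.matrix(cov))
      yy <- yy - d %*% qr.coef(qr(d), yy)
    }
    apply(yy, 2, function(col) {
      r <- rank(col)
      qnorm((r - 3 / 8) / (length(col) + 1 / 4))
    })
  }
  prep_f <- function(ff) {
    e <- eigen((ff + t(ff)) / 2, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    ff <- e$vectors %*% (ev * t(e$vectors))
    d <- sqrt(pmax(diag(ff), 1e-12))
    ff / outer(d, d)
  }

  fit_one <- function(yy, ff, cov) {
    yq <- prep_y(yy, cov)
    fp <- prep_f(ff)
    ed <- eigen(fp, symmetric = TRUE)
    lam <- pmax(ed$values, 0)
    yt <- crossprod(ed$vectors, yq)          # rows decouple
    se <- su <- cov(yq) / 2 + diag(1e-6, ncol(yq))
    n <- nrow(yt)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      se_new <- matrix(0, ncol(yq), ncol(yq))
      su_new <- matrix(0, ncol(yq), ncol(yq))
      npos <- 0
      for (i in seq_len(n)) {
        li <- lam[i]
        yi <- yt[i, ]
        ti <- li * se + su
        tinv <- solve(ti + diag(1e-10, ncol(yq)))
        a <- (li * se) %*% tinv
        mi <- drop(a %*% yi)
        ci <- li * se - a %*% (li * se)
        if (li > 1e-10) {
          se_new <- se_new + (tcrossprod(mi) + ci) / li
          npos <- npos + 1
        }
        ui <- yi - mi
        su_new <- su_new + tcrossprod(ui) + ci
      }
      se_new <- se_new / max(npos, 1)
      su_new <- su_new / n
      delta <- max(abs(se_new - se), abs(su_new - su)) /
        max(abs(se), abs(su), 1e-12)
      se <- (se_new + t(se_new)) / 2
      su <- (su_new + t(su_new)) / 2
      if (delta < tol) { conv <- TRUE; break }
    }
    list(se = se, su = su, conv = conv,
         m = sum(diag(se)) / (sum(diag(se)) + sum(diag(su))),
         lam_spread = sd(lam))
  }

  main <- fit_one(y, f, covariates)
  identifiable <- main$lam_spread > 1e-6
  if (!identifiable)
    warning("similarity kernel is (near) identity: common and unique ",
            "components are not identifiable; M is unreliable")
  jk <- NULL
  if (jackknife) {
    jk <- vapply(seq_len(s), function(i) {
      cov_i <- if (is.null(covariates)) NULL else
        as.matrix(covariates)[-i, , drop = FALSE]
      fit_one(y[-i, , drop = FALSE], f[-i, -i, drop = FALSE], cov_i)$m
    }, numeric(1))
  }
  structure(list(sigma_e = main$se, sigma_u = main$su, m = main$m,
                 jackknife_m = jk, h = hh, s = s,
                 converged = main$conv, identifiable = identifiable),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("<vc_fit S=%d H=%d: M = %.3f (tr Sigma_e %.3f, tr Sigma_u %.3f)%s>\n",
              x$s, x$h, x$m, sum(diag(x$sigma_e)), sum(diag(x$sigma_u)),
              if (!x$identifiable) ", NOT identifiable" else ""))
  invisible(x)
}

#' Subject-similarity kernel from feature vectors
#'
#' Pearson similarity between subjects' anatomical feature vectors,
#' projected to the nearest positive-semidefinite matrix and rescaled to
#' unit diagonal; the `F` kernel of [fit_variance_components()].
#'
#' @param features subjects x voxels matrix.
#' @return S x S kernel matrix.
#' @export
similarity_kernel <- function(features) {
  f <- cor(t(as.matrix(features)))
  e <- eigen((f + t(f)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  f <- e$vectors %*% (ev * t(e$vectors))
  d <- sqrt(pmax(diag(f), 1e-12))
  f / outer(d, d)
}

#' Spatial autocorrelation of specialization maps
#'
#' For randomly sampled in-mask voxels and each distance `k`, averages the
#' six axis-neighbors at offset `k` (in-mask only) and partial-correlates
#' the center against the neighbor mean across subjects, adjusting for
#' covariates. A one-way ANOVA compares the correlation distributions
#' across distances; in spatially structured maps the correlation decays
#' with distance.
#'
#' @param maps list of `specificity_map`s (one per subject, common grid).
#' @param covariates optional per-subject covariates.
#' @param distances integer offsets in voxels (default 1:3).
#' @param n_sample_voxels voxels to sample (capped at the mask size).
#' @param seed integer seed.
#' @return list with `r_table` (voxel, distance, r), `mean_r` per
#'   distance, and `anova_p`.
#' @export
spatial_autocorrelation <- function(maps, covariates = NULL,
                                    distances = 1:3,
                                    n_sample_voxels = 500, seed = 1) {
  mask <- maps[[1]]$mask
  dims <- dim(mask)
  m <- map_matrix(maps)          # subjects x voxels (in-mask)
  idx_mask <- which(mask)
  lin_of <- integer(length(mask))
  lin_of[idx_mask] <- seq_along(idx_mask)
  set.seed(seed)
  nv <- min(n_sample_voxels, length(idx_mask))
  sampled <- sample(idx_mask, nv)
  co <- arrayInd(sampled, dims)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  rows <- list()
  for (kd in distances) {
    for (v in seq_len(nv)) {
      nb <- sweep(offs * kd, 2, co[v, ], "+")
      keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (!any(keep)) next
      lin <- nb[keep, 1] + dims[1] * (nb[keep, 2] - 1) +
        dims[1] * dims[2] * (nb[keep, 3] - 1)
      lin <- lin[mask[lin]]
      if (!length(lin)) next
      nbv <- if (length(lin) == 1) m[, lin_of[lin]]
      else rowMeans(m[, lin_of[lin], drop = FALSE])
      ctr <- m[, lin_of[sampled[v]]]
      if (sd(ctr) == 0 || sd(nbv) == 0) next
      r <- partial_correlation(ctr, nbv, covariates)$r
      rows[[length(rows) + 1]] <- data.frame(voxel = v, distance = kd, r = r)
    }
  }
  tab <- do.call(rbind, rows)
  fit <- aov(r ~ factor(distance), data = tab)
  pv <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(r_table = tab,
       mean_r = tapply(tab$r, tab$distance, mean),
       anova_p = pv)
}
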