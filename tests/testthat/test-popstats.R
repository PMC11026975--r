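test_that("feature RDMs match the brute-force correlation-distance loop", {
  set.seed(2)
  f <- matrix(rnorm(5 * 20), 5, 20)
  r <- rdm_from_features(f)
  for (i in 1:5) for (j in 1:5)
    expect_equal(r$values[i, j], 1 - cor(f[i, ], f[j, ]), tolerance = 1e-12)
  expect_equal(diag(r$values), rep(0, 5))
  expect_equal(r$values, t(r$values))
  # duplicate rows -> 0; centred sign flip -> 2
  f2 <- rbind(f[1, ], f[1, ], -f[1, ] + mean(f[1, ]) * 2)
  r2 <- rdm_from_features(f2)
  expect_equal(r2$values[1, 2], 0, tolerance = 1e-12)
  expect_lt(abs(r2$values[1, 3] - 2), 0.3)  # near-antipodal after centering
  expect_error(rdm_from_features(rbind(f, 0 * f[1, ])), "constant")
})

test_that("categorical RDMs are exact 0/1 mismatch matrices", {
  expect_true(all(rdm_from_categories(rep("a", 4))$values == 0))
  rd <- rdm_from_categories(c("a", "b", "c"))
  expect_true(all(rd$values[upper.tri(rd$values)] == 1))
  lab <- c("x", "y", "x", "z")
  r <- rdm_from_categories(lab)
  for (i in 1:4) for (j in 1:4)
    expect_equal(r$values[i, j], as.numeric(lab[i] != lab[j]))
})

test_that("RDM comparison returns rho 1 on identity and a calibrated null p", {
  set.seed(3)
  f <- matrix(rnorm(8 * 30), 8, 30)
  a <- rdm_from_features(f)
  expect_equal(compare_rdms(a, a, n_perm = 50, seed = 1)$rho, 1)
  # kendall and spearman agree in sign with brute-force rank formulas
  f2 <- matrix(rnorm(4 * 30), 4, 30)
  b <- rdm_from_features(f2)
  va <- a$values[upper.tri(a$values)][1:6]
  vb <- b$values[upper.tri(b$values)][1:6]
  for (m in c("spearman", "kendall")) {
    got <- compare_rdms(structure(list(values = a$values[1:4, 1:4], ids = 1:4,
                                       kind = "feature"), class = "rdm"),
                        b, method = m, n_perm = 20, seed = 2)$rho
    expect_equal(sign(got), sign(cor(a$values[1:4, 1:4][upper.tri(diag(4))],
                                     vb, method = m)))
  }
})

test_that("Steiger's z matches a direct formula evaluation and is signed correctly", {
  expect_equal(steiger_z(0.5, 0.5, 0.3, 50)$z, 0)
  expect_lt(steiger_z(0.3, 0.6, 0.4, 80)$z, 0)
  expect_gt(steiger_z(0.6, 0.3, 0.4, 80)$z, 0)
  # independent re-derivation of the pooled dependent-correlation z
  r1 <- 0.63; r2 <- 0.21; r3 <- 0.45; n <- 103
  rbar <- (r1 + r2) / 2
  f <- min(1, (1 - r3) / (2 * (1 - rbar^2)))
  hbar <- (1 - f * rbar^2) / (1 - rbar^2)
  zexp <- (atanh(r1) - atanh(r2)) *
    sqrt((n - 3) / (2 * (1 - r3) * hbar))
  got <- steiger_z(r1, r2, r3, n)
  expect_equal(got$z, zexp, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(zexp)), tolerance = 1e-12)
  expect_error(steiger_z(1.2, 0.3, 0.1, 30), "in \\(-1, 1\\)")
  expect_error(steiger_z(0.2, 0.3, 0.1, 3), "exceed 3")
})

test_that("partial correlation equals the residualize-then-correlate oracle", {
  set.seed(8)
  n <- 60
  z <- cbind(rnorm(n), rnorm(n))
  x <- 0.5 * z[, 1] + rnorm(n)
  y <- -0.3 * z[, 1] + 0.2 * z[, 2] + rnorm(n)
  got <- partial_correlation(x, y, z)
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  expect_equal(got$r, cor(rx, ry), tolerance = 1e-12)
  # no covariates -> plain Pearson
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  # y an exact linear function of covariates -> r = 0
  ylin <- 2 + z %*% c(1, -2)
  expect_equal(partial_correlation(x, drop(ylin), z)$r, 0, tolerance = 1e-10)
  expect_error(partial_correlation(x, y, cbind(z, z[, 1])), "rank-deficient")
})

test_that("PC loci analysis recovers a planted single-factor pattern", {
  set.seed(4)
  s <- 60; nv <- 300
  pattern <- c(rep(1, 60), rep(0, nv - 60))
  score <- rnorm(s, sd = 2)
  maps <- outer(score, pattern) + matrix(rnorm(s * nv, sd = 0.05), s, nv)
  res <- pc_loci_analysis(maps, n_pcs = 2, train_frac = 0.7, seed = 5)
  te <- res$test_idx
  expect_gt(abs(cor(res$scores[, 1], score[te])), 0.99)
  # loci: significant voxels concentrate on the pattern support
  expect_gt(mean(res$pc1$significant[1:60]), 0.9)
  expect_lt(mean(res$pc1$significant[61:nv]), 0.2)
  expect_error(pc_loci_analysis(maps, n_pcs = 60), "n_pcs")
})

test_that("PC loci analysis controls FDR under a permuted null", {
  set.seed(6)
  s <- 50; nv <- 200
  maps <- matrix(rnorm(s * nv), s, nv)
  res <- pc_loci_analysis(maps, n_pcs = 2, fdr_q = 0.05,
                          train_frac = 0.6, seed = 7)
  expect_lte(mean(res$pc1$significant), 0.05)
  expect_lte(mean(res$pc2$significant), 0.05)
})

test_that("PC-ratio sweep favors the hemisphere that generated the targets", {
  set.seed(9)
  s <- 80; nv <- 120
  lh <- matrix(rnorm(s * nv), s, nv)
  rh <- matrix(rnorm(s * nv), s, nv)
  rp <- prcomp(rh)$x[, 1]
  targets <- sapply(1:10, function(k) rp * k / 10 + rnorm(s, sd = 0.2))
  sw <- fit_pc_regression_sweep(lh, rh, targets, n_total_pcs = 4)
  expect_equal(nrow(sw), 5)  # N + 1 rows
  r2_rh_only <- sw$mean_r2[sw$lh_pcs == 0]
  r2_lh_only <- sw$mean_r2[sw$lh_pcs == 4]
  expect_gt(r2_rh_only, r2_lh_only + 0.3)
})

test_that("PC-ratio sweep matches brute-force OLS on a tiny instance", {
  set.seed(10)
  s <- 12
  lh <- matrix(rnorm(s * 6), s, 6)
  rh <- matrix(rnorm(s * 6), s, 6)
  y <- cbind(rnorm(s), rnorm(s))
  sw <- fit_pc_regression_sweep(lh, rh, y, n_total_pcs = 2)
  p_lh <- prcomp(lh)$x[, 1:2]
  p_rh <- prcomp(rh)$x[, 1:2]
  for (k in 0:2) {
    x <- cbind(p_lh[, seq_len(k), drop = FALSE],
               p_rh[, seq_len(2 - k), drop = FALSE])
    x <- scale(x, scale = FALSE)
    yy <- scale(y, scale = FALSE)
    r2 <- sapply(1:2, function(j) summary(lm(yy[, j] ~ x))$r.squared)
    expect_equal(sw$mean_r2[sw$lh_pcs == k], mean(r2), tolerance = 1e-10)
  }
})

test_that("age transfer pipeline recovers a planted linear age effect", {
  set.seed(12)
  s_tr <- 80; s_te <- 30; nv <- 100
  age_tr <- runif(s_tr, 20, 80)
  age_te <- runif(s_te, 20, 80)
  pat1 <- rnorm(nv); pat2 <- rnorm(nv)
  mk <- function(age, noise) outer(age / 50, pat1) +
    outer(rnorm(length(age)), pat2 * 0.3) +
    matrix(rnorm(length(age) * nv, sd = noise), length(age), nv)
  tr_lh <- mk(age_tr, 0.2); tr_rh <- mk(age_tr, 0.2)
  te_lh <- mk(age_te, 0.2); te_rh <- mk(age_te, 0.2)
  res <- age_transfer_pipeline(tr_lh, tr_rh, age_tr, te_lh, te_rh,
                               te_lh, te_rh, var_explained = 0.5)
  # identical actual and reconstructed sets -> identical predictions, p = 1
  expect_equal(res$predictions$act_act, res$predictions$rec_rec)
  expect_equal(res$paired_test$p, 1)
  expect_gt(cor(res$predictions$act_act, age_te), 0.7)
  # degraded reconstructions shift the paired comparison
  res2 <- age_transfer_pipeline(tr_lh, tr_rh, age_tr, te_lh, te_rh,
                                te_lh * 0.2, te_rh * 0.2)
  expect_false(isTRUE(all.equal(res2$predictions$act_act,
                                res2$predictions$rec_rec)))
  expect_error(age_transfer_pipeline(tr_lh, tr_rh, age_tr, te_lh, te_rh,
                                     te_lh, te_rh, var_explained = 0),
               "var_explained")
})

test_that("variance-component limits behave: kernel-aligned data give M near 1", {
  set.seed(14)
  s <- 80; hh <- 3
  f <- similarity_kernel(matrix(rnorm(s * 40), s, 40))
  ed <- eigen(f, symmetric = TRUE)
  a <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  e <- a %*% matrix(rnorm(s * hh), s, hh) * 0.5
  fit <- fit_variance_components(e + matrix(rnorm(s * hh, sd = 1e-3), s, hh),
                                 f, max_iter = 2000)
  expect_gt(fit$m, 0.9)
  expect_true(all(eigen(fit$sigma_e, symmetric = TRUE)$values > -1e-8))
  # identity kernel is flagged non-identifiable
  expect_warning(fit_variance_components(matrix(rnorm(s * hh), s, hh), diag(s)),
                 "identifiable")
})

test_that("spatial autocorrelation is near zero for white maps and decays for smooth maps", {
  dims <- c(16, 16, 16)
  mask <- hemispec:::ellipsoid_mask(dims, 0.42)
  mk_maps <- function(smooth_sigma, n = 30, seed = 1) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      a <- array(rnorm(prod(dims)), dims)
      if (smooth_sigma > 0) a <- hemispec:::smooth3d(a, smooth_sigma)
      a[!mask] <- 0
      hemispec:::new_specificity_map(a, mask, "ANS", "LH",
                                     subject_id = paste0("s", i))
    })
  }
  white <- spatial_autocorrelation(mk_maps(0), n_sample_voxels = 150, seed = 3)
  expect_lt(max(abs(white$mean_r)), 0.05)
  sm <- spatial_autocorrelation(mk_maps(2, seed = 2), n_sample_voxels = 150,
                                seed = 3)
  expect_true(all(diff(sm$mean_r) < 0))
  expect_lt(sm$anova_p, 0.01)
})

test_that("leave-one-out jackknife returns one M per subject, near the full fit", {
  set.seed(33)
  s <- 30; hh <- 2
  f <- similarity_kernel(matrix(rnorm(s * 20), s, 20))
  ed <- eigen(f, symmetric = TRUE)
  a <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  y <- a %*% matrix(rnorm(s * hh), s, hh) * 0.4 + matrix(rnorm(s * hh, sd = 0.3), s, hh)
  fit <- fit_variance_components(y, f, covariates = data.frame(age = rnorm(s)),
                                 jackknife = TRUE)
  expect_length(fit$jackknife_m, s)
  expect_true(all(fit$jackknife_m >= 0 & fit$jackknife_m <= 1))
  expect_lt(abs(mean(fit$jackknife_m) - fit$m), 0.15)
})
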