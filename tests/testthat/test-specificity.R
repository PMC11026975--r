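make_map_pair <- function(seed = 1, dims = c(8, 8, 8)) {
  act <- tiny_grid(seed, dims, "RH")
  rec <- tiny_grid(seed + 50, dims, "RH")
  rec$mask <- act$mask
  rec$values[!rec$mask] <- 0
  list(act = act, rec = rec)
}

test_that("ANS is the symmetric absolute residual", {
  p <- make_map_pair()
  a <- ans_map(p$act, p$rec)
  expect_equal(a$values, abs(p$act$values - p$rec$values) *
                 (p$act$mask * 1), tolerance = 1e-14)
  expect_true(all(a$values >= 0))
  # worked example and argument symmetry
  g1 <- p$act; g1$values[g1$mask][1] <- 0.8
  g2 <- p$rec; g2$values[g2$mask][1] <- 0.5
  expect_equal(ans_map(g1, g2)$values[g1$mask][1], 0.3)
  expect_equal(ans_map(p$act, p$rec)$values, ans_map(p$rec, p$act)$values)
  expect_identical(a$metric, "ANS")
  expect_false(a$harmonized)
})

test_that("RNS is the scale-invariant residual proportion with a zero guard", {
  p <- make_map_pair(3)
  r <- rns_map(p$act, p$rec)
  i <- which(p$act$mask)[1:50]
  expect_equal(r$values[i],
               abs(p$act$values[i] - p$rec$values[i]) /
                 (p$act$values[i] + p$rec$values[i]), tolerance = 1e-14)
  expect_true(all(r$values >= 0 & r$values <= 1))
  # 0.8 vs 0.4 -> 1/3
  g1 <- p$act; g1$values[which(g1$mask)[1]] <- 0.8
  g2 <- p$rec; g2$values[which(g2$mask)[1]] <- 0.4
  expect_equal(rns_map(g1, g2)$values[which(g1$mask)[1]], 1 / 3)
  # invariance under positive rescaling (values kept in [0,1])
  for (cc in c(0.25, 0.6)) {
    a2 <- p$act; a2$values <- a2$values * cc
    r2 <- p$rec; r2$values <- r2$values * cc
    expect_equal(rns_map(a2, r2)$values, r$values, tolerance = 1e-12)
  }
  # both zero at a voxel -> 0, not NaN
  a0 <- p$act; r0 <- p$rec
  j <- which(a0$mask)[2]
  a0$values[j] <- 0; r0$values[j] <- 0
  expect_identical(rns_map(a0, r0)$values[j], 0)
})

test_that("decile partition matches a brute-force sort with raster ties", {
  dims <- c(8, 8, 8)
  mask <- array(FALSE, dims); mask[2:6, 2:6, 2:5] <- TRUE
  set.seed(4)
  v <- array(0, dims); v[mask] <- sample(seq_len(sum(mask)))
  m <- hemispec:::new_specificity_map(v, mask, "ANS", "LH")
  dp <- decile_partition(m)
  lab <- dp$part_labels
  # partition: union = mask, sizes within one voxel
  expect_true(all(lab[mask] %in% 1:10) && all(lab[!mask] == 0))
  expect_lte(diff(range(table(lab[mask]))), 1)
  # brute force: top values land in part 1
  idx <- which(mask)
  ord <- idx[order(-v[idx])]
  n1 <- sum(lab == 1)
  expect_setequal(which(lab == 1), ord[seq_len(n1)])
  # constant map: assignment fixed purely by raster order
  vc <- array(0, dims); vc[mask] <- 1
  mc <- hemispec:::new_specificity_map(vc, mask, "ANS", "LH")
  labc <- decile_partition(mc)$part_labels
  expect_equal(labc[mask][order(which(mask))],
               rep(1:10, times = table(labc[mask])))
  expect_error(decile_partition(
    hemispec:::new_specificity_map(array(1, c(8, 8, 8)),
      array(c(rep(TRUE, 5), rep(FALSE, 507)), c(8, 8, 8)), "ANS", "LH")),
    "fewer than 10")
})

test_that("regional summaries match brute-force accumulation", {
  dims <- c(8, 8, 8)
  mask <- array(FALSE, dims); mask[2:7, 2:7, 2:7] <- TRUE
  labels <- array(0L, dims)
  labels[2:7, 2:7, 2:4] <- 1L
  labels[2:7, 2:7, 5:7] <- 2L
  set.seed(9)
  v <- array(0, dims); v[mask] <- runif(sum(mask))
  m <- hemispec:::new_specificity_map(v, mask, "ANS", "LH")
  tab <- summarize_map(m, labels)
  expect_equal(tab$mean_value[tab$region_id == 0], mean(v[mask]))
  expect_equal(tab$mean_value[tab$region_id == 1], mean(v[labels == 1]))
  expect_equal(tab$mean_value[tab$region_id == 2], mean(v[labels == 2]))
  # two-region toy {1,1 | 3}
  mk <- array(FALSE, dims); mk[1, 1, 1:3] <- TRUE
  lv <- array(0L, dims); lv[1, 1, 1:2] <- 1L; lv[1, 1, 3] <- 2L
  vv <- array(0, dims); vv[1, 1, 1:3] <- c(1, 1, 3)
  t2 <- summarize_map(hemispec:::new_specificity_map(vv, mk, "ANS", "LH"), lv)
  expect_equal(t2$mean_value, c(5 / 3, 1, 3))
})

test_that("ComBat removes a planted batch shift and keeps an orthogonal age slope", {
  dims <- c(8, 8, 8)
  mask <- hemispec:::ellipsoid_mask(dims, 0.4)
  nv <- sum(mask)
  n <- 24
  set.seed(21)
  batch <- rep(c("A", "B"), each = n / 2)
  age <- rep(seq(20, 70, length.out = n / 2), 2)  # balanced across batches
  base <- runif(nv, 0.2, 0.6)
  subj <- rnorm(n, sd = 0.05)
  slope <- 0.002
  maps <- lapply(seq_len(n), function(i) {
    v <- array(0, dims)
    # identical voxel pattern + per-subject level + age slope + batch shift
    v[mask] <- base + subj[i] + slope * (age[i] - 45) +
      ifelse(batch[i] == "B", 0.1, 0)
    hemispec:::new_specificity_map(v, mask, "ANS", "LH",
                                   subject_id = sprintf("s%02d", i))
  })
  harm <- harmonize_combat(maps, batch, data.frame(age = age))
  expect_true(all(vapply(harm, function(m) m$harmonized, TRUE)))
  hm <- vapply(harm, function(m) m$values[mask], numeric(nv))
  mA <- rowMeans(hm[, batch == "A"])
  mB <- rowMeans(hm[, batch == "B"])
  expect_lt(max(abs(mA - mB)), 1e-6)
  # age slope preserved in sign and approximate magnitude
  sl <- apply(hm, 1, function(r) coef(lm(r ~ age))[2])
  expect_true(all(sl > 0))
  expect_equal(mean(sl), slope, tolerance = 0.35)
  expect_error(harmonize_combat(maps, rep("A", n)), "at least 2 batches")
  expect_error(harmonize_combat(maps, c("B", rep("A", n - 1))),
               "at least 2 subjects")
})

test_that("pairwise similarity and match rate behave as fingerprints", {
  maps <- lapply(1:5, function(i) {
    g <- tiny_grid(i, hemisphere = "LH")
    hemispec:::new_specificity_map(g$values, g$mask, "ANS", "LH",
                                   subject_id = paste0("s", i))
  })
  sim <- pairwise_similarity(maps, maps)
  expect_equal(diag(sim$values), rep(1, 5), tolerance = 1e-12)
  expect_equal(match_rate(sim), 100)
  # brute-force oracle on the full matrix
  mask <- maps[[1]]$mask
  for (i in 1:5) for (j in 1:5)
    expect_equal(sim$values[i, j],
                 cor(maps[[i]]$values[mask], maps[[j]]$values[mask]),
                 tolerance = 1e-12)
  # antipodal pair -> -1
  neg <- maps[[1]]
  neg$values[mask] <- -maps[[1]]$values[mask] + 0.9
  expect_equal(pairwise_similarity(list(maps[[1]]), list(neg))$values[1, 1], -1)
  # rows maxed off-diagonal -> 0%
  m2 <- matrix(c(0.1, 0.9, 0.9, 0.1), 2)
  expect_equal(match_rate(m2), 0)
})

test_that("within/between similarity test separates planted groups", {
  v <- matrix(0.1, 6, 6)
  grp <- rep(c("f1", "f2", "f3"), each = 2)
  for (i in 1:6) for (j in 1:6) if (grp[i] == grp[j]) v[i, j] <- 0.9
  sim <- structure(list(values = v, row_ids = paste0("s", 1:6),
                        col_ids = paste0("s", 1:6), stat = "Pearson"),
                   class = "similarity_matrix")
  res <- within_between_test(sim, grp)
  expect_gt(res$t_statistic, 0)
  expect_lt(res$p_value, 0.001)
  expect_equal(unname(res$group_means), c(0.9, 0.1))
  # within-family cells counted once per unordered pair
  expect_length(res$within, 3)
  expect_length(res$between, 12)
})

test_that("ranking AUC matches the Wilcoxon formula on a known case", {
  sc <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  lb <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(ranking_auc(sc, lb), 1)
  expect_equal(ranking_auc(-sc, lb), 0)
  set.seed(1)
  s <- rnorm(200); l <- rep(c(TRUE, FALSE), 100)
  pr <- mean(outer(s[l], s[!l], ">")) # brute force
  expect_equal(ranking_auc(s, l), pr, tolerance = 1e-12)
})
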