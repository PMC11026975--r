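test_that("reconstruction loss matches trivial cases and a brute-force oracle", {
  g <- tiny_grid(1)
  expect_equal(reconstruction_loss(g, g), 0)
  # all-ones vs all-zeros inside a 10-voxel mask -> exactly 1
  dims <- c(8, 8, 8)
  mask <- array(FALSE, dims); mask[1:2, 1, 1:5] <- TRUE
  a <- volume_grid(array(as.numeric(mask), dims), mask, "LH")
  b <- volume_grid(array(0, dims) + 1e-12 * mask, mask, "LH")
  b$values[] <- 0
  expect_equal(reconstruction_loss(a, b), 1)
  # random pair against an independent accumulation loop
  x <- tiny_grid(3); y <- tiny_grid(4); y$mask <- x$mask
  y$values[!y$mask] <- 0
  acc <- 0; nvox <- 0
  for (i in which(x$mask)) { acc <- acc + (x$values[i] - y$values[i])^2; nvox <- nvox + 1 }
  expect_equal(reconstruction_loss(x, y), acc / nvox, tolerance = 1e-10)
  z <- tiny_grid(5, c(16, 16, 16))
  expect_error(reconstruction_loss(x, z), "shape")
})

test_that("gradient penalty matches the analytic value for hand-set critics", {
  m <- build_ce_model(ce_config(in_shape = c(8, 8, 8), base_channels = 4, n_down_blocks = 3),
                      seed = 1)
  real <- tiny_grid(1, hemisphere = "RH")
  fake <- tiny_grid(2, hemisphere = "RH")
  # linear critic D(x) = w.x + b: penalty = (||w|| - 1)^2 for any epsilon
  set.seed(3)
  w <- rnorm(8^3, sd = 0.05)
  lm1 <- linear_critic_model(m, w, b = 0.7)
  expect_equal(gradient_penalty(lm1, real, fake, seed = 1),
               (sqrt(sum(w^2)) - 1)^2, tolerance = 1e-5)
  expect_equal(gradient_penalty(lm1, real, fake, seed = 99),
               (sqrt(sum(w^2)) - 1)^2, tolerance = 1e-5)
  # constant critic: zero gradient -> penalty (0 - 1)^2 = 1
  lm0 <- linear_critic_model(m, numeric(8^3), b = 2)
  expect_equal(gradient_penalty(lm0, real, fake, seed = 1), 1)
  # real = fake: interpolate is the input for any epsilon -> seed-independent
  p1 <- gradient_penalty(m, real, real, seed = 1)
  p2 <- gradient_penalty(m, real, real, seed = 2)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("gradient-penalty parameter gradients agree with finite differences", {
  m <- build_ce_model(ce_config(in_shape = c(8, 8, 8), base_channels = 2, n_down_blocks = 3),
                      seed = 4)
  set.seed(5)
  xhat <- array(runif(2 * 8^3), c(1, 8^3, 2))
  gp <- hemispec:::gp_eval(m$critic, xhat, with_grads = TRUE)
  pen_of <- function(layers) hemispec:::gp_eval(layers, xhat,
                                                with_grads = FALSE)$penalty
  eps <- 1e-5
  for (li in seq_along(m$critic)) {
    g <- gp$grads[[li]]
    if (!length(g)) next
    for (nm in names(g)) {
      j <- which.max(abs(g[[nm]]))
      l2 <- m$critic; l2[[li]][[nm]][j] <- l2[[li]][[nm]][j] + eps
      l1 <- m$critic; l1[[li]][[nm]][j] <- l1[[li]][[nm]][j] - eps
      num <- (pen_of(l2) - pen_of(l1)) / (2 * eps)
      expect_equal(g[[nm]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("training is a no-op at zero epochs and reproducible from the seed", {
  coh <- generate_cohort(synth_config(grid_shape = c(16, 16, 16),
                                      n_subjects = 4, seed = 2))
  m <- build_ce_model(ce_config(in_shape = c(16, 16, 16), base_channels = 4),
                      seed = 1)
  cfg0 <- train_config(epochs = 0, seed = 1)
  expect_identical(train_ce(m, coh$pairs, cfg0)$model$gen, m$gen)
  cfg2 <- train_config(learning_rate = 1e-3, batch_size = 4, epochs = 2,
                       critic_steps_per_gen_step = 1, seed = 7)
  f1 <- train_ce(m, coh$pairs, cfg2)
  f2 <- train_ce(m, coh$pairs, cfg2)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$gen, f2$model$gen)
  expect_true(all(f1$log$l_rec >= 0))
  expect_equal(f1$log$l_total,
               0.9 * f1$log$l_rec + 0.1 * (f1$log$l_g + f1$log$l_d),
               tolerance = 1e-12)
  expect_error(train_ce(m, list(), cfg2), "empty")
})

test_that("a reconstruction-only run shrinks validation loss five-fold on a no-specific cohort", {
  coh <- generate_cohort(synth_config(grid_shape = c(32, 32, 32),
                                      n_subjects = 48, specific_amplitude = 0,
                                      seed = 6))
  m <- build_ce_model(ce_config(in_shape = c(32, 32, 32), base_channels = 8,
                                bottleneck_channels = 128,
                                use_critic = FALSE),
                      seed = 2)
  cfg <- train_config(lambda_rec = 1, lambda_adv = 0, learning_rate = 1e-3,
                      lr_decay = 0.99, batch_size = 8, epochs = 150, seed = 3)
  fit <- train_ce(m, coh$pairs[1:40], cfg, val_cohort = coh$pairs[41:48])
  expect_lt(tail(fit$log$val_l_rec, 1), fit$log$val_l_rec[1] / 5)
  # smoothed validation trace decreases overall
  sm <- stats::filter(fit$log$val_l_rec, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(tail(sm, 1), sm[1])
  # reconstruction error against the true target improves >= 5x vs untrained
  pre <- mean(sapply(41:48, function(i)
    reconstruction_loss(coh$pairs[[i]]$rh, ce_generate(m, coh$pairs[[i]]$lh))))
  post <- mean(sapply(41:48, function(i)
    reconstruction_loss(coh$pairs[[i]]$rh,
                        ce_generate(fit$model, coh$pairs[[i]]$lh))))
  expect_lt(post, pre / 5)
})

test_that("virtual lesion bookkeeping: background ROI leaves the loss unchanged", {
  coh <- generate_cohort(synth_config(grid_shape = c(16, 16, 16),
                                      n_subjects = 2, seed = 4))
  m <- build_ce_model(ce_config(in_shape = c(16, 16, 16), base_channels = 4),
                      seed = 3)
  p <- coh$pairs[[1]]
  labels <- array(0L, dim(coh$mask))
  labels[coh$mask] <- 1L
  corner <- which(!coh$mask)[1:20]
  labels[corner] <- 2L           # ROI entirely outside the brain mask
  tab <- virtual_lesion(m, p, labels, "lh2rh")
  expect_equal(nrow(tab), 2)     # one row per nonzero ROI
  expect_equal(tab$lesioned_loss[tab$roi_id == 2],
               tab$intact_loss[tab$roi_id == 2], tolerance = 1e-12)
  expect_error(virtual_lesion(m, p, array(0L, c(8, 8, 8)), "lh2rh"),
               "aligned")
})
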