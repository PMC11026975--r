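#' Training configuration for the context encoder
#'
#' Defaults follow the published recipe: reconstruction weight 0.9,
#' adversarial weight 0.1, learning rate 1e-4, batch size 16, 3000 epochs.
#' The gradient-penalty weight (10) and five critic updates per generator
#' update follow the standard Wasserstein-GP recipe. Desk-scale runs pass
#' smaller `epochs` (and usually a larger learning rate); the defaults are
#' the full-scale values.
#'
#' @param lambda_rec weight of the voxelwise L2 reconstruction loss.
#' @param lambda_adv weight of the adversarial terms.
#' @param gp_lambda gradient-penalty weight.
#' @param critic_steps_per_gen_step critic updates per generator update.
#' @param learning_rate Adam step size (betas 0.5/0.9).
#' @param lr_decay multiplicative per-epoch learning-rate decay (1 = none).
#' @param batch_size minibatch size.
#' @param epochs passes over the cohort.
#' @param weight_decay decoupled L2 weight decay applied to generator
#'   multiplicative weights (0 disables; small desk-scale runs benefit from
#'   mild decay against overfitting).
#' @param direction `"lh2rh"` or `"rh2lh"`.
#' @param seed integer seed controlling shuffling and interpolation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(lambda_rec = 0.9, lambda_adv = 0.1, gp_lambda = 10,
                         critic_steps_per_gen_step = 5, learning_rate = 1e-4,
                         lr_decay = 1, batch_size = 16, epochs = 3000,
                         weight_decay = 0,
                         direction = c("lh2rh", "rh2lh"), seed = 1) {
  direction <- match.arg(direction)
  if (lambda_rec + lambda_adv <= 0) stop("lambda_rec + lambda_adv must be > 0")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  if (batch_size < 1 || critic_steps_per_gen_step < 1) stop("invalid counts")
  structure(list(lambda_rec = lambda_rec, lambda_adv = lambda_adv,
                 gp_lambda = gp_lambda,
                 critic_steps_per_gen_step = as.integer(critic_steps_per_gen_step),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 direction = direction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Masked voxelwise L2 reconstruction loss
#'
#' Mean squared difference over in-mask voxels.
#'
#' @param target,generated `volume_grid`s with identical shapes and masks.
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(target, generated) {
  stopifnot(inherits(target, "volume_grid"), inherits(generated, "volume_grid"))
  if (!identical(dim(target$values), dim(generated$values)))
    stop("shape mismatch")
  if (!identical(target$mask, generated$mask)) stop("mask mismatch")
  mean((target$values[target$mask] - generated$values[target$mask])^2)
}

#' Gradient penalty of the Wasserstein critic
#'
#' Draws one uniform interpolation coefficient per sample, forms the
#' interpolate between real and generated volumes, and returns the mean of
#' `(||grad_x D(xhat)||_2 - 1)^2` over the batch.
#'
#' @param model a `ce_model` with a critic.
#' @param real,fake `volume_grid`s (or lists of grids) of matching shape.
#' @param seed integer seed for the interpolation coefficients.
#' @return Nonnegative scalar penalty.
#' @export
gradient_penalty <- function(model, real, fake, seed = 1) {
  stopifnot(inherits(model, "ce_model"))
  if (is.null(model$critic)) stop("model was built without a critic")
  reals <- if (inherits(real, "volume_grid")) list(real) else real
  fakes <- if (inherits(fake, "volume_grid")) list(fake) else fake
  if (length(reals) != length(fakes)) stop("batch sizes differ")
  xr <- as_input_cube(reals)
  xf <- as_input_cube(fakes)
  if (!identical(dim(xr), dim(xf))) stop("shape mismatch")
  set.seed(seed)
  eps <- runif(length(reals))
  xhat <- xr
  for (s in seq_along(reals)) xhat[, , s] <- eps[s] * xr[, , s] + (1 - eps[s]) * xf[, , s]
  gp_eval(model$critic, xhat, with_grads = FALSE)$penalty
}

cube_mse <- function(a, b, maskvec) {
  n <- dim(a)[3]
  s <- 0
  for (i in seq_len(n)) s <- s + mean((a[1, , i][maskvec] - b[1, , i][maskvec])^2)
  s / n
}

#' Train the context-encoder GAN
#'
#' Alternates `critic_steps_per_gen_step` Wasserstein-GP critic updates
#' with one generator update minimizing
#' `lambda_rec * L_rec + lambda_adv * L_G`, where `L_rec` is the masked
#' voxelwise L2 loss and `L_G = -mean(D(G(x)))`. The critic loss is the
#' standard `mean(D(G(x))) - mean(D(y)) + gp_lambda * penalty`. Losses are
#' logged per epoch; when a validation cohort is given its reconstruction
#' loss is evaluated in inference mode each epoch. The run is deterministic
#' given the seed.
#'
#' @param model a [build_ce_model()] model (with critic unless
#'   `lambda_adv = 0`).
#' @param cohort list of `hemisphere_pair`s.
#' @param cfg a [train_config()].
#' @param val_cohort optional validation list of pairs.
#' @param verbose print per-epoch losses.
#' @return `list(model = <trained ce_model>, log = <data.frame of loss
#'   records>)`.
#' @export
train_ce <- function(model, cohort, cfg, val_cohort = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ce_model"), inherits(cfg, "train_config"))
  if (length(cohort) == 0) stop("cohort is empty")
  src <- function(p) if (cfg$direction == "lh2rh") p$lh else p$rh
  tgt <- function(p) if (cfg$direction == "lh2rh") p$rh else p$lh
  use_adv <- cfg$lambda_adv > 0
  if (use_adv && is.null(model$critic))
    stop("adversarial training requires a critic")

  x_all <- as_input_cube(lapply(cohort, src))
  y_all <- as_input_cube(lapply(cohort, tgt))
  maskvec <- as.logical(tgt(cohort[[1]])$mask)
  mvec <- as.numeric(maskvec)
  nmask <- sum(maskvec)
  n <- length(cohort)
  model$target_mask <- tgt(cohort[[1]])$mask
  model$direction <- cfg$direction
  on_pair <- isTRUE(model$config$critic_on_pair)

  xv <- yv <- NULL
  if (!is.null(val_cohort) && length(val_cohort)) {
    xv <- as_input_cube(lapply(val_cohort, src))
    yv <- as_input_cube(lapply(val_cohort, tgt))
  }
  val_rec <- function() {
    if (is.null(xv)) return(NA_real_)
    out <- net_forward(model$gen, xv, train = FALSE)$y
    for (i in seq_len(dim(out)[3])) out[1, , i] <- out[1, , i] * mvec
    cube_mse(out, yv, maskvec)
  }

  log <- vector("list", cfg$epochs)
  if (cfg$epochs == 0)
    return(list(model = model, log = data.frame()))

  set.seed(cfg$seed)
  st_g <- adam_init(model$gen)
  st_d <- if (use_adv) adam_init(model$critic) else NULL
  tg <- td <- 0L
  crit_in <- function(xb, v) if (on_pair) abind_channel(xb, v) else v

  for (ep in seq_len(cfg$epochs)) {
    lr_ep <- cfg$learning_rate * cfg$lr_decay^(ep - 1)
    perm <- sample.int(n)
    l_rec_ep <- l_g_ep <- l_d_ep <- 0
    nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1, n)]
      bs <- length(idx)
      xb <- x_all[, , idx, drop = FALSE]
      yb <- y_all[, , idx, drop = FALSE]

      l_d <- 0
      if (use_adv) {
        # fake batch (detached from the generator)
        fake <- net_forward(model$gen, xb, train = TRUE)$y
        for (i in seq_len(bs)) fake[1, , i] <- fake[1, , i] * mvec
        real_in <- crit_in(xb, yb)
        fake_in <- crit_in(xb, fake)
        for (k in seq_len(cfg$critic_steps_per_gen_step)) {
          fr <- critic_forward(model$critic, real_in)
          gr_r <- critic_backward(model$critic, fr$caches, rep(-1 / bs, bs),
                                  need_gx = FALSE)$grads
          ff <- critic_forward(model$critic, fake_in)
          gr_f <- critic_backward(model$critic, ff$caches, rep(1 / bs, bs),
                                  need_gx = FALSE)$grads
          eps <- runif(bs)
          xhat <- real_in
          for (s in seq_len(bs))
            xhat[, , s] <- eps[s] * real_in[, , s] + (1 - eps[s]) * fake_in[, , s]
          gp <- gp_eval(model$critic, xhat, with_grads = TRUE)
          g_tot <- grads_axpy(grads_axpy(gr_f, gr_r), gp$grads, cfg$gp_lambda)
          td <- td + 1L
          up <- adam_step(model$critic, g_tot, st_d, lr_ep, td)
          model$critic <- up$layers
          st_d <- up$state
          l_d <- mean(ff$y) - mean(fr$y) + cfg$gp_lambda * gp$penalty
        }
      }

      # generator update
      fw <- net_forward(model$gen, xb, train = TRUE)
      model$gen <- fw$layers  # batch-norm running stats
      fake <- fw$y
      for (i in seq_len(bs)) fake[1, , i] <- fake[1, , i] * mvec
      l_rec <- cube_mse(fake, yb, maskvec)
      dfake <- fake
      for (i in seq_len(bs))
        dfake[1, , i] <- cfg$lambda_rec * 2 * (fake[1, , i] - yb[1, , i]) *
          mvec / (nmask * bs)
      l_g <- 0
      if (use_adv) {
        fake_in <- crit_in(xb, fake)
        ffg <- critic_forward(model$critic, fake_in)
        l_g <- -mean(ffg$y)
        gadv <- critic_backward(model$critic, ffg$caches, rep(-1 / bs, bs),
                                need_gx = TRUE, need_gw = FALSE)$gx
        adv_part <- if (on_pair) {
          gadv[dim(gadv)[1], , , drop = FALSE]
        } else gadv
        dfake <- dfake + cfg$lambda_adv * adv_part
      }
      for (i in seq_len(bs)) dfake[1, , i] <- dfake[1, , i] * mvec
      bw <- net_backward(model$gen, fw$caches, dfake, need_gx = FALSE)
      tg <- tg + 1L
      upg <- adam_step(model$gen, bw$grads, st_g, lr_ep, tg,
                       weight_decay = cfg$weight_decay)
      model$gen <- upg$layers
      st_g <- upg$state

      if (!is.finite(l_rec) || (use_adv && (!is.finite(l_d) || !is.finite(l_g))))
        stop(sprintf("training diverged at epoch %d (l_rec=%g, l_d=%g)",
                     ep, l_rec, l_d))
      l_rec_ep <- l_rec_ep + l_rec
      l_g_ep <- l_g_ep + l_g
      l_d_ep <- l_d_ep + l_d
      nb <- nb + 1
    }
    rec <- l_rec_ep / nb; lg <- l_g_ep / nb; ld <- l_d_ep / nb
    log[[ep]] <- data.frame(epoch = ep, l_rec = rec, l_g = lg, l_d = ld,
                            l_total = cfg$lambda_rec * rec +
                              cfg$lambda_adv * (lg + ld),
                            val_l_rec = val_rec())
    if (verbose)
      message(sprintf("epoch %3d  l_rec %.5f  l_g %8.4f  l_d %8.4f  val %.5f",
                      ep, rec, lg, ld, log[[ep]]$val_l_rec))
  }
  list(model = model, log = do.call(rbind, log))
}

#' Virtual-lesion probe of a trained model
#'
#' Zeroes the source-hemisphere voxels of each ROI in turn, reconstructs
#' the target hemisphere, and reports the reconstruction loss against the
#' actual target next to the intact loss. A trained model that uses a
#' region's context should lose accuracy when it is masked out.
#'
#' @param model trained `ce_model`.
#' @param pair a `hemisphere_pair`.
#' @param roi_labels 3D integer array of ROI labels (0 = background),
#'   aligned to the source grid.
#' @param direction `"lh2rh"` or `"rh2lh"`.
#' @return data.frame with one row per nonzero ROI: `roi_id`,
#'   `lesioned_loss`, `intact_loss`.
#' @export
virtual_lesion <- function(model, pair, roi_labels,
                           direction = c("lh2rh", "rh2lh")) {
  direction <- match.arg(direction)
  source <- if (direction == "lh2rh") pair$lh else pair$rh
  target <- if (direction == "lh2rh") pair$rh else pair$lh
  if (!identical(dim(roi_labels), dim(source$values)))
    stop("roi_labels not aligned to the source grid")
  intact <- reconstruction_loss(target, ce_generate(model, source))
  ids <- sort(unique(roi_labels[roi_labels > 0]))
  rows <- lapply(ids, function(id) {
    sel <- roi_labels == id
    if (!any(sel)) {
      warning(sprintf("ROI %d has no voxels; skipped", id))
      return(NULL)
    }
    v <- source$values
    v[sel] <- 0
    lesioned <- volume_grid(v, source$mask, source$hemisphere,
                            source$voxel_size_mm)
    data.frame(roi_id = id,
               lesioned_loss = reconstruction_loss(target,
                                                   ce_generate(model, lesioned)),
               intact_loss = intact)
  })
  do.call(rbind, rows)
}
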