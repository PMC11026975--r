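#' Context-encoder model configuration
#'
#' The generator is an encoder of `n_down_blocks` strided-convolution /
#' batch-normalization / ReLU blocks, a channel-wise fully connected
#' bottleneck (one dense map per channel across all spatial positions, no
#' cross-channel weights), and a mirrored transposed-convolution decoder
#' ending in a sigmoid so outputs live in `(0, 1)`. The critic is four
#' strided convolutions with leaky rectifiers (no batch normalization, as
#' required for a per-sample meaningful gradient penalty) and one scalar
#' classification layer without squashing, i.e. a Wasserstein critic.
#'
#' @param in_shape input grid shape; each dim must be divisible by
#'   `2^n_down_blocks`.
#' @param base_channels channels after the first block; doubled per block.
#' @param n_down_blocks number of halvings (default 4).
#' @param bottleneck_channels channels at the channel-wise bottleneck;
#'   defaults to `base_channels * 2^(n_down_blocks - 1)`.
#' @param use_critic build the adversarial critic.
#' @param critic_on_pair if `TRUE` the critic receives the source and
#'   target hemispheres as two channels (the concatenated whole-brain
#'   variant); default sees the target hemisphere alone.
#' @return A `ce_config` list.
#' @export
ce_config <- function(in_shape = c(32, 32, 32), base_channels = 16,
                      n_down_blocks = 4, bottleneck_channels = NULL,
                      use_critic = TRUE, critic_on_pair = FALSE) {
  in_shape <- as.integer(in_shape)
  if (length(in_shape) != 3L) stop("in_shape must have 3 dims")
  if (any(in_shape %% 2L^n_down_blocks != 0L))
    stop("each dim of in_shape must be divisible by 2^n_down_blocks")
  if (is.null(bottleneck_channels))
    bottleneck_channels <- base_channels * 2L^(n_down_blocks - 1L)
  structure(list(in_shape = in_shape,
                 base_channels = as.integer(base_channels),
                 n_down_blocks = as.integer(n_down_blocks),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 use_critic = isTRUE(use_critic),
                 critic_on_pair = isTRUE(critic_on_pair)),
            class = "ce_config")
}

gen_channel_plan <- function(cfg) {
  nd <- cfg$n_down_blocks
  ch <- cfg$base_channels * 2L^(seq_len(nd) - 1L)
  ch[nd] <- cfg$bottleneck_channels
  ch
}

#' Build a context-encoder model
#'
#' Initializes generator and critic parameters reproducibly from `seed`.
#'
#' @param config a [ce_config()].
#' @param seed integer seed for parameter initialization.
#' @return A `ce_model` with elements `gen` (layer list), `critic` (layer
#'   list or `NULL`), `config` and `seed`.
#' @export
build_ce_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "ce_config"))
  set.seed(seed)
  nd <- config$n_down_blocks
  ch <- gen_channel_plan(config)
  dims <- config$in_shape

  gen <- list()
  cin <- 1L
  d <- dims
  for (i in seq_len(nd)) {
    gen <- c(gen, list(new_conv(cin, ch[i], d, sd = sqrt(2 / (cin * 64)))))
    gen <- c(gen, list(new_bn(ch[i])), list(new_act("relu")))
    cin <- ch[i]
    d <- conv_dims_out(d)
  }
  vb <- prod(d)
  gen <- c(gen, list(new_cwfc(cin, vb, sd = sqrt(1 / vb))))
  dec_ch <- c(rev(ch[-nd]), 1L)
  for (i in seq_len(nd)) {
    cout <- dec_ch[i]
    last <- i == nd
    sd <- if (last) sqrt(1 / (cin * 8)) else sqrt(2 / (cin * 8))
    gen <- c(gen, list(new_tconv(cin, cout, d, sd = sd)))
    if (!last) gen <- c(gen, list(new_bn(cout)), list(new_act("relu")))
    cin <- cout
    d <- 2L * d
  }
  gen <- c(gen, list(new_act("sigmoid")))

  critic <- NULL
  if (config$use_critic) {
    critic <- list()
    cin <- if (config$critic_on_pair) 2L else 1L
    d <- dims
    # four strided layers at full scale; shallower when the grid is small
    for (i in seq_len(min(4L, nd))) {
      cc <- config$base_channels * 2L^(i - 1L)
      critic <- c(critic, list(new_conv(cin, cc, d, sd = sqrt(2 / (cin * 64)))),
                  list(new_act("lrelu")))
      cin <- cc
      d <- conv_dims_out(d)
    }
    critic <- c(critic, list(new_linear(cin * prod(d), sd = sqrt(1 / (cin * prod(d))))))
  }

  structure(list(gen = gen, critic = critic, config = config, seed = seed,
                 target_mask = NULL, direction = NULL),
            class = "ce_model")
}

#' @export
print.ce_model <- function(x, ...) {
  np <- function(layers) sum(vapply(layers, function(l) {
    sum(vapply(intersect(names(l), c("W", "b", "gamma", "beta", "A", "w")),
               function(nm) length(l[[nm]]), 0))
  }, 0))
  cat(sprintf("<ce_model %s, base %d, %d down-blocks; gen %d params, critic %s>\n",
              paste(x$config$in_shape, collapse = "x"),
              x$config$base_channels, x$config$n_down_blocks,
              np(x$gen), if (is.null(x$critic)) "none" else np(x$critic)))
  if (!is.null(x$direction)) cat(sprintf("  trained direction: %s\n", x$direction))
  invisible(x)
}

as_input_cube <- function(grids) {
  v <- length(grids[[1]]$values)
  x <- array(0, c(1, v, length(grids)))
  for (i in seq_along(grids)) x[1, , i] <- as.numeric(grids[[i]]$values)
  x
}

#' Reconstruct the opposite hemisphere
#'
#' Runs the generator in inference mode (normalization layers use running
#' statistics, so repeated calls are identical) and masks the output with
#' the target-hemisphere mask.
#'
#' @param model a trained [build_ce_model()] model.
#' @param source a `volume_grid` matching the model's input shape.
#' @return A `volume_grid` of the reconstructed opposite hemisphere.
#' @export
ce_generate <- function(model, source) {
  stopifnot(inherits(model, "ce_model"), inherits(source, "volume_grid"))
  if (!identical(dim(source$values), as.integer(model$config$in_shape)) &&
      !identical(dim(source$values), model$config$in_shape))
    stop("source shape does not match model input shape")
  x <- as_input_cube(list(source))
  y <- net_forward(model$gen, x, train = FALSE)$y
  mask <- if (!is.null(model$target_mask)) model$target_mask else source$mask
  vals <- array(y[1, , 1], dim(source$values))
  vals[!mask] <- 0
  volume_grid(vals, mask,
              hemisphere = if (source$hemisphere == "LH") "RH" else "LH",
              voxel_size_mm = source$voxel_size_mm)
}

# Batched inference used by the training loop / saliency: x is a cube.
gen_infer_cube <- function(model, x) net_forward(model$gen, x, train = FALSE)$y

#' Wasserstein critic score
#'
#' @param model a `ce_model` with a critic.
#' @param volume a `volume_grid` (or list of grids for a batch); with the
#'   concatenated-pair critic variant, pass `source` as well.
#' @param source optional source-hemisphere grid(s) for the pair variant.
#' @return Finite unbounded scalar score(s); no squashing is applied.
#' @export
critic_score <- function(model, volume, source = NULL) {
  stopifnot(inherits(model, "ce_model"))
  if (is.null(model$critic)) stop("model was built without a critic")
  vols <- if (inherits(volume, "volume_grid")) list(volume) else volume
  x <- as_input_cube(vols)
  if (model$config$critic_on_pair) {
    if (is.null(source)) stop("pair-variant critic needs 'source'")
    srcs <- if (inherits(source, "volume_grid")) list(source) else source
    x <- abind_channel(as_input_cube(srcs), x)
  }
  out <- net_forward(model$critic, x, train = FALSE)$y
  drop(out)
}

abind_channel <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# -- critic passes used by WGAN-GP training ------------------------------

critic_forward <- function(layers, x) net_forward(layers, x, train = FALSE)

# Backward through the critic with per-sample output seeds `dout`; also
# returns the gradient at each convolution's pre-activation output, which
# the gradient-penalty parameter gradient reuses.
critic_backward <- function(layers, caches, dout, need_gx = TRUE,
                            need_gw = TRUE) {
  grads <- vector("list", length(layers))
  deltas <- vector("list", length(layers))
  gy <- dout
  for (i in rev(seq_along(layers))) {
    if (layers[[i]]$type == "conv") deltas[[i]] <- gy
    r <- layer_backward(layers[[i]], caches[[i]], gy,
                        need_gx = need_gx || i > 1, need_gw = need_gw)
    grads[[i]] <- r$grads
    gy <- r$gx
  }
  list(gx = gy, grads = grads, deltas = deltas)
}

# Parameter gradient of the gradient penalty for a piecewise-linear critic.
# With activation gates frozen, the input gradient g is linear in each
# weight matrix, so d/dW of (||g||-1)^2 pairs the ordinary backward deltas
# with a tangent forward pass seeded at u = 2(||g||-1) g / (N ||g||).
critic_gp_param_grads <- function(layers, caches, deltas, u) {
  grads <- vector("list", length(layers))
  t <- u
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- cpp_conv3d_bwd(t, l$W, deltas[[i]], l$in_dims[1], l$in_dims[2],
                          l$in_dims[3], l$k, l$s, l$p, FALSE, TRUE)
      grads[[i]] <- list(W = r$gW, b = drop(r$gb) * 0)
      t <- cpp_conv3d_fwd(t, l$W, numeric(l$cout), l$in_dims[1],
                          l$in_dims[2], l$in_dims[3], l$k, l$s, l$p)
    } else if (l$type == "lrelu") {
      t <- t * caches[[i]]$gate
      grads[[i]] <- list()
    } else if (l$type == "linear") {
      tm <- matrix(t, ncol = dim(t)[3])
      grads[[i]] <- list(w = rowSums(tm), b = 0)
    } else {
      grads[[i]] <- list()
    }
  }
  grads
}

# Penalty value and (optionally) critic parameter grads at interpolates.
gp_eval <- function(layers, xhat, with_grads = TRUE) {
  n <- dim(xhat)[3]
  cf <- critic_forward(layers, xhat)
  bk <- critic_backward(layers, cf$caches, rep(1, n), need_gx = TRUE,
                        need_gw = FALSE)
  g <- bk$gx
  norms <- sqrt(apply(g^2, 3, sum))
  penalty <- mean((norms - 1)^2)
  grads <- NULL
  if (with_grads) {
    u <- g
    for (s in seq_len(n)) {
      coef <- if (norms[s] > 1e-12) 2 * (norms[s] - 1) / (n * norms[s]) else 0
      u[, , s] <- coef * g[, , s]
    }
    grads <- critic_gp_param_grads(layers, cf$caches, bk$deltas, u)
  }
  list(penalty = penalty, grads = grads, norms = norms)
}
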