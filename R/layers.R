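# Minimal 3D CNN layer framework backing the context-encoder networks.
#
# A network is a list of layers; each layer is a list carrying its type,
# parameters and shape metadata. Feature maps travel as 3D arrays
# (channels, voxels, batch) so the compiled convolution kernels can treat
# them as Armadillo cubes. Gradients are returned as per-layer lists whose
# numeric fields mirror the parameter fields, which lets one generic Adam
# walker update any network.

conv_dims_out <- function(d, k = 4L, s = 2L, p = 1L) (d + 2L * p - k) %/% s + 1L

new_conv <- function(cin, cout, in_dims, sd, k = 4L, s = 2L, p = 1L) {
  list(type = "conv", cin = cin, cout = cout, k = k, s = s, p = p,
       in_dims = in_dims, out_dims = conv_dims_out(in_dims, k, s, p),
       W = matrix(rnorm(cout * cin * k^3, sd = sd), cout, cin * k^3),
       b = numeric(cout))
}

new_tconv <- function(cin, cout, small_dims, sd, k = 4L, s = 2L, p = 1L) {
  out_dims <- s * (small_dims - 1L) + k - 2L * p
  list(type = "tconv", cin = cin, cout = cout, k = k, s = s, p = p,
       in_dims = small_dims, out_dims = out_dims,
       W = matrix(rnorm(cin * cout * k^3, sd = sd), cin, cout * k^3),
       b = numeric(cout))
}

new_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", c = c, momentum = momentum, eps = eps,
       gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

new_act <- function(kind, alpha = 0.2) list(type = kind, alpha = alpha)

new_cwfc <- function(c, v, sd) {
  list(type = "cwfc", c = c, v = v,
       A = array(rnorm(v * v * c, sd = sd), c(v, v, c)),
       b = matrix(0, c, v))
}

new_linear <- function(n_in, sd) {
  list(type = "linear", n_in = n_in,
       w = rnorm(n_in, sd = sd), b = 0)
}

layer_forward <- function(layer, x, train = TRUE) {
  n <- dim(x)[3]
  switch(layer$type,
    conv = {
      y <- cpp_conv3d_fwd(x, layer$W, layer$b, layer$in_dims[1],
                          layer$in_dims[2], layer$in_dims[3],
                          layer$k, layer$s, layer$p)
      list(y = y, cache = list(x = x), layer = layer)
    },
    tconv = {
      y <- cpp_tconv3d_fwd(x, layer$W, layer$b, layer$out_dims[1],
                           layer$out_dims[2], layer$out_dims[3],
                           layer$k, layer$s, layer$p)
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      xm <- matrix(x, nrow = dim(x)[1])
      if (train) {
        m <- rowMeans(xm)
        v <- rowMeans(xm^2) - m^2
        layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * m
        layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
      } else {
        m <- layer$run_mean
        v <- layer$run_var
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- (xm - m) * invstd
      y <- array(layer$gamma * xhat + layer$beta, dim(x))
      list(y = y, cache = list(xhat = xhat, invstd = invstd), layer = layer)
    },
    relu = {
      gate <- x > 0
      list(y = x * gate, cache = list(gate = gate), layer = layer)
    },
    lrelu = {
      gate <- ifelse(x > 0, 1, layer$alpha)
      list(y = x * gate, cache = list(gate = gate), layer = layer)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = list(y = y), layer = layer)
    },
    cwfc = {
      v <- layer$v
      y <- array(0, dim(x))
      for (c in seq_len(layer$c)) {
        xc <- matrix(x[c, , ], v, n)
        y[c, , ] <- layer$A[, , c] %*% xc + layer$b[c, ]
      }
      list(y = y, cache = list(x = x), layer = layer)
    },
    linear = {
      xm <- matrix(x, ncol = n)
      out <- drop(crossprod(xm, layer$w)) + layer$b
      list(y = out, cache = list(xm = xm, xdim = dim(x)), layer = layer)
    },
    stop("unknown layer type"))
}

# gy matches the layer output shape (cube, or vector for 'linear').
# Returns gx plus a list of parameter gradients (possibly empty).
layer_backward <- function(layer, cache, gy, need_gx = TRUE, need_gw = TRUE) {
  switch(layer$type,
    conv = {
      r <- cpp_conv3d_bwd(cache$x, layer$W, gy, layer$in_dims[1],
                          layer$in_dims[2], layer$in_dims[3],
                          layer$k, layer$s, layer$p, need_gx, need_gw)
      list(gx = r$gx, grads = list(W = r$gW, b = drop(r$gb)))
    },
    tconv = {
      r <- cpp_tconv3d_bwd(cache$x, layer$W, gy, layer$out_dims[1],
                           layer$out_dims[2], layer$out_dims[3],
                           layer$k, layer$s, layer$p, need_gx, need_gw)
      list(gx = r$gx, grads = list(W = r$gW, b = drop(r$gb)))
    },
    bn = {
      gym <- matrix(gy, nrow = dim(gy)[1])
      ggamma <- rowSums(gym * cache$xhat)
      gbeta <- rowSums(gym)
      m <- ncol(gym)
      gxhat <- layer$gamma * gym
      gx <- cache$invstd *
        (gxhat - rowMeans(gxhat) - cache$xhat * rowMeans(gxhat * cache$xhat))
      list(gx = array(gx, dim(gy)), grads = list(gamma = ggamma, beta = gbeta))
    },
    relu = ,
    lrelu = list(gx = gy * cache$gate, grads = list()),
    sigmoid = list(gx = gy * cache$y * (1 - cache$y), grads = list()),
    cwfc = {
      n <- dim(gy)[3]
      v <- layer$v
      gx <- array(0, dim(gy))
      gA <- array(0, dim(layer$A))
      gb <- matrix(0, layer$c, v)
      for (c in seq_len(layer$c)) {
        gyc <- matrix(gy[c, , ], v, n)
        if (need_gx) gx[c, , ] <- crossprod(layer$A[, , c], gyc)
        xc <- matrix(cache$x[c, , ], v, n)
        gA[, , c] <- tcrossprod(gyc, xc)
        gb[c, ] <- rowSums(gyc)
      }
      list(gx = gx, grads = list(A = gA, b = gb))
    },
    linear = {
      gx <- NULL
      if (need_gx) gx <- array(outer(layer$w, gy), cache$xdim)
      list(gx = gx,
           grads = list(w = drop(cache$xm %*% gy), b = sum(gy)))
    },
    stop("unknown layer type"))
}

net_forward <- function(layers, x, train = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(y = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, gy, need_gx = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], gy,
                        need_gx = need_gx || i > 1, need_gw = TRUE)
    grads[[i]] <- r$grads
    gy <- r$gx
  }
  list(gx = gy, grads = grads)
}

# Adam with per-layer nested numeric fields -----------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- intersect(names(l), c("W", "b", "gamma", "beta", "A", "w"))
    st <- lapply(nm, function(n) list(m = l[[n]] * 0, v = l[[n]] * 0))
    names(st) <- nm
    st
  })
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.5, beta2 = 0.9,
                      eps = 1e-8, weight_decay = 0) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g) || !length(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      upd <- lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
      # decoupled weight decay on multiplicative weights only
      if (weight_decay > 0 && nm %in% c("W", "A", "w"))
        upd <- upd + lr * weight_decay * layers[[i]][[nm]]
      layers[[i]][[nm]] <- layers[[i]][[nm]] - upd
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

grads_axpy <- function(acc, g, a = 1) {
  if (is.null(acc)) return(lapply(g, function(l) lapply(l, function(x) a * x)))
  for (i in seq_along(g)) {
    for (nm in names(g[[i]])) {
      acc[[i]][[nm]] <- acc[[i]][[nm]] + a * g[[i]][[nm]]
    }
  }
  acc
}
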