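# Minimal neural-network engine: 1-D convolutions (im2col + BLAS gemm),
# max-pooling, batch normalization, dropout, dense layers, squeeze-and-
# excitation gating, Adam, and class-weighted soft-label cross-entropy.
# Internal: the exported surface is the model builders in models.R.
#
# Conventions: temporal tensors are [batch, length, channels] arrays, dense
# activations [batch, features] matrices. All reshapes below rely on R's
# column-major layout (batch index fastest), so dim<- is a free reinterpret.

# ---- layer constructors ----------------------------------------------------

nn_conv1d <- function(kernel, filters, in_channels, wd = 0, act = "relu") {
  list(type = "conv1d", k = kernel, f = filters, c_in = in_channels,
       wd = wd, act = act,
       W = NULL, b = NULL, param_names = c("W", "b"))
}

nn_dense <- function(units, in_features, wd = 0, act = "relu") {
  list(type = "dense", f = units, c_in = in_features, wd = wd, act = act,
       W = NULL, b = NULL, param_names = c("W", "b"))
}

nn_maxpool <- function(size) list(type = "maxpool", m = size, param_names = character())

# momentum 0.9: running statistics reach inference quality within ~50
# optimizer steps, matching the short training schedules used here
nn_batchnorm <- function(channels, momentum = 0.9, eps = 1e-3) {
  list(type = "batchnorm", c = channels, momentum = momentum, eps = eps,
       gamma = rep(1, channels), beta = rep(0, channels),
       run_mean = rep(0, channels), run_var = rep(1, channels),
       param_names = c("gamma", "beta"))
}

nn_dropout <- function(rate) list(type = "dropout", rate = rate, param_names = character())

nn_flatten <- function() list(type = "flatten", param_names = character())

nn_gap <- function() list(type = "gap", param_names = character())

nn_se <- function(channels, r = 8, wd = 0) {
  list(type = "se", c = channels, cr = max(1L, channels %/% r), wd = wd,
       W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
       param_names = c("W1", "b1", "W2", "b2"))
}

# He-normal for ReLU fan-in, Glorot-uniform for linear/sigmoid heads.
nn_init_layer <- function(layer) {
  init_mat <- function(fan_in, fan_out, act) {
    if (identical(act, "relu")) {
      matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
    } else {
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    }
  }
  if (layer$type == "conv1d") {
    layer$W <- init_mat(layer$k * layer$c_in, layer$f, layer$act)
    layer$b <- rep(0, layer$f)
  } else if (layer$type == "dense") {
    layer$W <- init_mat(layer$c_in, layer$f, layer$act)
    layer$b <- rep(0, layer$f)
  } else if (layer$type == "se") {
    layer$W1 <- init_mat(layer$c, layer$cr, "relu")
    layer$b1 <- rep(0, layer$cr)
    layer$W2 <- init_mat(layer$cr, layer$c, "sigmoid")
    layer$b2 <- rep(0, layer$c)
  }
  layer
}

nn_init_seq <- function(layers) lapply(layers, nn_init_layer)

# im2col/col2im and max-pooling live in src/conv_kernels.cpp; they are the
# memory-bound part of the conv stack, while the gemms below go through BLAS.

# ---- forward / backward per layer -----------------------------------------

nn_forward_layer <- function(layer, X, training) {
  t <- layer$type
  if (t == "conv1d") {
    d <- dim(X); B <- d[1]; L <- d[2]
    col <- cpp_im2col(X, layer$k)
    out <- cpp_add_bias(col %*% layer$W, layer$b)
    if (layer$act == "relu") out <- cpp_relu_fwd(out)
    dim(out) <- c(B, L, layer$f)
    return(list(out = out, cache = list(col = col, out = out, B = B, L = L),
                layer = layer))
  }
  if (t == "dense") {
    out <- cpp_add_bias(X %*% layer$W, layer$b)
    mask <- NULL
    if (layer$act == "relu") { mask <- out > 0; out <- out * mask }
    else if (layer$act == "sigmoid") out <- 1 / (1 + exp(-out))
    return(list(out = out,
                cache = list(X = X, mask = mask,
                             out = if (layer$act == "sigmoid") out),
                layer = layer))
  }
  if (t == "maxpool") {
    d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]; m <- layer$m
    Lg <- L %/% m
    if (Lg * m != L) X <- X[, seq_len(Lg * m), , drop = FALSE]  # floor lengths
    r <- cpp_maxpool_fwd(X, m)
    return(list(out = r$out, cache = list(amax = r$amax, B = B, L = L, Lg = Lg,
                                          C = C),
                layer = layer))
  }
  if (t == "batchnorm") {
    d <- dim(X)
    if (training) {
      st <- cpp_colstats(X, layer$c)
      mu <- st$mean; va <- st$var
      layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
      layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * va
    } else {
      mu <- layer$run_mean; va <- layer$run_var
    }
    inv <- 1 / sqrt(va + layer$eps)
    bn <- cpp_bn_fwd(X, layer$c, mu, inv, layer$gamma, layer$beta)
    out <- bn$out
    dim(out) <- d
    return(list(out = out, cache = list(xhat = bn$xhat, inv = inv, d = d,
                                        training = training),
                layer = layer))
  }
  if (t == "dropout") {
    if (!training || layer$rate <= 0) {
      return(list(out = X, cache = list(mask = NULL), layer = layer))
    }
    r <- cpp_dropout_fwd(X, layer$rate)
    return(list(out = r$out, cache = list(mask = r$mask), layer = layer))
  }
  if (t == "flatten") {
    d <- dim(X)
    out <- X; dim(out) <- c(d[1], prod(d[-1]))
    return(list(out = out, cache = list(d = d), layer = layer))
  }
  if (t == "gap") {
    d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
    Xp <- aperm(X, c(2, 1, 3)); dim(Xp) <- c(L, B * C)
    out <- matrix(colMeans(Xp), B, C)
    return(list(out = out, cache = list(d = d), layer = layer))
  }
  if (t == "se") {
    d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
    Xp <- aperm(X, c(2, 1, 3)); dim(Xp) <- c(L, B * C)
    z <- matrix(colMeans(Xp), B, C)
    pre1 <- sweep(z %*% layer$W1, 2, layer$b1, "+")
    m1 <- pre1 > 0
    h <- pre1 * m1
    g <- 1 / (1 + exp(-sweep(h %*% layer$W2, 2, layer$b2, "+")))
    gb <- array(rep(g, each = L), c(L, B, C))      # broadcast over time
    gb <- aperm(gb, c(2, 1, 3))
    return(list(out = X * gb, cache = list(X = X, z = z, h = h, m1 = m1, g = g,
                                           gb = gb, d = d),
                layer = layer))
  }
  stop("unknown layer type: ", t)
}

nn_backward_layer <- function(layer, cache, dout) {
  t <- layer$type
  if (t == "conv1d") {
    B <- cache$B; L <- cache$L
    dim(dout) <- c(B * L, layer$f)
    if (layer$act == "relu") dout <- cpp_relu_bwd(dout, cache$out)
    dW <- crossprod(cache$col, dout)
    db <- colSums(dout)
    dcol <- tcrossprod(dout, layer$W)
    dX <- cpp_col2im(dcol, layer$k, B, L, layer$c_in)
    if (layer$wd > 0) dW <- dW + 2 * layer$wd * layer$W
    return(list(dx = dX, grads = list(W = dW, b = db)))
  }
  if (t == "dense") {
    if (layer$act == "relu") dout <- dout * cache$mask
    else if (layer$act == "sigmoid") dout <- dout * cache$out * (1 - cache$out)
    dW <- crossprod(cache$X, dout)
    db <- colSums(dout)
    dX <- tcrossprod(dout, layer$W)
    if (layer$wd > 0) dW <- dW + 2 * layer$wd * layer$W
    return(list(dx = dX, grads = list(W = dW, b = db)))
  }
  if (t == "maxpool") {
    B <- cache$B; L <- cache$L; Lg <- cache$Lg; C <- cache$C; m <- layer$m
    dX <- cpp_maxpool_bwd(dout, cache$amax, m, m * Lg)
    if (m * Lg != L) {      # truncated tail received no gradient
      dXf <- array(0, c(B, L, C)); dXf[, seq_len(m * Lg), ] <- dX; dX <- dXf
    }
    return(list(dx = dX, grads = list()))
  }
  if (t == "batchnorm") {
    g <- cpp_bn_grads(dout, cache$xhat, layer$c)
    n <- length(dout) / layer$c
    if (cache$training) {
      dx <- cpp_bn_bwd(dout, cache$xhat, layer$c, layer$gamma * cache$inv,
                       g$dbeta / n, g$dgamma / n)
    } else {
      dx <- cpp_bn_bwd(dout, cache$xhat, layer$c, layer$gamma * cache$inv,
                       rep(0, layer$c), rep(0, layer$c))
    }
    dim(dx) <- cache$d
    return(list(dx = dx, grads = list(gamma = g$dgamma, beta = g$dbeta)))
  }
  if (t == "dropout") {
    if (is.null(cache$mask)) return(list(dx = dout, grads = list()))
    return(list(dx = cpp_dropout_bwd(dout, cache$mask, layer$rate),
                grads = list()))
  }
  if (t == "flatten") {
    dim(dout) <- cache$d
    return(list(dx = dout, grads = list()))
  }
  if (t == "gap") {
    d <- cache$d; B <- d[1]; L <- d[2]; C <- d[3]
    dX <- array(rep(dout / L, each = L), c(L, B, C))
    dX <- aperm(dX, c(2, 1, 3))
    return(list(dx = dX, grads = list()))
  }
  if (t == "se") {
    d <- cache$d; B <- d[1]; L <- d[2]; C <- d[3]
    dXdirect <- dout * cache$gb
    prod_ <- dout * cache$X
    pp <- aperm(prod_, c(2, 1, 3)); dim(pp) <- c(L, B * C)
    dg <- matrix(colSums(pp), B, C)
    dpre2 <- dg * cache$g * (1 - cache$g)
    dW2 <- crossprod(cache$h, dpre2); db2 <- colSums(dpre2)
    dh <- tcrossprod(dpre2, layer$W2) * cache$m1
    dW1 <- crossprod(cache$z, dh); db1 <- colSums(dh)
    dz <- tcrossprod(dh, layer$W1)
    dXgap <- aperm(array(rep(dz / L, each = L), c(L, B, C)), c(2, 1, 3))
    if (layer$wd > 0) {
      dW1 <- dW1 + 2 * layer$wd * layer$W1
      dW2 <- dW2 + 2 * layer$wd * layer$W2
    }
    return(list(dx = dXdirect + dXgap,
                grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)))
  }
  stop("unknown layer type: ", t)
}

nn_forward_seq <- function(layers, X, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_forward_layer(layers[[i]], X, training)
    X <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer        # batchnorm running stats
  }
  list(out = X, caches = caches, layers = layers)
}

nn_backward_seq <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_backward_layer(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

# ---- loss ------------------------------------------------------------------

# class-weighted soft-label cross-entropy on logits; returns loss (data term
# only) and dlogits. `w` is a per-sample weight vector.
nn_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_ce_loss <- function(logits, Y, w = NULL) {
  B <- nrow(logits)
  if (is.null(w)) w <- rep(1, B)
  p <- nn_softmax(logits)
  p[!is.finite(p)] <- 0.5      # diverged runs stay comparable, not NaN
  loss <- -sum(w * rowSums(Y * log(pmax(p, 1e-12)))) / B
  dlogits <- (p - Y) * (w / B)
  list(loss = loss, dlogits = dlogits, p = p)
}

nn_l2_penalty <- function(layers) {
  s <- 0
  for (ly in layers) {
    if (!is.null(ly$wd) && ly$wd > 0) {
      for (pn in intersect(c("W", "W1", "W2"), ly$param_names)) {
        s <- s + ly$wd * sum(ly[[pn]]^2)
      }
    }
  }
  s
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    st <- list()
    for (pn in ly$param_names) {
      st[[pn]] <- list(m = array(0, dim(as.array(ly[[pn]]))),
                       v = array(0, dim(as.array(ly[[pn]]))))
    }
    st
  })
}

adam_step <- function(layers, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    for (pn in layers[[i]]$param_names) {
      g <- grads[[i]][[pn]]
      if (is.null(g)) next
      st <- opt[[i]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * as.vector(g)
      st$v <- beta2 * st$v + (1 - beta2) * as.vector(g)^2
      upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      p <- layers[[i]][[pn]]
      layers[[i]][[pn]] <- p - array(as.vector(upd), dim(as.array(p))) +
        0 * p   # keep original dim/vector shape
      if (is.null(dim(p))) layers[[i]][[pn]] <- as.vector(layers[[i]][[pn]])
      opt[[i]][[pn]] <- st
    }
  }
  list(layers = layers, opt = opt)
}

nn_count_params <- function(layers) {
  sum(vapply(layers, function(ly) {
    sum(vapply(ly$param_names, function(pn) length(ly[[pn]]), 0))
  }, 0))
}
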