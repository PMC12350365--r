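# Minimal vectorized neural-network engine used by the CNN-DNN models.
# Tensor conventions: 1D sequences are (n, L, C) arrays, 2D grids are
# (n, H, W, C) arrays, flat features are (n, p) matrices. Convolutions are
# "valid" (no padding) and implemented via im2col so the inner loop is one
# BLAS matrix multiply. Training uses minibatch Adam on an MSE loss with
# optional L1 penalties on dense-layer weights.

#' Exponential linear unit
#'
#' g(x) = x for x > 0 and alpha * (exp(x) - 1) for x <= 0. Continuous at 0
#' and monotone increasing for every alpha > 0.
#'
#' @param x Numeric vector/array.
#' @param alpha Positive saturation scale (default 1).
#' @return g(x), same shape as x.
#' @export
elu <- function(x, alpha = 1) {
  if (alpha <= 0) stop("elu requires alpha > 0")
  y <- x
  i <- which(x <= 0)
  y[i] <- alpha * (exp(x[i]) - 1)
  y
}

# derivative of elu given its output y (x > 0 -> 1; else y + alpha)
elu_grad_from_output <- function(y, alpha = 1) {
  g <- y
  pos <- y > 0
  g[pos] <- 1
  g[!pos] <- y[!pos] + alpha
  g
}

apply_act <- function(z, act, alpha) {
  switch(act, elu = elu(z, alpha), linear = z,
         stop("unknown activation: ", act))
}
act_grad <- function(y, act, alpha) {
  switch(act, elu = elu_grad_from_output(y, alpha), linear = 1)
}

# ---- layer constructors (shapes resolved at init time) ----------------------

layer_conv1d <- function(filters, kernel = 5L, activation = "elu") {
  list(type = "conv1d", filters = as.integer(filters),
       kernel = as.integer(kernel), activation = activation)
}
layer_conv2d <- function(filters, kernel = c(3L, 3L), activation = "elu") {
  list(type = "conv2d", filters = as.integer(filters),
       kernel = as.integer(rep(kernel, length.out = 2)),
       activation = activation)
}
layer_avgpool1d <- function(pool = 2L) list(type = "avgpool1d", pool = as.integer(pool))
layer_avgpool2d <- function(pool = c(2L, 2L))
  list(type = "avgpool2d", pool = as.integer(rep(pool, length.out = 2)))
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(units, activation = "elu", l1 = 0) {
  list(type = "dense", units = as.integer(units), activation = activation,
       l1 = l1)
}
# input: list(cat = n x C integer codes, num = n x p); output (n, width, 1)
layer_embedding_concat <- function(cat_levels, embed_dims) {
  list(type = "embed", cat_levels = as.integer(cat_levels),
       embed_dims = as.integer(embed_dims))
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / max(1, fan_in))), nr, nc)
}

# initialize one layer given its input shape (shape excludes n)
init_layer <- function(layer, in_shape) {
  t <- layer$type
  if (t == "conv1d") {
    L <- in_shape[1]; C <- in_shape[2]; k <- layer$kernel
    if (L < k) stop("conv1d input length ", L, " smaller than kernel ", k)
    layer$W <- he_init(k * C, layer$filters, k * C)
    layer$b <- numeric(layer$filters)
    layer$in_shape <- in_shape
    layer$out_shape <- c(L - k + 1L, layer$filters)
  } else if (t == "conv2d") {
    H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
    kh <- layer$kernel[1]; kw <- layer$kernel[2]
    if (H < kh || W < kw) stop("conv2d input ", H, "x", W,
                               " smaller than kernel ", kh, "x", kw)
    layer$W <- he_init(kh * kw * C, layer$filters, kh * kw * C)
    layer$b <- numeric(layer$filters)
    layer$in_shape <- in_shape
    layer$out_shape <- c(H - kh + 1L, W - kw + 1L, layer$filters)
  } else if (t == "avgpool1d") {
    L <- in_shape[1]
    if (L < layer$pool) stop("avgpool1d input shorter than pool size")
    layer$in_shape <- in_shape
    layer$out_shape <- c(L %/% layer$pool, in_shape[2])
  } else if (t == "avgpool2d") {
    Ho <- in_shape[1] %/% layer$pool[1]; Wo <- in_shape[2] %/% layer$pool[2]
    if (Ho < 1 || Wo < 1) stop("avgpool2d input smaller than pool size")
    layer$in_shape <- in_shape
    layer$out_shape <- c(Ho, Wo, in_shape[3])
  } else if (t == "flatten") {
    layer$in_shape <- in_shape
    layer$out_shape <- prod(in_shape)
  } else if (t == "dense") {
    p <- in_shape[1]
    layer$W <- he_init(p, layer$units, p)
    layer$b <- numeric(layer$units)
    layer$in_shape <- in_shape
    layer$out_shape <- layer$units
  } else if (t == "embed") {
    layer$E <- lapply(seq_along(layer$cat_levels), function(i)
      he_init(layer$cat_levels[i], layer$embed_dims[i], layer$embed_dims[i]))
    layer$num_width <- in_shape$num
    layer$out_shape <- c(sum(layer$embed_dims) + in_shape$num, 1L)
  } else stop("unknown layer type: ", t)
  layer
}

init_stack <- function(layers, in_shape) {
  for (i in seq_along(layers)) {
    layers[[i]] <- init_layer(layers[[i]], in_shape)
    in_shape <- layers[[i]]$out_shape
  }
  attr(layers, "out_shape") <- in_shape
  layers
}

# ---- forward / backward -----------------------------------------------------

im2col1d <- function(X, k) {
  d <- dim(X); n <- d[1]; L <- d[2]; C <- d[3]; Lo <- L - k + 1L
  cols <- array(0, c(n, Lo, k * C))
  for (j in seq_len(k))
    cols[, , ((j - 1) * C + 1):(j * C)] <- X[, j:(j + Lo - 1), , drop = FALSE]
  cols
}

im2col2d <- function(X, kh, kw) {
  d <- dim(X); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Ho <- H - kh + 1L; Wo <- W - kw + 1L
  cols <- array(0, c(n, Ho, Wo, kh * kw * C))
  off <- 0
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    cols[, , , (off + 1):(off + C)] <-
      X[, a:(a + Ho - 1), b:(b + Wo - 1), , drop = FALSE]
    off <- off + C
  }
  cols
}

forward_layer <- function(layer, x, alpha) {
  t <- layer$type
  if (t == "conv1d") {
    n <- dim(x)[1]; Lo <- layer$out_shape[1]
    M <- im2col1d(x, layer$kernel)
    dim(M) <- c(n * Lo, length(M) %/% (n * Lo))
    Z <- M %*% layer$W
    Z <- Z + rep(layer$b, each = nrow(Z))
    Y <- apply_act(Z, layer$activation, alpha)
    out <- Y
    dim(out) <- c(n, Lo, layer$filters)
    list(out = out, cache = list(M = M, y = Y, n = n))
  } else if (t == "conv2d") {
    n <- dim(x)[1]; Ho <- layer$out_shape[1]; Wo <- layer$out_shape[2]
    M <- im2col2d(x, layer$kernel[1], layer$kernel[2])
    dim(M) <- c(n * Ho * Wo, length(M) %/% (n * Ho * Wo))
    Z <- M %*% layer$W
    Z <- Z + rep(layer$b, each = nrow(Z))
    Y <- apply_act(Z, layer$activation, alpha)
    out <- Y
    dim(out) <- c(n, Ho, Wo, layer$filters)
    list(out = out, cache = list(M = M, y = Y, n = n))
  } else if (t == "avgpool1d") {
    n <- dim(x)[1]; p <- layer$pool; Lo <- layer$out_shape[1]; C <- layer$out_shape[2]
    xt <- x[, seq_len(Lo * p), , drop = FALSE]
    dim(xt) <- c(n, p, Lo, C)
    out <- array(0, c(n, Lo, C))
    for (j in seq_len(p)) {
      sl <- xt[, j, , , drop = FALSE]
      dim(sl) <- c(n, Lo, C)
      out <- out + sl
    }
    out <- out / p
    list(out = out, cache = list(n = n))
  } else if (t == "avgpool2d") {
    n <- dim(x)[1]; ph <- layer$pool[1]; pw <- layer$pool[2]
    Ho <- layer$out_shape[1]; Wo <- layer$out_shape[2]; C <- layer$out_shape[3]
    xt <- x[, seq_len(Ho * ph), seq_len(Wo * pw), , drop = FALSE]
    dim(xt) <- c(n, ph, Ho, pw, Wo, C)
    out <- array(0, c(n, Ho, Wo, C))
    for (a in seq_len(ph)) for (b in seq_len(pw)) {
      sl <- xt[, a, , b, , , drop = FALSE]
      dim(sl) <- c(n, Ho, Wo, C)
      out <- out + sl
    }
    out <- out / (ph * pw)
    list(out = out, cache = list(n = n))
  } else if (t == "flatten") {
    n <- dim(x)[1]
    list(out = matrix(x, n, prod(dim(x)[-1])), cache = list(d = dim(x)))
  } else if (t == "dense") {
    Z <- sweep(x %*% layer$W, 2, layer$b, `+`)
    Y <- apply_act(Z, layer$activation, alpha)
    list(out = Y, cache = list(x = x, y = Y))
  } else if (t == "embed") {
    n <- nrow(x$num %||% x$cat)
    pieces <- lapply(seq_along(layer$E), function(i)
      layer$E[[i]][x$cat[, i], , drop = FALSE])
    flat <- do.call(cbind, c(pieces, if (!is.null(x$num) && ncol(x$num) > 0)
      list(x$num)))
    list(out = array(flat, c(n, ncol(flat), 1L)), cache = list(cat = x$cat))
  } else stop("unknown layer type")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

backward_layer <- function(layer, dout, cache, alpha, need_dx = TRUE) {
  t <- layer$type
  if (t == "conv1d" || t == "conv2d") {
    n <- cache$n
    dY <- dout
    dim(dY) <- c(nrow(cache$M), layer$filters)
    dY <- dY * act_grad(cache$y, layer$activation, alpha)
    gW <- crossprod(cache$M, dY)
    gb <- colSums(dY)
    if (!need_dx) return(list(dx = NULL, grads = list(W = gW, b = gb)))
    dM <- dY %*% t(layer$W)
    if (t == "conv1d") {
      Lo <- layer$out_shape[1]; k <- layer$kernel
      C <- layer$in_shape[2]; L <- layer$in_shape[1]
      dcols <- dM
      dim(dcols) <- c(n, Lo, k * C)
      dx <- array(0, c(n, L, C))
      for (j in seq_len(k))
        dx[, j:(j + Lo - 1), ] <- dx[, j:(j + Lo - 1), , drop = FALSE] +
          dcols[, , ((j - 1) * C + 1):(j * C), drop = FALSE]
    } else {
      Ho <- layer$out_shape[1]; Wo <- layer$out_shape[2]
      kh <- layer$kernel[1]; kw <- layer$kernel[2]
      H <- layer$in_shape[1]; W <- layer$in_shape[2]; C <- layer$in_shape[3]
      dcols <- dM
      dim(dcols) <- c(n, Ho, Wo, kh * kw * C)
      dx <- array(0, c(n, H, W, C))
      off <- 0
      for (a in seq_len(kh)) for (b in seq_len(kw)) {
        dx[, a:(a + Ho - 1), b:(b + Wo - 1), ] <-
          dx[, a:(a + Ho - 1), b:(b + Wo - 1), , drop = FALSE] +
          dcols[, , , (off + 1):(off + C), drop = FALSE]
        off <- off + C
      }
    }
    list(dx = dx, grads = list(W = gW, b = gb))
  } else if (t == "avgpool1d") {
    n <- cache$n; p <- layer$pool
    Lo <- layer$out_shape[1]; C <- layer$out_shape[2]; L <- layer$in_shape[1]
    dx <- array(0, c(n, L, C))
    dshare <- dout / p
    for (j in seq_len(p))
      dx[, seq(j, Lo * p, by = p), ] <- dshare
    list(dx = dx, grads = NULL)
  } else if (t == "avgpool2d") {
    n <- cache$n; ph <- layer$pool[1]; pw <- layer$pool[2]
    Ho <- layer$out_shape[1]; Wo <- layer$out_shape[2]; C <- layer$out_shape[3]
    H <- layer$in_shape[1]; W <- layer$in_shape[2]
    dx <- array(0, c(n, H, W, C))
    dshare <- dout / (ph * pw)
    for (a in seq_len(ph)) for (b in seq_len(pw))
      dx[, seq(a, Ho * ph, by = ph), seq(b, Wo * pw, by = pw), ] <- dshare
    list(dx = dx, grads = NULL)
  } else if (t == "flatten") {
    dx <- dout
    dim(dx) <- cache$d
    list(dx = dx, grads = NULL)
  } else if (t == "dense") {
    dZ <- dout * act_grad(cache$y, layer$activation, alpha)
    gW <- crossprod(cache$x, dZ)
    if (layer$l1 > 0) gW <- gW + layer$l1 * sign(layer$W)
    list(dx = if (need_dx) dZ %*% t(layer$W),
         grads = list(W = gW, b = colSums(dZ)))
  } else if (t == "embed") {
    n <- dim(dout)[1]
    flat <- matrix(dout, n, dim(dout)[2])
    off <- 0
    gE <- vector("list", length(layer$E))
    for (i in seq_along(layer$E)) {
      d <- layer$embed_dims[i]
      dpiece <- flat[, (off + 1):(off + d), drop = FALSE]
      g <- matrix(0, nrow(layer$E[[i]]), d)
      agg <- rowsum(dpiece, group = cache$cat[, i])
      g[as.integer(rownames(agg)), ] <- agg
      gE[[i]] <- g
      off <- off + d
    }
    list(dx = NULL, grads = list(E = gE))
  } else stop("unknown layer type")
}

forward_stack <- function(layers, x, alpha) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- forward_layer(layers[[i]], x, alpha)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

backward_stack <- function(layers, caches, dout, alpha) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- backward_layer(layers[[i]], dout, caches[[i]], alpha,
                         need_dx = i > 1)
    grads[i] <- list(bw$grads)  # [i]<- keeps NULL slots for param-free layers
    dout <- bw$dx
    if (is.null(dout) && i > 1) stop("gradient chain broken mid-stack")
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init_stack <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$W)) list(mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b)
    else if (!is.null(l$E)) list(mE = lapply(l$E, function(e) 0 * e),
                                 vE = lapply(l$E, function(e) 0 * e))
    else NULL
  })
}

adam_update_stack <- function(layers, grads, state, lr, t,
                              beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    if (!is.null(g$W)) {
      s$mW <- beta1 * s$mW + (1 - beta1) * g$W
      s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
      layers[[i]]$W <- layers[[i]]$W - corr * s$mW / (sqrt(s$vW) + eps)
      s$mb <- beta1 * s$mb + (1 - beta1) * g$b
      s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
      layers[[i]]$b <- layers[[i]]$b - corr * s$mb / (sqrt(s$vb) + eps)
    } else if (!is.null(g$E)) {
      for (k in seq_along(g$E)) {
        s$mE[[k]] <- beta1 * s$mE[[k]] + (1 - beta1) * g$E[[k]]
        s$vE[[k]] <- beta2 * s$vE[[k]] + (1 - beta2) * g$E[[k]]^2
        layers[[i]]$E[[k]] <- layers[[i]]$E[[k]] -
          corr * s$mE[[k]] / (sqrt(s$vE[[k]]) + eps)
      }
    }
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# ---- multi-branch model -----------------------------------------------------

# branches: named list of un-initialized layer stacks; input_shapes: named
# list of per-branch shapes (excluding n). head: stack applied to the
# concatenated flat branch outputs.
build_nn <- function(branches, input_shapes, head, alpha = 1, seed = 1L) {
  with_seed(seed, {
    branches <- lapply(names(branches), function(nm) {
      st <- init_stack(branches[[nm]], input_shapes[[nm]])
      os <- attr(st, "out_shape")
      if (length(os) != 1)
        stop("branch '", nm, "' must end flat (use layer_flatten/dense)")
      st
    })
    names(branches) <- names(input_shapes)
    width <- sum(vapply(branches, function(s) attr(s, "out_shape"), numeric(1)))
    head <- init_stack(head, width)
    structure(list(branches = branches, head = head, alpha = alpha,
                   input_shapes = input_shapes),
              class = "nn_net")
  })
}

nn_forward <- function(net, inputs, with_cache = FALSE) {
  outs <- list(); caches <- list()
  for (nm in names(net$branches)) {
    fw <- forward_stack(net$branches[[nm]], inputs[[nm]], net$alpha)
    outs[[nm]] <- fw$out
    caches[[nm]] <- fw$caches
  }
  concat <- do.call(cbind, outs)
  hf <- forward_stack(net$head, concat, net$alpha)
  if (!with_cache) return(hf$out)
  list(out = hf$out, branch_caches = caches, head_caches = hf$caches,
       branch_widths = vapply(outs, ncol, integer(1)))
}

# One Adam step on a minibatch; returns updated net + optimizer state.
nn_step <- function(net, inputs, y, opt, lr, t) {
  fw <- nn_forward(net, inputs, with_cache = TRUE)
  n <- length(y)
  dout <- matrix(2 * (fw$out - y) / n, n, 1)
  # head backward, capturing gradient at the concat boundary
  grads_head <- vector("list", length(net$head))
  dcur <- dout
  for (i in rev(seq_along(net$head))) {
    bw <- backward_layer(net$head[[i]], dcur, fw$head_caches[[i]], net$alpha)
    grads_head[i] <- list(bw$grads)
    dcur <- bw$dx
  }
  upd <- adam_update_stack(net$head, grads_head, opt$head, lr, t)
  net$head <- upd$layers; opt$head <- upd$state
  off <- 0
  for (nm in names(net$branches)) {
    w <- fw$branch_widths[[nm]]
    dbranch <- dcur[, (off + 1):(off + w), drop = FALSE]
    off <- off + w
    gb <- backward_stack(net$branches[[nm]], fw$branch_caches[[nm]], dbranch,
                         net$alpha)
    upd <- adam_update_stack(net$branches[[nm]], gb, opt$branches[[nm]], lr, t)
    net$branches[[nm]] <- upd$layers
    opt$branches[[nm]] <- upd$state
  }
  loss <- mean((fw$out - y)^2)
  list(net = net, opt = opt, loss = loss)
}

slice_input <- function(x, idx) {
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, slice_input, idx = idx))
  nd <- length(dim(x))
  if (nd <= 2 || is.null(dim(x))) {
    if (is.null(dim(x))) x[idx]
    else x[idx, , drop = FALSE]
  } else if (nd == 3) x[idx, , , drop = FALSE]
  else x[idx, , , , drop = FALSE]
}

# Full training loop: minibatch Adam, MSE loss (+L1 via dense layer flags).
nn_train <- function(net, inputs, y, epochs = 50, batch_size = 32,
                     lr = 0.01, seed = 1L, verbose = FALSE) {
  opt <- list(head = adam_init_stack(net$head),
              branches = lapply(net$branches, adam_init_stack))
  n <- length(y)
  t <- 0
  with_seed(seed + 104729L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        t <- t + 1
        st <- nn_step(net, lapply(inputs, slice_input, idx = idx), y[idx],
                      opt, lr, t)
        net <- st$net; opt <- st$opt
      }
      if (verbose && ep %% 10 == 0)
        message(sprintf("epoch %d  train MSE %.4f", ep, st$loss))
    }
  })
  net
}
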