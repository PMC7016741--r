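# Minimal 1-D neural-network engine: static layer graphs with explicit
# forward/backward passes, exact per-layer parameter accounting, and Adam.
#
# Tensor conventions:
#   * branch activations are 3-D arrays (batch, length, channels)
#   * head activations after flattening are matrices (batch, features)
# All layers are plain lists tagged with `kind`; models are built by the zoo
# (see model-zoo.R) and trained by the engine (training-engine.R).

EPS_BN <- 1e-5

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- layer constructors -------------------------------------------------

layer_conv1d <- function(kernel, filters, stride = 1L, pad = c("valid", "same"),
                         use_bias = TRUE, activation = "linear",
                         init = c("glorot", "he")) {
  list(kind = "conv1d", kernel = as.integer(kernel), filters = as.integer(filters),
       stride = as.integer(stride), pad = match.arg(pad), use_bias = use_bias,
       activation = activation, init = match.arg(init))
}

layer_dense <- function(units, use_bias = TRUE, activation = "linear",
                        init = c("glorot", "he")) {
  list(kind = "dense", units = as.integer(units), use_bias = use_bias,
       activation = activation, init = match.arg(init))
}

layer_batchnorm <- function(momentum = 0.9) {
  list(kind = "batchnorm", momentum = momentum)
}

layer_activation <- function(fun = c("relu", "sigmoid")) {
  list(kind = "activation", fun = match.arg(fun))
}

layer_maxpool <- function(size) list(kind = "maxpool", size = as.integer(size))

layer_avgpool <- function(size) list(kind = "avgpool", size = as.integer(size))

layer_globalavgpool <- function() list(kind = "globalavgpool")

layer_flatten <- function() list(kind = "flatten")

layer_dropout <- function(rate) list(kind = "dropout", rate = rate)

# Multiplicative attention gate: a sigmoid dense layer of the same width whose
# output scales the incoming activation elementwise.
layer_attention_gate <- function(use_bias = TRUE) {
  list(kind = "attention_gate", use_bias = use_bias)
}

# Post-activation residual unit: conv-BN-relu-conv-BN (+ shortcut) -> relu.
# The shortcut is the identity, or a kernel-1 projection when `project` is
# TRUE (needed on channel or stride changes); the projection can be built
# without bias and with or without its own batch norm, which is how the
# published parameter counts resolve.
layer_residual_unit <- function(kernel, filters, stride = 1L, project = FALSE,
                                proj_bias = FALSE, proj_bn = FALSE,
                                use_bias = TRUE, init = "he") {
  list(kind = "residual_unit", kernel = as.integer(kernel),
       filters = as.integer(filters), stride = as.integer(stride),
       project = project, proj_bias = proj_bias, proj_bn = proj_bn,
       use_bias = use_bias, init = init)
}

## ---- shape tracing and parameter accounting -----------------------------

conv_out_len <- function(L, kernel, stride, pad) {
  if (pad == "same") as.integer(ceiling(L / stride)) else (L - kernel) %/% stride + 1L
}

pool_out_len <- function(L, size) (L - size) %/% size + 1L

# Trace one layer: `shape` is c(L, C) for 3-D activations or a scalar for 2-D.
trace_layer <- function(layer, shape) {
  k <- layer$kind
  if (k == "conv1d") {
    stopifnot(length(shape) == 2)
    L <- conv_out_len(shape[1], layer$kernel, layer$stride, layer$pad)
    if (L < 1) stop("conv1d output length would be < 1")
    w <- layer$kernel * shape[2] * layer$filters + if (layer$use_bias) layer$filters else 0L
    list(shape = c(L, layer$filters), trainable = w, total = w)
  } else if (k == "dense") {
    stopifnot(length(shape) == 1)
    w <- shape * layer$units + if (layer$use_bias) layer$units else 0L
    list(shape = layer$units, trainable = w, total = w)
  } else if (k == "batchnorm") {
    C <- shape[length(shape)]
    list(shape = shape, trainable = 2L * C, total = 4L * C)
  } else if (k == "maxpool" || k == "avgpool") {
    stopifnot(length(shape) == 2)
    L <- pool_out_len(shape[1], layer$size)
    if (L < 1) stop(k, " output length would be < 1")
    list(shape = c(L, shape[2]), trainable = 0L, total = 0L)
  } else if (k == "globalavgpool") {
    list(shape = shape[2], trainable = 0L, total = 0L)
  } else if (k == "flatten") {
    list(shape = prod(shape), trainable = 0L, total = 0L)
  } else if (k == "dropout" || k == "activation") {
    list(shape = shape, trainable = 0L, total = 0L)
  } else if (k == "attention_gate") {
    stopifnot(length(shape) == 1)
    w <- shape * shape + if (layer$use_bias) shape else 0L
    list(shape = shape, trainable = w, total = w)
  } else if (k == "residual_unit") {
    C_in <- shape[2]; f <- layer$filters
    L <- conv_out_len(shape[1], layer$kernel, layer$stride, "same")
    w_main <- layer$kernel * C_in * f + layer$kernel * f * f +
      if (layer$use_bias) 2L * f else 0L
    bn_tr <- 4L * f; bn_tot <- 8L * f            # two BNs on the main path
    w_proj <- 0L; pbn_tr <- 0L; pbn_tot <- 0L
    if (layer$project) {
      w_proj <- C_in * f + if (layer$proj_bias) f else 0L
      if (layer$proj_bn) { pbn_tr <- 2L * f; pbn_tot <- 4L * f }
    }
    list(shape = c(L, f),
         trainable = w_main + bn_tr + w_proj + pbn_tr,
         total = w_main + bn_tot + w_proj + pbn_tot)
  } else stop("unknown layer kind: ", k)
}

trace_layers <- function(layers, shape) {
  tr <- 0; tot <- 0; shapes <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- trace_layer(layers[[i]], shape)
    shape <- res$shape
    shapes[[i]] <- shape
    tr <- tr + res$trainable; tot <- tot + res$total
  }
  list(shape = shape, shapes = shapes, trainable = tr, total = tot)
}

merged_shape <- function(shapes) {
  if (length(shapes) > 1) {
    chans <- vapply(shapes, function(s) s[2], numeric(1))
    stopifnot(length(unique(chans)) == 1)
    c(sum(vapply(shapes, function(s) s[1], numeric(1))), chans[1])
  } else shapes[[1]]
}

#' Count model parameters
#'
#' Walks the architecture graph, tracing output shapes layer by layer, and
#' returns both the trainable parameter count (batch-norm scale and shift
#' only) and the total count (additionally including the non-trainable
#' batch-norm moving mean and variance), following standard model-summary
#' accounting. The published per-model figure matches one of the two lines;
#' each builder records which in `metadata$printed_count_matches`.
#'
#' @param model A model built by one of the `build_*` functions.
#' @return Named numeric vector with elements `trainable` and `total`.
#' @examples
#' count_parameters(build_fnn(44))
#' @export
count_parameters <- function(model) {
  if (identical(model$kind, "combined")) {
    ft <- vapply(model$feeders, function(f) count_parameters(f)["total"], numeric(1))
    ht <- trace_layers(model$head, model$head_input_dim)
    return(c(trainable = ht$trainable,  # feeders are frozen
             total = sum(ft) + ht$total))
  }
  tr <- 0; tot <- 0
  shapes <- list()
  for (bn in names(model$branches)) {
    res <- trace_layers(model$branches[[bn]], model$input_shapes[[bn]])
    shapes[[bn]] <- res$shape
    tr <- tr + res$trainable; tot <- tot + res$total
  }
  res <- trace_layers(model$head, merged_shape(shapes))
  c(trainable = unname(tr + res$trainable), total = unname(tot + res$total))
}

# Symbolic shape trace of a whole model (used in tests and summaries).
trace_model <- function(model) {
  out <- list()
  shapes <- list()
  for (bn in names(model$branches)) {
    res <- trace_layers(model$branches[[bn]], model$input_shapes[[bn]])
    out[[bn]] <- res$shapes
    shapes[[bn]] <- res$shape
  }
  res <- trace_layers(model$head, merged_shape(shapes))
  out$head <- res$shapes
  out
}

## ---- weight initialization ----------------------------------------------

#' Glorot uniform initialization bounds
#'
#' Symmetric bounds \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}} for uniform weight
#' initialization, the default scheme for all non-residual layers (residual
#' networks use He-normal draws).
#'
#' @param fan_in,fan_out Positive integer fan counts.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' glorot_uniform_bounds(2, 4)  # c(-1, 1)
#' @export
glorot_uniform_bounds <- function(fan_in, fan_out) {
  if (fan_in < 1 || fan_out < 1) stop("fan_in and fan_out must be >= 1")
  b <- sqrt(6 / (fan_in + fan_out))
  c(-b, b)
}

init_weight <- function(dims, fan_in, fan_out, init) {
  n <- prod(dims)
  if (init == "he") {
    w <- stats::rnorm(n, 0, sqrt(2 / fan_in))
  } else {
    b <- glorot_uniform_bounds(fan_in, fan_out)
    w <- stats::runif(n, b[1], b[2])
  }
  array(w, dims)
}

init_layer <- function(layer, shape) {
  k <- layer$kind
  if (k == "conv1d") {
    C_in <- shape[2]
    layer$W <- init_weight(c(layer$kernel, C_in, layer$filters),
                           layer$kernel * C_in, layer$kernel * layer$filters,
                           layer$init)
    if (layer$use_bias) layer$b <- numeric(layer$filters)
  } else if (k == "dense") {
    layer$W <- init_weight(c(shape, layer$units), shape, layer$units, layer$init)
    if (layer$use_bias) layer$b <- numeric(layer$units)
  } else if (k == "attention_gate") {
    layer$W <- init_weight(c(shape, shape), shape, shape, "glorot")
    if (layer$use_bias) layer$b <- numeric(shape)
  } else if (k == "batchnorm") {
    C <- shape[length(shape)]
    layer$gamma <- rep(1, C); layer$beta <- numeric(C)
    layer$run_mean <- numeric(C); layer$run_var <- rep(1, C)
  } else if (k == "residual_unit") {
    C_in <- shape[2]; f <- layer$filters; kk <- layer$kernel
    layer$W1 <- init_weight(c(kk, C_in, f), kk * C_in, kk * f, layer$init)
    layer$W2 <- init_weight(c(kk, f, f), kk * f, kk * f, layer$init)
    if (layer$use_bias) { layer$b1 <- numeric(f); layer$b2 <- numeric(f) }
    layer$g1 <- rep(1, f); layer$be1 <- numeric(f)
    layer$rm1 <- numeric(f); layer$rv1 <- rep(1, f)
    layer$g2 <- rep(1, f); layer$be2 <- numeric(f)
    layer$rm2 <- numeric(f); layer$rv2 <- rep(1, f)
    if (layer$project) {
      layer$Wp <- init_weight(c(1, C_in, f), C_in, f, layer$init)
      if (layer$proj_bias) layer$bp <- numeric(f)
      if (layer$proj_bn) {
        layer$gp <- rep(1, f); layer$bep <- numeric(f)
        layer$rmp <- numeric(f); layer$rvp <- rep(1, f)
      }
    }
  }
  layer
}

#' Initialize model weights
#'
#' Materializes weight arrays for every layer of a built architecture, using
#' glorot-uniform draws (He-normal in residual networks) under the current
#' RNG state; call `set.seed()` first for reproducibility.
#'
#' @param model A model from a `build_*` function.
#' @return The model with weight arrays attached.
#' @export
init_model_weights <- function(model) {
  model$branch_out_shapes <- list()
  for (bn in names(model$branches)) {
    shape <- model$input_shapes[[bn]]
    for (i in seq_along(model$branches[[bn]])) {
      model$branches[[bn]][[i]] <- init_layer(model$branches[[bn]][[i]], shape)
      shape <- trace_layer(model$branches[[bn]][[i]], shape)$shape
    }
    model$branch_out_shapes[[bn]] <- shape
  }
  shape <- merged_shape(model$branch_out_shapes)
  for (i in seq_along(model$head)) {
    model$head[[i]] <- init_layer(model$head[[i]], shape)
    shape <- trace_layer(model$head[[i]], shape)$shape
  }
  model$initialized <- TRUE
  model
}

## ---- forward / backward primitives --------------------------------------

pad_same_amount <- function(L, kernel, stride) {
  out <- ceiling(L / stride)
  total <- max((out - 1) * stride + kernel - L, 0)
  c(left = unname(total %/% 2), right = unname(total - total %/% 2))
}



pad_input <- function(X, left, right) {
  left <- unname(left); right <- unname(right)
  if (left == 0 && right == 0) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1], d[2] + left + right, d[3]))
  Xp[, seq.int(left + 1L, left + d[2]), ] <- X
  Xp
}

# direct convolution in compiled code (src/convops.cpp)
conv1d_forward <- function(layer, X) {
  orig_L <- dim(X)[2]
  if (layer$pad == "same") {
    p <- pad_same_amount(orig_L, layer$kernel, layer$stride)
    X <- pad_input(X, p["left"], p["right"])
  }
  r <- .conv1d_fwd(X, dim(X), layer$W, dim(layer$W),
                   if (layer$use_bias) layer$b else numeric(layer$filters),
                   layer$stride, layer$use_bias)
  out <- apply_act(r$pre, layer$activation)
  list(out = out$y, cache = list(M = r$M, xdim = dim(X), pre = r$pre,
                                 act = out$cache, Lo = dim(r$pre)[2],
                                 orig_L = orig_L))
}

conv1d_backward <- function(layer, cache, dY) {
  dPre <- act_backward(dY, layer$activation, cache$act, cache$pre)
  r <- .conv1d_bwd(cache$M, cache$xdim, layer$W, dim(layer$W),
                   dPre, layer$stride)
  dX <- r$dX
  if (layer$pad == "same" && dim(dX)[2] != cache$orig_L) {
    p <- pad_same_amount(cache$orig_L, layer$kernel, layer$stride)
    dX <- dX[, seq.int(p["left"] + 1L, p["left"] + cache$orig_L), , drop = FALSE]
  }
  grads <- list(W = r$dW)
  if (layer$use_bias) grads$b <- r$db
  list(dX = dX, grads = grads)
}

apply_act <- function(x, fun) {
  if (fun == "relu") { y <- x; y[y < 0] <- 0; list(y = y, cache = NULL) }
  else if (fun == "sigmoid") { y <- 1 / (1 + exp(-x)); list(y = y, cache = y) }
  else list(y = x, cache = NULL)
}

act_backward <- function(dY, fun, cache, pre) {
  if (fun == "relu") dY * (pre > 0)
  else if (fun == "sigmoid") dY * cache * (1 - cache)
  else dY
}

bn_forward <- function(layer, X, training) {
  d <- dim(X)
  X2 <- X
  if (length(d) == 3) dim(X2) <- c(d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(X2)
    xc <- sweep(X2, 2, mu)
    v <- colMeans(xc^2)
  } else {
    mu <- layer$run_mean; v <- layer$run_var
    xc <- sweep(X2, 2, mu)
  }
  inv <- 1 / sqrt(v + EPS_BN)
  xhat <- sweep(xc, 2, inv, "*")
  Y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  if (length(d) == 3) dim(Y) <- d
  list(out = Y, cache = list(xhat = xhat, inv = inv, d = d, mu = mu, v = v,
                             training = training))
}

bn_backward <- function(layer, cache, dY) {
  d <- cache$d
  dY2 <- dY
  if (length(d) == 3) dim(dY2) <- c(d[1] * d[2], d[3])
  dgamma <- colSums(dY2 * cache$xhat)
  dbeta <- colSums(dY2)
  if (cache$training) {
    dxhat <- sweep(dY2, 2, layer$gamma, "*")
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dX2 <- sweep(t1 - t2, 2, cache$inv, "*")
  } else {
    dX2 <- sweep(sweep(dY2, 2, layer$gamma, "*"), 2, cache$inv, "*")
  }
  if (length(d) == 3) dim(dX2) <- d
  list(dX = dX2, grads = list(gamma = dgamma, beta = dbeta))
}

bn_update_running <- function(layer, cache) {
  if (!cache$training) return(layer)
  mom <- layer$momentum %||% 0.9
  layer$run_mean <- mom * layer$run_mean + (1 - mom) * cache$mu
  layer$run_var <- mom * layer$run_var + (1 - mom) * cache$v
  layer
}

maxpool_forward <- function(layer, X) {
  r <- .maxpool_fwd(X, dim(X), layer$size)
  list(out = r$Y, cache = list(AM = r$AM, d = dim(X), Lo = dim(r$Y)[2]))
}

maxpool_backward <- function(layer, cache, dY) {
  dX <- .maxpool_bwd(dY, cache$AM, dim(dY), layer$size, cache$d[2])
  list(dX = dX, grads = NULL)
}

avgpool_forward <- function(layer, X) {
  d <- dim(X); p <- layer$size
  Lo <- (d[2] - p) %/% p + 1L
  base <- seq.int(1L, by = p, length.out = Lo)
  Y <- X[, base, , drop = FALSE]
  if (p > 1) for (j in 2:p) Y <- Y + X[, base + (j - 1L), , drop = FALSE]
  list(out = Y / p, cache = list(d = d, Lo = Lo))
}

avgpool_backward <- function(layer, cache, dY) {
  p <- layer$size
  dX <- array(0, cache$d)
  base <- seq.int(1L, by = p, length.out = cache$Lo)
  for (j in seq_len(p)) dX[, base + (j - 1L), ] <-
      dX[, base + (j - 1L), , drop = FALSE] + dY / p
  list(dX = dX, grads = NULL)
}

gap_forward <- function(X) {
  d <- dim(X)
  M <- aperm(X, c(2, 1, 3)); dim(M) <- c(d[2], d[1] * d[3])
  Y <- matrix(colMeans(M), d[1], d[3])
  list(out = Y, cache = list(d = d))
}

gap_backward <- function(cache, dY) {
  d <- cache$d
  dX <- array(0, d)
  for (l in seq_len(d[2])) dX[, l, ] <- dY / d[2]
  list(dX = dX, grads = NULL)
}

layer_forward <- function(layer, X, training) {
  k <- layer$kind
  if (k == "conv1d") conv1d_forward(layer, X)
  else if (k == "dense") {
    pre <- X %*% layer$W
    if (layer$use_bias) pre <- sweep(pre, 2, layer$b, "+")
    out <- apply_act(pre, layer$activation)
    list(out = out$y, cache = list(X = X, pre = pre, act = out$cache))
  }
  else if (k == "batchnorm") bn_forward(layer, X, training)
  else if (k == "activation") {
    out <- apply_act(X, layer$fun)
    list(out = out$y, cache = list(pre = X, act = out$cache))
  }
  else if (k == "maxpool") maxpool_forward(layer, X)
  else if (k == "avgpool") avgpool_forward(layer, X)
  else if (k == "globalavgpool") gap_forward(X)
  else if (k == "flatten") {
    d <- dim(X); Y <- X; dim(Y) <- c(d[1], prod(d[-1]))
    list(out = Y, cache = list(d = d))
  }
  else if (k == "dropout") {
    if (training && layer$rate > 0) {
      mask <- stats::rbinom(length(X), 1, 1 - layer$rate) / (1 - layer$rate)
      dim(mask) <- dim(X)
      list(out = X * mask, cache = list(mask = mask))
    } else list(out = X, cache = list(mask = NULL))
  }
  else if (k == "attention_gate") {
    pre <- X %*% layer$W
    if (layer$use_bias) pre <- sweep(pre, 2, layer$b, "+")
    a <- 1 / (1 + exp(-pre))
    list(out = X * a, cache = list(X = X, a = a))
  }
  else if (k == "residual_unit") residual_forward(layer, X, training)
  else stop("unknown layer kind: ", k)
}

layer_backward <- function(layer, cache, dY) {
  k <- layer$kind
  if (k == "conv1d") conv1d_backward(layer, cache, dY)
  else if (k == "dense") {
    dPre <- act_backward(dY, layer$activation, cache$act, cache$pre)
    grads <- list(W = crossprod(cache$X, dPre))
    if (layer$use_bias) grads$b <- colSums(dPre)
    list(dX = dPre %*% t(layer$W), grads = grads)
  }
  else if (k == "batchnorm") bn_backward(layer, cache, dY)
  else if (k == "activation")
    list(dX = act_backward(dY, layer$fun, cache$act, cache$pre), grads = NULL)
  else if (k == "maxpool") maxpool_backward(layer, cache, dY)
  else if (k == "avgpool") avgpool_backward(layer, cache, dY)
  else if (k == "globalavgpool") gap_backward(cache, dY)
  else if (k == "flatten") { dX <- dY; dim(dX) <- cache$d; list(dX = dX, grads = NULL) }
  else if (k == "dropout") {
    if (is.null(cache$mask)) list(dX = dY, grads = NULL)
    else list(dX = dY * cache$mask, grads = NULL)
  }
  else if (k == "attention_gate") {
    a <- cache$a; X <- cache$X
    dPre <- dY * X * a * (1 - a)
    grads <- list(W = crossprod(X, dPre))
    if (layer$use_bias) grads$b <- colSums(dPre)
    list(dX = dY * a + dPre %*% t(layer$W), grads = grads)
  }
  else if (k == "residual_unit") residual_backward(layer, cache, dY)
  else stop("unknown layer kind: ", k)
}

## ---- residual unit ------------------------------------------------------

res_conv <- function(layer, which) {
  if (which == 1)
    list(kind = "conv1d", kernel = layer$kernel, filters = layer$filters,
         stride = layer$stride, pad = "same", use_bias = layer$use_bias,
         activation = "linear", W = layer$W1, b = layer$b1)
  else
    list(kind = "conv1d", kernel = layer$kernel, filters = layer$filters,
         stride = 1L, pad = "same", use_bias = layer$use_bias,
         activation = "linear", W = layer$W2, b = layer$b2)
}

res_bn <- function(layer, which) {
  if (which == 1)
    list(kind = "batchnorm", momentum = 0.9, gamma = layer$g1, beta = layer$be1,
         run_mean = layer$rm1, run_var = layer$rv1)
  else if (which == 2)
    list(kind = "batchnorm", momentum = 0.9, gamma = layer$g2, beta = layer$be2,
         run_mean = layer$rm2, run_var = layer$rv2)
  else
    list(kind = "batchnorm", momentum = 0.9, gamma = layer$gp, beta = layer$bep,
         run_mean = layer$rmp, run_var = layer$rvp)
}

res_proj <- function(layer) {
  list(kind = "conv1d", kernel = 1L, filters = layer$filters,
       stride = layer$stride, pad = "same",
       use_bias = isTRUE(layer$proj_bias), activation = "linear",
       W = layer$Wp, b = layer$bp)
}

residual_forward <- function(layer, X, training) {
  f1 <- conv1d_forward(res_conv(layer, 1), X)
  f1b <- bn_forward(res_bn(layer, 1), f1$out, training)
  r1 <- f1b$out; r1[r1 < 0] <- 0
  f2 <- conv1d_forward(res_conv(layer, 2), r1)
  f2b <- bn_forward(res_bn(layer, 2), f2$out, training)
  fp <- NULL; fpb <- NULL
  if (layer$project) {
    fp <- conv1d_forward(res_proj(layer), X)
    if (layer$proj_bn) {
      fpb <- bn_forward(res_bn(layer, 3), fp$out, training)
      short <- fpb$out
    } else short <- fp$out
  } else short <- X
  pre <- f2b$out + short
  y <- pre; y[y < 0] <- 0
  list(out = y,
       cache = list(f1 = f1, f1b = f1b, pre1 = f1b$out, f2 = f2, f2b = f2b,
                    fp = fp, fpb = fpb, pre = pre))
}

residual_backward <- function(layer, cache, dY) {
  dPre <- dY * (cache$pre > 0)
  db2 <- bn_backward(list(gamma = layer$g2), cache$f2b$cache, dPre)
  dc2 <- conv1d_backward(res_conv(layer, 2), cache$f2$cache, db2$dX)
  dRelu1 <- dc2$dX * (cache$pre1 > 0)
  db1 <- bn_backward(list(gamma = layer$g1), cache$f1b$cache, dRelu1)
  dc1 <- conv1d_backward(res_conv(layer, 1), cache$f1$cache, db1$dX)
  dX <- dc1$dX
  grads <- list(W1 = dc1$grads$W, W2 = dc2$grads$W,
                g1 = db1$grads$gamma, be1 = db1$grads$beta,
                g2 = db2$grads$gamma, be2 = db2$grads$beta)
  if (layer$use_bias) { grads$b1 <- dc1$grads$b; grads$b2 <- dc2$grads$b }
  if (layer$project) {
    dShort <- dPre
    if (layer$proj_bn) {
      dbp <- bn_backward(list(gamma = layer$gp), cache$fpb$cache, dShort)
      grads$gp <- dbp$grads$gamma; grads$bep <- dbp$grads$beta
      dShort <- dbp$dX
    }
    dcp <- conv1d_backward(res_proj(layer), cache$fp$cache, dShort)
    grads$Wp <- dcp$grads$W
    if (isTRUE(layer$proj_bias)) grads$bp <- dcp$grads$b
    dX <- dX + dcp$dX
  } else {
    dX <- dX + dPre
  }
  list(dX = dX, grads = grads)
}

## ---- whole-model passes -------------------------------------------------

forward_layers <- function(layers, X, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], X, training)
    X <- res$out
    caches[[i]] <- res$cache
  }
  list(out = X, caches = caches)
}

backward_layers <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    res <- layer_backward(layers[[i]], caches[[i]], dY)
    dY <- res$dX
    if (!is.null(res$grads)) grads[[i]] <- res$grads  # NULL assignment would drop the slot
  }
  list(dX = dY, grads = grads)
}

concat_time <- function(A, B) {
  da <- dim(A); db <- dim(B)
  stopifnot(da[1] == db[1], da[3] == db[3])
  Y <- array(0, c(da[1], da[2] + db[2], da[3]))
  Y[, seq_len(da[2]), ] <- A
  Y[, da[2] + seq_len(db[2]), ] <- B
  Y
}

model_forward <- function(model, x, training = FALSE) {
  if (identical(model$kind, "combined")) {
    feats <- combined_features(model, x)
    hf <- forward_layers(model$head, feats, training)
    return(list(prob = as.vector(hf$out), head_caches = hf$caches, feats = feats,
                merged_dim = ncol(feats)))
  }
  if (length(model$branches) == 1 && names(model$branches)[1] == "input") {
    bf <- forward_layers(model$branches$input, x, training)
    merged <- bf$out
    bcaches <- list(input = bf$caches)
  } else {
    stopifnot(is.list(x), !is.null(x$enhancer), !is.null(x$promoter))
    fe <- forward_layers(model$branches$enhancer, x$enhancer, training)
    fp <- forward_layers(model$branches$promoter, x$promoter, training)
    merged <- concat_time(fe$out, fp$out)
    bcaches <- list(enhancer = fe$caches, promoter = fp$caches,
                    split = dim(fe$out)[2])
  }
  hf <- forward_layers(model$head, merged, training)
  list(prob = as.vector(hf$out), branch_caches = bcaches, head_caches = hf$caches,
       merged_dim = dim(merged))
}

model_backward <- function(model, fw, dProb) {
  dY <- matrix(dProb, ncol = 1)
  hb <- backward_layers(model$head, fw$head_caches, dY)
  grads <- list(head = hb$grads)
  if (identical(model$kind, "combined")) return(grads)
  if (!is.null(fw$branch_caches$split)) {
    s <- fw$branch_caches$split
    dM <- hb$dX
    dE <- dM[, seq_len(s), , drop = FALSE]
    dP <- dM[, s + seq_len(dim(dM)[2] - s), , drop = FALSE]
    be <- backward_layers(model$branches$enhancer, fw$branch_caches$enhancer, dE)
    bp <- backward_layers(model$branches$promoter, fw$branch_caches$promoter, dP)
    grads$branches <- list(enhancer = be$grads, promoter = bp$grads)
  } else {
    bi <- backward_layers(model$branches$input, fw$branch_caches$input, hb$dX)
    grads$branches <- list(input = bi$grads)
  }
  grads
}

# refresh batch-norm running statistics from the caches of a training step
model_update_bn <- function(model, fw) {
  upd <- function(layers, caches) {
    for (i in seq_along(layers)) {
      if (layers[[i]]$kind == "batchnorm") {
        layers[[i]] <- bn_update_running(layers[[i]], caches[[i]])
      } else if (layers[[i]]$kind == "residual_unit") {
        lay <- layers[[i]]; cc <- caches[[i]]; mom <- 0.9
        lay$rm1 <- mom * lay$rm1 + (1 - mom) * cc$f1b$cache$mu
        lay$rv1 <- mom * lay$rv1 + (1 - mom) * cc$f1b$cache$v
        lay$rm2 <- mom * lay$rm2 + (1 - mom) * cc$f2b$cache$mu
        lay$rv2 <- mom * lay$rv2 + (1 - mom) * cc$f2b$cache$v
        if (lay$project && lay$proj_bn) {
          lay$rmp <- mom * lay$rmp + (1 - mom) * cc$fpb$cache$mu
          lay$rvp <- mom * lay$rvp + (1 - mom) * cc$fpb$cache$v
        }
        layers[[i]] <- lay
      }
    }
    layers
  }
  if (identical(model$kind, "combined")) {
    model$head <- upd(model$head, fw$head_caches)
    return(model)
  }
  if (!is.null(fw$branch_caches$split)) {
    model$branches$enhancer <- upd(model$branches$enhancer, fw$branch_caches$enhancer)
    model$branches$promoter <- upd(model$branches$promoter, fw$branch_caches$promoter)
  } else {
    model$branches$input <- upd(model$branches$input, fw$branch_caches$input)
  }
  model$head <- upd(model$head, fw$head_caches)
  model
}

## ---- parameter plumbing -------------------------------------------------

PARAM_FIELDS <- c("W", "b", "gamma", "beta", "W1", "b1", "W2", "b2",
                  "g1", "be1", "g2", "be2", "Wp", "bp", "gp", "bep")

layer_param_names <- function(layer) intersect(PARAM_FIELDS, names(layer))

# Apply fn(param, grad, key, kind, name) over all parameters with a parallel
# grads structure; fn returns the updated parameter (used by Adam).
map_model_params <- function(model, grads, fn) {
  walk <- function(layers, glist, prefix) {
    for (i in seq_along(layers)) {
      g <- if (i <= length(glist)) glist[[i]] else NULL
      if (is.null(g)) next
      for (nm in names(g)) {
        key <- paste(prefix, i, nm, sep = ".")
        layers[[i]][[nm]] <- fn(layers[[i]][[nm]], g[[nm]], key,
                                layers[[i]]$kind, nm)
      }
    }
    layers
  }
  if (!identical(model$kind, "combined")) {
    for (bn in names(model$branches)) {
      if (!is.null(grads$branches[[bn]])) {
        model$branches[[bn]] <- walk(model$branches[[bn]], grads$branches[[bn]],
                                     paste0("br.", bn))
      }
    }
  }
  model$head <- walk(model$head, grads$head, "head")
  model
}

model_weights <- function(model) {
  grab <- function(layers) lapply(layers, function(l) l[layer_param_names(l)])
  if (identical(model$kind, "combined")) return(list(.head = grab(model$head)))
  c(lapply(model$branches, grab), list(.head = grab(model$head)))
}

restore_weights <- function(model, snap) {
  putl <- function(layers, snaps) {
    for (i in seq_along(layers)) for (nm in names(snaps[[i]]))
      layers[[i]][[nm]] <- snaps[[i]][[nm]]
    layers
  }
  if (!identical(model$kind, "combined")) {
    for (bn in names(model$branches)) model$branches[[bn]] <- putl(model$branches[[bn]], snap[[bn]])
  }
  model$head <- putl(model$head, snap$.head)
  model
}
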