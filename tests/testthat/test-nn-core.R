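# Numerical core: forward primitives against naive oracles, analytic
# gradients against finite differences, training determinism.

naive_conv1d_valid <- function(X, W, b) {
  # X: (n, L, C), W: (k, C, F)
  n <- dim(X)[1]; L <- dim(X)[2]; k <- dim(W)[1]; F <- dim(W)[3]
  Lo <- L - k + 1
  out <- array(0, c(n, Lo, F))
  for (i in seq_len(n)) for (t in seq_len(Lo)) for (f in seq_len(F)) {
    out[i, t, f] <- sum(X[i, t:(t + k - 1), ] * W[, , f]) + b[f]
  }
  out
}

test_that("conv1d forward matches a direct convolution oracle", {
  set.seed(11)
  lay <- epiholdout:::init_layer(
    epiholdout:::layer_conv1d(5, 3, pad = "valid"), c(12L, 2L))
  X <- array(stats::rnorm(4 * 12 * 2), c(4, 12, 2))
  got <- epiholdout:::conv1d_forward(lay, X)$out
  expect_equal(got, naive_conv1d_valid(X, lay$W, lay$b), tolerance = 1e-12)
  # same padding preserves length
  lay_s <- epiholdout:::init_layer(
    epiholdout:::layer_conv1d(5, 3, pad = "same"), c(12L, 2L))
  expect_equal(dim(epiholdout:::conv1d_forward(lay_s, X)$out)[2], 12)
  # stride-2 same padding gives ceil(L / 2)
  lay_2 <- epiholdout:::init_layer(
    epiholdout:::layer_conv1d(5, 3, stride = 2, pad = "same"), c(13L, 2L))
  X13 <- array(stats::rnorm(4 * 13 * 2), c(4, 13, 2))
  expect_equal(dim(epiholdout:::conv1d_forward(lay_2, X13)$out)[2], 7)
})

test_that("pooling layers match naive implementations", {
  set.seed(12)
  X <- array(stats::rnorm(3 * 12 * 2), c(3, 12, 2))
  mp <- epiholdout:::maxpool_forward(epiholdout:::layer_maxpool(3), X)$out
  ap <- epiholdout:::avgpool_forward(epiholdout:::layer_avgpool(3), X)$out
  for (i in 1:3) for (w in 1:4) for (c in 1:2) {
    seg <- X[i, (3 * w - 2):(3 * w), c]
    expect_equal(mp[i, w, c], max(seg))
    expect_equal(ap[i, w, c], mean(seg))
  }
  gp <- epiholdout:::gap_forward(X)$out
  expect_equal(gp[2, 1], mean(X[2, , 1]))
})

test_that("batch norm standardizes per channel in training mode", {
  set.seed(13)
  lay <- epiholdout:::init_layer(epiholdout:::layer_batchnorm(), c(30L, 4L))
  X <- array(stats::rnorm(10 * 30 * 4, mean = 3, sd = 2), c(10, 30, 4))
  out <- epiholdout:::bn_forward(lay, X, training = TRUE)$out
  m <- apply(out, 3, mean)
  v <- apply(out, 3, function(ch) stats::var(as.vector(ch)))
  expect_true(all(abs(m) < 1e-10))
  expect_true(all(abs(v - 1) < 0.02))    # n*L normalization vs var()'s n-1
})

test_that("analytic gradients match finite differences across all layer kinds", {
  set.seed(42)
  branch <- list(
    epiholdout:::layer_conv1d(3, 6, pad = "same", activation = "relu"),
    epiholdout:::layer_batchnorm(),
    epiholdout:::layer_maxpool(2),
    epiholdout:::layer_residual_unit(3, 8, stride = 2, project = TRUE,
                                     proj_bias = FALSE, proj_bn = TRUE),
    epiholdout:::layer_avgpool(2)
  )
  head <- list(
    epiholdout:::layer_flatten(),
    epiholdout:::layer_dense(10, activation = "relu"),
    epiholdout:::layer_batchnorm(),
    epiholdout:::layer_attention_gate(),
    epiholdout:::layer_dense(1, use_bias = FALSE),
    epiholdout:::layer_batchnorm(),
    epiholdout:::layer_activation("sigmoid")
  )
  m <- epiholdout:::new_model("tiny", list(enhancer = branch, promoter = branch),
                              head, list(enhancer = c(20L, 4L), promoter = c(16L, 4L)))
  m <- init_model_weights(m)
  n <- 5
  x <- list(enhancer = array(stats::rnorm(n * 20 * 4), c(n, 20, 4)),
            promoter = array(stats::rnorm(n * 16 * 4), c(n, 16, 4)))
  y <- c(1, 0, 1, 0, 1)
  w <- list(w_pos = 1.3, w_neg = 0.8)
  lossfun <- function(model) {
    fw <- epiholdout:::model_forward(model, x, training = TRUE)
    weighted_bce(fw$prob, y, w)
  }
  fw <- epiholdout:::model_forward(m, x, training = TRUE)
  gr <- epiholdout:::model_backward(m, fw, epiholdout:::weighted_bce_grad(fw$prob, y, w))
  eps <- 1e-6
  check_set <- function(get, set, g) {
    p <- get(m)
    for (i in sample(length(p), min(3, length(p)))) {
      num <- (lossfun(set(m, replace(p, i, p[i] + eps))) -
              lossfun(set(m, replace(p, i, p[i] - eps)))) / (2 * eps)
      if (abs(num) < 1e-8 && abs(g[i]) < 1e-8) next  # true-zero gradients
      expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i])), 1e-4)
    }
  }
  for (br in c("enhancer", "promoter")) for (bi in seq_along(m$branches[[br]])) {
    gs <- gr$branches[[br]][[bi]]
    if (is.null(gs)) next
    for (nm in names(gs)) {
      check_set(function(mm) mm$branches[[br]][[bi]][[nm]],
                function(mm, v) { mm$branches[[br]][[bi]][[nm]][] <- v; mm },
                gs[[nm]])
    }
  }
  for (hi in seq_along(m$head)) {
    gs <- gr$head[[hi]]
    if (is.null(gs)) next
    for (nm in names(gs)) {
      check_set(function(mm) mm$head[[hi]][[nm]],
                function(mm, v) { mm$head[[hi]][[nm]][] <- v; mm },
                gs[[nm]])
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  set.seed(1)
  X <- matrix(stats::rnorm(200 * 6), 200)
  y <- rbinom(200, 1, 1 / (1 + exp(-X[, 1] * 2)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  run <- function() {
    train_model(build_fnn(6, hidden = c(8, 4)), X, y, X, y,
                config = list(lr = 1e-2, batch_size = 50, l2_conv = 0),
                max_epochs = 5, seed = 99)$history$train_loss
  }
  expect_identical(run(), run())
})
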