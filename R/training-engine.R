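# Imbalance-aware training: weighted binary cross-entropy, Adam with the
# published per-model configurations, early stopping on validation F1 with
# patience 10, and batch-rebalancing (oversampling / down-sampling) as the
# alternative to loss weighting.

#' Balancing class weights
#'
#' The weight for each class is half the sample size divided by the class
#' count, \eqn{w_c = ((n_{pos}+n_{neg})/2)/n_c}, so both classes contribute
#' equally to the expected loss whatever the imbalance. Satisfies the balance
#' identity `w_pos * n_pos + w_neg * n_neg == n_pos + n_neg`.
#'
#' @param n_pos,n_neg Positive class counts (must both be >= 1).
#' @return List with `w_pos` and `w_neg`.
#' @examples
#' class_weights(1977, 39500)
#' @export
class_weights <- function(n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1) stop("both class counts must be >= 1")
  half <- (n_pos + n_neg) / 2
  list(w_pos = half / n_pos, w_neg = half / n_neg)
}

#' Weighted binary cross-entropy
#'
#' Mean over the batch of
#' \eqn{-[w_{pos} y \log p + w_{neg} (1-y) \log(1-p)]}, with probabilities
#' clipped away from 0 and 1 at machine tolerance.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels.
#' @param w Class weights from [class_weights()]; defaults to unweighted.
#' @return Scalar loss.
#' @examples
#' weighted_bce(0.5, 1)  # log(2)
#' @export
weighted_bce <- function(p, y, w = list(w_pos = 1, w_neg = 1)) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(w$w_pos * y * log(p) + w$w_neg * (1 - y) * log(1 - p))
}

# gradient of weighted BCE w.r.t. p (mean reduction)
weighted_bce_grad <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  (-(w$w_pos * y / p) + w$w_neg * (1 - y) / (1 - p)) / length(y)
}

#' F1 score of thresholded predictions
#'
#' Harmonic mean of precision and recall at the given probability threshold;
#' defined as 0 when there are no positive predictions but positives exist,
#' and 1 when there are neither positives nor positive predictions.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels.
#' @param threshold Classification threshold in (0,1).
#' @return Scalar F1.
#' @examples
#' f1_score(c(.9, .8, .2, .6), c(1, 1, 0, 0))  # 2 TP, 1 FP, 0 FN
#' @export
f1_score <- function(p, y, threshold = 0.5) {
  yhat <- as.integer(p > threshold)
  tp <- sum(yhat == 1 & y == 1)
  fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1)
  if (tp == 0) {
    if (fn == 0 && fp == 0) return(1)
    return(0)
  }
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Per-model training configuration
#'
#' Batch size, learning rate, convolution L2 weight decay and the two dropout
#' rates, as published for each model family; unknown names fall back to the
#' FNN row.
#'
#' @param model_name One of the zoo names.
#' @return List of training hyperparameters.
#' @export
training_config <- function(model_name = "fnn") {
  tab <- list(
    sequence_basic_cnn     = list(batch_size = 64,  lr = 1e-5, l2_conv = 1e-6, dropout1 = 0.2, dropout2 = 0.8),
    sequence_attention_cnn = list(batch_size = 64,  lr = 1e-5, l2_conv = 2e-5, dropout1 = 0.2, dropout2 = NA),
    sequence_resnet        = list(batch_size = 200, lr = 1e-5, l2_conv = 2e-5, dropout1 = 0.5, dropout2 = NA),
    epi_basic_cnn          = list(batch_size = 200, lr = 1e-6, l2_conv = 1e-5, dropout1 = 0.3, dropout2 = 0.6),
    epi_resnet             = list(batch_size = 64,  lr = 1e-3, l2_conv = 1e-5, dropout1 = 0.3, dropout2 = 0.6),
    fnn                    = list(batch_size = 200, lr = 1e-6, l2_conv = 1e-5, dropout1 = 0.7, dropout2 = NA),
    combined               = list(batch_size = 200, lr = 1e-5, l2_conv = 1e-6, dropout1 = 0.3, dropout2 = 0.5)
  )
  hit <- tab[[model_name]]
  if (is.null(hit)) {
    pre <- names(tab)[vapply(names(tab), function(nm) startsWith(model_name, nm), logical(1))]
    hit <- if (length(pre)) tab[[pre[1]]] else tab$fnn
  }
  hit
}

subset_x <- function(x, idx) {
  if (is.matrix(x)) return(x[idx, , drop = FALSE])
  if (is.list(x)) return(lapply(x, subset_x, idx = idx))
  if (is.array(x) && length(dim(x)) == 3) return(x[idx, , , drop = FALSE])
  stop("unsupported feature container")
}

n_samples_x <- function(x) {
  if (is.matrix(x) || (is.array(x) && length(dim(x)) == 3)) return(dim(x)[1])
  n_samples_x(x[[1]])
}

#' Predict interaction probabilities
#'
#' @param model A trained (initialized) model.
#' @param x Features in the model's input form (matrix, or a list with
#'   `enhancer` and `promoter` arrays).
#' @param batch_size Forward-pass batch size.
#' @return Numeric vector of probabilities.
#' @export
predict_model <- function(model, x, batch_size = 512) {
  n <- n_samples_x(x)
  out <- numeric(n)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    out[idx] <- model_forward(model, subset_x(x, idx), training = FALSE)$prob
  }
  out
}

adam_new <- function() new.env(parent = emptyenv())

adam_step <- function(state, key, param, grad, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  slot <- state[[key]]
  if (is.null(slot)) slot <- list(m = param * 0, v = param * 0)
  slot$m <- beta1 * slot$m + (1 - beta1) * grad
  slot$v <- beta2 * slot$v + (1 - beta2) * grad^2
  state[[key]] <- slot
  mhat <- slot$m / (1 - beta1^t)
  vhat <- slot$v / (1 - beta2^t)
  param - lr * mhat / (sqrt(vhat) + eps)
}

# convolution-kernel fields that receive L2 weight decay (read literally from
# the published table: "L2 weight decay in the convolution")
CONV_KERNEL_FIELDS <- c("W1", "W2", "Wp")

is_conv_kernel <- function(kind, name) {
  (kind == "conv1d" && name == "W") ||
    (kind == "residual_unit" && name %in% CONV_KERNEL_FIELDS)
}

#' Train a model under the imbalance-aware protocol
#'
#' Adam with the per-model learning rate and batch size, L2 penalty on
#' convolution kernels only, class-imbalance handling by loss weighting or
#' batch rebalancing, and early stopping: training halts once the validation
#' F1 has not improved for `patience` consecutive epochs (ties count as
#' non-improvement), and the weights with the highest validation F1 (earliest
#' epoch on ties) are restored.
#'
#' @param model A built model (weights are initialized here if absent).
#' @param x,y Training features and 0/1 labels.
#' @param x_val,y_val Validation data for early stopping.
#' @param config Training configuration, e.g. [training_config()]; any of
#'   `batch_size`, `lr`, `l2_conv` may be overridden.
#' @param weighting `"weighted_loss"` (default), `"oversample"` (positives
#'   resampled to 1:1 in each epoch), or `"downsample"` (negatives
#'   subsampled to 1:1).
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and resampling.
#' @param verbose Print per-epoch progress.
#' @return A train state: `model` (best weights), `history` data frame with
#'   per-epoch loss/F1/AUROC, `best_epoch`, `best_val_f1`, `stopped_early`.
#' @export
train_model <- function(model, x, y, x_val, y_val,
                        config = training_config(model$name),
                        weighting = c("weighted_loss", "oversample", "downsample"),
                        max_epochs = 100, patience = 10, seed = 1,
                        verbose = FALSE) {
  weighting <- match.arg(weighting)
  n <- n_samples_x(x)
  if (n == 0) stop("empty training partition")
  if (n_samples_x(x_val) == 0) stop("empty validation partition")
  if (length(y) != n) stop("length(y) does not match features")
  set.seed(seed)
  if (!isTRUE(model$initialized)) {
    model <- if (identical(model$kind, "combined")) init_combined(model) else init_model_weights(model)
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("training data must contain both classes")
  w <- if (weighting == "weighted_loss") class_weights(n_pos, n_neg)
       else list(w_pos = 1, w_neg = 1)
  lr <- config$lr %||% 1e-3
  bs <- config$batch_size %||% 64
  l2 <- config$l2_conv %||% 0
  state <- adam_new()
  tstep <- 0
  best_f1 <- -Inf; best_snap <- NULL; best_epoch <- 0; since <- 0
  hist <- list()
  pos_idx <- which(y == 1); neg_idx <- which(y == 0)
  for (epoch in seq_len(max_epochs)) {
    idx <- switch(weighting,
      weighted_loss = sample(n),
      oversample = sample(c(neg_idx, sample(pos_idx, length(neg_idx), replace = TRUE))),
      downsample = sample(c(pos_idx, sample(neg_idx, min(length(pos_idx), length(neg_idx)))))
    )
    ep_loss <- 0; nb <- 0
    for (s in seq(1, length(idx), by = bs)) {
      bi <- idx[s:min(s + bs - 1, length(idx))]
      if (length(bi) < 2) next
      xb <- subset_x(x, bi); yb <- y[bi]
      fw <- model_forward(model, xb, training = TRUE)
      loss <- weighted_bce(fw$prob, yb, w)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
      dP <- weighted_bce_grad(fw$prob, yb, w)
      grads <- model_backward(model, fw, dP)
      tstep <- tstep + 1
      model <- map_model_params(model, grads, function(param, grad, key, kind, nm) {
        if (l2 > 0 && is_conv_kernel(kind, nm)) grad <- grad + l2 * param
        adam_step(state, key, param, grad, lr, tstep)
      })
      model <- model_update_bn(model, fw)
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    p_val <- predict_model(model, x_val)
    vf1 <- f1_score(p_val, y_val)
    vauc <- if (length(unique(y_val)) > 1) auroc(p_val, y_val) else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / max(nb, 1),
                                val_f1 = vf1, val_auroc = vauc)
    if (verbose) message(sprintf("epoch %3d  loss %.4f  val F1 %.4f  val AUROC %s",
                                 epoch, ep_loss / max(nb, 1), vf1,
                                 ifelse(is.na(vauc), "NA", sprintf("%.4f", vauc))))
    if (vf1 > best_f1) {           # strict improvement; ties keep the earlier epoch
      best_f1 <- vf1; best_snap <- model_weights(model); best_epoch <- epoch
      since <- 0
    } else {
      since <- since + 1
      if (since >= patience) break
    }
  }
  if (!is.null(best_snap)) model <- restore_weights(model, best_snap)
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best_epoch, best_val_f1 = best_f1,
       stopped_early = since >= patience, class_weights = w)
}
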