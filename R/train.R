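# Minibatch training with Adam, cross-entropy loss, and between-epoch
# fuzzy c-means refresh of the FNB centroids.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(params, grads, opt, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        skip = character(0)) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    if (nm %in% skip || is.null(grads[[nm]])) next
    g <- grads[[nm]]
    if (!is.null(dim(params[[nm]]))) dim(g) <- dim(params[[nm]]) else
      g <- as.vector(g)
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}

#' Train a model
#'
#' Minibatch Adam on cross-entropy. For EEG-CLFCNet models with the fuzzy
#' block enabled, the last LSTM hidden state of every training example is
#' buffered during each epoch and the rule centroids are refreshed by
#' fuzzy c-means before the next epoch (they stay at zero throughout the
#' first epoch). The `alpha` scaling vector is kept strictly positive by
#' clipping from below after each update. Deterministic given `seed`.
#'
#' @param model A [build_compact_cnn()] or [assemble_eeg_clfcnet()] model.
#' @param x Input array `[N, channels, samples]`.
#' @param y 0-based integer labels.
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 3e-3).
#' @param seed Integer seed for shuffling, dropout and centroid refresh.
#' @param verbose Log per-epoch loss/accuracy?
#' @return List with the fitted `model` and a `history` data.frame
#'   (epoch, loss, accuracy).
#' @export
train_model <- function(model, x, y, epochs = 30L, batch_size = 32L,
                        lr = 3e-3, seed = 1L, verbose = FALSE) {
  check_that(inherits(model, "clfc_model"), "need a built model")
  y <- as.integer(y)
  n <- dim(x)[1]
  check_that(length(y) == n, "one label per trial")
  check_that(length(unique(y)) >= 2L, "labels must cover >= 2 classes",
             "contract_error")
  set.seed(seed)
  clfc_log("debug", sprintf("train_model: n=%d epochs=%d seed=%d",
                            n, epochs, seed))
  opt <- adam_init(model$params)
  fnb_on <- model$type == "eeg_clfcnet" && model$config$fnb_enabled
  hist_loss <- numeric(epochs)
  hist_acc <- numeric(epochs)
  last_finite <- NA_real_
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0
    fnb_buffer <- if (fnb_on) vector("list", ceiling(n / batch_size))
    bi <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      bi <- bi + 1L
      take <- idx[start:min(start + batch_size - 1L, n)]
      xb <- x[take, , , drop = FALSE]
      yb <- y[take]
      fwd <- model_fwd(model, xb, training = TRUE)
      model$state[c("bn1", "bn2", "bn3")] <-
        fwd$state[c("bn1", "bn2", "bn3")]
      loss <- cross_entropy(fwd$probs, yb)
      if (!is.finite(loss)) {
        clfc_error(sprintf(
          "training diverged (loss not finite; last finite loss %.4g)",
          last_finite), "training_error")
      }
      last_finite <- loss
      ep_loss <- ep_loss + loss * length(take)
      ep_hits <- ep_hits + sum(max.col(fwd$probs) - 1L == yb)
      if (fnb_on) fnb_buffer[[bi]] <- t(fwd$cache$h_last)
      grads <- model_bwd(model, xb, yb, fwd)
      upd <- adam_update(model$params, grads, opt, lr,
                         skip = "fnb_centroids")
      model$params <- upd$params
      opt <- upd$opt
      if (fnb_on) {
        model$params$fnb_alpha <- pmax(model$params$fnb_alpha, 1e-3)
      }
    }
    if (fnb_on) {
      history <- do.call(rbind, fnb_buffer)
      model$state$fnb_centroids <- update_fnb_centroids(
        history, model$config$fnb_rules, epoch_index = ep,
        seed = derive_seed(seed, ep))
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_hits / n
    if (verbose) {
      clfc_log("info", sprintf("epoch %d/%d loss %.4f acc %.3f",
                               ep, epochs, hist_loss[ep], hist_acc[ep]))
    }
  }
  list(model = model,
       history = data.frame(epoch = seq_len(epochs), loss = hist_loss,
                            accuracy = hist_acc))
}
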