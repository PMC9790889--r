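# Stratified cross-validation, Cohen's kappa, per-channel and per-region
# accuracy surfaces.

#' Stratified k-fold partition
#'
#' Seeded shuffle within each class, then round-robin assignment, so folds
#' are disjoint, exhaustive, and per-class proportions differ by at most
#' one trial across folds.
#'
#' @param labels 0-based integer labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per trial.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  counts <- table(labels)
  if (k > min(counts)) {
    clfc_error(sprintf("k = %d exceeds the smallest class count (%d)",
                       k, min(counts)), "fold_error")
  }
  set.seed(seed)
  folds <- integer(length(labels))
  pos <- 0L
  for (cl in as.integer(names(counts))) {
    idx <- sample(which(labels == cl))
    # continue the round-robin across classes so fold sizes differ by at
    # most one both globally and within every class
    folds[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- pos + length(idx)
  }
  folds
}

#' Confusion matrix
#'
#' @param truth,pred 0-based integer labels.
#' @param k Number of classes.
#' @return `[k x k]` integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, k) {
  m <- matrix(0L, k, k)
  for (i in seq_along(truth)) {
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  m
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement from the marginal products. For balanced K-class marginals
#' this reduces to `(acc - 1/K) / (1 - 1/K)`.
#'
#' @param cm Nonnegative confusion matrix with positive total.
#' @return Kappa in `[-1, 1]`; a degenerate matrix with `p_e = 1` returns
#'   0 with a warning.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  check_that(nrow(cm) == ncol(cm) && all(cm >= 0) && sum(cm) > 0,
             "confusion matrix must be square, nonnegative, with total > 0")
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (p_e >= 1) {
    warning("degenerate confusion matrix (expected agreement 1); kappa = 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Stratified k-fold cross-validation of a classifier on feature arrays
#'
#' Every trial is tested exactly once. The report carries per-fold accuracy
#' and kappa, their mean and SD, and kappa from the pooled confusion matrix.
#'
#' @param x Input array `[N, channels, samples]`.
#' @param y 0-based integer labels.
#' @param model_factory Zero-argument function returning a fresh model.
#' @param k Number of folds (default 10).
#' @param seed Integer seed (folds and per-fold training).
#' @param train_args List of arguments passed on to [train_model()].
#' @return Object of class `evaluation_report`.
#' @export
cross_validate <- function(x, y, model_factory, k = 10L, seed = 1L,
                           train_args = list()) {
  y <- as.integer(y)
  folds <- stratified_folds(y, k, seed)
  n_cls <- length(unique(y))
  acc <- numeric(k); kap <- numeric(k)
  pooled <- matrix(0L, n_cls, n_cls)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- do.call(train_model, c(
      list(model = model_factory(), x = x[tr, , , drop = FALSE],
           y = y[tr], seed = derive_seed(seed, f)),
      train_args))
    pred <- predict(fit$model, x[!tr, , , drop = FALSE], type = "class")
    cm <- confusion_matrix(y[!tr], pred, n_cls)
    pooled <- pooled + cm
    acc[f] <- sum(diag(cm)) / sum(cm)
    kap[f] <- cohen_kappa(cm)
  }
  structure(list(fold_accuracy = acc, fold_kappa = kap,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 mean_kappa = mean(kap),
                 pooled_confusion = pooled,
                 pooled_kappa = cohen_kappa(pooled),
                 k = k, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold CV\n", x$k))
  cat(sprintf("  accuracy %.3f +/- %.3f, kappa (pooled) %.3f\n",
              x$mean_accuracy, x$sd_accuracy, x$pooled_kappa))
  invisible(x)
}

#' Per-channel accuracy table
#'
#' For each named channel the model is rebuilt with a single input channel
#' on that channel's epochs and cross-validated; the table rows are
#' channels plus a final mean row, columns are recordings (subjects or
#' sessions) plus a final mean column.
#'
#' @param recordings A single [eeg_recording()] or a named list of them.
#' @param channels Character channel names (default: all channels of the
#'   first recording).
#' @param model_factory Function of one argument (the single-channel
#'   [network_config()]-compatible input shape `c(1, T)`) returning a
#'   fresh model.
#' @param k Folds per channel evaluation (default 5).
#' @param seed Integer seed.
#' @param train_args List of arguments passed on to [train_model()].
#' @return Numeric matrix `[n_channels + 1, n_recordings + 1]` of
#'   accuracies, with `"mean"` row and column.
#' @export
per_channel_evaluation <- function(recordings, channels = NULL,
                                   model_factory, k = 5L, seed = 1L,
                                   train_args = list()) {
  if (inherits(recordings, "eeg_recording")) {
    recordings <- list(session1 = recordings)
  }
  if (is.null(channels)) channels <- recordings[[1]]$channel_names
  res <- matrix(NA_real_, length(channels), length(recordings),
                dimnames = list(channels, names(recordings)))
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    for (ci in seq_along(channels)) {
      sub <- select_channels(rec, channels[ci])
      shape <- c(1L, dim(sub$signals)[3])
      rep_ <- cross_validate(sub$signals, sub$labels,
                             model_factory = function() model_factory(shape),
                             k = k, seed = derive_seed(seed, ri * 101L + ci),
                             train_args = train_args)
      res[ci, ri] <- rep_$mean_accuracy
    }
  }
  res <- rbind(res, mean = colMeans(res))
  cbind(res, mean = rowMeans(res))
}

#' Region-averaged accuracy
#'
#' Unweighted mean of the member-channel accuracies of each named region.
#'
#' @param channel_table Numeric matrix or vector of per-channel accuracies
#'   with channel names (a `"mean"` column of [per_channel_evaluation()]
#'   output works directly).
#' @param regions Named list of channel groups (default
#'   [default_region_map()]).
#' @return Named numeric vector of region means.
#' @export
region_average <- function(channel_table, regions = default_region_map()) {
  if (is.matrix(channel_table)) {
    accs <- if ("mean" %in% colnames(channel_table))
      channel_table[, "mean"] else rowMeans(channel_table)
  } else {
    accs <- channel_table
  }
  vapply(names(regions), function(rn) {
    ch <- regions[[rn]]
    check_that(length(ch) > 0, sprintf("region %s is empty", rn),
               "contract_error")
    miss <- setdiff(ch, names(accs))
    if (length(miss) > 0) {
      clfc_error(sprintf("region %s references unknown channel(s): %s",
                         rn, paste(miss, collapse = ", ")), "lookup_error")
    }
    mean(accs[ch])
  }, numeric(1))
}
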