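# End-to-end pipeline: filter bank -> time-step segmentation -> CSP ->
# Hilbert envelopes -> EEG-CLFCNet, with fold-wise refitting of the
# supervised stages so cross-validation never leaks test labels.

#' Pipeline configuration
#'
#' Bundles the per-stage settings. `preprocessing$time_steps = NULL` (the
#' default) analyses one window spanning the whole epoch; supply a list of
#' `c(start, end)` second pairs (e.g. [default_time_steps()]) for the
#' multi-scale analysis of longer, cue-referenced epochs.
#'
#' @param simulation Named list of [simulation_config()] arguments.
#' @param preprocessing Named list: `bands` (list of Hz pairs),
#'   `filter_order`, `time_steps`, `m` (CSP filters per end), `scheme`
#'   (`"ovr"`/`"pairwise"`), `n_points` (envelope points), `cutoff`.
#' @param network Named list of [network_config()] arguments
#'   (`input_shape` is derived from the data).
#' @param training Named list: `epochs`, `batch_size`, `lr`, `folds`.
#' @param tuning Named list: `method` (`"cd"`/`"bo"`), `iterations`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(),
                            preprocessing = list(),
                            network = list(),
                            training = list(),
                            tuning = list()) {
  prep_defaults <- list(bands = default_filter_bands(), filter_order = 4L,
                        time_steps = NULL, m = 1L, scheme = "ovr",
                        n_points = 40L, cutoff = 4)
  train_defaults <- list(epochs = 15L, batch_size = 32L, lr = 3e-3,
                         folds = 10L)
  tune_defaults <- list(method = "bo", iterations = 20L)
  # shallow merge: a user-supplied field replaces the default wholesale
  # (modifyList would merge list-valued fields like `bands` elementwise)
  merge_opts <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  prep <- merge_opts(prep_defaults, preprocessing)
  train <- merge_opts(train_defaults, training)
  tune <- merge_opts(tune_defaults, tuning)
  check_that(train$folds >= 2L, "folds must be >= 2", "configuration_error")
  check_that(train$epochs >= 1L && train$batch_size >= 1L,
             "epochs and batch_size must be positive", "configuration_error")
  structure(list(simulation = simulation, preprocessing = prep,
                 network = network, training = train, tuning = tune),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any of the sections `simulation`,
#'   `preprocessing`, `network`, `training`, `tuning`.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         c("simulation", "preprocessing",
                                           "network", "training", "tuning"))])
}

# filter + segment once (label-free, so it can be shared across folds)
prepare_msfb <- function(recording, prep) {
  spec <- filter_bank_spec(bands = prep$bands,
                           filter_order = prep$filter_order)
  bank_f <- design_filter_bank(spec, recording$fs)
  bt <- apply_filter_bank(recording, bank_f)
  epoch_dur <- dim(recording$signals)[3] / recording$fs
  steps <- if (is.null(prep$time_steps)) {
    time_step_spec(list(c(0, epoch_dur)))
  } else {
    time_step_spec(prep$time_steps)
  }
  segment_time_steps(bt, steps, recording$fs)
}

# CSP + envelope features for network input
msfb_to_features <- function(msfb, bank, prep) {
  proj <- project_msfbcsp(msfb, bank)
  env <- envelope_pipeline(proj, n_points = prep$n_points,
                           cutoff = prep$cutoff)
  envelope_to_input(env)
}

#' Fit the preprocessing front end and extract network input features
#'
#' Fits the multi-scale filter-bank CSP model on the given labels and
#' returns the Hilbert-envelope feature array for the same recording.
#'
#' @param recording An [eeg_recording()].
#' @param config A [pipeline_config()].
#' @param fit_idx Optional indices of the trials used for CSP fitting
#'   (default: all trials).
#' @return List with the fitted `bank` and `features`
#'   `[trials, components, points]`.
#' @export
extract_features <- function(recording, config, fit_idx = NULL) {
  prep <- config$preprocessing
  msfb <- prepare_msfb(recording, prep)
  if (is.null(fit_idx)) fit_idx <- seq_len(msfb$n_trials)
  msfb_fit <- subset_msfb(msfb, fit_idx)
  bank <- fit_msfbcsp(msfb_fit, recording$labels[fit_idx],
                      m = prep$m, scheme = prep$scheme)
  list(bank = bank, features = msfb_to_features(msfb, bank, prep))
}

subset_msfb <- function(msfb, idx) {
  out <- msfb
  out$blocks <- lapply(msfb$blocks, function(per_band)
    lapply(per_band, function(blk) blk[idx, , , drop = FALSE]))
  out$n_trials <- length(idx)
  out
}

clfcnet_from_features <- function(features, config, n_classes, seed) {
  args <- config$network
  args$input_shape <- dim(features)[2:3]
  args$n_classes <- n_classes
  if (is.null(args$temporal_kernel)) {
    args$temporal_kernel <- min(9L, dim(features)[3])
  }
  if (is.null(args$pool1)) args$pool1 <- 2L
  if (is.null(args$pool2)) args$pool2 <- 2L
  if (is.null(args$input_mode)) args$input_mode <- "envelope"
  cfg <- do.call(network_config, args)
  assemble_eeg_clfcnet(cfg, seed = seed)
}

# Fold-wise CSP + envelope features, computed band-major so that the
# expensive label-independent work (per-trial covariances, analytic
# signals) is done once per block and only the projection, modulus and
# anti-aliased resampling are repeated per fold. Numerically equivalent to
# fit_msfbcsp + project_msfbcsp + envelope_pipeline on each training fold
# (the analytic transform and the spatial projection are both linear, so
# they commute).
cv_compute_features <- function(msfb, labels, folds, prep) {
  k <- max(folds)
  n <- msfb$n_trials
  c_dim <- msfb$n_channels
  classes <- sort(unique(labels))
  pairs <- contrast_pairs(classes, prep$scheme)
  n_comp <- length(pairs) * 2L * prep$m
  n_cols <- msfb$n_bands * msfb$n_steps * n_comp
  feats <- lapply(seq_len(k), function(f)
    array(0, c(n, n_cols, prep$n_points)))
  col0 <- 0L
  for (bi in seq_len(msfb$n_bands)) {
    for (ti in seq_len(msfb$n_steps)) {
      blk <- msfb$blocks[[bi]][[ti]]
      len <- dim(blk)[3]
      pt <- per_trial_covariances(blk)
      xm <- matrix(aperm(blk, c(3, 1, 2)), len)        # [len, n*C]
      pd <- good_fft_pad(len, max(4L, round(0.1 * len)))
      ana <- analytic_mat(reflect_pad(xm, pd$left, pd$right))
      ana <- ana[(pd$left + 1L):(pd$left + len), , drop = FALSE]
      # [C, n*len] layout for the spatial projection
      anam <- matrix(aperm(array(ana, c(len, n, c_dim)), c(3, 2, 1)), c_dim)
      avg_over <- function(idx) {
        r <- matrix(colMeans(pt[idx, , drop = FALSE]), c_dim, c_dim)
        (r + t(r)) / 2
      }
      for (f in seq_len(k)) {
        tr <- which(folds != f)
        covs <- lapply(classes, function(cl) avg_over(tr[labels[tr] == cl]))
        names(covs) <- as.character(classes)
        omega <- do.call(rbind, lapply(pairs, function(pr) {
          r_j <- if (identical(pr$j, "rest")) {
            avg_over(tr[labels[tr] != pr$i])
          } else {
            covs[[as.character(pr$j)]]
          }
          select_filters(
            solve_csp(covs[[as.character(pr$i)]], r_j, contrast = pr),
            prep$m)
        }))
        env <- Mod(omega %*% anam)                     # [comp, n*len]
        em <- matrix(aperm(array(env, c(n_comp, n, len)), c(3, 2, 1)), len)
        res <- lowpass_resample(em, msfb$fs, prep$n_points,
                                cutoff = prep$cutoff)
        feats[[f]][, col0 + seq_len(n_comp), ] <-
          aperm(array(res, c(prep$n_points, n, n_comp)), c(2, 3, 1))
      }
      col0 <- col0 + n_comp
    }
  }
  feats
}

#' Cross-validate the full pipeline on one recording
#'
#' Stratified k-fold cross-validation in which the CSP bank and the
#' network are refitted on each training fold; envelopes of held-out
#' trials are computed through the training fold's spatial filters.
#'
#' @param recording An [eeg_recording()].
#' @param config A [pipeline_config()].
#' @param k Folds (default from `config$training$folds`).
#' @param seed Integer seed.
#' @param shuffle_labels Permute the labels before the run (chance-level
#'   control)?
#' @return An `evaluation_report` (see [cross_validate()]).
#' @export
clfcnet_cv <- function(recording, config = pipeline_config(), k = NULL,
                       seed = 1L, shuffle_labels = FALSE) {
  prep <- config$preprocessing
  train_cfg <- config$training
  if (is.null(k)) k <- train_cfg$folds
  labels <- recording$labels
  if (shuffle_labels) {
    set.seed(derive_seed(seed, 999L))
    labels <- sample(labels)
  }
  n_cls <- length(unique(labels))
  msfb <- prepare_msfb(recording, prep)
  folds <- stratified_folds(labels, k, seed)
  fold_feats <- cv_compute_features(msfb, labels, folds, prep)
  acc <- numeric(k); kap <- numeric(k)
  pooled <- matrix(0L, n_cls, n_cls)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    feats <- fold_feats[[f]]
    model <- clfcnet_from_features(feats, config, n_cls,
                                   seed = derive_seed(seed, 10L + f))
    fit <- train_model(model, feats[tr, , , drop = FALSE], labels[tr],
                       epochs = train_cfg$epochs,
                       batch_size = train_cfg$batch_size,
                       lr = train_cfg$lr, seed = derive_seed(seed, 20L + f))
    pred <- predict(fit$model, feats[te, , , drop = FALSE], type = "class")
    cm <- confusion_matrix(labels[te], pred, n_cls)
    pooled <- pooled + cm
    acc[f] <- sum(diag(cm)) / sum(cm)
    kap[f] <- cohen_kappa(cm)
    clfc_log("debug", sprintf("fold %d/%d accuracy %.3f", f, k, acc[f]))
  }
  structure(list(fold_accuracy = acc, fold_kappa = kap,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 mean_kappa = mean(kap), pooled_confusion = pooled,
                 pooled_kappa = cohen_kappa(pooled), k = k, seed = seed),
            class = "evaluation_report")
}

#' Single train/test split of the full pipeline
#'
#' Stratified holdout evaluation: the CSP bank and network are fitted on
#' the training portion only.
#'
#' @param recording An [eeg_recording()].
#' @param config A [pipeline_config()].
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Integer seed.
#' @return List with `accuracy`, `kappa`, `confusion`, and the fitted
#'   `model`.
#' @export
clfcnet_holdout <- function(recording, config = pipeline_config(),
                            test_fraction = 0.2, seed = 1L) {
  labels <- recording$labels
  n_cls <- length(unique(labels))
  k <- max(2L, round(1 / test_fraction))
  folds <- stratified_folds(labels, k, seed)
  te <- which(folds == 1L)
  tr <- which(folds != 1L)
  prep <- config$preprocessing
  msfb <- prepare_msfb(recording, prep)
  bank <- fit_msfbcsp(subset_msfb(msfb, tr), labels[tr],
                      m = prep$m, scheme = prep$scheme)
  feats <- msfb_to_features(msfb, bank, prep)
  model <- clfcnet_from_features(feats, config, n_cls,
                                 seed = derive_seed(seed, 11L))
  fit <- train_model(model, feats[tr, , , drop = FALSE], labels[tr],
                     epochs = config$training$epochs,
                     batch_size = config$training$batch_size,
                     lr = config$training$lr, seed = derive_seed(seed, 21L))
  pred <- predict(fit$model, feats[te, , , drop = FALSE], type = "class")
  cm <- confusion_matrix(labels[te], pred, n_cls)
  list(accuracy = sum(diag(cm)) / sum(cm), kappa = cohen_kappa(cm),
       confusion = cm, model = fit$model, history = fit$history)
}
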