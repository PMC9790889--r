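# Model builders: the compact CNN classifier (temporal convolution ->
# depthwise spatial convolution -> separable convolution, all bias-free
# with batch-norm) and the full EEG-CLFCNet assembly (compact CNN feature
# extractor -> LSTM over the pre-flatten feature sequence -> parallel
# fully connected and fuzzy-neural-block heads -> softmax).

#' Network configuration
#'
#' @param input_shape `c(channels, time_samples)`.
#' @param n_classes Number of output classes (default 4).
#' @param F1 Temporal filter count (default 8).
#' @param temporal_kernel Temporal kernel length (default 64).
#' @param D Depth multiplier of the spatial convolution (default 2).
#' @param F2 Pointwise filter count (default 8).
#' @param separable_kernel Separable kernel length (default 16).
#' @param pool1,pool2 Average-pool widths (defaults 4 and 8). When the time
#'   axis is not divisible the remainder is truncated.
#' @param dropout Dropout rate in `[0, 1)` (default 0.5).
#' @param lstm_units LSTM hidden size (default 16).
#' @param fnb_rules Number of fuzzy rules K (default 8).
#' @param fnb_enabled Include the fuzzy neural block head? (default `TRUE`).
#' @param fc_units Width of the parallel fully connected branch (default 16).
#' @param candidate_activation LSTM candidate mode, `"tanh_standard"`
#'   (default) or `"linear"` (linear candidate, no output squashing).
#' @param head_merge `"concat"` (default) or `"sum"` (requires
#'   `fc_units == fnb_rules`).
#' @param input_mode Informational: `"raw"` epochs or `"envelope"` features.
#' @return Object of class `network_config`.
#' @export
network_config <- function(input_shape = c(22L, 288L), n_classes = 4L,
                           F1 = 8L, temporal_kernel = 64L, D = 2L, F2 = 8L,
                           separable_kernel = 16L, pool1 = 4L, pool2 = 8L,
                           dropout = 0.5, lstm_units = 16L, fnb_rules = 8L,
                           fnb_enabled = TRUE, fc_units = 16L,
                           candidate_activation = c("tanh_standard",
                                                    "linear"),
                           head_merge = c("concat", "sum"),
                           input_mode = c("raw", "envelope")) {
  candidate_activation <- match.arg(candidate_activation)
  head_merge <- match.arg(head_merge)
  input_mode <- match.arg(input_mode)
  check_that(length(input_shape) == 2L && all(input_shape >= 1L),
             "input_shape must be c(channels, samples)", "build_error")
  for (v in list(F1, D, F2, lstm_units, fnb_rules, fc_units, pool1, pool2,
                 temporal_kernel, separable_kernel, n_classes)) {
    check_that(is_count(v), "all size parameters must be positive counts",
               "build_error")
  }
  check_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)",
             "build_error")
  check_that(input_shape[2] >= temporal_kernel,
             "time axis shorter than the temporal kernel", "build_error")
  if (head_merge == "sum") {
    check_that(fc_units == fnb_rules,
               "head_merge = \"sum\" requires fc_units == fnb_rules",
               "build_error")
  }
  structure(list(input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), F1 = as.integer(F1),
                 temporal_kernel = as.integer(temporal_kernel),
                 D = as.integer(D), F2 = as.integer(F2),
                 separable_kernel = as.integer(separable_kernel),
                 pool1 = as.integer(pool1), pool2 = as.integer(pool2),
                 dropout = dropout, lstm_units = as.integer(lstm_units),
                 fnb_rules = as.integer(fnb_rules),
                 fnb_enabled = isTRUE(fnb_enabled),
                 fc_units = as.integer(fc_units),
                 candidate_activation = candidate_activation,
                 head_merge = head_merge, input_mode = input_mode),
            class = "network_config")
}

cnn_out_lengths <- function(config) {
  t1 <- config$input_shape[2] %/% config$pool1
  t2 <- t1 %/% config$pool2
  check_that(t2 >= 1L, "time axis too short after pooling", "build_error")
  c(t1 = t1, t2 = t2)
}

cnn_init_params <- function(config) {
  c_dim <- config$input_shape[1]
  kw <- config$temporal_kernel
  m1 <- config$F1 * config$D
  list(
    conv_temporal = glorot(config$F1, kw, c(config$F1, kw)),
    bn1_gamma = rep(1, config$F1), bn1_beta = rep(0, config$F1),
    conv_spatial = glorot(config$D, c_dim, c(config$F1, config$D, c_dim)),
    bn2_gamma = rep(1, m1), bn2_beta = rep(0, m1),
    sep_depth = glorot(m1, config$separable_kernel,
                       c(m1, config$separable_kernel)),
    sep_point = glorot(config$F2, m1, c(config$F2, m1)),
    bn3_gamma = rep(1, config$F2), bn3_beta = rep(0, config$F2)
  )
}

cnn_init_state <- function(config) {
  m1 <- config$F1 * config$D
  list(bn1 = list(mean = numeric(config$F1), var = rep(1, config$F1)),
       bn2 = list(mean = numeric(m1), var = rep(1, m1)),
       bn3 = list(mean = numeric(config$F2), var = rep(1, config$F2)))
}

#' Build the compact CNN classifier
#'
#' Layer sequence: temporal convolution (`F1` kernels `1 x kw`, same
#' padding, no bias) -> batch-norm -> depthwise spatial convolution
#' (kernel `C x 1`, depth `D`, no padding, no bias) -> batch-norm -> ELU ->
#' average-pool -> dropout -> separable convolution (`F2`, kernel `1 x ks`,
#' no bias) -> batch-norm -> ELU -> average-pool -> dropout -> flatten ->
#' dense softmax.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for deterministic initialization.
#' @return Object of classes `compact_cnn`, `clfc_model`.
#' @export
build_compact_cnn <- function(config, seed = NULL) {
  check_that(inherits(config, "network_config"), "need a network_config")
  if (!is.null(seed)) set.seed(seed)
  lens <- cnn_out_lengths(config)
  flat <- config$F2 * lens["t2"]
  params <- cnn_init_params(config)
  params$dense_w <- glorot(config$n_classes, flat,
                           c(config$n_classes, flat))
  params$dense_b <- numeric(config$n_classes)
  structure(list(type = "compact_cnn", config = config, params = params,
                 state = cnn_init_state(config)),
            class = c("compact_cnn", "clfc_model"))
}

#' Assemble the full EEG-CLFCNet model
#'
#' The compact CNN's pre-flatten feature map (`F2` maps over the pooled
#' time axis) is treated as a feature sequence and fed to an LSTM; the
#' last hidden state drives a fully connected branch and, when enabled,
#' the fuzzy neural block, whose outputs are merged and classified by a
#' dense softmax layer. FNB centroids start at zero and are refreshed
#' between training epochs by fuzzy c-means; the scaling vector `alpha`
#' is trained by backpropagation.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for deterministic initialization.
#' @return Object of classes `eeg_clfcnet`, `clfc_model`.
#' @export
assemble_eeg_clfcnet <- function(config, seed = NULL) {
  check_that(inherits(config, "network_config"), "need a network_config")
  if (!is.null(seed)) set.seed(seed)
  h <- config$lstm_units
  params <- cnn_init_params(config)
  params$lstm_w <- glorot(4L * h, config$F2, c(4L * h, config$F2))
  params$lstm_u <- glorot(4L * h, h, c(4L * h, h))
  params$lstm_b <- numeric(4L * h)
  params$fc_w <- glorot(config$fc_units, h, c(config$fc_units, h))
  params$fc_b <- numeric(config$fc_units)
  head_in <- if (!config$fnb_enabled) {
    config$fc_units
  } else if (config$head_merge == "concat") {
    config$fc_units + config$fnb_rules
  } else {
    config$fc_units
  }
  if (config$fnb_enabled) params$fnb_alpha <- rep(1, h)
  params$head_w <- glorot(config$n_classes, head_in,
                          c(config$n_classes, head_in))
  params$head_b <- numeric(config$n_classes)
  state <- cnn_init_state(config)
  state$fnb_centroids <- matrix(0, config$fnb_rules, h)
  structure(list(type = "eeg_clfcnet", config = config, params = params,
                 state = state),
            class = c("eeg_clfcnet", "clfc_model"))
}

#' Per-layer output shapes of the compact CNN
#'
#' Reproduces the architecture table for a given configuration: one row per
#' layer with its output shape (maps x height x time) and trainable
#' parameter count.
#'
#' @param config A [network_config()].
#' @return `data.frame` with columns `layer`, `output` and `n_params`.
#' @export
compact_cnn_shapes <- function(config) {
  c_dim <- config$input_shape[1]; t_dim <- config$input_shape[2]
  lens <- cnn_out_lengths(config)
  m1 <- config$F1 * config$D
  flat <- config$F2 * lens["t2"]
  data.frame(
    layer = c("reshape", "conv_temporal", "batchnorm1", "conv_depthwise",
              "batchnorm2", "activation1", "avgpool1", "dropout1",
              "conv_separable", "batchnorm3", "activation2", "avgpool2",
              "dropout2", "flatten", "dense"),
    output = c(sprintf("1x%dx%d", c_dim, t_dim),
               sprintf("%dx%dx%d", config$F1, c_dim, t_dim),
               sprintf("%dx%dx%d", config$F1, c_dim, t_dim),
               sprintf("%dx1x%d", m1, t_dim),
               sprintf("%dx1x%d", m1, t_dim),
               sprintf("%dx1x%d", m1, t_dim),
               sprintf("%dx1x%d", m1, lens["t1"]),
               sprintf("%dx1x%d", m1, lens["t1"]),
               sprintf("%dx1x%d", config$F2, lens["t1"]),
               sprintf("%dx1x%d", config$F2, lens["t1"]),
               sprintf("%dx1x%d", config$F2, lens["t1"]),
               sprintf("%dx1x%d", config$F2, lens["t2"]),
               sprintf("%dx1x%d", config$F2, lens["t2"]),
               sprintf("%d", flat),
               sprintf("%d", config$n_classes)),
    n_params = c(0L,
                 config$F1 * config$temporal_kernel,
                 2L * config$F1,
                 c_dim * config$F1 * config$D,
                 2L * m1,
                 0L, 0L, 0L,
                 m1 * config$separable_kernel + m1 * config$F2,
                 2L * config$F2,
                 0L, 0L, 0L, 0L,
                 (flat + 1L) * config$n_classes),
    stringsAsFactors = FALSE)
}

#' Count trainable parameters
#'
#' @param model A built model ([build_compact_cnn()] or
#'   [assemble_eeg_clfcnet()]).
#' @return List with a per-parameter-group `data.frame` (`counts`) and the
#'   `total`. FNB centroids are excluded: they are updated by clustering,
#'   not by gradient descent.
#' @export
count_trainable_parameters <- function(model) {
  check_that(inherits(model, "clfc_model"), "need a built model")
  counts <- data.frame(
    group = names(model$params),
    n_params = vapply(model$params, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, total = sum(counts$n_params))
}

# shared CNN trunk; input [N, C, T], output the F2-map feature sequence
# [F2, N, T2] plus caches for backward
cnn_trunk_fwd <- function(model, x, training) {
  p <- model$params; cfg <- model$config
  st <- model$state
  cache <- list(x = x)
  ct <- conv_temporal_fwd(x, p$conv_temporal)        # [F1, N, C, T]
  cache$xcol <- ct$xcol
  bn1 <- bn_fwd(ct$y, p$bn1_gamma, p$bn1_beta, st$bn1, training)
  st$bn1 <- bn1$running
  cache$bn1 <- bn1$cache
  y2 <- conv_spatial_fwd(bn1$y, p$conv_spatial)      # [M, N, T]
  cache$bn1_out <- bn1$y
  bn2 <- bn_fwd(y2, p$bn2_gamma, p$bn2_beta, st$bn2, training)
  st$bn2 <- bn2$running
  cache$bn2 <- bn2$cache
  a1 <- elu_fwd(bn2$y)
  cache$a1 <- a1
  p1 <- pool_fwd(a1, cfg$pool1)
  cache$t_a1 <- dim(a1)[3]
  d1 <- dropout_fwd(p1, cfg$dropout, training)
  cache$drop1 <- d1$mask
  y3 <- conv_sepdepth_fwd(d1$y, p$sep_depth)
  cache$d1_out <- d1$y
  y4 <- conv_pointwise_fwd(y3, p$sep_point)          # [F2, N, T1]
  cache$y3 <- y3
  bn3 <- bn_fwd(y4, p$bn3_gamma, p$bn3_beta, st$bn3, training)
  st$bn3 <- bn3$running
  cache$bn3 <- bn3$cache
  a2 <- elu_fwd(bn3$y)
  cache$a2 <- a2
  p2 <- pool_fwd(a2, cfg$pool2)                      # [F2, N, T2]
  cache$t_a2 <- dim(a2)[3]
  d2 <- dropout_fwd(p2, cfg$dropout, training)
  cache$drop2 <- d2$mask
  list(seq = d2$y, cache = cache, state = st)
}

cnn_trunk_bwd <- function(model, dseq, cache) {
  p <- model$params; cfg <- model$config
  g <- list()
  dy <- dseq
  if (!is.null(cache$drop2)) dy <- dy * cache$drop2
  dy <- pool_bwd(dy, cfg$pool2, cache$t_a2)
  dy <- elu_bwd(cache$a2, dy)
  bn3 <- bn_bwd(dy, cache$bn3)
  g$bn3_gamma <- bn3$dgamma; g$bn3_beta <- bn3$dbeta
  pw <- conv_pointwise_bwd(cache$y3, p$sep_point, bn3$dx)
  g$sep_point <- pw$dwsp
  sd <- conv_sepdepth_bwd(cache$d1_out, p$sep_depth, pw$dx)
  g$sep_depth <- sd$dwsd
  dy <- sd$dx
  if (!is.null(cache$drop1)) dy <- dy * cache$drop1
  dy <- pool_bwd(dy, cfg$pool1, cache$t_a1)
  dy <- elu_bwd(cache$a1, dy)
  bn2 <- bn_bwd(dy, cache$bn2)
  g$bn2_gamma <- bn2$dgamma; g$bn2_beta <- bn2$dbeta
  sp <- conv_spatial_bwd(cache$bn1_out, p$conv_spatial, bn2$dx)
  g$conv_spatial <- sp$dwd
  bn1 <- bn_bwd(sp$dx, cache$bn1)
  g$bn1_gamma <- bn1$dgamma; g$bn1_beta <- bn1$dbeta
  ct <- conv_temporal_bwd(cache$x, p$conv_temporal, bn1$dx, cache$xcol)
  g$conv_temporal <- ct$dk
  g
}

# full forward pass; returns class probabilities and caches for backward
model_fwd <- function(model, x, training = FALSE) {
  cfg <- model$config
  check_that(length(dim(x)) == 3L && dim(x)[2] == cfg$input_shape[1] &&
               dim(x)[3] == cfg$input_shape[2],
             sprintf("input must be [N x %d x %d]",
                     cfg$input_shape[1], cfg$input_shape[2]),
             "contract_error")
  trunk <- cnn_trunk_fwd(model, x, training)
  p <- model$params
  if (model$type == "compact_cnn") {
    d2 <- dim(trunk$seq)                 # [F2, N, T2]
    # flatten per trial in (filter, time) order: [F2*T2, N]
    flat <- matrix(aperm(trunk$seq, c(1, 3, 2)), d2[1] * d2[3])
    logits <- t(dense_fwd(flat, p$dense_w, p$dense_b))
    probs <- softmax_rows(logits)
    return(list(probs = probs,
                cache = list(trunk = trunk$cache, flat = flat),
                state = trunk$state))
  }
  lstm <- lstm_seq_fwd(trunk$seq, p$lstm_w, p$lstm_u, p$lstm_b,
                       cfg$candidate_activation)
  h_last <- lstm$h                       # [H, N]
  zfc_pre <- p$fc_w %*% h_last + p$fc_b
  zfc <- elu_fwd(zfc_pre)
  if (cfg$fnb_enabled) {
    fnb <- fnb_batch_fwd(h_last, model$state$fnb_centroids, p$fnb_alpha)
    zh <- if (cfg$head_merge == "concat") rbind(zfc, fnb$o) else zfc + fnb$o
  } else {
    fnb <- NULL
    zh <- zfc
  }
  logits <- t(p$head_w %*% zh + p$head_b)
  probs <- softmax_rows(logits)
  list(probs = probs,
       cache = list(trunk = trunk$cache, lstm = lstm$cache,
                    h_last = h_last, zfc = zfc, fnb = fnb, zh = zh),
       state = trunk$state)
}

model_bwd <- function(model, x, y, fwd) {
  cfg <- model$config; p <- model$params
  dlogits <- softmax_ce_bwd(fwd$probs, y)   # [N, K]
  g <- list()
  if (model$type == "compact_cnn") {
    dn <- dense_bwd(fwd$cache$flat, p$dense_w, t(dlogits))
    g$dense_w <- dn$dw; g$dense_b <- dn$db
    n <- dim(x)[1]
    t2 <- nrow(fwd$cache$flat) / cfg$F2
    # undo the (filter, time) flatten back to [F2, N, T2]
    dseq <- aperm(array(dn$dz, c(cfg$F2, t2, n)), c(1, 3, 2))
    g <- c(g, cnn_trunk_bwd(model, dseq, fwd$cache$trunk))
    return(g)
  }
  dlog_t <- t(dlogits)                     # [K, N]
  g$head_w <- tcrossprod(dlog_t, fwd$cache$zh)
  g$head_b <- rowSums(dlog_t)
  dzh <- crossprod(p$head_w, dlog_t)       # [head_in, N]
  if (cfg$fnb_enabled) {
    if (cfg$head_merge == "concat") {
      dzfc <- dzh[seq_len(cfg$fc_units), , drop = FALSE]
      dfnb <- dzh[cfg$fc_units + seq_len(cfg$fnb_rules), , drop = FALSE]
    } else {
      dzfc <- dzh; dfnb <- dzh
    }
    fb <- fnb_batch_bwd(dfnb, fwd$cache$fnb$cache)
    g$fnb_alpha <- fb$dalpha
    g$fnb_centroids <- fb$dcentroids       # reported, never applied by Adam
    dh_fnb <- fb$dv
  } else {
    dzfc <- dzh
    dh_fnb <- 0
  }
  dzfc_pre <- elu_bwd(fwd$cache$zfc, dzfc)
  g$fc_w <- tcrossprod(dzfc_pre, fwd$cache$h_last)
  g$fc_b <- rowSums(dzfc_pre)
  dh <- crossprod(p$fc_w, dzfc_pre) + dh_fnb
  lb <- lstm_seq_bwd(dh, p$lstm_w, p$lstm_u, fwd$cache$lstm)
  g$lstm_w <- lb$dw; g$lstm_u <- lb$du; g$lstm_b <- lb$db
  g <- c(g, cnn_trunk_bwd(model, lb$ds, fwd$cache$trunk))
  g
}

#' Forward prediction
#'
#' Inference-mode forward pass (dropout disabled, batch-norm running
#' statistics): two passes on the same input are identical.
#'
#' @param object A fitted or freshly built model.
#' @param x Input array `[N, channels, samples]`.
#' @param type `"prob"` for class probabilities, `"class"` for 0-based
#'   class labels.
#' @param ... Unused.
#' @return `[N x K]` probability matrix or integer label vector.
#' @export
predict.clfc_model <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  out <- model_fwd(object, x, training = FALSE)
  if (type == "prob") out$probs else max.col(out$probs) - 1L
}

#' Cross-entropy loss of a model on a batch
#'
#' @param model A built model.
#' @param x Input array `[N, channels, samples]`.
#' @param y 0-based integer labels.
#' @return Scalar mean cross-entropy (inference mode).
#' @export
model_loss <- function(model, x, y) {
  fwd <- model_fwd(model, x, training = FALSE)
  cross_entropy(fwd$probs, as.integer(y))
}

#' Analytic gradients of the loss on a batch
#'
#' Inference-mode (deterministic) gradients of the mean cross-entropy with
#' respect to every trainable parameter, plus `fnb_centroids` (which are
#' clustering-updated during training but differentiable, so their gradient
#' is exposed for finite-difference verification).
#'
#' @param model A built model.
#' @param x Input array `[N, channels, samples]`.
#' @param y 0-based integer labels.
#' @return Named list of gradient arrays.
#' @export
model_gradients <- function(model, x, y) {
  fwd <- model_fwd(model, x, training = FALSE)
  model_bwd(model, x, as.integer(y), fwd)
}
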