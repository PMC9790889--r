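test_that("the reference architecture reproduces its shape table", {
  cfg <- network_config(input_shape = c(22, 288))
  sh <- compact_cnn_shapes(cfg)
  expect_equal(sh$n_params[sh$layer == "conv_temporal"], 512L)
  expect_equal(sh$n_params[sh$layer == "batchnorm1"], 16L)
  expect_equal(sh$n_params[sh$layer == "conv_depthwise"], 352L)
  expect_equal(sh$n_params[sh$layer == "batchnorm2"], 32L)
  expect_equal(sh$n_params[sh$layer == "conv_separable"], 384L)
  expect_equal(sh$n_params[sh$layer == "batchnorm3"], 16L)
  expect_equal(sh$output[sh$layer == "conv_temporal"], "8x22x288")
  expect_equal(sh$output[sh$layer == "conv_depthwise"], "16x1x288")
  expect_equal(sh$output[sh$layer == "avgpool1"], "16x1x72")
  expect_equal(sh$output[sh$layer == "avgpool2"], "8x1x9")
  expect_equal(sh$output[sh$layer == "flatten"], "72")
  expect_equal(sh$n_params[sh$layer == "dense"], (72L + 1L) * 4L)
})

test_that("parameter counts follow the closed forms", {
  m <- build_compact_cnn(network_config(input_shape = c(22, 288)), seed = 1)
  ct <- count_trainable_parameters(m)
  get <- function(g) ct$counts$n_params[ct$counts$group == g]
  expect_equal(get("conv_temporal"), 512L)       # F1 * kernel
  expect_equal(get("conv_spatial"), 352L)        # C * F1 * D
  expect_equal(get("sep_depth") + get("sep_point"), 384L)
  expect_equal(get("dense_w") + get("dense_b"), 292L)
  # F1 = 4 halves the temporal kernel bank
  m4 <- build_compact_cnn(network_config(input_shape = c(22, 288), F1 = 4),
                          seed = 1)
  ct4 <- count_trainable_parameters(m4)
  expect_equal(ct4$counts$n_params[ct4$counts$group == "conv_temporal"],
               4L * 64L)
})

test_that("single-electrode and non-divisible time axes build and run", {
  cfg1 <- network_config(input_shape = c(1, 288))
  m1 <- build_compact_cnn(cfg1, seed = 2)
  p <- predict(m1, array(rnorm(3 * 288), c(3, 1, 288)))
  expect_equal(dim(p), c(3L, 4L))
  # remainder samples are truncated by the pools
  cfg2 <- network_config(input_shape = c(4, 41), temporal_kernel = 8,
                         pool1 = 2, pool2 = 2)
  m2 <- build_compact_cnn(cfg2, seed = 2)
  p2 <- predict(m2, array(rnorm(2 * 4 * 41), c(2, 4, 41)))
  expect_equal(dim(p2), c(2L, 4L))
  expect_error(network_config(input_shape = c(4, 16), temporal_kernel = 64),
               class = "build_error")
  expect_error(network_config(dropout = 1), class = "build_error")
})

test_that("softmax outputs form a simplex and inference is deterministic", {
  cfg <- network_config(input_shape = c(6, 64), temporal_kernel = 16,
                        pool1 = 2, pool2 = 2)
  m <- assemble_eeg_clfcnet(cfg, seed = 3)
  x <- array(rnorm(5 * 6 * 64, sd = 3), c(5, 6, 64))
  p1 <- predict(m, x)
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p1 >= 0))
  expect_identical(p1, predict(m, x))   # dropout off at inference
})

test_that("disabling the fuzzy block changes only the head", {
  cfg_on <- network_config(input_shape = c(6, 64), temporal_kernel = 16,
                           pool1 = 2, pool2 = 2, fnb_enabled = TRUE)
  cfg_off <- network_config(input_shape = c(6, 64), temporal_kernel = 16,
                            pool1 = 2, pool2 = 2, fnb_enabled = FALSE)
  on <- count_trainable_parameters(assemble_eeg_clfcnet(cfg_on, seed = 1))
  off <- count_trainable_parameters(assemble_eeg_clfcnet(cfg_off, seed = 1))
  trunk <- c("conv_temporal", "bn1_gamma", "bn1_beta", "conv_spatial",
             "bn2_gamma", "bn2_beta", "sep_depth", "sep_point",
             "bn3_gamma", "bn3_beta", "lstm_w", "lstm_u", "lstm_b",
             "fc_w", "fc_b")
  for (g in trunk) {
    expect_equal(on$counts$n_params[on$counts$group == g],
                 off$counts$n_params[off$counts$group == g])
  }
  expect_gt(on$counts$n_params[on$counts$group == "head_w"],
            off$counts$n_params[off$counts$group == "head_w"])
})

test_that("the LSTM cell reproduces its closed-form zero-parameter cases", {
  p <- lstm_params(2, 1, init = "zero")
  # all gates sigmoid(0) = 0.5; zero candidate
  st <- lstm_step(c(0.3, -0.2), list(h = 0, c = 0), p)
  expect_equal(as.numeric(st$h), 0)
  expect_equal(as.numeric(st$c), 0)
  # literal linear recursions: c = 0.5 * c_prev, h = o * c = 0.25
  st2 <- lstm_step(c(1, 1), list(h = 0, c = 1), p, mode = "linear")
  expect_equal(as.numeric(st2$c), 0.5)
  expect_equal(as.numeric(st2$h), 0.25)
  expect_true(all(st2$i > 0 & st2$i < 1))
  expect_error(lstm_step(c(NaN, 1), list(h = 0, c = 0), p),
               class = "contract_error")
})

test_that("the LSTM cell matches a naive reference over random steps", {
  for (mode in c("tanh_standard", "linear")) {
    set.seed(21)
    p <- lstm_params(3, 4)
    h <- rep(0, 4); c_st <- rep(0, 4)
    href <- h; cref <- c_st
    for (t in 1:20) {
      x <- rnorm(3)
      st <- lstm_step(x, list(h = h, c = c_st), p, mode = mode)
      ref <- lstm_reference_step(x, href, cref, p, mode)
      expect_lt(max(abs(as.numeric(st$h) - ref$h)), 1e-6)
      expect_lt(max(abs(as.numeric(st$c) - ref$c)), 1e-6)
      h <- as.numeric(st$h); c_st <- as.numeric(st$c)
      href <- ref$h; cref <- ref$c
    }
  }
})

test_that("the batched sequence pass agrees with stepwise application", {
  set.seed(22)
  h_dim <- 4; d_in <- 3; l <- 6; n <- 5
  w <- matrix(rnorm(4 * h_dim * d_in, sd = 0.3), 4 * h_dim)
  u <- matrix(rnorm(4 * h_dim * h_dim, sd = 0.3), 4 * h_dim)
  b <- rnorm(4 * h_dim, sd = 0.1)
  s <- array(rnorm(d_in * n * l), c(d_in, n, l))
  out <- eegclfcnet:::lstm_seq_fwd(s, w, u, b, "tanh_standard")
  # stepwise with per-gate parameter views
  idx <- function(g) ((g - 1) * h_dim + 1):(g * h_dim)
  p <- list(W_i = w[idx(1), ], W_f = w[idx(2), ], W_o = w[idx(3), ],
            W_c = w[idx(4), ], U_i = u[idx(1), ], U_f = u[idx(2), ],
            U_o = u[idx(3), ], U_c = u[idx(4), ], b_i = b[idx(1)],
            b_f = b[idx(2)], b_o = b[idx(3)], b_c = b[idx(4)])
  h <- matrix(0, h_dim, n); c_st <- matrix(0, h_dim, n)
  for (t in 1:l) {
    st <- lstm_step(s[, , t], list(h = h, c = c_st), p)
    h <- st$h; c_st <- st$c
  }
  expect_equal(out$h, h, tolerance = 1e-12)
})

test_that("fuzzy memberships follow the Gaussian rule", {
  expect_equal(fnb_membership(1.5, 1.5, 2), 1)
  expect_equal(fnb_membership(2, 0, 1), exp(-1))
  expect_equal(fnb_membership(0, 0.1, 1e6), 1, tolerance = 1e-9)
  expect_error(fnb_membership(1, 0, -1), class = "contract_error")
})

test_that("fnb activations normalize, symmetrize and permute", {
  st <- list(centroids = matrix(c(0, 2), 2, 1), alpha = 1)
  o <- fnb_forward(0, st)
  expect_equal(o, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-9)
  # identical centroids -> uniform
  st_u <- list(centroids = matrix(1, 5, 3), alpha = rep(2, 3))
  expect_equal(fnb_forward(rnorm(3), st_u), rep(0.2, 5))
  # normalization and permutation equivariance on random cases
  set.seed(31)
  for (i in 1:10) {
    ct <- matrix(rnorm(4 * 6), 4, 6)
    al <- runif(6, 0.5, 2)
    v <- rnorm(6)
    o <- fnb_forward(v, list(centroids = ct, alpha = al))
    expect_equal(sum(o), 1, tolerance = 1e-9)
    pm <- sample(4)
    o_p <- fnb_forward(v, list(centroids = ct[pm, ], alpha = al))
    expect_equal(o_p, o[pm], tolerance = 1e-12)
  }
  # underflow-prone high dimension still normalizes
  d <- 500
  o_big <- fnb_forward(rep(10, d),
                       list(centroids = matrix(0, 3, d), alpha = rep(0.5, d)))
  expect_equal(sum(o_big), 1, tolerance = 1e-9)
})

test_that("centroid refresh follows the epoch schedule", {
  expect_equal(update_fnb_centroids(NULL, 4, epoch_index = 0),
               matrix(0, 4, 0))
  hist0 <- matrix(rnorm(20), 10, 2)
  expect_equal(update_fnb_centroids(hist0, 3, 0), matrix(0, 3, 2))
  expect_error(update_fnb_centroids(matrix(0, 0, 2), 2, 1),
               class = "update_error")
  # K = 1: the membership-weighted mean is the global mean
  expect_equal(update_fnb_centroids(hist0, 1, 1),
               matrix(colMeans(hist0), 1, 2))
  # two well-separated clouds
  set.seed(41)
  cloud <- rbind(matrix(rnorm(60, mean = 0, sd = 0.05), 30, 2),
                 matrix(rnorm(60, mean = 5, sd = 0.05), 30, 2))
  ct <- update_fnb_centroids(cloud, 2, epoch_index = 1, seed = 2)
  ct <- ct[order(ct[, 1]), ]
  expect_lt(max(abs(ct[1, ] - colMeans(cloud[1:30, ]))), 0.1)
  expect_lt(max(abs(ct[2, ] - colMeans(cloud[31:60, ]))), 0.1)
})

test_that("analytic gradients match finite differences", {
  set.seed(51)
  cfg <- network_config(input_shape = c(4, 48), n_classes = 3, F1 = 3,
                        temporal_kernel = 8, D = 2, F2 = 4,
                        separable_kernel = 5, pool1 = 2, pool2 = 2,
                        dropout = 0, lstm_units = 5, fnb_rules = 3,
                        fc_units = 4)
  m <- assemble_eeg_clfcnet(cfg, seed = 7)
  m$state$fnb_centroids <- matrix(rnorm(15, sd = 0.3), 3, 5)
  x <- array(rnorm(3 * 4 * 48), c(3, 4, 48))
  y <- c(0L, 1L, 2L)
  g <- model_gradients(m, x, y)
  rel_err <- function(name, in_state = FALSE, n_checks = 4) {
    v <- if (in_state) m$state[[name]] else m$params[[name]]
    idx <- sample(seq_along(v), min(n_checks, length(v)))
    max(vapply(idx, function(i) {
      eps <- 1e-5
      m1 <- m; m2 <- m
      if (in_state) {
        m1$state[[name]][i] <- v[i] + eps
        m2$state[[name]][i] <- v[i] - eps
      } else {
        m1$params[[name]][i] <- v[i] + eps
        m2$params[[name]][i] <- v[i] - eps
      }
      gn <- (model_loss(m1, x, y) - model_loss(m2, x, y)) / (2 * eps)
      abs(gn - g[[name]][i]) / max(abs(gn), abs(g[[name]][i]), 1e-8)
    }, numeric(1)))
  }
  # the fuzzy block's learnable scale and its clustering-set centroids
  expect_lt(rel_err("fnb_alpha"), 1e-4)
  expect_lt(rel_err("fnb_centroids", in_state = TRUE), 1e-4)
  # representative weights from every stage
  for (nm in c("conv_temporal", "conv_spatial", "sep_depth", "lstm_w",
               "lstm_u", "fc_w", "head_w", "bn2_gamma")) {
    expect_lt(rel_err(nm), 1e-4)
  }
})
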