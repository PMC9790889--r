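test_that("stratified folds partition exhaustively and evenly", {
  labels <- rep(0:3, each = 72)
  folds <- stratified_folds(labels, 10, seed = 3)
  expect_setequal(unique(folds), 1:10)
  sizes <- as.integer(table(folds))
  expect_true(all(sizes %in% c(28L, 29L)))
  expect_equal(sum(sizes), 288L)
  # per-class proportions within one trial across folds
  for (cl in 0:3) {
    per_fold <- table(factor(folds[labels == cl], levels = 1:10))
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_error(stratified_folds(rep(0:1, each = 3), 4, 1),
               class = "fold_error")
})

test_that("kappa reproduces closed forms and the balanced identity", {
  expect_equal(cohen_kappa(diag(10)), 1)
  # constant prediction on balanced truth: observed = expected = 1/K
  cm_const <- matrix(0, 4, 4); cm_const[, 1] <- 25
  expect_equal(cohen_kappa(cm_const), 0)
  # balanced identity, brute-force expected agreement as the oracle
  brute_kappa <- function(cm) {
    n <- sum(cm)
    p_o <- sum(diag(cm)) / n
    p_e <- 0
    for (i in seq_len(nrow(cm))) {
      p_e <- p_e + (sum(cm[i, ]) / n) * (sum(cm[, i]) / n)
    }
    (p_o - p_e) / (1 - p_e)
  }
  set.seed(7)
  for (k in c(2, 4)) {
    for (r in 1:5) {
      cm <- matrix(rpois(k * k, 10), k)
      expect_equal(cohen_kappa(cm), brute_kappa(cm), tolerance = 1e-12)
    }
    # balanced marginals: kappa = (acc - 1/K) / (1 - 1/K)
    acc_target <- 0.7
    n_per <- 100
    cm <- matrix((1 - acc_target) * n_per / (k - 1), k, k)
    diag(cm) <- acc_target * n_per
    expect_equal(cohen_kappa(cm),
                 (acc_target - 1 / k) / (1 - 1 / k), tolerance = 1e-12)
  }
  expect_warning(k0 <- cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "degenerate")
  expect_equal(k0, 0)
})

test_that("training learns separable features and is seed-deterministic", {
  fx <- separable_features(n_per_class = 10, seed = 2)
  cfg <- tiny_net_config(6, 24, dropout = 0.25)
  fit <- train_model(assemble_eeg_clfcnet(cfg, seed = 5), fx$x, fx$y,
                     epochs = 30, batch_size = 16, lr = 1e-2, seed = 5)
  pred <- predict(fit$model, fx$x, type = "class")
  expect_gte(mean(pred == fx$y), 0.9)
  # smoothed loss trend decreases
  sm <- stats::filter(fit$history$loss, rep(1 / 5, 5))
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  # bit-identical refit under the same seed
  fit2 <- train_model(assemble_eeg_clfcnet(cfg, seed = 5), fx$x, fx$y,
                      epochs = 30, batch_size = 16, lr = 1e-2, seed = 5)
  expect_identical(fit$model$params, fit2$model$params)
  expect_identical(fit$model$state$fnb_centroids,
                   fit2$model$state$fnb_centroids)
})

test_that("cross-validation tests every trial exactly once", {
  fx <- separable_features(n_per_class = 8, seed = 3)
  cfg <- tiny_net_config(6, 24)
  rep_ <- cross_validate(fx$x, fx$y, function() build_compact_cnn(cfg, 1),
                         k = 4, seed = 11,
                         train_args = list(epochs = 10, batch_size = 16))
  expect_length(rep_$fold_accuracy, 4)
  expect_equal(sum(rep_$pooled_confusion), length(fx$y))
  expect_gte(rep_$mean_accuracy, 0.75)   # separable by construction
  expect_true(all(rep_$fold_kappa >= -1 & rep_$fold_kappa <= 1))
})

test_that("shuffled labels drop held-out accuracy to chance", {
  fx <- separable_features(n_per_class = 12, seed = 4)
  set.seed(99)
  y_shuf <- sample(fx$y)
  cfg <- tiny_net_config(6, 24)
  rep_ <- cross_validate(fx$x, y_shuf, function() build_compact_cnn(cfg, 1),
                         k = 4, seed = 12,
                         train_args = list(epochs = 8, batch_size = 16))
  expect_lt(rep_$mean_accuracy, 0.5)
  expect_gt(rep_$mean_accuracy, 0.05)
})

test_that("per-channel evaluation ranks informative over noise channels", {
  # channel 1 carries a strong class-dependent pattern; channel 2 is noise
  set.seed(13)
  n_per <- 10; t_dim <- 32
  n <- 4 * n_per
  x <- array(rnorm(n * 2 * t_dim, sd = 0.4), c(n, 2, t_dim))
  y <- rep(0:3, each = n_per)
  for (i in seq_len(n)) {
    x[i, 1, ] <- x[i, 1, ] + 3 * sin(2 * pi * (y[i] + 1) * (1:t_dim) / t_dim)
  }
  rec <- eeg_recording(x, y, fs = 32, channel_names = c("sig", "noise"))
  factory <- function(shape) {
    build_compact_cnn(network_config(
      input_shape = shape, F1 = 4, temporal_kernel = 8, D = 2, F2 = 4,
      separable_kernel = 5, pool1 = 2, pool2 = 2, dropout = 0), seed = 3)
  }
  tab <- per_channel_evaluation(rec, model_factory = factory, k = 2,
                                seed = 5,
                                train_args = list(epochs = 12,
                                                  batch_size = 20))
  expect_equal(dim(tab), c(3L, 2L))    # 2 channels + mean row, 1 col + mean
  expect_gt(tab["sig", "mean"], tab["noise", "mean"])
  expect_equal(tab["mean", 1], mean(tab[1:2, 1]))
})

test_that("region averages are unweighted channel means", {
  accs <- c(Fz = 0.8, FC3 = 0.9, C3 = 0.7, Cz = 0.75)
  regions <- list(front = c("Fz", "FC3"), central = c("C3", "Cz"))
  out <- region_average(accs, regions)
  expect_equal(unname(out["front"]), 0.85)
  expect_equal(unname(out["central"]), 0.725)
  # all-equal table: every region at the common value
  accs2 <- stats::setNames(rep(0.6, 22), mi22_channels())
  expect_equal(unname(region_average(accs2)), rep(0.6, 3))
  # independent mean oracle on a random table
  set.seed(17)
  accs3 <- stats::setNames(runif(22), mi22_channels())
  rm_ <- default_region_map()
  expect_equal(unname(region_average(accs3)["parietal"]),
               sum(accs3[rm_$parietal]) / length(rm_$parietal))
  expect_error(region_average(accs, list(bad = character(0))),
               class = "contract_error")
  expect_error(region_average(accs, list(bad = "Oz")),
               class = "lookup_error")
})

test_that("label checks and divergence are reported as errors", {
  fx <- separable_features(n_per_class = 4, seed = 6)
  cfg <- tiny_net_config(6, 24)
  m <- build_compact_cnn(cfg, seed = 1)
  expect_error(train_model(m, fx$x, rep(0L, dim(fx$x)[1]), epochs = 1),
               class = "contract_error")
  expect_error(train_model(m, fx$x, fx$y[-1], epochs = 1))
})
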