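test_that("normalized covariance follows its closed forms", {
  r <- normalized_covariance(diag(2))
  expect_equal(unclass(r), diag(2) / 2, ignore_attr = TRUE)
  expect_equal(sum(diag(r)), 1)
  r2 <- normalized_covariance(rbind(c(1, 1), c(0, 0)))
  expect_equal(unclass(r2), rbind(c(1, 0), c(0, 0)), ignore_attr = TRUE)
  # averaging N copies changes nothing
  x <- matrix(rnorm(12), 3)
  one <- normalized_covariance(x)
  five <- normalized_covariance(array(rep(x, each = 5),
                                      c(5, 3, 4))[, , , drop = FALSE])
  expect_equal(unclass(five), unclass(one), ignore_attr = TRUE)
  expect_error(normalized_covariance(matrix(0, 2, 4)),
               class = "degenerate_trial_error")
})

test_that("normalized covariance invariants hold on random trials", {
  set.seed(10)
  for (rep in 1:5) {
    trials <- array(rnorm(8 * 5 * 50), c(8, 5, 50))
    r <- normalized_covariance(trials)
    expect_lt(max(abs(r - t(r))), 1e-10)
    expect_equal(sum(diag(r)), 1, tolerance = 1e-8)
    expect_gte(min(eigen(r, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("solve_csp handles the symmetric and diagonal closed forms", {
  s <- solve_csp(0.5 * diag(3), 0.5 * diag(3), shrinkage = 0)
  expect_equal(s$eigenvalues, rep(0.5, 3))
  s2 <- solve_csp(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)), shrinkage = 0)
  expect_equal(s2$eigenvalues, c(0.8, 0.2))
  # filters along coordinate axes (up to scale; sign fixed positive)
  expect_equal(abs(s2$W) > 1e-8, rbind(c(TRUE, FALSE), c(FALSE, TRUE)))
})

test_that("solve_csp matches a brute-force generalized eigensolver", {
  worst <- 0
  for (k in 1:100) {
    pair <- random_spd_pair(6, seed = k)
    sol <- solve_csp(pair$a, pair$b, shrinkage = 0)
    ref <- csp_bruteforce(pair$a, pair$b)
    worst <- max(worst, max(abs(sol$eigenvalues - ref$values)))
    for (r in 1:6) {
      d <- min(max(abs(sol$W[r, ] - ref$W[r, ])),
               max(abs(sol$W[r, ] + ref$W[r, ])))
      worst <- max(worst, d)
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("eigenvalues are complementary and satisfy the Rayleigh identity", {
  for (k in 1:20) {
    pair <- random_spd_pair(5, seed = 200 + k)
    s_ij <- solve_csp(pair$a, pair$b, shrinkage = 0)
    s_ji <- solve_csp(pair$b, pair$a, shrinkage = 0)
    expect_equal(s_ij$eigenvalues + rev(s_ji$eigenvalues), rep(1, 5),
                 tolerance = 1e-8)
    # w' R_i w / w' R_j w = lambda / (1 - lambda)
    for (r in 1:5) {
      w <- s_ij$W[r, ]
      lhs <- as.numeric((w %*% pair$a %*% w) / (w %*% pair$b %*% w))
      lam <- s_ij$eigenvalues[r]
      expect_equal(lhs, lam / (1 - lam), tolerance = 1e-6)
    }
    # simultaneous diagonalization and composite identity
    d1 <- s_ij$W %*% pair$a %*% t(s_ij$W)
    d2 <- s_ij$W %*% pair$b %*% t(s_ij$W)
    expect_lt(max(abs(d1 - diag(diag(d1)))), 1e-8)
    expect_lt(max(abs(d2 - diag(diag(d2)))), 1e-8)
    expect_equal(d1 + d2, diag(5), tolerance = 1e-8)
  }
})

test_that("filter selection takes both spectral ends", {
  pair <- random_spd_pair(22, seed = 7)
  sol <- solve_csp(pair$a, pair$b)
  f1 <- select_filters(sol, 1)
  expect_equal(f1, sol$W[c(1, 22), ])
  expect_equal(dim(select_filters(sol, 2)), c(4L, 22L))
  expect_error(select_filters(sol, 12), class = "selection_error")
})

test_that("projection is the plain linear map", {
  x <- matrix(rnorm(4 * 30), 4)
  id_rows <- diag(4)[c(2, 3), ]
  expect_equal(csp_project(x, id_rows), x[c(2, 3), ])
  w <- matrix(rnorm(8), 2, 4)
  expect_equal(csp_project(3 * x, w), 3 * csp_project(x, w))
  expect_error(csp_project(x, matrix(0, 2, 5)), class = "contract_error")
})

test_that("msfbcsp fit produces the configured filter counts", {
  rec <- generate_session(simulation_config(
    trials_per_class = 4, n_channels = 22, include_fixation = TRUE,
    seed = 6))
  bank_f <- design_filter_bank(filter_bank_spec(), 250)
  msfb <- segment_time_steps(apply_filter_bank(rec, bank_f),
                             time_step_spec(), 250)
  bank <- fit_msfbcsp(msfb, rec$labels, m = 2, scheme = "ovr")
  expect_equal(bank$n_bands, 9)
  expect_equal(bank$n_steps, 7)
  expect_length(bank$contrasts, 4)
  n_filters <- sum(vapply(unlist(unlist(bank$filters, recursive = FALSE),
                                 recursive = FALSE), nrow, integer(1)))
  expect_equal(n_filters, 9 * 7 * 4 * 4)     # 1008
  # pairwise two-class case: one contrast per block
  rec2 <- small_session(seed = 6, tpc = 4, nch = 5)
  keep <- rec2$labels < 2L
  msfb2 <- segment_time_steps(
    apply_filter_bank(rec2$signals[keep, , , drop = FALSE],
                      design_filter_bank(filter_bank_spec(list(c(8, 12))), 250)),
    time_step_spec(list(c(0, 4))), 250)
  bank2 <- fit_msfbcsp(msfb2, rec2$labels[keep], m = 1, scheme = "pairwise")
  expect_length(bank2$contrasts, 1)
  expect_error(fit_msfbcsp(msfb2, rep(0L, sum(keep))),
               class = "fitting_error")
})

test_that("csp recovers the generating spatial direction", {
  rec <- generate_session(simulation_config(snr_db = 6, seed = 1))
  mix <- attr(rec, "mixing_matrix")
  bank_f <- design_filter_bank(filter_bank_spec(list(c(8, 12))), 250)
  msfb <- segment_time_steps(apply_filter_bank(rec, bank_f),
                             time_step_spec(list(c(0, 4))), 250)
  bank <- fit_msfbcsp(msfb, rec$labels, m = 1)
  w <- bank$filters[[1]][[1]][[1]][1, ]
  expect_gte(cosine_abs(w, mix[, 1]), 0.95)
  # projecting concentrates the class-variance contrast beyond any raw channel
  blk <- msfb$blocks[[1]][[1]]
  ratio <- function(series) {
    v <- apply(series, 1, stats::var)
    mean(v[rec$labels == 0L]) / mean(v[rec$labels != 0L])
  }
  proj <- t(vapply(seq_len(dim(blk)[1]),
                   function(i) as.numeric(w %*% matrix(blk[i, , ], 22)),
                   numeric(dim(blk)[3])))
  best_raw <- max(vapply(1:22, function(ch) ratio(blk[, ch, ]), numeric(1)))
  expect_gt(ratio(proj), best_raw)
})

test_that("filters are invariant to common global scaling", {
  rec <- small_session(seed = 8, tpc = 6, nch = 5)
  bank_f <- design_filter_bank(filter_bank_spec(list(c(8, 12))), 250)
  msfb1 <- segment_time_steps(apply_filter_bank(rec$signals, bank_f),
                              time_step_spec(list(c(0, 4))), 250)
  msfb2 <- segment_time_steps(apply_filter_bank(rec$signals * 7.5, bank_f),
                              time_step_spec(list(c(0, 4))), 250)
  b1 <- fit_msfbcsp(msfb1, rec$labels, m = 1)
  b2 <- fit_msfbcsp(msfb2, rec$labels, m = 1)
  expect_equal(b1$filters[[1]][[1]][[1]], b2$filters[[1]][[1]][[1]],
               tolerance = 1e-5)
})

test_that("variance features have the configured shape and scaling", {
  rec <- small_session(seed = 9, tpc = 3, nch = 5)
  bank_f <- design_filter_bank(filter_bank_spec(list(c(8, 12), c(20, 24))),
                               250)
  msfb <- segment_time_steps(apply_filter_bank(rec, bank_f),
                             time_step_spec(list(c(0, 2), c(2, 4))), 250)
  bank <- fit_msfbcsp(msfb, rec$labels, m = 1)
  feats <- transform_msfbcsp(msfb, bank)
  expect_equal(dim(feats), c(12L, 2L, 2L, 4L, 2L))
  expect_true(all(feats >= 0))
  # quadratic form: doubling amplitude multiplies variance by 4
  msfb2 <- msfb
  msfb2$blocks <- lapply(msfb$blocks, function(pb) lapply(pb, function(b) 2 * b))
  expect_equal(transform_msfbcsp(msfb2, bank), 4 * feats, tolerance = 1e-10)
  # zero input gives zero features through a pre-fitted bank
  msfb0 <- msfb
  msfb0$blocks <- lapply(msfb$blocks, function(pb) lapply(pb, function(b) b * 0))
  expect_true(all(transform_msfbcsp(msfb0, bank) == 0))
  # log-normalized variant is finite and ordered consistently
  lf <- transform_msfbcsp(msfb, bank, feature = "log_normalized_variance")
  expect_true(all(is.finite(lf)))
  expect_true(all(lf <= 0))
})
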