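# Common spatial patterns and the multi-scale filter-bank extension.
#
# CSP filters w maximize the class variance ratio w' R_i w / w' R_j w and
# are obtained from the generalized eigenproblem R_i W = (R_i + R_j) W D:
# the composite covariance is whitened through its (condition-capped)
# eigendecomposition, followed by an ordinary symmetric eigenproblem.

#' Averaged trace-normalized class covariance
#'
#' Mean over trials of `(x x') / tr(x x')`: each trial contributes a unit
#' trace, so the average is symmetric, positive semidefinite and has unit
#' trace regardless of per-trial amplitude.
#'
#' @param trials Array `[n_trials, n_channels, n_samples]` (a single
#'   `[channels x samples]` matrix is treated as one trial).
#' @return Symmetric `[n_channels x n_channels]` matrix with attributes
#'   `n_trials`.
#' @export
normalized_covariance <- function(trials) {
  if (is.matrix(trials)) {
    trials <- array(trials, c(1L, nrow(trials), ncol(trials)))
  }
  d <- dim(trials)
  check_that(length(d) == 3L && d[1] >= 1L,
             "trials must be [n x channels x samples]")
  if (d[3] < d[2]) {
    clfc_log("warn", sprintf(
      "covariance from %d samples for %d channels is rank-deficient",
      d[3], d[2]))
  }
  acc <- matrix(0, d[2], d[2])
  for (i in seq_len(d[1])) {
    x <- matrix(trials[i, , ], nrow = d[2])
    p <- tcrossprod(x)
    tr <- sum(diag(p))
    if (tr <= 0) {
      clfc_error(sprintf("trial %d has zero total power", i),
                 "degenerate_trial_error")
    }
    acc <- acc + p / tr
  }
  r <- acc / d[1]
  r <- (r + t(r)) / 2
  attr(r, "n_trials") <- d[1]
  r
}

# flattened per-trial normalized covariances: [n_trials, C*C]
per_trial_covariances <- function(trials) {
  d <- dim(trials)
  out <- matrix(0, d[1], d[2] * d[2])
  for (i in seq_len(d[1])) {
    x <- matrix(trials[i, , ], nrow = d[2])
    p <- tcrossprod(x)
    tr <- sum(diag(p))
    if (tr <= 0) {
      clfc_error(sprintf("trial %d has zero total power", i),
                 "degenerate_trial_error")
    }
    out[i, ] <- p / tr
  }
  out
}

shrink_cov <- function(r, gamma) {
  c_dim <- nrow(r)
  (1 - gamma) * r + gamma * (sum(diag(r)) / c_dim) * diag(c_dim)
}

#' Solve the two-class CSP generalized eigenproblem
#'
#' Solves `R_i W = (R_i + R_j) W D` with rows of `W` scaled so that
#' `W (R_i + R_j) W' = I`. Eigenvalues lie in `[0, 1]`, sorted descending;
#' each filter `w` satisfies `(w' R_i w) / (w' R_j w) = lambda / (1 - lambda)`.
#' The largest-magnitude coefficient of each filter is made positive so
#' outputs are deterministic.
#'
#' Narrowband covariances are often nearly rank-deficient: whitening by the
#' composite then amplifies estimation noise in the near-empty directions
#' enormously, polluting the extreme filters. The whitening therefore caps
#' the composite's condition: eigenvalues below `cond_tol` times the
#' largest are floored before inversion. For well-conditioned inputs the
#' floor is inactive and the solution is the exact generalized
#' eigendecomposition.
#'
#' @param r_i,r_j Symmetric PSD class covariance matrices.
#' @param shrinkage Shrinkage weight toward the scaled identity applied to
#'   each matrix before decomposition (default `1e-6`).
#' @param cond_tol Relative eigenvalue floor of the composite whitening
#'   (default 0.05, a 20:1 condition cap); 0 disables it.
#' @param contrast Optional label describing the class contrast.
#' @return Object of class `csp_solution` with elements `W` (rows are
#'   filters), `eigenvalues`, and `contrast`.
#' @export
solve_csp <- function(r_i, r_j, shrinkage = 1e-6, cond_tol = 0.05,
                      contrast = NULL) {
  check_that(is.matrix(r_i) && is.matrix(r_j) &&
               all(dim(r_i) == dim(r_j)) && nrow(r_i) == ncol(r_i),
             "covariances must be square matrices of equal size")
  r_i <- shrink_cov((r_i + t(r_i)) / 2, shrinkage)
  r_j <- shrink_cov((r_j + t(r_j)) / 2, shrinkage)
  comp <- r_i + r_j
  ec <- eigen(comp, symmetric = TRUE)
  if (ec$values[1] <= 0 || ec$values[length(ec$values)] <= -1e-10 * ec$values[1]) {
    clfc_error("composite covariance is not positive definite",
               "numerical_error")
  }
  floor_val <- cond_tol * ec$values[1]
  n_floored <- sum(ec$values < floor_val)
  if (n_floored > 0) {
    clfc_log("debug", sprintf(
      "whitening floored %d composite eigendirections below %.2g",
      n_floored, floor_val))
  }
  vals <- pmax(ec$values, floor_val)
  p <- ec$vectors %*% diag(1 / sqrt(vals), length(vals))
  m <- t(p) %*% r_i %*% p
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)      # values already descending
  w <- t(p %*% es$vectors)              # rows are filters
  # deterministic sign: largest-|coefficient| positive per filter
  for (r in seq_len(nrow(w))) {
    j <- which.max(abs(w[r, ]))
    if (w[r, j] < 0) w[r, ] <- -w[r, ]
  }
  structure(list(W = w, eigenvalues = pmin(pmax(es$values, 0), 1),
                 contrast = contrast),
            class = "csp_solution")
}

#' Select the discriminative filters from both ends of the spectrum
#'
#' @param solution A [solve_csp()] result (eigenvalues descending).
#' @param m Filters per end.
#' @return `[2m x n_channels]` matrix: rows `1..m` are the top-eigenvalue
#'   filters, rows `m+1..2m` the bottom.
#' @export
select_filters <- function(solution, m) {
  check_that(inherits(solution, "csp_solution"), "need a csp_solution")
  n <- nrow(solution$W)
  if (2L * m > n) {
    clfc_error(sprintf("cannot select 2*%d filters from %d channels", m, n),
               "selection_error")
  }
  rbind(solution$W[seq_len(m), , drop = FALSE],
        solution$W[(n - m + 1L):n, , drop = FALSE])
}

#' Project a trial into the CSP subspace
#'
#' @param trial `[n_channels x n_samples]` matrix.
#' @param filters `[n_filters x n_channels]` filter block.
#' @return `[n_filters x n_samples]` spatially filtered signal.
#' @export
csp_project <- function(trial, filters) {
  check_that(is.matrix(trial) && is.matrix(filters) &&
               ncol(filters) == nrow(trial),
             sprintf("filter width %d does not match %d channels",
                     ncol(filters), nrow(trial)), "contract_error")
  filters %*% trial
}

contrast_pairs <- function(classes, scheme) {
  if (scheme == "ovr") {
    lapply(classes, function(k) list(i = k, j = "rest"))
  } else {
    out <- list()
    for (a in seq_along(classes)) {
      for (b in seq_along(classes)) {
        if (b > a) out[[length(out) + 1L]] <- list(i = classes[a], j = classes[b])
      }
    }
    out
  }
}

#' Fit the multi-scale filter-bank CSP model
#'
#' One CSP solution per (band, step, class contrast); from each, the `m`
#' largest- and `m` smallest-eigenvalue filters are kept.
#'
#' @param msfb An [segment_time_steps()] result (`msfb_tensor`).
#' @param labels Integer class labels (0-based), one per trial.
#' @param m Filters per end (default 2).
#' @param scheme `"ovr"` (one-vs-rest, default) or `"pairwise"`.
#' @param shrinkage Covariance shrinkage passed to [solve_csp()].
#' @param cond_tol Whitening condition cap passed to [solve_csp()].
#' @return Object of class `csp_filter_bank`.
#' @export
fit_msfbcsp <- function(msfb, labels, m = 2L, scheme = c("ovr", "pairwise"),
                        shrinkage = 1e-6, cond_tol = 0.05) {
  scheme <- match.arg(scheme)
  check_that(inherits(msfb, "msfb_tensor"), "msfb must be an msfb_tensor")
  labels <- as.integer(labels)
  check_that(length(labels) == msfb$n_trials, "one label per trial")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    clfc_error("need at least 2 classes to fit CSP", "fitting_error")
  }
  pairs <- contrast_pairs(classes, scheme)
  filters <- vector("list", msfb$n_bands)
  eigvals <- vector("list", msfb$n_bands)
  for (bi in seq_len(msfb$n_bands)) {
    filters[[bi]] <- vector("list", msfb$n_steps)
    eigvals[[bi]] <- vector("list", msfb$n_steps)
    for (ti in seq_len(msfb$n_steps)) {
      blk <- msfb$blocks[[bi]][[ti]]
      # per-trial trace-normalized covariances computed once, then averaged
      # over whichever trial subsets the contrasts need
      pt <- per_trial_covariances(blk)
      avg_over <- function(idx) {
        r <- matrix(colMeans(pt[idx, , drop = FALSE]),
                    msfb$n_channels, msfb$n_channels)
        (r + t(r)) / 2
      }
      covs <- lapply(classes, function(k) {
        idx <- which(labels == k)
        if (length(idx) == 0L) {
          clfc_error(sprintf("class %d absent from labels", k),
                     "fitting_error")
        }
        avg_over(idx)
      })
      names(covs) <- as.character(classes)
      fl <- vector("list", length(pairs))
      ev <- vector("list", length(pairs))
      for (pi in seq_along(pairs)) {
        pr <- pairs[[pi]]
        r_i <- covs[[as.character(pr$i)]]
        r_j <- if (identical(pr$j, "rest")) {
          avg_over(which(labels != pr$i))
        } else {
          covs[[as.character(pr$j)]]
        }
        sol <- solve_csp(r_i, r_j, shrinkage = shrinkage,
                         cond_tol = cond_tol, contrast = pr)
        fl[[pi]] <- select_filters(sol, m)
        ev[[pi]] <- sol$eigenvalues
      }
      filters[[bi]][[ti]] <- fl
      eigvals[[bi]][[ti]] <- ev
    }
  }
  structure(list(filters = filters, eigenvalues = eigvals,
                 m = as.integer(m), scheme = scheme,
                 contrasts = pairs, classes = classes,
                 n_bands = msfb$n_bands, n_steps = msfb$n_steps,
                 n_channels = msfb$n_channels,
                 bands = msfb$bands, intervals = msfb$intervals),
            class = "csp_filter_bank")
}

#' Project every block of an msfb tensor through a fitted CSP bank
#'
#' @param msfb An `msfb_tensor` shape-compatible with `bank`.
#' @param bank A [fit_msfbcsp()] result.
#' @return List of per-(band, step) arrays
#'   `[trials, n_contrasts * 2m, samples]` with metadata, class
#'   `msfb_projected`.
#' @export
project_msfbcsp <- function(msfb, bank) {
  check_msfb_compat(msfb, bank)
  n_comp <- length(bank$contrasts) * 2L * bank$m
  blocks <- vector("list", msfb$n_bands)
  for (bi in seq_len(msfb$n_bands)) {
    blocks[[bi]] <- vector("list", msfb$n_steps)
    for (ti in seq_len(msfb$n_steps)) {
      blk <- msfb$blocks[[bi]][[ti]]
      omega <- do.call(rbind, bank$filters[[bi]][[ti]])
      len <- dim(blk)[3]
      m <- matrix(aperm(blk, c(2, 1, 3)), msfb$n_channels)
      y <- omega %*% m                       # [comp, trials*len]
      blocks[[bi]][[ti]] <-
        aperm(array(y, c(n_comp, msfb$n_trials, len)), c(2, 1, 3))
    }
  }
  structure(list(blocks = blocks, n_bands = msfb$n_bands,
                 n_steps = msfb$n_steps, n_trials = msfb$n_trials,
                 n_components = n_comp, fs = msfb$fs,
                 bands = msfb$bands, intervals = msfb$intervals),
            class = "msfb_projected")
}

check_msfb_compat <- function(msfb, bank) {
  check_that(inherits(bank, "csp_filter_bank"), "bank must be a csp_filter_bank")
  if (msfb$n_bands != bank$n_bands || msfb$n_steps != bank$n_steps ||
      msfb$n_channels != bank$n_channels) {
    clfc_error(sprintf(
      "tensor (%d bands, %d steps, %d channels) does not match bank (%d, %d, %d)",
      msfb$n_bands, msfb$n_steps, msfb$n_channels,
      bank$n_bands, bank$n_steps, bank$n_channels), "contract_error")
  }
  invisible(TRUE)
}

#' Variance features in the CSP subspace
#'
#' Variance across time of each projected component within each
#' (band, step) window -- the conventional band-power feature. Optionally
#' the log of the within-block normalized variance.
#'
#' @param msfb An `msfb_tensor` compatible with `bank`.
#' @param bank A [fit_msfbcsp()] result.
#' @param feature `"variance"` (default) or `"log_normalized_variance"`.
#' @return Array `[n_trials, n_bands, n_steps, n_contrasts, 2m]`.
#' @export
transform_msfbcsp <- function(msfb, bank,
                              feature = c("variance",
                                          "log_normalized_variance")) {
  feature <- match.arg(feature)
  proj <- project_msfbcsp(msfb, bank)
  n_con <- length(bank$contrasts)
  two_m <- 2L * bank$m
  out <- array(0, c(msfb$n_trials, msfb$n_bands, msfb$n_steps, n_con, two_m))
  for (bi in seq_len(msfb$n_bands)) {
    for (ti in seq_len(msfb$n_steps)) {
      blk <- proj$blocks[[bi]][[ti]]
      len <- dim(blk)[3]
      v <- apply(blk, c(1, 2), function(z) sum((z - mean(z))^2)) /
        max(len - 1L, 1L)
      for (ci in seq_len(n_con)) {
        cols <- ((ci - 1L) * two_m + 1L):(ci * two_m)
        vv <- v[, cols, drop = FALSE]
        if (feature == "log_normalized_variance") {
          vv <- log(sweep(vv, 1, rowSums(vv), "/") + 1e-300)
        }
        out[, bi, ti, ci, ] <- vv
      }
    }
  }
  out
}
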