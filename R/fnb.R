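# Fuzzy neural block: Gaussian rule memberships of a flattened activation
# vector to K centroids, combined by a product t-norm and normalized to a
# probability simplex. Products are computed in the log domain (sum of log
# memberships, log-sum-exp normalization) so large input dimensions cannot
# underflow to a 0/0 division.

#' Gaussian rule membership
#'
#' Elementwise membership `mu_j = exp(-(v_j - c_j)^2 / (4 alpha_j^2))`:
#' 1 at the centroid, `exp(-1)` at distance `2 alpha_j`.
#'
#' @param v Input vector.
#' @param centroid Rule centroid, same length as `v`.
#' @param alpha Positive scaling vector (scalar recycled).
#' @return Membership vector in `(0, 1]`.
#' @export
fnb_membership <- function(v, centroid, alpha) {
  check_that(all(alpha > 0), "alpha must be strictly positive",
             "contract_error")
  exp(-0.25 * (v - centroid)^2 / alpha^2)
}

#' Forward pass of the fuzzy neural block
#'
#' Combines the per-dimension memberships of `v` to each rule centroid with
#' a product t-norm and normalizes across rules, yielding activations that
#' sum to one.
#'
#' @param v Flattened input vector `[d]`.
#' @param state List with `centroids` `[K x d]` and `alpha` `[d]` (> 0).
#' @return Normalized rule activations, length `K`, summing to 1.
#' @export
fnb_forward <- function(v, state) {
  check_that(all(state$alpha > 0), "alpha must be strictly positive",
             "contract_error")
  ct <- state$centroids
  check_that(ncol(ct) == length(v),
             sprintf("centroid dimension %d != input dimension %d",
                     ncol(ct), length(v)), "contract_error")
  log_o <- vapply(seq_len(nrow(ct)), function(k) {
    sum(-0.25 * (v - ct[k, ])^2 / state$alpha^2)
  }, numeric(1))
  log_o <- log_o - max(log_o)
  e <- exp(log_o)
  e / sum(e)
}

# batched forward: v [d x N] -> activations [K x N]; cache for backward
fnb_batch_fwd <- function(v, centroids, alpha) {
  k <- nrow(centroids); n <- ncol(v); d <- nrow(v)
  a2 <- alpha^2
  log_o <- matrix(0, k, n)
  diffs <- vector("list", k)
  for (kk in seq_len(k)) {
    df <- v - centroids[kk, ]
    diffs[[kk]] <- df
    log_o[kk, ] <- colSums(-0.25 * df^2 / a2)
  }
  m <- apply(log_o, 2, max)
  e <- exp(sweep(log_o, 2, m))
  o <- sweep(e, 2, colSums(e), "/")
  list(o = o, cache = list(diffs = diffs, o = o, alpha = alpha,
                           k = k, n = n, d = d))
}

fnb_batch_bwd <- function(do_act, cache) {
  o <- cache$o; alpha <- cache$alpha
  a2 <- alpha^2; a3 <- alpha^3
  # softmax backward per column
  dlog <- o * sweep(do_act, 2, colSums(do_act * o))
  dv <- matrix(0, cache$d, cache$n)
  dalpha <- numeric(cache$d)
  dcent <- matrix(0, cache$k, cache$d)
  for (kk in seq_len(cache$k)) {
    df <- cache$diffs[[kk]]
    wk <- dlog[kk, ]
    dv <- dv + sweep(df, 2, wk, "*") * (-0.5 / a2)
    dalpha <- dalpha + rowSums(sweep(df^2, 2, wk, "*")) * (0.5 / a3)
    dcent[kk, ] <- rowSums(sweep(df, 2, wk, "*")) * (0.5 / a2)
  }
  list(dv = dv, dalpha = dalpha, dcentroids = dcent)
}

#' Refresh fuzzy-rule centroids from the previous epoch's activations
#'
#' Centroids start at zero for the first training epoch; afterwards they
#' are the fuzzy c-means centroids (fuzzifier `m = 2`) of the history of
#' flattened layer outputs collected during the preceding epoch.
#'
#' @param history Matrix `[n x d]` of flattened outputs from the preceding
#'   epoch (ignored when `epoch_index = 0`).
#' @param k Number of rules.
#' @param epoch_index 0 for the initial period, >= 1 afterwards.
#' @param seed Integer seed controlling the c-means initialization.
#' @return `[k x d]` centroid matrix.
#' @export
update_fnb_centroids <- function(history, k, epoch_index, seed = 1L) {
  check_that(is_count(k), "k must be a positive count")
  if (epoch_index == 0L) {
    d <- if (is.matrix(history)) ncol(history) else length(history)
    return(matrix(0, k, d))
  }
  if (is.null(history) || NROW(history) == 0L) {
    clfc_error("empty activation history after the initial epoch",
               "update_error")
  }
  history <- as.matrix(history)
  if (k == 1L) {
    # c-means with one cluster: all memberships are 1, centroid = mean
    return(matrix(colMeans(history), 1L, ncol(history)))
  }
  if (nrow(history) <= k) {
    idx <- rep_len(seq_len(nrow(history)), k)
    return(history[idx, , drop = FALSE])
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  cm <- e1071::cmeans(history, centers = k, m = 2, iter.max = 100L)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  unname(cm$centers)
}
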