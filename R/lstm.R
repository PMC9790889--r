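# LSTM cell and sequence pass (batched, with BPTT).
#
# Gates follow the classical formulation: i, f, o are sigmoids of affine
# maps of (x_t, h_{t-1}); the candidate uses tanh in "tanh_standard" mode.
# "linear" mode drops both nonlinearities: a linear candidate and
# h_t = o * c_t (no output squashing).

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM parameter set
#'
#' Per-gate input weights `W_g`, recurrent weights `U_g` and biases `b_g`
#' for gates `i`, `f`, `o` and candidate `c`.
#'
#' @param d_in Input dimension.
#' @param hidden Hidden size `H`.
#' @param init `"zero"` or `"glorot"`.
#' @return Named list of twelve arrays (class `lstm_params`).
#' @export
lstm_params <- function(d_in, hidden, init = c("glorot", "zero")) {
  init <- match.arg(init)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else
      matrix(glorot(nr, nc, c(nr, nc)), nr, nc)
  }
  p <- list()
  for (g in c("i", "f", "o", "c")) {
    p[[paste0("W_", g)]] <- mk(hidden, d_in)
    p[[paste0("U_", g)]] <- mk(hidden, hidden)
    p[[paste0("b_", g)]] <- numeric(hidden)
  }
  structure(p, class = "lstm_params", hidden = hidden, d_in = d_in)
}

#' One LSTM step
#'
#' Computes the gate activations and the next `(h, c)` state for a single
#' input vector (or a matrix whose columns are batch elements).
#'
#' @param x_t Input vector `[d]` or matrix `[d x N]`.
#' @param state List with `h` and `c` (vectors `[H]` or matrices `[H x N]`).
#' @param params An [lstm_params()] set.
#' @param mode `"tanh_standard"` (default) or `"linear"`.
#' @return List with `h`, `c` and the gate activations `i`, `f`, `o`.
#' @export
lstm_step <- function(x_t, state, params,
                      mode = c("tanh_standard", "linear")) {
  mode <- match.arg(mode)
  x_t <- as.matrix(x_t)
  h <- as.matrix(state$h); c_prev <- as.matrix(state$c)
  check_that(all(is.finite(x_t)) && all(is.finite(h)) && all(is.finite(c_prev)),
             "non-finite values in LSTM step input", "contract_error")
  i <- sigmoid(params$W_i %*% x_t + params$U_i %*% h + params$b_i)
  f <- sigmoid(params$W_f %*% x_t + params$U_f %*% h + params$b_f)
  o <- sigmoid(params$W_o %*% x_t + params$U_o %*% h + params$b_o)
  a_c <- params$W_c %*% x_t + params$U_c %*% h + params$b_c
  g <- if (mode == "tanh_standard") tanh(a_c) else a_c
  c_t <- f * c_prev + i * g
  h_t <- if (mode == "tanh_standard") o * tanh(c_t) else o * c_t
  list(h = h_t, c = c_t, i = i, f = f, o = o)
}

# fast batched sequence pass over S [d, N, L]; stacked gate order i,f,o,c
lstm_seq_fwd <- function(s, w, u, b, mode) {
  d <- dim(s); n <- d[2]; l <- d[3]
  h_dim <- ncol(u)
  h <- matrix(0, h_dim, n); c_st <- matrix(0, h_dim, n)
  steps <- vector("list", l)
  idx <- function(g) ((g - 1L) * h_dim + 1L):(g * h_dim)
  for (t in seq_len(l)) {
    xt <- matrix(s[, , t], d[1])                      # [d, N]
    a <- w %*% xt + u %*% h + b
    i <- sigmoid(a[idx(1), , drop = FALSE])
    f <- sigmoid(a[idx(2), , drop = FALSE])
    o <- sigmoid(a[idx(3), , drop = FALSE])
    ac <- a[idx(4), , drop = FALSE]
    g <- if (mode == "tanh_standard") tanh(ac) else ac
    c_new <- f * c_st + i * g
    tc <- if (mode == "tanh_standard") tanh(c_new) else c_new
    h_new <- o * tc
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = c_st,
                       i = i, f = f, o = o, g = g, c = c_new, tc = tc)
    h <- h_new; c_st <- c_new
  }
  list(h = h, cache = list(steps = steps, mode = mode,
                           h_dim = h_dim, n = n, l = l, d_in = d[1]))
}

lstm_seq_bwd <- function(dh_last, w, u, cache) {
  h_dim <- cache$h_dim; n <- cache$n; l <- cache$l
  mode <- cache$mode
  dw <- matrix(0, nrow(w), ncol(w))
  du <- matrix(0, nrow(u), ncol(u))
  db <- numeric(nrow(w))
  ds <- array(0, c(cache$d_in, n, l))
  dh <- dh_last
  dc <- matrix(0, h_dim, n)
  for (t in rev(seq_len(l))) {
    st <- cache$steps[[t]]
    if (mode == "tanh_standard") {
      do_g <- dh * st$tc
      dc <- dc + dh * st$o * (1 - st$tc^2)
    } else {
      do_g <- dh * st$c
      dc <- dc + dh * st$o
    }
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_prev <- dc * st$f
    da <- rbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_g * st$o * (1 - st$o),
                if (mode == "tanh_standard") dg * (1 - st$g^2) else dg)
    dw <- dw + tcrossprod(da, st$xt)
    du <- du + tcrossprod(da, st$h_prev)
    db <- db + rowSums(da)
    ds[, , t] <- crossprod(w, da)
    dh <- crossprod(u, da)
    dc <- dc_prev
  }
  list(dw = dw, du = du, db = db, ds = ds)
}
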