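# shared fixtures: small sessions, oracles, reference implementations

cosine_abs <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

small_session <- function(seed = 1, tpc = 10, nch = 6, snr = 10, ...) {
  generate_session(simulation_config(trials_per_class = tpc,
                                     n_channels = nch, snr_db = snr,
                                     seed = seed, ...))
}

# well-conditioned random SPD pair (eigenvalues in [0.5, 2]) so the CSP
# whitening condition cap stays inactive and the solution is the exact
# generalized eigendecomposition
random_spd_pair <- function(dim, seed) {
  set.seed(seed)
  mk <- function() {
    q <- qr.Q(qr(matrix(rnorm(dim * dim), dim)))
    q %*% diag(runif(dim, 0.5, 2)) %*% t(q)
  }
  list(a = mk(), b = mk())
}

# brute-force generalized eigensolver oracle: whiten the composite through
# its symmetric eigen square root, then an ordinary symmetric eigenproblem
csp_bruteforce <- function(r_i, r_j) {
  comp <- r_i + r_j
  ec <- eigen(comp, symmetric = TRUE)
  p <- ec$vectors %*% diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  m <- p %*% r_i %*% p
  em <- eigen((m + t(m)) / 2, symmetric = TRUE)
  list(W = t(p %*% em$vectors), values = em$values)
}

# naive scalar-loop LSTM reference (independent of the vectorized pass)
lstm_reference_step <- function(x, h, c_st, p, mode) {
  hdim <- length(h)
  i <- f <- o <- g <- numeric(hdim)
  for (r in seq_len(hdim)) {
    i[r] <- 1 / (1 + exp(-(sum(p$W_i[r, ] * x) + sum(p$U_i[r, ] * h) + p$b_i[r])))
    f[r] <- 1 / (1 + exp(-(sum(p$W_f[r, ] * x) + sum(p$U_f[r, ] * h) + p$b_f[r])))
    o[r] <- 1 / (1 + exp(-(sum(p$W_o[r, ] * x) + sum(p$U_o[r, ] * h) + p$b_o[r])))
    a <- sum(p$W_c[r, ] * x) + sum(p$U_c[r, ] * h) + p$b_c[r]
    g[r] <- if (mode == "tanh_standard") tanh(a) else a
  }
  c_new <- f * c_st + i * g
  h_new <- if (mode == "tanh_standard") o * tanh(c_new) else o * c_new
  list(h = h_new, c = c_new)
}

# tiny network configuration used by training tests
tiny_net_config <- function(c_dim, t_dim, ...) {
  network_config(input_shape = c(c_dim, t_dim), n_classes = 4, F1 = 4,
                 temporal_kernel = min(8L, t_dim), D = 2, F2 = 4,
                 separable_kernel = 5, pool1 = 2, pool2 = 2,
                 lstm_units = 8, fnb_rules = 4, fc_units = 8, ...)
}

# class-separable feature fixture: class-specific amplitude patterns
separable_features <- function(n_per_class = 12, c_dim = 6, t_dim = 24,
                               noise = 0.3, seed = 1) {
  set.seed(seed)
  n <- 4 * n_per_class
  x <- array(rnorm(n * c_dim * t_dim, sd = noise), c(n, c_dim, t_dim))
  y <- rep(0:3, each = n_per_class)
  for (i in seq_len(n)) {
    ch <- y[i] + 1L
    x[i, ch, ] <- x[i, ch, ] + 2
  }
  list(x = x, y = y)
}
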