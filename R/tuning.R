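# Hyperparameter selection: axis-by-axis coordinate descent and Bayesian
# optimization with a Gaussian-process surrogate (Matern 5/2 on normalized
# coordinates) and expected-improvement acquisition.

#' Hyperparameter search space
#'
#' @param ... Named parameter descriptors, each a list with `type`
#'   (`"integer"` or `"categorical"`) and either `bounds = c(low, high)`
#'   or `choices = c(...)`.
#' @return Object of class `search_space`.
#' @export
search_space <- function(...) {
  params <- list(...)
  check_that(length(params) > 0 && !is.null(names(params)) &&
               all(nzchar(names(params))), "parameters must be named")
  for (nm in names(params)) {
    p <- params[[nm]]
    check_that(p$type %in% c("integer", "categorical"),
               sprintf("%s: type must be integer or categorical", nm))
    if (p$type == "integer") {
      check_that(length(p$bounds) == 2L && p$bounds[1] <= p$bounds[2],
                 sprintf("%s: bounds must satisfy low <= high", nm))
    } else {
      check_that(length(p$choices) >= 1L,
                 sprintf("%s: choices must be non-empty", nm))
    }
  }
  structure(params, class = "search_space")
}

#' Default search space over the three convolutional size parameters
#'
#' Temporal filter count, depth multiplier and pointwise filter count.
#' @return A [search_space()].
#' @export
default_search_space <- function() {
  search_space(
    F1 = list(type = "categorical", choices = c(4L, 8L, 16L)),
    D = list(type = "categorical", choices = c(1L, 2L, 4L)),
    F2 = list(type = "categorical", choices = c(4L, 8L, 16L)))
}

axis_values <- function(p) {
  if (p$type == "integer") seq(p$bounds[1], p$bounds[2]) else p$choices
}

safe_objective <- function(objective, config) {
  tryCatch(objective(config), error = function(e) {
    clfc_log("warn", "objective failed (", conditionMessage(e),
             "); scored as -Inf")
    -Inf
  })
}

tuning_result <- function(best_config, best_score, history, method, meta) {
  structure(list(best_config = best_config, best_score = best_score,
                 history = history, method = method, meta = meta),
            class = "tuning_result")
}

#' Coordinate-descent hyperparameter search
#'
#' Each sweep optimizes every parameter in turn along its axis with the
#' others held fixed, committing the best value before moving to the next
#' axis; accepted scores never decrease. Deterministic for a deterministic
#' objective.
#'
#' @param space A [search_space()].
#' @param objective Function taking a named configuration list and
#'   returning a scalar score to maximize. Failures are logged and scored
#'   `-Inf`.
#' @param init Named list giving the starting configuration (inside the
#'   space).
#' @param n_sweeps Number of full sweeps (default 1).
#' @return A `tuning_result` with the evaluation history.
#' @export
coordinate_descent <- function(space, objective, init, n_sweeps = 1L) {
  check_that(inherits(space, "search_space"), "need a search_space")
  check_that(all(names(space) %in% names(init)),
             "init must cover every parameter")
  theta <- init[names(space)]
  cache <- new.env(parent = emptyenv())
  key <- function(cfg) paste(unlist(cfg), collapse = "|")
  eval_cached <- function(cfg) {
    k <- key(cfg)
    if (is.null(cache[[k]])) cache[[k]] <- safe_objective(objective, cfg)
    cache[[k]]
  }
  history <- list()
  best <- eval_cached(theta)
  history[[1]] <- c(theta, list(score = best))
  for (sweep in seq_len(n_sweeps)) {
    for (nm in names(space)) {
      vals <- axis_values(space[[nm]])
      scores <- vapply(vals, function(v) {
        cfg <- theta; cfg[[nm]] <- v
        s <- eval_cached(cfg)
        history[[length(history) + 1L]] <<- c(cfg, list(score = s))
        s
      }, numeric(1))
      if (max(scores) > best) {
        best <- max(scores)
        theta[[nm]] <- vals[which.max(scores)]
      }
    }
  }
  hist_df <- do.call(rbind, lapply(history, function(h)
    as.data.frame(h, stringsAsFactors = FALSE)))
  tuning_result(theta, best, hist_df, "coordinate_descent",
                list(n_sweeps = n_sweeps))
}

# --- Gaussian-process machinery for Bayesian optimization ----------------

matern52 <- function(d, ell) {
  r <- sqrt(5) * d / ell
  (1 + r + r^2 / 3) * exp(-r)
}

dist_mat <- function(x1, x2) {
  # Euclidean distances between rows
  n1 <- nrow(x1); n2 <- nrow(x2)
  s1 <- rowSums(x1^2); s2 <- rowSums(x2^2)
  d2 <- outer(s1, s2, "+") - 2 * tcrossprod(x1, x2)
  sqrt(pmax(d2, 0))
}

gp_fit <- function(x, y, ell_grid = c(0.1, 0.2, 0.5, 1), nugget = 1e-6) {
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy < 1e-12) return(NULL)   # degenerate surrogate
  ys <- (y - mu) / sdy
  best <- NULL; best_ll <- -Inf
  d <- dist_mat(x, x)
  for (ell in ell_grid) {
    kmat <- matern52(d, ell) + diag(nugget, nrow(x))
    ch <- tryCatch(chol(kmat), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (ll > best_ll) {
      best_ll <- ll
      best <- list(x = x, ell = ell, chol = ch, alpha = alpha,
                   mu = mu, sdy = sdy)
    }
  }
  best
}

gp_predict <- function(fit, xnew) {
  ks <- matern52(dist_mat(fit$x, xnew), fit$ell)
  mean_s <- crossprod(ks, fit$alpha)
  v <- forwardsolve(t(fit$chol), ks)
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = fit$mu + fit$sdy * as.vector(mean_s),
       sd = fit$sdy * sqrt(var_s))
}

expected_improvement <- function(mean_s, sd_s, best, xi = 0.01) {
  z <- (mean_s - best - xi) / sd_s
  (mean_s - best - xi) * stats::pnorm(z) + sd_s * stats::dnorm(z)
}

space_to_unit <- function(space, cfg) {
  vapply(names(space), function(nm) {
    p <- space[[nm]]
    if (p$type == "integer") {
      if (p$bounds[2] == p$bounds[1]) return(0.5)
      (cfg[[nm]] - p$bounds[1]) / (p$bounds[2] - p$bounds[1])
    } else {
      i <- match(cfg[[nm]], p$choices)
      (i - 1) / max(length(p$choices) - 1, 1)
    }
  }, numeric(1))
}

unit_to_config <- function(space, u) {
  cfg <- list()
  for (i in seq_along(space)) {
    p <- space[[i]]
    if (p$type == "integer") {
      cfg[[names(space)[i]]] <-
        as.integer(round(p$bounds[1] + u[i] * (p$bounds[2] - p$bounds[1])))
    } else {
      j <- 1L + round(u[i] * (length(p$choices) - 1L))
      cfg[[names(space)[i]]] <- p$choices[[j]]
    }
  }
  cfg
}

#' Bayesian optimization with a Gaussian-process surrogate
#'
#' Random initial design, then: fit a GP (Matern 5/2 on unit-normalized
#' coordinates, length-scale by marginal likelihood) to the (config, score)
#' history, and evaluate the configuration maximizing expected improvement
#' over a random candidate set. Integer parameters are relaxed to the unit
#' cube and rounded at evaluation. If all observed scores are equal the
#' surrogate is degenerate and the step falls back to random sampling with
#' a warning. Seeded and reproducible.
#'
#' @param space A [search_space()].
#' @param objective Function from configuration list to scalar score
#'   (maximized). Failures are scored `-Inf`.
#' @param n_iter Surrogate-guided iterations (default 20).
#' @param n_init Random initial evaluations (default 5, minimum 2).
#' @param seed Integer seed.
#' @param xi Expected-improvement exploration margin (default 0.01).
#' @param n_candidates Random acquisition candidates per iteration
#'   (default 256).
#' @return A `tuning_result`; history has `n_init + n_iter` rows.
#' @export
bayesian_optimize <- function(space, objective, n_iter = 20L, n_init = 5L,
                              seed = 1L, xi = 0.01, n_candidates = 256L) {
  check_that(inherits(space, "search_space"), "need a search_space")
  check_that(n_init >= 2L, "n_init must be >= 2")
  set.seed(seed)
  p_dim <- length(space)
  xs <- matrix(stats::runif(n_init * p_dim), n_init, p_dim)
  configs <- apply(xs, 1, function(u) unit_to_config(space, u),
                   simplify = FALSE)
  scores <- vapply(configs, function(cfg) safe_objective(objective, cfg),
                   numeric(1))
  for (it in seq_len(n_iter)) {
    ok <- is.finite(scores)
    fit <- if (sum(ok) >= 2L)
      gp_fit(xs[ok, , drop = FALSE], scores[ok]) else NULL
    cand <- matrix(stats::runif(n_candidates * p_dim), n_candidates, p_dim)
    if (is.null(fit)) {
      if (sum(ok) >= 2L) {
        warning("degenerate GP surrogate (constant scores); sampling at random")
      }
      u_next <- cand[1L, ]
    } else {
      pr <- gp_predict(fit, cand)
      ei <- expected_improvement(pr$mean, pr$sd, max(scores[ok]), xi)
      u_next <- cand[which.max(ei), ]
    }
    cfg <- unit_to_config(space, u_next)
    configs[[length(configs) + 1L]] <- cfg
    xs <- rbind(xs, u_next)
    scores <- c(scores, safe_objective(objective, cfg))
  }
  hist_df <- do.call(rbind, lapply(seq_along(configs), function(i)
    as.data.frame(c(configs[[i]], list(score = scores[i])),
                  stringsAsFactors = FALSE)))
  best_i <- which.max(scores)
  tuning_result(configs[[best_i]], scores[best_i], hist_df,
                "bayesian_optimization",
                list(n_iter = n_iter, n_init = n_init, seed = seed, xi = xi))
}
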