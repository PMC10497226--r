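#' Tuning configuration for the l0/DC nodewise regressions
#'
#' Defaults follow the theory-driven scalings: per-column threshold
#' `tau_j = tau_scale * sd(y_j) * sqrt((log q + log n)/n)`; a descending
#' log-spaced grid of `n_gamma` values from `gamma_max =
#' max|X'y| / (n tau)` down to `gamma_min_ratio * gamma_max`, solved with
#' warm starts; DC iteration cap `1 + ceiling(log(q)/log 4)`; and an
#' extended-BIC model-selection penalty `df * (log n + 2 *
#' ebic_gamma * log q)` (set `ebic_gamma = 0` for the plain BIC).
#'
#' @param kappa Per-column sparsity bound(s); `NULL` selects per column by
#'   the information criterion over `kappa_grid`.
#' @param kappa_grid Candidate sparsity bounds used when `kappa` is `NULL`.
#' @param tau Per-column thresholds; `NULL` uses the default scaling.
#' @param tau_scale Multiplier on the default `tau`.
#' @param gamma_grid Decreasing positive grid; `NULL` uses the default.
#' @param n_gamma,gamma_min_ratio Default grid size and lower ratio.
#' @param tol DC convergence tolerance (sup-norm change of the iterate).
#' @param max_dc_iter Cap on DC iterations; `NULL` uses the default.
#' @param ebic_gamma Extended-BIC weight (default 1).
#' @param cd_tol,max_sweeps Inner coordinate-descent tolerances.
#' @param standardize Standardize columns of the design before fitting and
#'   back-transform (off by default; the method is scale-robust).
#' @return A list of class `tuning_config`.
#' @export
tuning_config <- function(kappa = NULL, kappa_grid = NULL,
                          tau = NULL, tau_scale = 1,
                          gamma_grid = NULL, n_gamma = 10,
                          gamma_min_ratio = 0.01,
                          tol = 1e-8, max_dc_iter = NULL,
                          ebic_gamma = 1,
                          cd_tol = 1e-10, max_sweeps = 2000,
                          standardize = FALSE) {
  if (!is.null(gamma_grid)) {
    if (any(gamma_grid <= 0) || any(diff(gamma_grid) >= 0)) {
      stop("gamma_grid must be strictly decreasing and positive")
    }
  }
  structure(list(kappa = kappa, kappa_grid = kappa_grid,
                 tau = tau, tau_scale = tau_scale,
                 gamma_grid = gamma_grid, n_gamma = n_gamma,
                 gamma_min_ratio = gamma_min_ratio,
                 tol = tol, max_dc_iter = max_dc_iter,
                 ebic_gamma = ebic_gamma,
                 cd_tol = cd_tol, max_sweeps = max_sweeps,
                 standardize = standardize),
            class = "tuning_config")
}

default_tau <- function(y, q, n, tau_scale = 1) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) s <- 1
  tau_scale * s * sqrt((log(q) + log(n)) / n)
}

default_gamma_grid <- function(Xty, n, tau, n_gamma, min_ratio) {
  gmax <- max(abs(Xty)) / (n * tau)
  if (!is.finite(gmax) || gmax <= 0) gmax <- 1
  exp(seq(log(gmax), log(min_ratio * gmax), length.out = n_gamma))
}

df_penalty <- function(n, q_pen, ebic_gamma) {
  log(n) + 2 * ebic_gamma * log(max(q_pen, 1L))
}

#' Weighted Lasso by coordinate descent
#'
#' Minimizes `sum_i (y_i - v'x_i)^2 + 2 n gamma tau sum_l w_l |v_l|` with
#' activity weights `w_l` in `{0, 1}`; coordinates with `w_l = 0` are
#' unpenalized. This is the convex subproblem of each DC iteration.
#'
#' @param X `n x q` design matrix.
#' @param y Response vector.
#' @param active_weights Length-`q` vector of 0/1 penalty weights.
#' @param gamma,tau Positive penalty parameters.
#' @param start Starting coefficient vector (default zeros).
#' @param details If `TRUE`, return a list with the per-sweep objective
#'   trace instead of just the coefficients.
#' @return Length-`q` coefficient vector (or a list when `details`).
#' @export
weighted_lasso <- function(X, y, active_weights, gamma, tau,
                           start = rep(0, ncol(X)), details = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("weighted_lasso: non-finite inputs")
  }
  if (gamma <= 0 || tau <= 0) stop("weighted_lasso: gamma and tau must be > 0")
  n <- nrow(X)
  lam <- n * gamma * tau * as.numeric(active_weights)
  fit <- cpp_weighted_lasso(crossprod(X), crossprod(X, y), sum(y^2), lam,
                            start, cd_tol = 1e-12, max_sweeps = 100000L,
                            trace_objective = details)
  if (details) fit else as.numeric(fit$coef)
}

#' l0 projection
#'
#' Keeps the `kappa` entries of largest absolute value (ties broken by
#' lower index) and zeroes the rest.
#'
#' @param v Numeric vector.
#' @param kappa Number of entries to keep (`1 <= kappa <= length(v)`).
#' @return Vector of the same length.
#' @export
l0_project <- function(v, kappa) {
  stopifnot(kappa >= 1, kappa <= length(v))
  nz <- which(v != 0)
  if (length(nz) <= kappa) return(v)
  keep <- nz[order(-abs(v[nz]), nz)][seq_len(kappa)]
  out <- numeric(length(v))
  out[keep] <- v[keep]
  out
}

## Internal: DC solve of one l0-constrained column from Gram quantities.
dc_column_gram <- function(XtX, Xty, yty, n, kappa, tau, gamma_grid,
                           tol, max_dc_iter, pen_mask = NULL,
                           dc_start = NULL, ebic_gamma = 1,
                           cd_tol = 1e-10, max_sweeps = 2000) {
  q <- length(Xty)
  if (is.null(pen_mask)) pen_mask <- rep(1L, q)
  if (is.null(dc_start)) dc_start <- rep(0, q)
  q_pen <- sum(pen_mask > 0)
  fit <- cpp_dc_column(XtX, Xty, yty, as.integer(n), as.integer(kappa),
                       tau, gamma_grid, tol, as.integer(max_dc_iter),
                       as.integer(pen_mask != 0), dc_start,
                       df_penalty(n, q_pen, ebic_gamma),
                       cd_tol, as.integer(max_sweeps))
  fit$support <- as.integer(fit$support) + 1L
  fit$coef <- as.numeric(fit$coef)
  fit$vtilde <- as.numeric(fit$vtilde)
  fit
}

#' l0-constrained regression of one response column
#'
#' Solves `min ||y - X v||^2 s.t. ||v||_0 <= kappa` by truncated-L1
#' difference-of-convex iterations over weighted Lasso subproblems, warm
#' started along a descending `gamma` grid, followed by an l0 projection
#' and an OLS refit on the selected support. The grid value is chosen by
#' the extended-BIC score of the refit.
#'
#' @inheritParams weighted_lasso
#' @param kappa Sparsity bound.
#' @param config A [tuning_config()].
#' @return List with `coef` (refit coefficients, exact zeros off
#'   support), `support`, `rss`, `iterations` (DC iterations at the
#'   chosen grid value), `gamma`, `tau`.
#' @export
dc_l0_column <- function(X, y, kappa, config = tuning_config()) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("dc_l0_column: non-finite inputs")
  }
  n <- nrow(X); q <- ncol(X)
  stopifnot(kappa >= 1, kappa <= q)
  XtX <- crossprod(X)
  degenerate <- which(diag(XtX) == 0)
  if (length(degenerate) > 0L) {
    warning("dc_l0_column: zero-variance design column(s) ",
            paste(degenerate, collapse = ", "), " dropped from candidacy")
  }
  Xty <- as.numeric(crossprod(X, y))
  tau <- config$tau %||% default_tau(y, q, n, config$tau_scale)
  gg <- config$gamma_grid %||%
    default_gamma_grid(Xty, n, tau, config$n_gamma, config$gamma_min_ratio)
  maxit <- config$max_dc_iter %||% (1L + ceiling(log(q) / log(4)))
  fit <- dc_column_gram(XtX, Xty, sum(y^2), n, kappa, tau, gg,
                        config$tol, maxit,
                        ebic_gamma = config$ebic_gamma,
                        cd_tol = config$cd_tol,
                        max_sweeps = config$max_sweeps)
  fit$tau <- tau
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the sparsity bound by the information criterion
#'
#' Fits [dc_l0_column()] for each candidate `kappa` and scores the OLS
#' refit by `n log(RSS/n) + df (log n + 2 ebic_gamma log q)`; ties go to
#' the smaller `kappa`.
#'
#' @inheritParams dc_l0_column
#' @param kappa_grid Integer candidates.
#' @return List with `kappa` (the selection) and `table` (per-candidate
#'   scores, RSS and support sizes).
#' @export
select_kappa_bic <- function(X, y, kappa_grid, config = tuning_config()) {
  stopifnot(length(kappa_grid) >= 1)
  n <- nrow(X); q <- ncol(X)
  pen <- df_penalty(n, q, config$ebic_gamma)
  fits <- lapply(kappa_grid, function(k) dc_l0_column(X, y, k, config))
  tab <- data.frame(
    kappa = as.integer(kappa_grid),
    df = vapply(fits, function(f) length(f$support), integer(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1))
  )
  tab$score <- n * log(pmax(tab$rss, 1e-300) / n) + tab$df * pen
  best <- which(tab$score == min(tab$score))
  best <- best[which.min(tab$kappa[best])]
  list(kappa = tab$kappa[best], table = tab, fit = fits[[best]])
}

#' Fit the reduced-form coefficient matrix column by column
#'
#' Each column of `Y` is regressed on `X` under its l0 constraint; the
#' columns are independent problems. When `config[["kappa"]]` is `NULL` the
#' per-column bound is selected by the information criterion over
#' `config[["kappa_grid"]]` (default `1..min(10, q)`).
#'
#' @param data A [new_dataset()] (or [sample_dataset()]) object.
#' @param config A [tuning_config()].
#' @return Object of class `v_estimate`: `V_hat` (`q x p`), per-column
#'   `support`, `rss`, `kappa`, `tau`, `gamma`, `iterations`.
#' @export
fit_V <- function(data, config = tuning_config()) {
  stopifnot(inherits(data, "peeldag_data"))
  if (data$n < 2L) stop("fit_V: need at least two observations")
  X <- data$X; Y <- data$Y
  n <- data$n; p <- data$p; q <- data$q
  Xs <- X
  scale_x <- rep(1, q)
  if (isTRUE(config$standardize)) {
    scale_x <- apply(X, 2, sd)
    scale_x[scale_x == 0] <- 1
    Xs <- sweep(X, 2, scale_x, "/")
  }
  XtX <- crossprod(Xs)
  XtY <- crossprod(Xs, Y)
  kappa_grid <- config[["kappa_grid"]] %||% seq_len(max(1L, min(q, n - 2L)))
  kappas <- if (is.null(config[["kappa"]])) rep(NA_integer_, p)
            else rep_len(as.integer(config[["kappa"]]), p)
  taus <- if (is.null(config$tau)) rep(NA_real_, p)
          else rep_len(config$tau, p)
  maxit <- config$max_dc_iter %||% (1L + ceiling(log(q) / log(4)))
  pen <- df_penalty(n, q, config$ebic_gamma)

  V <- matrix(0, q, p)
  support <- vector("list", p)
  rss <- gammas <- numeric(p)
  iters <- integer(p)
  for (j in seq_len(p)) {
    y <- Y[, j]
    yty <- sum(y^2)
    if (is.na(taus[j])) taus[j] <- default_tau(y, q, n, config$tau_scale)
    gg <- config$gamma_grid %||%
      default_gamma_grid(XtY[, j], n, taus[j], config$n_gamma,
                         config$gamma_min_ratio)
    if (is.na(kappas[j])) {
      # ascending search; the DC path itself does not depend on kappa, so
      # once the selected support stops growing the fits are constant and
      # the search can stop (two consecutive non-growing supports).
      best_fit <- NULL; best_score <- Inf; best_k <- NA_integer_
      stagnant <- 0L
      for (k in sort(kappa_grid)) {
        f <- dc_column_gram(XtX, XtY[, j], yty, n, k, taus[j], gg,
                            config$tol, maxit,
                            ebic_gamma = config$ebic_gamma,
                            cd_tol = config$cd_tol,
                            max_sweeps = config$max_sweeps)
        sc <- n * log(max(f$rss, 1e-300) / n) + length(f$support) * pen
        if (sc < best_score - 1e-9) {
          best_score <- sc; best_fit <- f; best_k <- k
        }
        stagnant <- if (length(f$support) < k) stagnant + 1L else 0L
        if (stagnant >= 2L) break
      }
      kappas[j] <- best_k
      fit <- best_fit
    } else {
      fit <- dc_column_gram(XtX, XtY[, j], yty, n, kappas[j], taus[j], gg,
                            config$tol, maxit,
                            ebic_gamma = config$ebic_gamma,
                            cd_tol = config$cd_tol,
                            max_sweeps = config$max_sweeps)
    }
    V[, j] <- fit$coef / scale_x
    support[[j]] <- fit$support
    rss[j] <- fit$rss
    gammas[j] <- fit$gamma
    iters[j] <- fit$iterations
  }
  structure(list(V_hat = V, support = support, rss = rss,
                 kappa = kappas, tau = taus, gamma = gammas,
                 iterations = iters, n = n, p = p, q = q),
            class = "v_estimate")
}

#' @export
print.v_estimate <- function(x, ...) {
  cat(sprintf("Reduced-form estimate: q = %d x p = %d, support sizes %s\n",
              x$q, x$p, paste(lengths(x$support), collapse = " ")))
  invisible(x)
}

## Refit a v_estimate on perturbed responses, reusing the per-column
## tuning (kappa, tau, chosen gamma) and warm-starting from the original
## solution. Used by the data-perturbation scheme.
refit_V <- function(ref, X, Ystar, config = tuning_config()) {
  n <- nrow(X); q <- ncol(X); p <- ncol(Ystar)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Ystar)
  maxit <- config$max_dc_iter %||% (1L + ceiling(log(q) / log(4)))
  V <- matrix(0, q, p)
  support <- vector("list", p)
  for (j in seq_len(p)) {
    fit <- dc_column_gram(XtX, XtY[, j], sum(Ystar[, j]^2), n,
                          ref$kappa[j], ref$tau[j], ref$gamma[j],
                          config$tol, maxit,
                          dc_start = ref$V_hat[, j],
                          ebic_gamma = config$ebic_gamma,
                          cd_tol = config$cd_tol,
                          max_sweeps = config$max_sweeps)
    V[, j] <- fit$coef
    support[[j]] <- fit$support
  }
  structure(list(V_hat = V, support = support,
                 kappa = ref$kappa, tau = ref$tau, gamma = ref$gamma,
                 n = n, p = p, q = q),
            class = "v_estimate")
}
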