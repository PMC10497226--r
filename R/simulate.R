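## Seed substreams: every consumer of randomness draws from its own
## substream derived by an exact integer mix, so adding a consumer never
## changes earlier draws and every derived seed stays below 2^31.
mix_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) * 69069 + as.numeric(k) * 7919 + 1
  as.integer(s %% 2147483647)
}

#' Random upper-triangular DAG coefficient matrix
#'
#' Upper off-diagonal entries `U[k, j]`, `k < j`, are drawn independently
#' from `{0, 1}` with success probability `1/p`; all other entries are
#' zero. Optional `weight` rescales the nonzero entries.
#'
#' @param p Number of primary variables.
#' @param seed Integer seed.
#' @param weight Value given to sampled edges (default 1).
#' @return A `p x p` matrix.
#' @export
random_graph_U <- function(p, seed, weight = 1) {
  p <- as.integer(p)
  if (p < 1L) stop("random_graph_U: p must be >= 1")
  U <- matrix(0, p, p)
  if (p > 1L) {
    set.seed(mix_seed(seed, 101L))
    upper <- which(upper.tri(U))
    U[upper] <- weight * rbinom(length(upper), 1L, 1 / p)
  }
  U
}

#' Hub-graph coefficient matrix
#'
#' Nodes 1 and 2 are hubs: `U[1, 2j+1] = U[2, 2j+2] = weight` for
#' `j = 1, ..., floor(p/2) - 2`; all other entries are zero.
#'
#' @param p Number of primary variables (at least 6).
#' @param weight Edge weight (default 1).
#' @return A `p x p` matrix.
#' @export
hub_graph_U <- function(p, weight = 1) {
  p <- as.integer(p)
  jmax <- p %/% 2L - 2L
  if (p < 6L || jmax < 1L) stop("hub_graph_U: p too small for any hub edge")
  U <- matrix(0, p, p)
  for (j in seq_len(jmax)) {
    U[1L, 2L * j + 1L] <- weight
    U[2L, 2L * j + 2L] <- weight
  }
  U
}

#' Intervention coefficient matrix for simulation setups A/B/C
#'
#' `W = rbind(A, B, 0)` with `A`, `B` `p x p` blocks:
#' * Setup A: `A = I`; `B[j, j] = B[j, j+1] = 1` for `j = 1..p-1`. The
#'   first `p` intervention variables are instruments, the next `p - 1`
#'   are invalid instruments with two targets each, the rest inactive.
#' * Setup B: as A but additionally `A[j, j+1] = 1` for `j = 1..p-1`, so
#'   the only instrument is `X_p` and the coverage condition fails.
#' * Setup C: `W = rbind(I, 0)`; `X_1..X_p` are instruments, the rest
#'   inactive.
#'
#' @param setup `"A"`, `"B"` or `"C"`.
#' @param p Number of primary variables.
#' @param q Number of intervention variables (`q >= 2p` for A/B,
#'   `q >= p` for C).
#' @return A `q x p` matrix.
#' @export
intervention_W <- function(setup = c("A", "B", "C"), p, q) {
  setup <- match.arg(setup)
  p <- as.integer(p); q <- as.integer(q)
  if (setup %in% c("A", "B") && q < 2L * p) {
    stop("intervention_W: setups A and B need q >= 2p")
  }
  if (setup == "C") {
    if (q < p) stop("intervention_W: setup C needs q >= p")
    W <- matrix(0, q, p)
    W[cbind(seq_len(p), seq_len(p))] <- 1
    return(W)
  }
  A <- diag(p)
  B <- matrix(0, p, p)
  for (j in seq_len(p - 1L)) {
    B[j, j] <- 1
    B[j, j + 1L] <- 1
    if (setup == "B") A[j, j + 1L] <- 1
  }
  rbind(A, B, matrix(0, q - 2L * p, p))
}

#' Default error variances
#'
#' Equally spaced from 0.5 to 1; the single-node convention is 0.5.
#'
#' @param p Number of primary variables.
#' @return Numeric vector of length `p`.
#' @export
default_sigma2 <- function(p) {
  p <- as.integer(p)
  stopifnot(p >= 1L)
  if (p == 1L) return(0.5)
  seq(0.5, 1, length.out = p)
}

#' Bundle structural-equation parameters
#'
#' Holds the directed-edge coefficients `U` (support must be acyclic),
#' the intervention coefficients `W`, and the error variances. The
#' reduced-form matrix is `V = W (I - U)^{-1}` and the precision of the
#' reduced-form errors is `(I - U) Sigma^{-1} (I - U)^T`.
#'
#' @param U `p x p` coefficient matrix with acyclic support.
#' @param W `q x p` intervention coefficient matrix.
#' @param sigma2 Length-`p` vector of positive error variances
#'   (default [default_sigma2()]).
#' @return An object of class `sem_parameters`.
#' @export
sem_parameters <- function(U, W, sigma2 = default_sigma2(ncol(U))) {
  U <- as.matrix(U); W <- as.matrix(W)
  p <- ncol(U)
  stopifnot(nrow(U) == p, ncol(W) == p, length(sigma2) == p, all(sigma2 > 0))
  supp <- which(U != 0, arr.ind = TRUE)
  if (!is_acyclic(supp, p)) stop("sem_parameters: support of U is cyclic")
  structure(list(U = U, W = W, sigma2 = as.numeric(sigma2),
                 p = p, q = nrow(W)),
            class = "sem_parameters")
}

#' @export
print.sem_parameters <- function(x, ...) {
  cat(sprintf("SEM parameters: p = %d, q = %d, %d directed edges, %d intervention edges\n",
              x$p, x$q, sum(x$U != 0), sum(x$W != 0)))
  invisible(x)
}

#' DAG of the nonzero supports of (U, W)
#'
#' @param params A [sem_parameters()].
#' @return An [intervention_dag()].
#' @export
dag_of_parameters <- function(params) {
  stopifnot(inherits(params, "sem_parameters"))
  intervention_dag(params$p, params$q,
                   primary_edges = which(params$U != 0, arr.ind = TRUE),
                   intervention_edges = which(params$W != 0, arr.ind = TRUE))
}

#' Reduced-form coefficient matrix
#'
#' Computes `V = W (I - U)^{-1}` by a triangular solve along a
#' topological order of the DAG (never by explicit inversion). Row `l`
#' of `V` carries the total effect of `X_l` on each primary variable.
#'
#' @param params A [sem_parameters()].
#' @return A `q x p` matrix.
#' @export
implied_V <- function(params) {
  stopifnot(inherits(params, "sem_parameters"))
  U <- params$U; W <- params$W; p <- params$p
  supp <- which(U != 0, arr.ind = TRUE)
  ord <- topological_order(edge_matrix(supp), p)
  # solve V (I - U) = W column-by-column along the order:
  # V_{.j} = W_{.j} + sum_k U[k, j] V_{.k}
  V <- matrix(0, params$q, p)
  for (j in ord) {
    pa <- which(U[, j] != 0)
    V[, j] <- W[, j]
    if (length(pa) > 0L) {
      V[, j] <- V[, j] + V[, pa, drop = FALSE] %*% U[pa, j]
    }
  }
  V
}

ar_covariance <- function(q, rho = 0.5) {
  rho^abs(outer(seq_len(q), seq_len(q), "-"))
}

#' Simulate a data set from the structural equation model
#'
#' Rows of `X` are iid `N(0, x_cov)` (default AR covariance
#' `0.5^|l - l'|`); error rows are iid `N(0, Diag(sigma2))`; `Y` solves
#' the structural equations exactly along a topological order.
#'
#' @param params A [sem_parameters()].
#' @param n Sample size.
#' @param seed Integer seed.
#' @param x_cov `q x q` positive-definite covariance for `X`.
#' @return List with class `peeldag_data`: `Y` (`n x p`), `X` (`n x q`),
#'   `e` (the simulated error matrix, for oracle checks), and counts.
#' @export
sample_dataset <- function(params, n, seed,
                           x_cov = ar_covariance(params$q)) {
  stopifnot(inherits(params, "sem_parameters"))
  n <- as.integer(n)
  p <- params$p; q <- params$q
  R <- tryCatch(chol(x_cov), error = function(e)
    stop("sample_dataset: x_cov is not positive definite"))
  set.seed(mix_seed(seed, 1L))
  X <- matrix(rnorm(n * q), n, q) %*% R
  set.seed(mix_seed(seed, 2L))
  e <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(params$sigma2), p)
  U <- params$U
  ord <- topological_order(edge_matrix(which(U != 0, arr.ind = TRUE)), p)
  WX <- X %*% params$W
  Y <- matrix(0, n, p)
  for (j in ord) {
    pa <- which(U[, j] != 0)
    Y[, j] <- WX[, j] + e[, j]
    if (length(pa) > 0L) {
      Y[, j] <- Y[, j] + Y[, pa, drop = FALSE] %*% U[pa, j]
    }
  }
  colnames(Y) <- paste0("Y", seq_len(p))
  colnames(X) <- paste0("X", seq_len(q))
  new_dataset(Y, X, e = e)
}

#' Assemble a data set from matrices
#'
#' @param Y `n x p` matrix of primary variables.
#' @param X `n x q` matrix of intervention variables.
#' @param e Optional `n x p` error matrix (kept when simulated).
#' @return An object of class `peeldag_data`.
#' @export
new_dataset <- function(Y, X, e = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same number of rows")
  if (anyNA(Y) || anyNA(X)) stop("missing values are not supported")
  structure(list(Y = Y, X = X, e = e,
                 n = nrow(Y), p = ncol(Y), q = ncol(X)),
            class = "peeldag_data")
}

#' @export
print.peeldag_data <- function(x, ...) {
  cat(sprintf("Data set: n = %d, p = %d primary, q = %d intervention variables\n",
              x$n, x$p, x$q))
  invisible(x)
}

#' Simulation scenario parameters for the benchmark designs
#'
#' Convenience constructor for the study designs: a random or hub graph,
#' one of the intervention setups, and default error variances.
#'
#' @param graph `"random"` or `"hub"`.
#' @param setup Intervention setup `"A"`, `"B"` or `"C"`.
#' @param p,q Dimensions.
#' @param seed Seed for the random graph draw.
#' @param weight Edge weight for the graph generator.
#' @return A [sem_parameters()].
#' @export
scenario_parameters <- function(graph = c("random", "hub"),
                                setup = c("A", "B", "C"),
                                p, q, seed = 1L, weight = 1) {
  graph <- match.arg(graph)
  setup <- match.arg(setup)
  U <- if (graph == "random") random_graph_U(p, seed, weight)
       else hub_graph_U(p, weight)
  sem_parameters(U, intervention_W(setup, p, q))
}
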