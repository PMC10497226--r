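#' Identify leaves and their instruments from a reduced-form matrix
#'
#' Restricted to the active columns, a column `j` is a leaf candidate
#' when some row `l` has its sole nonzero at `j`; every such row is an
#' instrument of the leaf. Rests on the fact that an instrument of a
#' childless variable affects no other active variable, so its
#' reduced-form row is supported on that single column.
#'
#' @param V_hat `q x p` reduced-form coefficient matrix (exact zeros).
#' @param active_cols Indices of the still-active columns.
#' @return Named list mapping each leaf column to its instrument rows
#'   (empty list when no leaf is detectable).
#' @export
find_leaf_instruments <- function(V_hat, active_cols) {
  stopifnot(length(active_cols) >= 1)
  sub <- V_hat[, active_cols, drop = FALSE]
  nz <- sub != 0
  single <- which(rowSums(nz) == 1L)
  out <- list()
  for (l in single) {
    j <- active_cols[which(nz[l, ])]
    key <- as.character(j)
    out[[key]] <- c(out[[key]], l)
  }
  out[order(as.integer(names(out)))]
}

#' Recover the ancestral relation graph by peeling
#'
#' Repeatedly identifies all current leaves (with their instruments) and
#' peels them: for a leaf `k` and a previously peeled column `j`, the
#' ancestral pair `(k, j)` is recorded when every instrument row of `k`
#' is nonzero at `j`. After all columns are peeled, the collected pairs
#' are transitively closed, and a candidate intervention edge `(l, j)`
#' is recorded when `V_hat[l, k] != 0` for `k = j` or some ancestor `k`
#' of `j`.
#'
#' If some round finds no row with a single nonzero among the active
#' columns, the identifiability premise (each variable carrying its own
#' instrument) is violated; by default this is a hard error of condition
#' class `peeldag_no_leaf`. The opt-in greedy fallback instead takes the
#' active-support row whose second-largest magnitude is smallest,
#' treating its smaller entries as zero, and logs a message.
#'
#' @param V_hat `q x p` reduced-form coefficient matrix.
#' @param fallback `"error"` (default) or `"greedy"`.
#' @return List with `arg` (an [ancestral_graph()]) and `trace`
#'   (per-round leaves and instruments, and the peel order).
#' @export
peel <- function(V_hat, fallback = c("error", "greedy")) {
  fallback <- match.arg(fallback)
  V_hat <- as.matrix(V_hat)
  q <- nrow(V_hat); p <- ncol(V_hat)
  stopifnot(p >= 1)
  active <- seq_len(p)
  peeled <- integer(0)
  edges <- matrix(integer(0), ncol = 2L)
  rounds <- list()
  while (length(active) > 0L) {
    leaves <- find_leaf_instruments(V_hat, active)
    if (length(leaves) == 0L) {
      if (fallback == "error") {
        stop(structure(class = c("peeldag_no_leaf", "error", "condition"),
                       list(message = paste0(
                              "peel: no leaf identifiable among active columns {",
                              paste(active, collapse = ", "),
                              "}; instrument-per-variable condition violated"),
                            call = sys.call(-1), active = active)))
      }
      # greedy: row supported on active columns whose second-largest
      # |entry| is smallest; entries below the largest are zeroed
      sub <- abs(V_hat[, active, drop = FALSE])
      second <- apply(sub, 1L, function(r) {
        s <- sort(r, decreasing = TRUE)
        if (s[1L] == 0) Inf else if (length(s) > 1L) s[2L] else 0
      })
      l <- which.min(second)
      j <- active[which.max(sub[l, ])]
      message(sprintf(
        "peel: greedy fallback treats X%d as instrument of Y%d (second-largest |entry| %.3g zeroed)",
        l, j, second[l]))
      leaves <- stats::setNames(list(l), as.character(j))
    }
    leaf_idx <- as.integer(names(leaves))
    for (i in seq_along(leaves)) {
      k <- leaf_idx[i]
      instr <- leaves[[i]]
      if (length(peeled) > 0L) {
        hit <- peeled[colSums(V_hat[instr, peeled, drop = FALSE] != 0) ==
                        length(instr)]
        if (length(hit) > 0L) edges <- rbind(edges, cbind(k, hit))
      }
    }
    rounds[[length(rounds) + 1L]] <- list(leaves = leaf_idx,
                                          instruments = leaves)
    peeled <- c(peeled, leaf_idx)
    active <- setdiff(active, leaf_idx)
  }
  anc <- transitive_closure(unique_edges(edges), p)
  # candidate intervention edges: (l, j) iff V_hat[l, k] != 0 for k = j
  # or some ancestor k of j
  anc_of <- lapply(seq_len(p), function(j) c(j, anc[anc[, 2L] == j, 1L]))
  ce <- do.call(rbind, lapply(seq_len(p), function(j) {
    rows <- which(rowSums(V_hat[, anc_of[[j]], drop = FALSE] != 0) > 0L)
    if (length(rows) == 0L) NULL else cbind(rows, j)
  }))
  arg <- ancestral_graph(p, q, anc, ce)
  list(arg = arg,
       trace = list(rounds = rounds, peel_order = peeled))
}

#' Estimate (U, W) given an ancestral relation graph
#'
#' For each node `j`, regresses `Y_j` on its candidate ancestors
#' `{Y_k : (k, j) ancestral}` and candidate interventions
#' `{X_l : (l, j) candidate}` under an l0 constraint on the ancestor
#' coefficients only (the intervention coefficients are unpenalized),
#' using the same DC machinery. Entries outside the ARG are exactly
#' zero. The per-node bound is selected by the information criterion
#' over `kappa_grid` unless `kappa_prime` is given.
#'
#' @param data A dataset object.
#' @param arg An [ancestral_graph()].
#' @param kappa_prime Per-node integer bounds (recycled), or `NULL` to
#'   select over `kappa_grid`.
#' @param kappa_grid Candidate bounds (default `1:5`).
#' @param config A [tuning_config()].
#' @return List with `U_hat` (`p x p`), `W_hat` (`q x p`), and
#'   `kappa_prime` (the per-node bounds used; `NA` for nodes with no
#'   ancestor candidates).
#' @export
estimate_coefficients <- function(data, arg, kappa_prime = NULL,
                                  kappa_grid = 1:5,
                                  config = tuning_config()) {
  stopifnot(inherits(data, "peeldag_data"), inherits(arg, "ancestral_graph"))
  n <- data$n; p <- data$p; q <- data$q
  stopifnot(arg$p == p, arg$q == q)
  kp_in <- if (is.null(kappa_prime)) rep(NA_integer_, p)
           else rep_len(as.integer(kappa_prime), p)
  U <- matrix(0, p, p)
  W <- matrix(0, q, p)
  kp_used <- rep(NA_integer_, p)
  anc <- arg$ancestral_edges
  ce <- arg$candidate_intervention_edges
  for (j in seq_len(p)) {
    an <- anc[anc[, 2L] == j, 1L]
    iv <- ce[ce[, 2L] == j, 1L]
    m <- length(an) + length(iv)
    if (m == 0L) next
    if (m >= n) {
      stop(sprintf("estimate_coefficients: node %d has %d regressors for %d observations",
                   j, m, n))
    }
    Z <- cbind(data$Y[, an, drop = FALSE], data$X[, iv, drop = FALSE])
    y <- data$Y[, j]
    pen_mask <- c(rep(1L, length(an)), rep(0L, length(iv)))
    if (length(an) == 0L) {
      b <- qr.coef(qr(Z), y)
      b[is.na(b)] <- 0
      W[iv, j] <- b
      next
    }
    ZtZ <- crossprod(Z); Zty <- as.numeric(crossprod(Z, y)); yty <- sum(y^2)
    tau <- config$tau %||% default_tau(y, m, n, config$tau_scale)
    gg <- config$gamma_grid %||%
      default_gamma_grid(Zty * pen_mask, n, tau, config$n_gamma,
                         config$gamma_min_ratio)
    maxit <- config$max_dc_iter %||% (1L + ceiling(log(m) / log(4)))
    grid <- if (is.na(kp_in[j])) pmin(kappa_grid, length(an))
            else min(kp_in[j], length(an))
    grid <- unique(grid)
    pen <- df_penalty(n, length(an), config$ebic_gamma)
    best <- NULL; best_score <- Inf; best_k <- NA_integer_
    for (k in grid) {
      fit <- dc_column_gram(ZtZ, Zty, yty, n, k, tau, gg,
                            config$tol, maxit, pen_mask = pen_mask,
                            ebic_gamma = config$ebic_gamma,
                            cd_tol = config$cd_tol,
                            max_sweeps = config$max_sweeps)
      nz_pen <- sum(fit$support <= length(an))
      score <- n * log(max(fit$rss, 1e-300) / n) + nz_pen * pen
      if (score < best_score - 1e-12) {
        best_score <- score; best <- fit; best_k <- k
      }
    }
    kp_used[j] <- best_k
    coef <- best$coef
    U[an, j] <- coef[seq_along(an)]
    W[iv, j] <- coef[length(an) + seq_along(iv)]
  }
  list(U_hat = U, W_hat = W, kappa_prime = kp_used)
}
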