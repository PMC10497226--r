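#' Learn the ancestral relation graph from data
#'
#' Runs the nodewise l0/DC regressions ([fit_V()]) and the peeling
#' algorithm ([peel()]); optionally estimates the coefficient matrices
#' on the recovered graph ([estimate_coefficients()]).
#'
#' @param data A dataset object.
#' @param config A [tuning_config()].
#' @param fallback Passed to [peel()].
#' @param estimate Also estimate `(U, W)` given the recovered graph.
#' @param kappa_grid_u Sparsity grid for the coefficient step.
#' @return List of class `peeldag_learn`: `v` (the [fit_V()] result),
#'   `arg`, `trace`, and (when `estimate`) `U_hat`, `W_hat`,
#'   `kappa_prime`.
#' @export
learn_structure <- function(data, config = tuning_config(),
                            fallback = c("error", "greedy"),
                            estimate = FALSE, kappa_grid_u = 1:5) {
  fallback <- match.arg(fallback)
  v <- fit_V(data, config)
  peeled <- peel(v$V_hat, fallback = fallback)
  out <- list(v = v, arg = peeled$arg, trace = peeled$trace)
  if (estimate) {
    est <- estimate_coefficients(data, peeled$arg, kappa_grid = kappa_grid_u,
                                 config = config)
    out <- c(out, est)
  }
  structure(out, class = "peeldag_learn")
}

#' @export
print.peeldag_learn <- function(x, ...) {
  print(x$arg)
  invisible(x)
}

dof_error <- function(msg) {
  stop(structure(class = c("peeldag_dof_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## Z-column indices for a node's regressor set: ancestors as Y columns,
## interventions offset by p.
node_regressors <- function(j, s_edges, cand_edges, p) {
  pa <- s_edges[s_edges[, 2L] == j, 1L]
  iv <- cand_edges[cand_edges[, 2L] == j, 1L]
  c(pa, p + iv)
}

rss_of <- function(Z, cols, y) {
  if (length(cols) == 0L) return(sum(y^2))
  sum(qr.resid(qr(Z[, cols, drop = FALSE]), y)^2)
}

#' Build the testing context for a hypothesis
#'
#' Forms the testing graph (ancestral edges plus the nondegenerate
#' hypothesized edges, with the candidate intervention edges), each
#' node's regressor set, the reduced set with hypothesized parents
#' removed, and the residual-variance estimates
#' `sigma2_hat[j] = RSS_j / (n - #regressors(j))` from the full fit.
#'
#' @param data A dataset object.
#' @param arg An [ancestral_graph()] (estimated or oracle).
#' @param h A [hypothesis_spec()]; must be nondegenerate and regular
#'   with respect to `arg`.
#' @return List of class `test_context`.
#' @export
build_context <- function(data, arg, h) {
  stopifnot(inherits(data, "peeldag_data"))
  cls <- classify_hypothesis(h, arg)
  if (cls$degenerate) stop("build_context: hypothesis is degenerate")
  if (!cls$regular) stop("build_context: hypothesis is irregular")
  p <- data$p; q <- data$q; n <- data$n
  D <- cls$nondegenerate_edges
  s_edges <- unique_edges(rbind(arg$ancestral_edges, D))
  ce <- arg$candidate_intervention_edges
  Z <- cbind(data$Y, data$X)
  A <- lapply(seq_len(p), node_regressors, s_edges = s_edges,
              cand_edges = ce, p = p)
  D_of <- lapply(seq_len(p), function(j) D[D[, 2L] == j, 1L])
  contributing <- which(lengths(D_of) > 0L)
  B <- A
  for (j in contributing) B[[j]] <- setdiff(A[[j]], D_of[[j]])
  sigma2 <- numeric(p)
  rss_full <- numeric(p)
  for (j in seq_len(p)) {
    cols <- A[[j]]
    if (n - length(cols) < 1L) {
      dof_error(sprintf("node %d: %d regressors leave no residual degrees of freedom (n = %d)",
                        j, length(cols), n))
    }
    if (length(cols) > 0L) {
      qrj <- qr(Z[, cols, drop = FALSE])
      if (qrj$rank < length(cols)) {
        warning(sprintf("build_context: exact collinearity in regressors of node %d; pseudo-inverse projection used", j))
      }
      rss_full[j] <- sum(qr.resid(qrj, data$Y[, j])^2)
    } else {
      rss_full[j] <- sum(data$Y[, j]^2)
    }
    sigma2[j] <- rss_full[j] / (n - length(cols))
    if (j %in% contributing && sigma2[j] <= 0) {
      dof_error(sprintf("node %d: perfect fit leaves a zero variance estimate", j))
    }
  }
  structure(list(p = p, q = q, n = n, arg = arg, h = h,
                 classification = cls, s_edges = s_edges,
                 A = A, B = B, D = D_of, contributing = contributing,
                 sigma2_hat = sigma2, rss_full = rss_full),
            class = "test_context")
}

#' Likelihood ratio for the hypothesized edges
#'
#' Sums, over the nodes carrying nondegenerate hypothesized edges, the
#' scaled reduction in residual sum of squares when the hypothesized
#' parents are added back. Two algebraically identical computations are
#' provided: `"rss"` refits the restricted and full models and differences
#' their RSS; `"projection"` takes the squared norm of the difference of
#' the two projections of `Y_j` directly.
#'
#' @param ctx A [build_context()] result.
#' @param data The dataset used to build `ctx`.
#' @param form `"rss"` or `"projection"`.
#' @return The likelihood ratio (nonnegative up to rounding), with the
#'   per-node contributions as attribute `"by_node"`.
#' @export
likelihood_ratio <- function(ctx, data, form = c("rss", "projection")) {
  form <- match.arg(form)
  Z <- cbind(data$Y, data$X)
  n <- ctx$n
  by_node <- numeric(0)
  for (j in ctx$contributing) {
    y <- data$Y[, j]
    if (form == "rss") {
      num <- rss_of(Z, ctx$B[[j]], y) - rss_of(Z, ctx$A[[j]], y)
      lr_j <- num / (2 * ctx$sigma2_hat[j])
    } else {
      qa <- qr(Z[, ctx$A[[j]], drop = FALSE])
      fa <- qr.fitted(qa, y)
      fb <- if (length(ctx$B[[j]]) > 0L) {
        qr.fitted(qr(Z[, ctx$B[[j]], drop = FALSE]), y)
      } else rep(0, n)
      num <- sum((fa - fb)^2)
      lr_j <- num / (2 * sum((y - fa)^2) / (n - length(ctx$A[[j]])))
    }
    by_node <- c(by_node, stats::setNames(lr_j, j))
  }
  structure(sum(by_node), by_node = by_node)
}

## Per-sub-hypothesis likelihood ratio for pathway tests: same testing
## graph, but only the nu-th hypothesized parent is removed.
likelihood_ratio_nu <- function(ctx, data) {
  Z <- cbind(data$Y, data$X)
  edges <- ctx$classification$nondegenerate_edges
  vapply(seq_len(nrow(edges)), function(nu) {
    k <- edges[nu, 1L]; j <- edges[nu, 2L]
    y <- data$Y[, j]
    rss_a <- rss_of(Z, ctx$A[[j]], y)
    rss_b <- rss_of(Z, setdiff(ctx$A[[j]], k), y)
    (rss_b - rss_a) / (2 * ctx$sigma2_hat[j])
  }, numeric(1))
}

## Draw the perturbation matrix e*: rows iid N(0, Diag(sigma2_hat)).
draw_perturbation <- function(n, sigma2_hat, seed) {
  set.seed(seed)
  matrix(rnorm(n * length(sigma2_hat)), n) %*%
    diag(sqrt(sigma2_hat), length(sigma2_hat))
}

#' One data-perturbation replicate
#'
#' Adds known Gaussian noise `e*` (rows `N(0, Diag(sigma2_hat))`) to
#' `Y`, re-runs structure learning on the perturbed data warm-started
#' from the reference fit with the reference tuning, and recomputes the
#' likelihood-ratio statistic from `e*` itself on the perturbed
#' regressor sets (the hypothesized-edge index set is held fixed at the
#' unperturbed estimate). The replicate is valid when the re-estimated
#' graph contains the reference graph.
#'
#' @param data A dataset object.
#' @param ctx The unperturbed [build_context()].
#' @param ref_learn The unperturbed [learn_structure()] result.
#' @param config The [tuning_config()] used for learning.
#' @param seed Integer seed for this replicate.
#' @param mode `"edge"` (scalar statistic, ARG superset validity) or
#'   `"pathway"` (per-sub-hypothesis statistics, testing-graph superset
#'   validity).
#' @param e_star Optional perturbation matrix override (testing hook).
#' @return List with `valid`, `lr_star`, and `reason` when invalid.
#' @export
dp_replicate <- function(data, ctx, ref_learn, config, seed,
                         mode = c("edge", "pathway"), e_star = NULL) {
  mode <- match.arg(mode)
  n <- ctx$n; p <- ctx$p
  if (is.null(e_star)) e_star <- draw_perturbation(n, ctx$sigma2_hat, seed)
  vstar <- refit_V(ref_learn$v, data$X, data$Y + e_star, config)
  peeled <- tryCatch(peel(vstar$V_hat, fallback = "error"),
                     peeldag_no_leaf = function(e) NULL)
  if (is.null(peeled)) {
    return(list(valid = FALSE, lr_star = NA_real_, reason = "no_leaf"))
  }
  argstar <- peeled$arg
  arg <- ctx$arg
  D <- ctx$classification$nondegenerate_edges
  cover_cand <- edge_set_contains(argstar$candidate_intervention_edges,
                                  arg$candidate_intervention_edges, p)
  cover_anc <- if (mode == "edge") {
    edge_set_contains(argstar$ancestral_edges, arg$ancestral_edges, p)
  } else {
    edge_set_contains(unique_edges(rbind(argstar$ancestral_edges, D)),
                      unique_edges(rbind(arg$ancestral_edges, D)), p)
  }
  if (!(cover_anc && cover_cand)) {
    return(list(valid = FALSE, lr_star = NA_real_, reason = "not_superset"))
  }
  s_star <- unique_edges(rbind(argstar$ancestral_edges, D))
  Z_star <- cbind(data$Y + e_star, data$X)
  lr_parts <- function(j, drop_cols) {
    a_cols <- node_regressors(j, s_star, argstar$candidate_intervention_edges, p)
    if (n - length(a_cols) < 1L) return(NA_real_)
    b_cols <- setdiff(a_cols, drop_cols)
    e_j <- e_star[, j]
    qa <- qr(Z_star[, a_cols, drop = FALSE])
    fa <- qr.fitted(qa, e_j)
    fb <- if (length(b_cols) > 0L) {
      qr.fitted(qr(Z_star[, b_cols, drop = FALSE]), e_j)
    } else rep(0, n)
    den <- 2 * sum((e_j - fa)^2) / (n - length(a_cols))
    if (den <= 0) return(NA_real_)
    sum((fa - fb)^2) / den
  }
  if (mode == "edge") {
    vals <- vapply(ctx$contributing, function(j) lr_parts(j, ctx$D[[j]]),
                   numeric(1))
    if (anyNA(vals)) {
      return(list(valid = FALSE, lr_star = NA_real_, reason = "degenerate_fit"))
    }
    list(valid = TRUE, lr_star = sum(vals))
  } else {
    edges <- D
    vals <- vapply(seq_len(nrow(edges)), function(nu) {
      lr_parts(edges[nu, 2L], edges[nu, 1L])
    }, numeric(1))
    if (anyNA(vals)) {
      return(list(valid = FALSE, lr_star = NA_real_, reason = "degenerate_fit"))
    }
    list(valid = TRUE, lr_star = vals)
  }
}

#' Data-perturbation p-value for an edge test
#'
#' The p-value is the fraction of valid replicates whose perturbation
#' statistic is at least the observed one.
#'
#' @param lr Observed likelihood ratio.
#' @param replicates List of [dp_replicate()] results.
#' @return List with `pvalue`, `M_total`, `M_valid`.
#' @export
dp_pvalue_edges <- function(lr, replicates) {
  valid <- vapply(replicates, function(r) isTRUE(r$valid), logical(1))
  if (!any(valid)) {
    stop(structure(class = c("peeldag_no_valid_replicates", "error",
                             "condition"),
                   list(message = "no valid data-perturbation replicates",
                        call = sys.call(-1))))
  }
  lr_star <- vapply(replicates[valid], function(r) r$lr_star, numeric(1))
  list(pvalue = mean(lr_star >= lr), M_total = length(replicates),
       M_valid = sum(valid))
}

#' Asymptotic reference p-value for an edge test
#'
#' Twice the likelihood ratio is referred to its limiting chi-squared
#' law with degrees of freedom equal to the number of nondegenerate
#' hypothesized edges; for many edges the normal approximation
#' `(2 Lr - d)/sqrt(2 d)` is used instead (`regime = "auto"` switches at
#' `d > 50`).
#'
#' @param lr Observed likelihood ratio.
#' @param d_size Number of nondegenerate hypothesized edges.
#' @param regime `"auto"`, `"fixed"` (chi-squared) or `"large"` (normal).
#' @return Upper-tail p-value.
#' @export
asymptotic_pvalue <- function(lr, d_size, regime = c("auto", "fixed", "large")) {
  regime <- match.arg(regime)
  stopifnot(d_size >= 1)
  if (regime == "auto") regime <- if (d_size > 50) "large" else "fixed"
  if (regime == "fixed") {
    pchisq(2 * lr, df = d_size, lower.tail = FALSE)
  } else {
    pnorm((2 * lr - d_size) / sqrt(2 * d_size), lower.tail = FALSE)
  }
}

#' Configuration for hypothesis tests
#'
#' @param M Number of data-perturbation replicates.
#' @param alpha Nominal significance level.
#' @param method `"dp"` (data perturbation), `"asymptotic"` (chi-squared
#'   reference on the estimated graph), or `"oracle"` (chi-squared
#'   reference on a user-supplied true graph).
#' @param seed Integer seed driving all randomness of the test.
#' @param tuning A [tuning_config()] for the learning steps.
#' @param oracle_graph An [intervention_dag()] or [sem_parameters()]
#'   (required for `method = "oracle"`).
#' @param fallback Passed to [peel()].
#' @return List of class `test_config`.
#' @export
test_config <- function(M = 1000, alpha = 0.05,
                        method = c("dp", "asymptotic", "oracle"),
                        seed = 1L, tuning = tuning_config(),
                        oracle_graph = NULL,
                        fallback = c("error", "greedy")) {
  structure(list(M = as.integer(M), alpha = alpha,
                 method = match.arg(method), seed = as.integer(seed),
                 tuning = tuning, oracle_graph = oracle_graph,
                 fallback = match.arg(fallback)),
            class = "test_config")
}

new_report <- function(pvalue, lr, method, mode, classification,
                       M_total = 0L, M_valid = 0L, per_edge = NULL,
                       alpha = 0.05, seed = NA_integer_, arg = NULL) {
  structure(list(pvalue = pvalue, lr = lr, method = method, mode = mode,
                 classification = classification,
                 M_total = M_total, M_valid = M_valid,
                 per_edge = per_edge, alpha = alpha, seed = seed,
                 arg = arg, reject = isTRUE(pvalue < alpha)),
            class = "dp_test_report")
}

#' @export
print.dp_test_report <- function(x, ...) {
  lab <- if (x$classification$degenerate) "degenerate"
         else if (!x$classification$regular) "irregular"
         else "regular"
  cat(sprintf("%s test (%s): p-value = %.4g [%s]\n",
              x$mode, x$method, x$pvalue, lab))
  if (x$M_total > 0L) {
    cat(sprintf("  Lr = %.4g; %d/%d valid perturbation replicates\n",
                sum(x$lr), x$M_valid, x$M_total))
  }
  invisible(x)
}

## Shared: estimated or oracle graph for a test.
test_graph <- function(data, config) {
  if (config$method == "oracle") {
    g <- config$oracle_graph
    if (inherits(g, "sem_parameters")) g <- dag_of_parameters(g)
    if (!inherits(g, "intervention_dag")) {
      stop("method = 'oracle' needs an oracle_graph (intervention_dag or sem_parameters)")
    }
    list(arg = arg_of_dag(g), learn = NULL)
  } else {
    learn <- learn_structure(data, config$tuning, fallback = config$fallback)
    list(arg = learn$arg, learn = learn)
  }
}

## DP machinery for one regular nondegenerate edge hypothesis.
dp_edge_test <- function(data, ctx, learn, config, seed_offset = 0L) {
  lr <- as.numeric(likelihood_ratio(ctx, data, form = "rss"))
  reps <- lapply(seq_len(config$M), function(m) {
    dp_replicate(data, ctx, learn, config$tuning,
                 seed = mix_seed(config$seed, 1000L + seed_offset + m),
                 mode = "edge")
  })
  pv <- dp_pvalue_edges(lr, reps)
  list(lr = lr, pvalue = pv$pvalue, M_total = pv$M_total,
       M_valid = pv$M_valid)
}

#' Data-perturbation p-value for a directed pathway
#'
#' Convenience wrapper around [test_edges()] for pathway hypotheses: the
#' p-value is the maximum of the per-link valid-replicate fractions, and
#' it is exactly 1 when any link is degenerate against the learned
#' ancestral relations (or the pathway is irregular).
#'
#' @param data A dataset object.
#' @param h A [hypothesis_spec()] with `mode = "pathway"` (an edge-mode
#'   spec is re-interpreted as a pathway).
#' @param M Number of perturbation replicates.
#' @param seed Integer seed.
#' @param config Optional [test_config()] overriding `M` and `seed`.
#' @return A `dp_test_report`.
#' @export
dp_pvalue_pathway <- function(data, h, M = 1000, seed = 1L,
                              config = test_config(M = M, seed = seed)) {
  if (h$mode != "pathway") h <- hypothesis_spec(h$edges, mode = "pathway")
  test_edges(data, h, config)
}

#' Test hypothesized directed edges or a directed pathway
#'
#' Full pipeline: learn the ancestral relation graph (or take the
#' oracle graph), classify the hypothesis, and compute the p-value.
#' Degenerate hypotheses (every hypothesized edge closes a cycle with
#' the ancestral relations) have p-value exactly 1. Irregular edge
#' hypotheses are decomposed into single-edge sub-hypotheses that are
#' tested separately and combined by the Holm correction, reporting the
#' adjusted minimum. Irregular pathway hypotheses have p-value 1.
#'
#' @param data A dataset object.
#' @param h A [hypothesis_spec()].
#' @param config A [test_config()].
#' @return A report of class `dp_test_report`.
#' @export
test_edges <- function(data, h, config = test_config()) {
  stopifnot(inherits(h, "hypothesis_spec"))
  tg <- test_graph(data, config)
  arg <- tg$arg
  cls <- classify_hypothesis(h, arg)
  base <- function(pvalue, lr = 0, ...) {
    new_report(pvalue, lr, config$method, h$mode, cls,
               alpha = config$alpha, seed = config$seed, arg = arg, ...)
  }
  if (h$mode == "pathway") {
    if (cls$degenerate || nrow(cls$nondegenerate_edges) < nrow(h$edges) ||
        !cls$regular) {
      return(base(1))
    }
    ctx <- build_context(data, arg, h)
    lr_nu <- likelihood_ratio_nu(ctx, data)
    if (config$method %in% c("asymptotic", "oracle")) {
      pv <- max(vapply(lr_nu, asymptotic_pvalue, numeric(1), d_size = 1))
      return(base(pv, lr = lr_nu))
    }
    reps <- lapply(seq_len(config$M), function(m) {
      dp_replicate(data, ctx, tg$learn, config$tuning,
                   seed = mix_seed(config$seed, 1000L + m), mode = "pathway")
    })
    valid <- vapply(reps, function(r) isTRUE(r$valid), logical(1))
    if (!any(valid)) {
      stop(structure(class = c("peeldag_no_valid_replicates", "error",
                               "condition"),
                     list(message = "no valid data-perturbation replicates",
                          call = sys.call())))
    }
    stars <- do.call(rbind, lapply(reps[valid], function(r) r$lr_star))
    ratios <- vapply(seq_along(lr_nu), function(nu) {
      mean(stars[, nu] >= lr_nu[nu])
    }, numeric(1))
    return(base(max(ratios), lr = lr_nu,
                M_total = length(reps), M_valid = sum(valid)))
  }
  # edge mode
  if (cls$degenerate) return(base(1))
  if (cls$regular) {
    ctx <- build_context(data, arg, h)
    if (config$method %in% c("asymptotic", "oracle")) {
      lr <- as.numeric(likelihood_ratio(ctx, data, form = "rss"))
      return(base(asymptotic_pvalue(lr, nrow(cls$nondegenerate_edges)),
                  lr = lr))
    }
    res <- dp_edge_test(data, ctx, tg$learn, config)
    return(base(res$pvalue, lr = res$lr,
                M_total = res$M_total, M_valid = res$M_valid))
  }
  # irregular: decompose into single edges, Holm-adjust
  edges <- h$edges
  raw <- rep(NA_real_, nrow(edges))
  lrs <- rep(NA_real_, nrow(edges))
  for (nu in seq_len(nrow(edges))) {
    h_nu <- hypothesis_spec(edges[nu, , drop = FALSE], mode = "edge")
    cls_nu <- classify_hypothesis(h_nu, arg)
    if (cls_nu$degenerate) {
      raw[nu] <- 1; lrs[nu] <- 0
    } else {
      ctx_nu <- build_context(data, arg, h_nu)
      if (config$method %in% c("asymptotic", "oracle")) {
        lrs[nu] <- as.numeric(likelihood_ratio(ctx_nu, data, form = "rss"))
        raw[nu] <- asymptotic_pvalue(lrs[nu], 1)
      } else {
        res <- dp_edge_test(data, ctx_nu, tg$learn, config,
                            seed_offset = 100000L * nu)
        raw[nu] <- res$pvalue; lrs[nu] <- res$lr
      }
    }
  }
  adj <- p.adjust(raw, method = "holm")
  per_edge <- data.frame(from = edges[, 1L], to = edges[, 2L],
                         lr = lrs, pvalue = raw, pvalue_holm = adj)
  base(min(adj), lr = sum(lrs), per_edge = per_edge,
       M_total = if (config$method == "dp") config$M else 0L)
}
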