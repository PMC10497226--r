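#' Structural Hamming distance between coefficient supports
#'
#' Counts the entries on which the supports of two matrices disagree.
#'
#' @param U_hat,U_true Matrices of the same shape.
#' @return Integer count.
#' @export
shd <- function(U_hat, U_true) {
  if (!all(dim(U_hat) == dim(U_true))) stop("shd: shape mismatch")
  sum((U_hat != 0) != (U_true != 0))
}

#' Monte-Carlo scenario for the simulation designs
#'
#' Each replicate draws a fresh graph (for `graph = "random"`), forces
#' the hypothesized edge coefficients to the cell's signal value (0
#' under the null), simulates data, and runs the requested tests.
#'
#' @param graph `"random"` or `"hub"`.
#' @param setup Intervention setup `"A"`, `"B"` or `"C"`.
#' @param p,q Dimensions.
#' @param n_grid Sample sizes to sweep.
#' @param signal_grid Hypothesized-edge coefficient values (0 = null).
#' @param hypothesis A [hypothesis_spec()].
#' @param methods Character subset of `dp`, `asymptotic`, `oracle`.
#' @param replicates Monte-Carlo replicates per cell.
#' @param M Data-perturbation replicates per test.
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @param tuning A [tuning_config()].
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(graph = "random", setup = "A", p, q,
                          n_grid, signal_grid = 0, hypothesis,
                          methods = "dp", replicates = 200, M = 200,
                          alpha = 0.05, seed = 1L,
                          tuning = tuning_config()) {
  stopifnot(alpha > 0, alpha < 1, all(n_grid >= 1), replicates >= 1,
            inherits(hypothesis, "hypothesis_spec"))
  structure(list(graph = graph, setup = setup, p = as.integer(p),
                 q = as.integer(q), n_grid = as.integer(n_grid),
                 signal_grid = signal_grid, hypothesis = hypothesis,
                 methods = methods, replicates = as.integer(replicates),
                 M = as.integer(M), alpha = alpha, seed = as.integer(seed),
                 tuning = tuning),
            class = "scenario_spec")
}

## Truth for one replicate of a scenario cell: fresh graph, hypothesized
## edges forced to `signal`.
scenario_truth <- function(spec, signal, rep_seed) {
  U <- if (spec$graph == "random") random_graph_U(spec$p, rep_seed)
       else hub_graph_U(spec$p)
  U[spec$hypothesis$edges] <- signal
  sem_parameters(U, intervention_W(spec$setup, spec$p, spec$q))
}

#' Empirical rejection rates over a scenario grid
#'
#' For each `(n, signal, method)` cell, simulates `replicates` data sets,
#' runs the test, and records the rejection indicator at the nominal
#' level. Per-replicate failures are recorded (with their message), not
#' fatal. Fully seeded: results do not depend on evaluation order.
#'
#' @param spec A [scenario_spec()].
#' @return List with `results` (one row per replicate per cell) and
#'   `summary` (per-cell rates with binomial standard errors).
#' @export
rejection_rate <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  rows <- list()
  for (n in spec$n_grid) for (sig in spec$signal_grid) {
    for (r in seq_len(spec$replicates)) {
      cell_seed <- mix_seed(spec$seed, 7L * n + round(1000 * sig))
      truth <- scenario_truth(spec, sig, mix_seed(cell_seed, 3L * r))
      data <- sample_dataset(truth, n, seed = mix_seed(cell_seed, 3L * r + 1L))
      for (method in spec$methods) {
        cfg <- test_config(M = spec$M, alpha = spec$alpha, method = method,
                           seed = mix_seed(cell_seed, 3L * r + 2L),
                           tuning = spec$tuning, oracle_graph = truth)
        res <- tryCatch(test_edges(data, spec$hypothesis, cfg),
                        error = function(e) e)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, signal = sig, method = method, replicate = r,
          pvalue = if (inherits(res, "error")) NA_real_ else res$pvalue,
          reject = if (inherits(res, "error")) NA else res$reject,
          error = if (inherits(res, "error")) conditionMessage(res)
                  else NA_character_)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(results, interaction(results$n, results$signal, results$method,
                               drop = TRUE)),
    function(d) {
      ok <- !is.na(d$reject)
      rate <- mean(d$reject[ok])
      data.frame(n = d$n[1], signal = d$signal[1], method = d$method[1],
                 replicates = sum(ok), failures = sum(!ok), rate = rate,
                 se = sqrt(rate * (1 - rate) / max(sum(ok), 1)))
    }))
  rownames(agg) <- NULL
  list(results = results, summary = agg)
}

#' Frequency of information-criterion sparsity choices
#'
#' For each replicate, simulates the scenario under its first signal
#' value and records the per-node sparsity bound selected for the
#' nodewise reduced-form regressions over `kappa_grid`.
#'
#' @param spec A [scenario_spec()] (the first `n_grid` and `signal_grid`
#'   entries define the cell).
#' @param kappa_grid Integer candidates.
#' @param nodes Nodes to record (default all).
#' @return List with `choices` (`replicates x length(nodes)` matrix),
#'   `freq` (relative frequency of each candidate over all recorded
#'   choices), and `freq_by_node`.
#' @export
selection_frequency <- function(spec, kappa_grid = 1:5,
                                nodes = seq_len(spec$p)) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_grid[1]; sig <- spec$signal_grid[1]
  cfg <- spec$tuning
  cfg["kappa"] <- list(NULL)     # keep the element; avoid partial matching
  cfg$kappa_grid <- kappa_grid
  choices <- matrix(NA_integer_, spec$replicates, length(nodes),
                    dimnames = list(NULL, paste0("Y", nodes)))
  for (r in seq_len(spec$replicates)) {
    truth <- scenario_truth(spec, sig, mix_seed(spec$seed, 31L * r))
    data <- sample_dataset(truth, n, seed = mix_seed(spec$seed, 31L * r + 1L))
    v <- fit_V(data, cfg)
    choices[r, ] <- v$kappa[nodes]
  }
  all_counts <- table(factor(choices, levels = kappa_grid))
  by_node <- apply(choices, 2, function(x)
    table(factor(x, levels = kappa_grid)) / length(x))
  list(choices = choices,
       freq = as.numeric(all_counts) / sum(all_counts),
       kappa_grid = kappa_grid,
       freq_by_node = by_node)
}
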