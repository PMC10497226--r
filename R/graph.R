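#' @useDynLib peeldag, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rbinom pchisq pnorm p.adjust sd setNames
#' @importFrom utils read.table write.table
"_PACKAGE"

## Edge sets are integer matrices with two columns (from, to), 1-based.
## An empty edge set is a 0 x 2 integer matrix.

edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      (!is.matrix(edges) && length(edges) == 0L)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) as.integer(e[1:2])))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.vector(edges) && length(edges) == 2L) edges <- matrix(edges, ncol = 2L)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L) stop("an edge set needs exactly two columns (from, to)")
  dimnames(edges) <- list(NULL, c("from", "to"))
  edges
}

edge_key <- function(edges, p) {
  edges <- edge_matrix(edges)
  (edges[, 1L] - 1L) * p + edges[, 2L]
}

edge_set_equal <- function(a, b, p) {
  setequal(edge_key(a, p), edge_key(b, p))
}

edge_set_contains <- function(a, b, p) {
  # does a contain b?
  all(edge_key(b, p) %in% edge_key(a, p))
}

sort_edges <- function(edges) {
  edges <- edge_matrix(edges)
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

check_edge_indices <- function(edges, max_from, max_to, what) {
  edges <- edge_matrix(edges)
  if (nrow(edges) == 0L) return(edges)
  if (anyNA(edges)) stop(what, ": missing edge indices")
  if (any(edges[, 1L] < 1L) || any(edges[, 1L] > max_from) ||
      any(edges[, 2L] < 1L) || any(edges[, 2L] > max_to)) {
    stop(what, ": edge index out of range")
  }
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) {
    stop(what, ": duplicate edges")
  }
  edges
}

#' Test whether a directed graph is acyclic
#'
#' Cycle detection by Kahn-style topological sort with deterministic
#' (ascending-index) node ordering.
#'
#' @param edges Two-column matrix of directed edges `(from, to)`, 1-based.
#' @param p Number of nodes.
#' @return `TRUE` if the graph has no directed cycle.
#' @export
is_acyclic <- function(edges, p) {
  edges <- edge_matrix(edges)
  if (nrow(edges) > 0L &&
      (any(edges < 1L) || any(edges > p))) {
    stop("is_acyclic: edge index out of range")
  }
  length(topological_order(edges, p)) == p
}

## Kahn topological sort; returns the order found (length < p when cyclic).
topological_order <- function(edges, p) {
  edges <- edge_matrix(edges)
  indeg <- tabulate(edges[, 2L], nbins = p)
  out <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(p)))
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready) > 0L) {
    v <- ready[1L]                      # ascending index: `which` is sorted
    ready <- ready[-1L]
    order <- c(order, v)
    ch <- out[[v]]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- sort(c(ready, w))
    }
  }
  order
}

#' Transitive closure of an acyclic edge set
#'
#' Returns every ordered pair `(k, j)` such that a directed path from `k`
#' to `j` exists.
#'
#' @inheritParams is_acyclic
#' @return Two-column matrix of ancestral pairs, sorted.
#' @export
transitive_closure <- function(edges, p) {
  edges <- edge_matrix(edges)
  if (!is_acyclic(edges, p)) stop("transitive_closure: input graph is cyclic")
  adj <- matrix(FALSE, p, p)
  adj[edges] <- TRUE
  reach <- adj
  # process in reverse topological order so each node's reach is final
  ord <- topological_order(edges, p)
  for (v in rev(ord)) {
    ch <- which(adj[v, ])
    if (length(ch) > 0L) {
      reach[v, ] <- adj[v, ] | (colSums(reach[ch, , drop = FALSE]) > 0L)
    }
  }
  sort_edges(which(reach, arr.ind = TRUE)[, c(1L, 2L), drop = FALSE])
}

#' Construct an intervention DAG
#'
#' A DAG over `p` primary variables and `q` intervention variables, with
#' primary edges `Y_k -> Y_j` and intervention edges `X_l -> Y_j`. Edges
#' from primary to intervention variables are unrepresentable. The pair
#' `(k, j)` always means `k -> j`; the coefficient convention is that
#' `U[k, j]` weights `Y_k` in the equation for `Y_j`.
#'
#' @param p,q Counts of primary and intervention variables.
#' @param primary_edges Two-column matrix of `(k, j)` pairs among `1..p`.
#' @param intervention_edges Two-column matrix of `(l, j)` pairs,
#'   `l` in `1..q`, `j` in `1..p`.
#' @return An object of class `intervention_dag`.
#' @export
intervention_dag <- function(p, q, primary_edges = NULL,
                             intervention_edges = NULL) {
  p <- as.integer(p); q <- as.integer(q)
  stopifnot(p >= 1L, q >= 0L)
  pe <- check_edge_indices(primary_edges, p, p, "primary_edges")
  if (nrow(pe) > 0L && any(pe[, 1L] == pe[, 2L])) {
    stop("primary_edges: self-loops are not allowed")
  }
  ie <- check_edge_indices(intervention_edges, q, p, "intervention_edges")
  if (!is_acyclic(pe, p)) stop("primary_edges contain a directed cycle")
  structure(list(p = p, q = q,
                 primary_edges = sort_edges(pe),
                 intervention_edges = sort_edges(ie)),
            class = "intervention_dag")
}

#' @export
print.intervention_dag <- function(x, ...) {
  cat(sprintf("Intervention DAG: p = %d primary, q = %d intervention variables\n",
              x$p, x$q))
  cat(sprintf("  %d primary edges, %d intervention edges\n",
              nrow(x$primary_edges), nrow(x$intervention_edges)))
  invisible(x)
}

#' Construct an ancestral relation graph (ARG)
#'
#' The ARG holds all ancestral pairs among primary variables (the
#' transitive closure of the primary edges) together with candidate
#' intervention edges: `(l, j)` when `X_l` intervenes on `Y_j` or on an
#' ancestor of `Y_j`.
#'
#' @param p,q Counts of primary and intervention variables.
#' @param ancestral_edges Two-column matrix; must be acyclic and
#'   transitively closed.
#' @param candidate_intervention_edges Two-column matrix of `(l, j)` pairs.
#' @return An object of class `ancestral_graph`.
#' @export
ancestral_graph <- function(p, q, ancestral_edges = NULL,
                            candidate_intervention_edges = NULL) {
  p <- as.integer(p); q <- as.integer(q)
  ae <- check_edge_indices(ancestral_edges, p, p, "ancestral_edges")
  ce <- check_edge_indices(candidate_intervention_edges, q, p,
                           "candidate_intervention_edges")
  if (!is_acyclic(ae, p)) stop("ancestral_edges contain a directed cycle")
  if (!edge_set_equal(transitive_closure(ae, p), ae, p)) {
    stop("ancestral_edges are not transitively closed")
  }
  structure(list(p = p, q = q,
                 ancestral_edges = sort_edges(ae),
                 candidate_intervention_edges = sort_edges(ce)),
            class = "ancestral_graph")
}

#' @export
print.ancestral_graph <- function(x, ...) {
  cat(sprintf("Ancestral relation graph: p = %d, q = %d\n", x$p, x$q))
  cat(sprintf("  %d ancestral pairs, %d candidate intervention edges\n",
              nrow(x$ancestral_edges), nrow(x$candidate_intervention_edges)))
  invisible(x)
}

#' Derive the ARG of an intervention DAG
#'
#' Ancestral edges are the transitive closure of the primary edges; a
#' candidate intervention edge `(l, j)` is present when `X_l` intervenes
#' on `Y_j` itself or on any ancestor of `Y_j`.
#'
#' @param g An [intervention_dag()].
#' @return An [ancestral_graph()].
#' @export
arg_of_dag <- function(g) {
  stopifnot(inherits(g, "intervention_dag"))
  p <- g$p; q <- g$q
  anc <- transitive_closure(g$primary_edges, p)
  # ancestors-of list per node, including the node itself
  anc_of <- lapply(seq_len(p), function(j) {
    c(j, anc[anc[, 2L] == j, 1L])
  })
  ie <- g$intervention_edges
  ce <- matrix(integer(0), ncol = 2L)
  if (nrow(ie) > 0L) {
    targets_of <- split(ie[, 2L], factor(ie[, 1L], levels = seq_len(q)))
    pairs <- lapply(seq_len(q), function(l) {
      tg <- targets_of[[l]]
      if (length(tg) == 0L) return(NULL)
      hit <- which(vapply(anc_of, function(a) any(tg %in% a), logical(1)))
      cbind(l, hit)
    })
    ce <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
    if (is.null(ce)) ce <- matrix(integer(0), ncol = 2L)
  }
  ancestral_graph(p, q, anc, ce)
}

#' Classify intervention variables as instruments
#'
#' An intervention variable is an instrument when it intervenes on exactly
#' one primary variable; with two or more targets it is an invalid
#' instrument, and with none it is inactive. Also reports whether every
#' primary variable has at least one instrument (the coverage condition
#' required for identifiability).
#'
#' @param g An [intervention_dag()].
#' @return List with `status` (factor of length `q` with levels
#'   `instrument`, `invalid_instrument`, `inactive`), `targets` (list of
#'   target index vectors), and `all_nodes_instrumented` (logical).
#' @export
classify_interventions <- function(g) {
  stopifnot(inherits(g, "intervention_dag"))
  ie <- g$intervention_edges
  targets <- split(ie[, 2L], factor(ie[, 1L], levels = seq_len(g$q)))
  n_targets <- lengths(targets)
  status <- factor(ifelse(n_targets == 1L, "instrument",
                          ifelse(n_targets >= 2L, "invalid_instrument",
                                 "inactive")),
                   levels = c("instrument", "invalid_instrument", "inactive"))
  instrumented <- unique(unlist(targets[n_targets == 1L], use.names = FALSE))
  list(status = status,
       targets = targets,
       all_nodes_instrumented = length(instrumented) == g$p &&
         all(seq_len(g$p) %in% instrumented))
}

#' Specify a hypothesis on directed edges
#'
#' @param edges Two-column matrix of hypothesized `(k, j)` edges among
#'   primary variables (no duplicates, no self-loops). For `mode =
#'   "pathway"` the edges are the consecutive links of a directed pathway.
#' @param mode `"edge"` (simultaneous test of directed edges) or
#'   `"pathway"` (test of a directed pathway).
#' @return An object of class `hypothesis_spec`.
#' @export
hypothesis_spec <- function(edges, mode = c("edge", "pathway")) {
  mode <- match.arg(mode)
  edges <- edge_matrix(edges)
  if (nrow(edges) == 0L) stop("hypothesis_spec: empty edge set")
  if (any(edges[, 1L] == edges[, 2L])) stop("hypothesis_spec: self-loop")
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) {
    stop("hypothesis_spec: duplicate edges")
  }
  structure(list(edges = edges, mode = mode), class = "hypothesis_spec")
}

#' @export
print.hypothesis_spec <- function(x, ...) {
  cat(sprintf("Hypothesis (%s): %s\n", x$mode,
              paste(sprintf("%d->%d", x$edges[, 1L], x$edges[, 2L]),
                    collapse = ", ")))
  invisible(x)
}

#' Classify a hypothesis against an ARG
#'
#' A hypothesized edge `(k, j)` is nondegenerate when adding it to the
#' ancestral edges creates no directed cycle (equivalently, `(j, k)` is
#' not an ancestral pair). The hypothesis is degenerate when no edge is
#' nondegenerate, and regular when the nondegenerate edges jointly with
#' the ancestral edges remain acyclic.
#'
#' @param h A [hypothesis_spec()].
#' @param arg An [ancestral_graph()].
#' @return List with `nondegenerate_edges`, `degenerate`, `regular`.
#' @export
classify_hypothesis <- function(h, arg) {
  stopifnot(inherits(h, "hypothesis_spec"), inherits(arg, "ancestral_graph"))
  p <- arg$p
  if (any(h$edges > p)) stop("classify_hypothesis: hypothesis index out of range")
  anc_key <- edge_key(arg$ancestral_edges, p)
  rev_key <- edge_key(h$edges[, c(2L, 1L), drop = FALSE], p)
  nondeg <- !(rev_key %in% anc_key)
  d_edges <- h$edges[nondeg, , drop = FALSE]
  degenerate <- nrow(d_edges) == 0L
  regular <- if (degenerate) TRUE else {
    is_acyclic(unique_edges(rbind(arg$ancestral_edges, d_edges)), p)
  }
  list(nondegenerate_edges = sort_edges(d_edges),
       degenerate = degenerate,
       regular = regular)
}

unique_edges <- function(edges) {
  edges <- edge_matrix(edges)
  edges[!duplicated(paste(edges[, 1L], edges[, 2L])), , drop = FALSE]
}
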