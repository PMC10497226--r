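# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no stored data.

# Random SEM with continuous weights, one instrument per node plus
# optional extra (possibly multi-target) interventions: satisfies the
# instrument-per-variable coverage condition by construction.
random_sem <- function(p, extra = 0, edge_prob = 0.35, seed = 1) {
  set.seed(seed)
  q <- p + extra
  U <- matrix(0, p, p)
  if (p > 1) {
    up <- which(upper.tri(U))
    sel <- up[runif(length(up)) < edge_prob]
    U[sel] <- runif(length(sel), 0.5, 1.5) * sample(c(-1, 1), length(sel), TRUE)
  }
  W <- matrix(0, q, p)
  W[cbind(seq_len(p), seq_len(p))] <- runif(p, 0.5, 1.5)
  if (extra > 0) {
    for (l in (p + 1):q) {
      tg <- sample(seq_len(p), sample(0:min(3, p), 1))
      if (length(tg) > 0) {
        W[l, tg] <- runif(length(tg), 0.5, 1.5) * sample(c(-1, 1), length(tg), TRUE)
      }
    }
  }
  sem_parameters(U, W, rep(1, p))
}

# Two-node chain Y1 -> Y2 with its own instruments.
chain_sem <- function(beta = 0.8, sigma2 = c(0.5, 1)) {
  U <- matrix(0, 2, 2)
  U[1, 2] <- beta
  sem_parameters(U, diag(2), sigma2)
}

edge_sets_equal <- function(a, b, p) peeldag:::edge_set_equal(a, b, p)

arg_equal <- function(a, b) {
  a$p == b$p && a$q == b$q &&
    edge_sets_equal(a$ancestral_edges, b$ancestral_edges, a$p) &&
    edge_sets_equal(a$candidate_intervention_edges,
                    b$candidate_intervention_edges, a$p)
}

# Independent closure oracle: boolean matrix powers.
closure_by_matrix_power <- function(edges, p) {
  adj <- matrix(FALSE, p, p)
  if (nrow(edges) > 0) adj[edges] <- TRUE
  reach <- matrix(FALSE, p, p)
  pow <- adj
  for (m in seq_len(p)) {
    reach <- reach | pow
    pow <- (pow %*% adj) > 0
  }
  which(reach, arr.ind = TRUE)
}

# Independent DFS cycle detector.
has_cycle_dfs <- function(edges, p) {
  adj <- vector("list", p)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
  }
  state <- integer(p) # 0 new, 1 on stack, 2 done
  found <- FALSE
  visit <- function(v) {
    if (found) return()
    state[v] <<- 1L
    for (w in adj[[v]]) {
      if (state[w] == 1L) { found <<- TRUE; return() }
      if (state[w] == 0L) visit(w)
    }
    state[v] <<- 2L
  }
  for (v in seq_len(p)) if (state[v] == 0L) visit(v)
  found
}
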