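test_that("acyclicity detection matches a DFS oracle", {
  expect_true(is_acyclic(matrix(integer(0), ncol = 2), 3))
  expect_false(is_acyclic(rbind(c(1, 2), c(2, 1)), 2))
  expect_error(is_acyclic(cbind(1, 5), 3), "out of range")
  set.seed(11)
  for (i in 1:50) {
    p <- sample(3:9, 1)
    # random graph, sometimes cyclic
    m <- matrix(runif(p * p) < 0.25, p, p)
    diag(m) <- FALSE
    edges <- which(m, arr.ind = TRUE)
    expect_identical(is_acyclic(edges, p), !has_cycle_dfs(edges, p))
  }
})

test_that("transitive closure matches the matrix-power oracle and is idempotent", {
  expect_equal(transitive_closure(rbind(c(1, 2), c(2, 3)), 3),
               rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
               ignore_attr = TRUE)
  expect_equal(nrow(transitive_closure(matrix(integer(0), ncol = 2), 4)), 0)
  expect_error(transitive_closure(rbind(c(1, 2), c(2, 1)), 2), "cyclic")
  set.seed(7)
  for (i in 1:30) {
    p <- 7
    U <- matrix(0, p, p)
    up <- which(upper.tri(U))
    U[up[runif(length(up)) < 0.3]] <- 1
    edges <- which(U != 0, arr.ind = TRUE)
    cl <- transitive_closure(edges, p)
    expect_true(edge_sets_equal(cl, closure_by_matrix_power(edges, p), p))
    expect_true(edge_sets_equal(transitive_closure(cl, p), cl, p))
  }
})

test_that("the ARG of a DAG holds ancestral pairs and inherited interventions", {
  g <- intervention_dag(2, 2, primary_edges = cbind(1, 2),
                        intervention_edges = rbind(c(1, 1), c(2, 2)))
  a <- arg_of_dag(g)
  expect_true(edge_sets_equal(a$ancestral_edges, cbind(1, 2), 2))
  expect_true(edge_sets_equal(a$candidate_intervention_edges,
                              rbind(c(1, 1), c(1, 2), c(2, 2)), 2))
  g0 <- intervention_dag(2, 1, intervention_edges = cbind(1, 1))
  a0 <- arg_of_dag(g0)
  expect_equal(nrow(a0$ancestral_edges), 0)
  expect_true(edge_sets_equal(a0$candidate_intervention_edges, cbind(1, 1), 2))
})

test_that("the ARG agrees with brute-force path enumeration on random DAGs", {
  for (i in 1:50) {
    pars <- random_sem(p = sample(2:7, 1), extra = sample(0:6, 1), seed = 100 + i)
    g <- dag_of_parameters(pars)
    a <- arg_of_dag(g)
    p <- g$p
    # oracle: ancestors via matrix powers, interventions via union over
    # the ancestral closure including the node itself
    anc <- closure_by_matrix_power(g$primary_edges, p)
    expect_true(edge_sets_equal(a$ancestral_edges, anc, p))
    ce <- NULL
    for (j in seq_len(p)) {
      up <- c(j, anc[anc[, 2] == j, 1])
      rows <- which(rowSums(pars$W[, up, drop = FALSE] != 0) > 0)
      if (length(rows) > 0) ce <- rbind(ce, cbind(rows, j))
    }
    if (is.null(ce)) ce <- matrix(integer(0), ncol = 2)
    expect_true(edge_sets_equal(a$candidate_intervention_edges, ce, p))
    # output invariants
    expect_true(is_acyclic(a$ancestral_edges, p))
    expect_true(edge_sets_equal(transitive_closure(a$ancestral_edges, p),
                                a$ancestral_edges, p))
  }
})

test_that("interventions classify as instruments per their target counts", {
  p <- 3; q <- 8
  gA <- dag_of_parameters(sem_parameters(matrix(0, p, p),
                                         intervention_W("A", p, q)))
  cA <- classify_interventions(gA)
  expect_equal(as.character(cA$status),
               c(rep("instrument", 3), rep("invalid_instrument", 2),
                 rep("inactive", 3)))
  expect_true(cA$all_nodes_instrumented)
  gB <- dag_of_parameters(sem_parameters(matrix(0, p, p),
                                         intervention_W("B", p, q)))
  cB <- classify_interventions(gB)
  expect_equal(which(cB$status == "instrument"), 3L)
  expect_false(cB$all_nodes_instrumented)
  g0 <- dag_of_parameters(sem_parameters(matrix(0, p, p), matrix(0, q, p)))
  expect_true(all(classify_interventions(g0)$status == "inactive"))
})

test_that("hypothesis classification finds nondegenerate edges and regularity", {
  arg1 <- ancestral_graph(3, 0, ancestral_edges = cbind(1, 2))
  cls <- classify_hypothesis(hypothesis_spec(cbind(2, 1)), arg1)
  expect_true(cls$degenerate)
  expect_true(cls$regular)          # empty set adds no cycle
  expect_equal(nrow(cls$nondegenerate_edges), 0)

  cls2 <- classify_hypothesis(hypothesis_spec(cbind(3, 1)), arg1)
  expect_false(cls2$degenerate)
  expect_true(cls2$regular)

  # two nondegenerate edges that jointly close a cycle: irregular
  arg2 <- ancestral_graph(5, 0, ancestral_edges = cbind(3, 4))
  cls3 <- classify_hypothesis(hypothesis_spec(rbind(c(4, 5), c(5, 3))), arg2)
  expect_equal(nrow(cls3$nondegenerate_edges), 2)
  expect_false(cls3$regular)
})

test_that("removing a nondegenerate edge never makes a regular hypothesis irregular", {
  set.seed(21)
  for (i in 1:40) {
    pars <- random_sem(p = 6, seed = 300 + i)
    arg <- arg_of_dag(dag_of_parameters(pars))
    pairs <- which(diag(6) == 0, arr.ind = TRUE)
    h <- hypothesis_spec(pairs[sample(nrow(pairs), 3), ])
    cls <- classify_hypothesis(h, arg)
    if (cls$regular && nrow(cls$nondegenerate_edges) > 1) {
      for (drop in seq_len(nrow(cls$nondegenerate_edges))) {
        sub <- hypothesis_spec(cls$nondegenerate_edges[-drop, , drop = FALSE])
        expect_true(classify_hypothesis(sub, arg)$regular)
      }
    }
  }
})

test_that("nondegeneracy wrt the true edge set equals nondegeneracy wrt its closure", {
  set.seed(31)
  for (i in 1:40) {
    p <- sample(3:6, 1)
    pars <- random_sem(p = p, seed = 400 + i)
    edges <- which(pars$U != 0, arr.ind = TRUE)
    closed <- transitive_closure(edges, p)
    pairs <- which(diag(p) == 0, arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      e <- pairs[r, , drop = FALSE]
      nd_edges <- is_acyclic(rbind(edges, e), p)
      nd_closed <- !(peeldag:::edge_key(e[, 2:1, drop = FALSE], p) %in%
                       peeldag:::edge_key(closed, p))
      expect_identical(nd_edges, nd_closed)
    }
  }
})
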