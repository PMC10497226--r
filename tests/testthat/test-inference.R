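# A small null-true system reused across inference tests: chain
# Y1 -> Y2 -> Y3 with per-node instruments, nodes 4 and 5 isolated.
null_system <- function(p = 5, q = 12) {
  U <- matrix(0, p, p); U[1, 2] <- 0.8; U[2, 3] <- 0.7
  sem_parameters(U, intervention_W("A", p, q))
}

test_that("the testing context estimates residual variances consistently", {
  pars <- null_system()
  oarg <- arg_of_dag(dag_of_parameters(pars))
  h <- hypothesis_spec(cbind(3, 5))
  sig <- matrix(NA_real_, 100, pars$p)
  for (i in 1:100) {
    d <- sample_dataset(pars, 2000, seed = 2200 + i)
    ctx <- build_context(d, oarg, h)
    sig[i, ] <- ctx$sigma2_hat
    if (i == 1) {
      # only node 5 carries a hypothesized parent
      expect_equal(ctx$contributing, 5L)
      expect_true(all(ctx$B[[5]] %in% ctx$A[[5]]))
    }
  }
  expect_true(all(abs(colMeans(sig) / pars$sigma2 - 1) < 0.1))
})

test_that("context building refuses degenerate and dof-starved inputs", {
  pars <- null_system()
  oarg <- arg_of_dag(dag_of_parameters(pars))
  expect_error(build_context(sample_dataset(pars, 50, seed = 1), oarg,
                             hypothesis_spec(cbind(2, 1))), "degenerate")
  d_small <- sample_dataset(pars, 4, seed = 2)
  expect_error(build_context(d_small, oarg, hypothesis_spec(cbind(3, 5))),
               class = "peeldag_dof_error")
})

test_that("RSS-difference and projection forms of the likelihood ratio agree", {
  for (i in 1:20) {
    pars <- random_sem(sample(4:7, 1), extra = 3, seed = 2400 + i)
    oarg <- arg_of_dag(dag_of_parameters(pars))
    p <- pars$p
    pairs <- which(diag(p) == 0, arr.ind = TRUE)
    set.seed(2500 + i)
    h <- hypothesis_spec(pairs[sample(nrow(pairs), 2), ])
    cls <- classify_hypothesis(h, oarg)
    if (cls$degenerate || !cls$regular) next
    d <- sample_dataset(pars, 150, seed = 2600 + i)
    ctx <- build_context(d, oarg, h)
    lr1 <- as.numeric(likelihood_ratio(ctx, d, form = "rss"))
    lr2 <- as.numeric(likelihood_ratio(ctx, d, form = "projection"))
    expect_lt(abs(lr1 - lr2) / max(abs(lr1), 1e-8), 1e-8)
    expect_gte(lr1, -1e-10)
  }
})

test_that("asymptotic reference p-values follow the stated tails", {
  expect_equal(asymptotic_pvalue(3.841 / 2, 1), 0.05, tolerance = 1e-3)
  expect_equal(asymptotic_pvalue(25, 50, regime = "large"), 0.5)  # z = 0
  expect_equal(asymptotic_pvalue(0, 3), 1)
  expect_equal(asymptotic_pvalue(10, 2, regime = "fixed"),
               pchisq(20, 2, lower.tail = FALSE))
})

test_that("the DP p-value is the valid-replicate rank statistic", {
  reps <- lapply(c(1.0, 2.5, 3.0, 0.5),
                 function(l) list(valid = TRUE, lr_star = l))
  expect_equal(dp_pvalue_edges(2.0, reps)$pvalue, 0.5)
  expect_equal(dp_pvalue_edges(0, reps)$pvalue, 1)
  mixed <- c(reps, list(list(valid = FALSE, lr_star = NA_real_)))
  out <- dp_pvalue_edges(2.0, mixed)
  expect_equal(out$pvalue, 0.5)       # the filter only removes replicates
  expect_equal(out$M_valid, 4L)
  expect_error(dp_pvalue_edges(1, list(list(valid = FALSE, lr_star = NA))),
               class = "peeldag_no_valid_replicates")
})

test_that("perturbation replicates are seeded and guard the zero-noise hook", {
  pars <- null_system()
  d <- sample_dataset(pars, 300, seed = 31)
  learn <- learn_structure(d)
  ctx <- build_context(d, learn$arg, hypothesis_spec(cbind(3, 5)))
  cfg <- tuning_config()
  r1 <- dp_replicate(d, ctx, learn, cfg, seed = 99)
  r2 <- dp_replicate(d, ctx, learn, cfg, seed = 99)
  expect_identical(r1, r2)
  r0 <- dp_replicate(d, ctx, learn, cfg, seed = 99,
                     e_star = matrix(0, d$n, d$p))
  expect_false(r0$valid)
})

test_that("perturbation statistics match their limiting chi-squared law", {
  pars <- null_system()
  d <- sample_dataset(pars, 500, seed = 37)
  learn <- learn_structure(d)
  ctx <- build_context(d, learn$arg, hypothesis_spec(cbind(3, 5)))
  lr2 <- numeric(0)
  for (m in 1:300) {
    r <- dp_replicate(d, ctx, learn, tuning_config(), seed = 5000 + m)
    if (r$valid) lr2 <- c(lr2, 2 * r$lr_star)
  }
  expect_gt(length(lr2), 250)
  ks <- suppressWarnings(stats::ks.test(lr2, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("edges that close an ancestral cycle give p-value exactly one", {
  pars <- null_system()
  d <- sample_dataset(pars, 400, seed = 41)
  rep1 <- test_edges(d, hypothesis_spec(cbind(2, 1)),
                     test_config(M = 10, seed = 5))
  expect_identical(rep1$pvalue, 1)
  expect_true(rep1$classification$degenerate)
})

test_that("a single-edge pathway reproduces the edge test on the same stream", {
  pars <- null_system()
  d <- sample_dataset(pars, 400, seed = 43)
  cfg <- test_config(M = 60, seed = 11)
  pe <- test_edges(d, hypothesis_spec(cbind(3, 5), mode = "edge"), cfg)
  pp <- test_edges(d, hypothesis_spec(cbind(3, 5), mode = "pathway"), cfg)
  expect_equal(pp$M_valid, pe$M_valid)
  expect_equal(pp$pvalue, pe$pvalue)
})

test_that("pathways with any degenerate link have p-value one", {
  pars <- null_system()
  d <- sample_dataset(pars, 400, seed = 47)
  # (2,1) closes a cycle with the learned 1 -> 2 relation
  h <- hypothesis_spec(rbind(c(3, 2), c(2, 1)), mode = "pathway")
  rep1 <- test_edges(d, h, test_config(M = 10, seed = 7))
  expect_identical(rep1$pvalue, 1)
})

test_that("irregular edge hypotheses decompose with a Holm correction", {
  # truth has 3 -> 4; hypothesized {(4,5), (5,3)} are each nondegenerate
  # but jointly close the cycle 3 -> 4 -> 5 -> 3
  p <- 5
  U <- matrix(0, p, p); U[3, 4] <- 0.8
  pars <- sem_parameters(U, intervention_W("A", p, 12))
  d <- sample_dataset(pars, 500, seed = 53)
  h <- hypothesis_spec(rbind(c(4, 5), c(5, 3)))
  rep1 <- test_edges(d, h, test_config(method = "asymptotic", seed = 3))
  expect_false(rep1$classification$regular)
  expect_s3_class(rep1$per_edge, "data.frame")
  expect_equal(rep1$per_edge$pvalue_holm,
               p.adjust(rep1$per_edge$pvalue, "holm"))
  expect_equal(rep1$pvalue, min(rep1$per_edge$pvalue_holm))
})

test_that("the full DP edge test is reproducible and calibrated on one draw", {
  U <- random_graph_U(8, seed = 61); U[1, 8] <- 0
  pars <- sem_parameters(U, intervention_W("A", 8, 20))
  d <- sample_dataset(pars, 400, seed = 61)
  h <- hypothesis_spec(cbind(1, 8))
  cfg <- test_config(M = 80, seed = 13)
  r1 <- test_edges(d, h, cfg)
  r2 <- test_edges(d, h, cfg)
  expect_identical(r1$pvalue, r2$pvalue)
  expect_true(r1$pvalue >= 0 && r1$pvalue <= 1)
  expect_gte(r1$lr, 0)
  # the oracle method uses the true graph and the chi-squared reference
  ro <- test_edges(d, h, test_config(method = "oracle", oracle_graph = pars))
  expect_equal(ro$pvalue, asymptotic_pvalue(ro$lr, 1))
})
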