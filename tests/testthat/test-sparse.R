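test_that("weighted lasso reduces to soft-thresholding on orthonormal designs", {
  set.seed(2)
  n <- 50; q <- 8
  X <- qr.Q(qr(matrix(rnorm(n * q), n))) * sqrt(n)  # X'X = n I
  v0 <- c(2, -1.2, 0.6, rep(0, 5))
  y <- as.numeric(X %*% v0 + rnorm(n, sd = 0.3))
  gamma <- 0.4; tau <- 0.5
  v <- weighted_lasso(X, y, rep(1, q), gamma, tau)
  ols <- as.numeric(crossprod(X, y) / n)
  soft <- sign(ols) * pmax(abs(ols) - gamma * tau, 0)
  expect_equal(v, soft, tolerance = 1e-8)
})

test_that("weighted lasso with all weights zero is ordinary least squares", {
  set.seed(3)
  X <- matrix(rnorm(60 * 5), 60)
  y <- rnorm(60)
  v <- weighted_lasso(X, y, rep(0, 5), gamma = 1, tau = 1)
  expect_equal(v, as.numeric(qr.coef(qr(X), y)), tolerance = 1e-7)
  expect_error(weighted_lasso(X, c(y[-1], NA), rep(1, 5), 1, 1), "non-finite")
})

test_that("weighted lasso attains the convex optimum found by an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  n <- 60; q <- 20
  for (i in 1:5) {
    X <- matrix(rnorm(n * q), n)
    y <- as.numeric(X[, 1] - 0.5 * X[, 2] + rnorm(n))
    w <- rbinom(q, 1, 0.8)
    if (sum(w) == 0) w[1] <- 1
    gamma <- runif(1, 0.05, 0.5); tau <- runif(1, 0.2, 1)
    v <- weighted_lasso(X, y, w, gamma, tau)
    obj <- function(b) sum((y - X %*% b)^2) + 2 * n * gamma * tau * sum(w * abs(b))
    # glmnet objective is (1/2n)RSS + lambda sum(pf |b|) with pf rescaled
    # to sum to q, so lambda = gamma tau sum(w)/q matches ours
    fit <- glmnet::glmnet(X, y, intercept = FALSE, standardize = FALSE,
                          penalty.factor = w,
                          lambda = gamma * tau * sum(w) / q, thresh = 1e-14)
    v_ref <- as.numeric(stats::coef(fit))[-1]
    expect_lt(abs(obj(v) - obj(v_ref)) / max(obj(v_ref), 1), 1e-6)
  }
})

test_that("coordinate descent never increases the convex objective across sweeps", {
  set.seed(5)
  for (i in 1:10) {
    n <- 40; q <- 15
    X <- matrix(rnorm(n * q), n)
    y <- rnorm(n)
    fit <- weighted_lasso(X, y, rbinom(q, 1, 0.7), gamma = 0.2, tau = 0.4,
                          details = TRUE)
    expect_true(all(diff(fit$objective) <= 1e-8))
  }
})

test_that("l0 projection keeps the largest entries with lower-index ties", {
  expect_equal(l0_project(c(3, -1, 2), 2), c(3, 0, 2))
  expect_equal(l0_project(c(1, -1, 0), 1), c(1, 0, 0))
  v <- c(0.2, 0, -0.1)
  expect_equal(l0_project(v, 3), v)
})

test_that("the first DC iteration from zero is a plain lasso", {
  set.seed(6)
  n <- 80; q <- 10
  X <- matrix(rnorm(n * q), n)
  y <- as.numeric(X[, 3] + rnorm(n))
  tau <- 0.4; gamma <- 0.3
  fit <- dc_l0_column(X, y, kappa = q,
                      config = tuning_config(tau = tau, gamma_grid = gamma,
                                             max_dc_iter = 1))
  lasso <- weighted_lasso(X, y, rep(1, q), gamma, tau)
  expect_equal(fit$vtilde, lasso, tolerance = 1e-7)
})

test_that("the DC surrogate objective is non-increasing across iterations", {
  # emulate the DC loop with explicit weighted-lasso solves and track the
  # truncated-L1 objective (majorize-minimize property)
  set.seed(7)
  for (i in 1:5) {
    n <- 60; q <- 12
    X <- matrix(rnorm(n * q), n)
    v0 <- numeric(q); v0[sample(q, 2)] <- c(1.5, -1)
    y <- as.numeric(X %*% v0 + rnorm(n, sd = 0.5))
    tau <- 0.3; gamma <- 0.25
    surrogate <- function(v) {
      sum((y - X %*% v)^2) + 2 * n * gamma * tau * sum(pmin(abs(v) / tau, 1))
    }
    v <- rep(0, q)
    objs <- surrogate(v)
    for (t in 1:6) {
      v <- weighted_lasso(X, y, as.numeric(abs(v) <= tau), gamma, tau, start = v)
      objs <- c(objs, surrogate(v))
    }
    expect_true(all(diff(objs) <= 1e-6))
  }
})

test_that("noiseless sparse signals are recovered exactly", {
  set.seed(8)
  for (i in 1:10) {
    n <- 80; q <- 8
    X <- matrix(rnorm(n * q), n)
    supp <- sample(q, 2)
    v0 <- numeric(q); v0[supp] <- sample(c(-1, 1), 2, TRUE) * runif(2, 1, 2)
    y <- as.numeric(X %*% v0)
    fit <- dc_l0_column(X, y, 2)
    expect_setequal(fit$support, supp)
    expect_equal(fit$coef, v0, tolerance = 1e-6)
    expect_lte(fit$rss, sum(y^2))
  }
})

test_that("degenerate designs and tiny samples are guarded", {
  set.seed(9)
  X <- cbind(matrix(rnorm(20 * 4), 20), 0)  # zero-variance column
  y <- rnorm(20)
  expect_warning(fit <- dc_l0_column(X, y, 2), "zero-variance")
  expect_equal(fit$coef[5], 0)
  # n much smaller than q: overdetermined refit guarded
  Xs <- matrix(rnorm(5 * 30), 5)
  ys <- rnorm(5)
  expect_no_error(dc_l0_column(Xs, ys, 1))
})

test_that("the information criterion selects the true sparsity", {
  set.seed(10)
  n <- 400; q <- 10
  X <- matrix(rnorm(n * q), n)
  v0 <- numeric(q); v0[c(2, 7)] <- c(1.5, -1)
  y <- as.numeric(X %*% v0)           # noiseless
  sel <- select_kappa_bic(X, y, 1:5)
  expect_equal(sel$kappa, 2L)
  # response independent of the design: smallest candidate wins
  y2 <- rnorm(n)
  sel2 <- select_kappa_bic(X, y2, 2:6)
  expect_equal(sel2$kappa, 2L)
  expect_equal(select_kappa_bic(X, y, 3)$kappa, 3L)
})

test_that("fitted reduced-form columns are equivariant to design permutations", {
  pars <- random_sem(4, extra = 2, seed = 11)
  d <- sample_dataset(pars, 300, seed = 11)
  cfg <- tuning_config(kappa = 3)
  v1 <- fit_V(d, cfg)
  perm <- sample(ncol(d$X))
  d2 <- new_dataset(d$Y, d$X[, perm])
  v2 <- fit_V(d2, cfg)
  expect_equal(v2$V_hat, v1$V_hat[perm, ], tolerance = 1e-9)
})

test_that("fit_V recovers the reduced-form support on simulated systems", {
  ok <- 0
  for (r in 1:20) {
    U <- random_graph_U(10, seed = 900 + r)
    pars <- sem_parameters(U, intervention_W("A", 10, 30))
    d <- sample_dataset(pars, 2000, seed = 950 + r)
    v <- fit_V(d)
    V <- implied_V(pars)
    if (identical(lapply(seq_len(10), function(j) which(V[, j] != 0)),
                  lapply(v$support, as.integer))) ok <- ok + 1
  }
  expect_gte(ok, 19)
})
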