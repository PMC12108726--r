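test_that("component log-density matches dense quadratic-form evaluation", {
  # standard normal at its mode, dim 1
  expect_equal(component_logpdf(0, 0, matrix(1)), -0.9189385332046727,
               tolerance = 1e-12)
  set.seed(61)
  for (trial in 1:25) {
    d <- 3
    A <- matrix(rnorm(d * d), d)
    sigma <- crossprod(A) + diag(d)   # strictly PD
    mu <- rnorm(d)
    x <- rnorm(d)
    expect_equal(component_logpdf(x, mu, sigma),
                 oracle_logpdf(x, mu, sigma), tolerance = 1e-10)
    # symmetry about the mean
    v <- rnorm(d)
    expect_equal(component_logpdf(mu + v, mu, sigma),
                 component_logpdf(mu - v, mu, sigma), tolerance = 1e-10)
  }
  # cross-check against an established implementation
  skip_if_not_installed("mclust")
  set.seed(62)
  sigma <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(component_logpdf(X, rep(0, 4), sigma),
               as.numeric(mclust::dmvnorm(X, rep(0, 4), sigma,
                                          log = TRUE)),
               tolerance = 1e-8)
  expect_error(component_logpdf(0, c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("initial parameters follow the stated scheme", {
  set.seed(9)
  p <- init_params(8, 16)
  expect_equal(p$weights, rep(1 / 8, 8))
  for (k in 1:8) expect_equal(p$covariances[, , k], diag(16))
  expect_true(all(p$means >= 0 & p$means <= 1))
  # determinism under a fixed seed
  set.seed(4); p1 <- init_params(3, 5)
  set.seed(4); p2 <- init_params(3, 5)
  expect_identical(p1, p2)
  # data-point scheme picks rows of X
  X <- matrix(rnorm(50), 10, 5)
  set.seed(5)
  pd <- init_params(3, 5, scheme = "random_datapoint", X = X)
  expect_true(all(apply(pd$means, 1,
                        function(m) any(apply(X, 1, identical, m)))))
})

test_that("the E-step reproduces hand-computed Bayes posteriors", {
  # single component: all responsibilities 1
  p1 <- init_params(1, 2, reg_eps = 0)
  p1$means[1, ] <- c(0, 0)
  X <- matrix(rnorm(10), 5, 2)
  es <- e_step(p1, X)
  expect_equal(es$R, matrix(1, 5, 1))
  # two identical components: every row (0.5, 0.5)
  p2 <- init_params(2, 2, reg_eps = 0)
  p2$means[1, ] <- c(1, 2); p2$means[2, ] <- c(1, 2)
  es2 <- e_step(p2, X)
  expect_equal(es2$R, matrix(0.5, 5, 2))
  # well-separated unit-variance components: direct arithmetic oracle
  p3 <- init_params(2, 1, reg_eps = 0)
  p3$means <- matrix(c(0, 6), 2, 1)
  p3$weights <- c(0.3, 0.7)
  xs <- matrix(c(1, 5), 2, 1)
  es3 <- e_step(p3, xs)
  for (i in 1:2) {
    num <- p3$weights * dnorm(xs[i], c(0, 6), 1)
    expect_equal(es3$R[i, ], num / sum(num), tolerance = 1e-10)
  }
  # normalization and effective-count bookkeeping
  expect_equal(rowSums(es3$R), c(1, 1), tolerance = 1e-10)
  expect_equal(sum(es3$Nk), 2, tolerance = 1e-8)
})

test_that("the M-step reproduces hand-computed weighted updates", {
  # hard 0/1 responsibilities give per-cluster arithmetic means
  X <- rbind(c(0, 0), c(2, 0), c(10, 10))
  R_hard <- rbind(c(1, 0), c(1, 0), c(0, 1))
  p <- m_step(X, R_hard, reg_eps = 0)
  expect_equal(p$means, rbind(c(1, 0), c(10, 10)))
  expect_equal(p$weights, c(2 / 3, 1 / 3))
  # uniform responsibilities collapse every mean onto the grand mean
  R_unif <- matrix(1 / 2, 3, 2)
  pu <- m_step(X, R_unif, reg_eps = 0)
  expect_equal(pu$means, rbind(colMeans(X), colMeans(X)))
  # weighted 3-point, 2-component case against explicit sums
  R_w <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  pw <- m_step(X, R_w, reg_eps = 0)
  for (k in 1:2) {
    Nk <- sum(R_w[, k])
    mk <- colSums(R_w[, k] * X) / Nk
    Sk <- matrix(0, 2, 2)
    for (i in 1:3) Sk <- Sk + R_w[i, k] * tcrossprod(X[i, ] - mk)
    expect_equal(pw$means[k, ], mk, tolerance = 1e-12)
    expect_equal(pw$covariances[, , k], Sk / Nk, tolerance = 1e-12)
    expect_equal(pw$weights[k], Nk / 3, tolerance = 1e-12)
  }
})

test_that("log-likelihood is additive and matches a naive evaluation", {
  set.seed(63)
  p <- init_params(2, 2, reg_eps = 0)
  p$means <- rbind(c(0, 0), c(3, 3))
  X <- matrix(rnorm(20), 10, 2)
  # one point, one component reduces to the component density
  p1 <- init_params(1, 2, reg_eps = 0)
  p1$means[1, ] <- c(0, 0)
  expect_equal(log_likelihood(p1, X[1, , drop = FALSE]),
               component_logpdf(X[1, ], c(0, 0), diag(2)))
  # duplicating the data doubles the log-likelihood
  expect_equal(log_likelihood(p, rbind(X, X)), 2 * log_likelihood(p, X),
               tolerance = 1e-10)
  # naive non-log-space evaluation on well-scaled data
  naive <- sum(log(
    0.5 * exp(apply(X, 1, oracle_logpdf, mu = c(0, 0), sigma = diag(2))) +
    0.5 * exp(apply(X, 1, oracle_logpdf, mu = c(3, 3), sigma = diag(2)))))
  expect_equal(log_likelihood(p, X), naive, tolerance = 1e-8)
})

test_that("EM is monotone, normalized and deterministic under a seed", {
  set.seed(64)
  X <- rbind(matrix(rnorm(60, 0, 0.5), ncol = 2),
             matrix(rnorm(60, 4, 0.5), ncol = 2),
             matrix(rnorm(60, c(0, 8), 0.5), ncol = 2))
  fit <- gmm_em(X, K = 3, seed = 11, n_init = 4)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  es <- e_step(fit, X)
  expect_equal(rowSums(es$R), rep(1, nrow(X)), tolerance = 1e-10)
  expect_equal(sum(es$Nk), nrow(X), tolerance = 1e-8)
  fit2 <- gmm_em(X, K = 3, seed = 11, n_init = 4)
  fit$call <- fit2$call <- NULL
  expect_equal(fit, fit2)
  expect_error(gmm_em(X[1:2, ], K = 3), "at least K")
})

test_that("a single tight component converges immediately to the sample mean", {
  set.seed(65)
  X <- matrix(rnorm(100, 5, 0.1), ncol = 2)
  fit <- gmm_em(X, K = 1, seed = 2, n_init = 1)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 3)
  expect_equal(fit$means[1, ], colMeans(X), tolerance = 1e-6)
})

test_that("EM recovers the generating means of two separated blobs", {
  set.seed(66)
  truth <- rbind(c(0, 0), c(4, 4))
  X <- rbind(matrix(rnorm(400, sd = 0.25), 200, 2),
             sweep(matrix(rnorm(400, sd = 0.25), 200, 2), 2, truth[2, ], "+"))
  fit <- gmm_em(X, K = 2, seed = 3, n_init = 5)
  got <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(got - truth)), 0.05)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.05)
})

test_that("hard assignment is the row-wise argmax with low-index ties", {
  set.seed(67)
  X <- matrix(rnorm(40), 20, 2)
  fit <- gmm_em(X, K = 2, seed = 8, n_init = 2)
  lab <- predict(fit, X)
  R <- predict(fit, X, type = "responsibility")
  expect_equal(lab, max.col(R, ties.method = "first") - 1L)
  # exact tie between identical components resolves to the lower label
  p <- init_params(3, 2, reg_eps = 0)
  p$means <- rbind(c(5, 5), c(0, 0), c(0, 0))
  tied <- structure(c(p, list(n_obs = 1)), class = "gmm_em")
  expect_equal(predict(tied, matrix(c(0, 0), 1, 2)), 1L)
  # single component labels everything 0
  expect_true(all(predict(gmm_em(X, K = 1, seed = 1, n_init = 1), X) == 0L))
})

test_that("permuting data rows permutes labels identically", {
  set.seed(68)
  X <- rbind(matrix(rnorm(100, 0, 0.3), ncol = 2),
             matrix(rnorm(100, 3, 0.3), ncol = 2))
  fit <- gmm_em(X, K = 2, seed = 5, n_init = 3)
  perm <- sample(nrow(X))
  expect_identical(predict(fit, X)[perm], predict(fit, X[perm, ]))
})
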