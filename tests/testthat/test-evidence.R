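conjugate_problem <- function(seed = 5, n = 40, p = 3, sigma = 1.2, tau = 2) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  y <- drop(X %*% rnorm(p) + rnorm(n, 0, sigma))
  V <- solve(crossprod(X) / sigma^2 + diag(p) / tau^2)
  m <- drop(V %*% crossprod(X, y) / sigma^2)
  S <- sigma^2 * diag(n) + tau^2 * X %*% t(X)
  log_evidence <- -0.5 * n * log(2 * pi) -
    0.5 * as.numeric(determinant(S)$modulus) -
    0.5 * drop(t(y) %*% solve(S, y))
  log_post <- function(Th) apply(Th, 1, function(th)
    sum(dnorm(y - X %*% th, 0, sigma, log = TRUE)) +
      sum(dnorm(th, 0, tau, log = TRUE)))
  list(m = m, V = V, log_evidence = log_evidence, log_post = log_post, p = p)
}

test_that("warp-III bridge sampling reproduces conjugate model evidence", {
  pr <- conjugate_problem()
  set.seed(9)
  draws <- matrix(rnorm(4000 * pr$p), 4000) %*% chol(pr$V) +
    matrix(pr$m, 4000, pr$p, byrow = TRUE)
  ev <- bridge_log_ml(draws, pr$log_post, n_repetitions = 5)
  mc_se <- max(ev$sd / sqrt(ev$n_repetitions), 0.005)
  expect_lt(abs(ev$log_ml - pr$log_evidence), 3 * mc_se + 0.02)
  expect_equal(ev$log_ml, mean(ev$repetition_values))
  expect_equal(ev$n_repetitions, 5L)
})

test_that("bridge estimates agree with one-dimensional quadrature", {
  # concentrated posterior under a flat-ish prior, checked against
  # numerical integration of likelihood x prior
  set.seed(4)
  y <- rnorm(25, 3, 0.5)
  logf <- function(th) vapply(th, function(t)
    sum(dnorm(y, t, 0.5, log = TRUE)) + dnorm(t, 0, 10, log = TRUE),
    numeric(1))
  quad <- log(integrate(function(t) exp(logf(t)), -20, 20,
                        rel.tol = 1e-10)$value)
  post_sd <- 0.5 / sqrt(25)
  draws <- matrix(rnorm(4000, mean(y) * (1 / post_sd^2) /
                          (1 / post_sd^2 + 1 / 100), post_sd), ncol = 1)
  ev <- bridge_log_ml(draws, function(Th) logf(Th[, 1]), n_repetitions = 5)
  expect_lt(abs(ev$log_ml - quad), 0.02)
})

test_that("the bridge estimate is invariant to the repetition split seed", {
  pr <- conjugate_problem(seed = 11)
  set.seed(2)
  draws <- matrix(rnorm(3000 * pr$p), 3000) %*% chol(pr$V) +
    matrix(pr$m, 3000, pr$p, byrow = TRUE)
  set.seed(101); e1 <- bridge_log_ml(draws, pr$log_post, n_repetitions = 3)
  set.seed(202); e2 <- bridge_log_ml(draws, pr$log_post, n_repetitions = 3)
  expect_lt(abs(e1$log_ml - e2$log_ml), 0.05)
})

test_that("evidence estimates on a fitted hierarchical model are stable", {
  fit <- tiny_fit()
  set.seed(1); e1 <- log_marginal_likelihood(fit, n_repetitions = 3)
  set.seed(2); e2 <- log_marginal_likelihood(fit, n_repetitions = 3)
  expect_true(is.finite(e1$log_ml))
  expect_lt(abs(e1$log_ml - e2$log_ml), 1.5)
  expect_equal(e1$log_ml, mean(e1$repetition_values))
  expect_true(all(e1$convergence_iterations <= 1000))
})

test_that("posterior model probabilities follow the two-model formula", {
  expect_equal(posterior_model_probability(0, 0), 0.5)
  expect_equal(posterior_model_probability(log(19), 0), 0.95)
  expect_equal(posterior_model_probability(-Inf, 0), 0)
  expect_equal(posterior_model_probability(0, -Inf), 1)
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(1, 0, 50); b <- rnorm(1, 0, 50)
    expect_equal(posterior_model_probability(a, b) +
                   posterior_model_probability(b, a), 1)
  }
})
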