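test_that("the generic NUTS recovers a conjugate regression posterior", {
  set.seed(5)
  n <- 40; p <- 3; sigma <- 1.2; tau <- 2
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  y <- X %*% c(0.5, -1, 0.8) + rnorm(n, 0, sigma)
  V <- solve(crossprod(X) / sigma^2 + diag(p) / tau^2)
  m <- drop(V %*% crossprod(X, y) / sigma^2)
  lp_grad <- function(th) {
    r <- y - X %*% th
    list(lp = sum(dnorm(r, 0, sigma, log = TRUE)) +
           sum(dnorm(th, 0, tau, log = TRUE)),
         grad = drop(crossprod(X, r) / sigma^2 - th / tau^2))
  }
  ch <- piheal:::nuts_chain(lp_grad, rep(0, p), 400, 1500)
  mc_se <- sqrt(diag(V)) / sqrt(200)    # generous effective-sample bound
  expect_true(all(abs(colMeans(ch$draws) - m) < 6 * mc_se))
  expect_equal(apply(ch$draws, 2, sd), sqrt(diag(V)), tolerance = 0.15)
})

test_that("posterior sampling is deterministic under a fixed seed", {
  obs <- score_change_observations(calib_cohort(n_pis = 5, seed = 17))
  spec <- calibration_truth()$spec
  mc <- quick_mcmc(seed = 3, warmup = 120, draws = 150)
  f1 <- sample_posterior(obs, spec, mcmc = mc)
  f2 <- sample_posterior(obs, spec, mcmc = mc)
  expect_identical(f1$draws, f2$draws)
  expect_identical(summary(f1), summary(f2))
})

test_that("posterior draws respect the domain constraints draw by draw", {
  fit <- tiny_fit()
  dm <- as_draws_matrix(fit)
  expect_true(all(dm[, "sigma"] > 0))
  expect_true(all(dm[, grepl("^zeta\\[", colnames(dm))] >= 0))
  om <- dm[, grepl("^Omega\\[", colnames(dm)), drop = FALSE]
  expect_true(all(abs(om) <= 1))
  expect_equal(dim(fit$draws)[1] * dim(fit$draws)[2],
               fit$mcmc$n_chains * fit$mcmc$n_draws)
})

test_that("a pooled-information fit recovers a regression slope", {
  # near-degenerate heterogeneity: hierarchical slope approaches the
  # ordinary pooled estimate
  ct <- calibration_truth()
  tr <- hyperparameters(ct$truth$mu, c(1e-3, 1e-3, 1e-3), sigma = 2)
  cc <- cohort_config(n_pis = 12, assessments_per_pi = 4,
                      integer_scores = FALSE, seed = 23,
                      truth = tr, truth_spec = ct$spec)
  obs <- score_change_observations(generate_cohort(cc))
  fit <- sample_posterior(obs, ct$spec, mcmc = quick_mcmc(seed = 2))
  ols <- lm(d ~ duration_for_next + age, data = obs)
  s <- summary(fit)
  mu_s <- s[s$parameter == "mu[duration_for_next]", ]
  expect_lt(abs(mu_s$mean - coef(ols)[["duration_for_next"]]),
            3 * summary(ols)$coefficients["duration_for_next", 2] +
              3 * mu_s$sd)
})

test_that("split R-hat flags divergent chains and passes exchangeable ones", {
  set.seed(8)
  same <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(same), 1.02)
  apart <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(rhat(apart), 2)
  expect_error(rhat(matrix(rnorm(100), 100, 1)), "at least 2 chains")
})

test_that("split R-hat matches an independently coded textbook formula", {
  set.seed(12)
  mat <- matrix(rnorm(600, sd = 1.3) + rep(c(0, 0.4, -0.2), each = 200),
                200, 3)
  # textbook: split each chain in half, B/W over the 6 sequences
  halves <- do.call(cbind, lapply(1:3, function(j)
    cbind(mat[1:100, j], mat[101:200, j])))
  nn <- 100
  means <- colMeans(halves)
  W <- mean(apply(halves, 2, var))
  B <- nn * var(means)
  oracle <- sqrt(((nn - 1) / nn * W + B / nn) / W)
  expect_equal(rhat(mat), oracle, tolerance = 1e-12)
})

test_that("fitted models expose convergence diagnostics for every parameter", {
  fit <- tiny_fit()
  expect_equal(length(fit$rhat), dim(fit$draws)[3])
  expect_true(all(is.finite(fit$rhat)))
  expect_lt(fit$max_rhat, 1.1)
})
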