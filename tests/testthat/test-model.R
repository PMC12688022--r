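test_that("design rows follow the intercept-gap-square-predictors order", {
  expect_equal(build_design_row(list(duration_for_next = 7),
                                model_spec(include_quadratic_duration = TRUE)),
               c(intercept = 1, duration_for_next = 7,
                 duration_for_next_sq = 49))
  r0 <- build_design_row(list(duration_for_next = 0, age = 80),
                         model_spec("age", include_quadratic_duration = TRUE))
  expect_equal(unname(r0), c(1, 0, 0, 80))
  best <- best_model_spec()
  expect_equal(coef_names(best),
               c("intercept", "duration_for_next", "duration_for_next_sq",
                 "age", "duration_from_day0", "duration_from_day0_sq",
                 "baseline_score"))
  row <- build_design_row(list(duration_for_next = 10, age = 79,
                               duration_from_day0 = 20,
                               duration_from_day0_sq = 400,
                               baseline_score = 19), best)
  expect_length(row, 7)
  expect_equal(unname(row), c(1, 10, 100, 79, 20, 400, 19))
  expect_error(build_design_row(list(duration_for_next = 1), best),
               "missing covariate")
})

test_that("model specs validate predictors and absorb the quadratic flag", {
  sp <- model_spec(c("age", "duration_for_next_sq"))
  expect_true(sp$include_quadratic_duration)
  expect_equal(sp$predictors, "age")
  expect_error(model_spec(c("age", "age")), "duplicate")
  expect_error(model_spec("shoe_size"), "unknown predictor")
})

test_that("covariance Cholesky assembly scales the correlation factor", {
  expect_equal(assemble_covariance_chol(c(1, 1), diag(2)), diag(2))
  expect_equal(assemble_covariance_chol(c(2, 3), diag(2)), diag(c(2, 3)))
  set.seed(1)
  for (K in c(2, 4)) {
    zeta <- runif(K, 0.2, 2)
    L <- rlkj_chol(K, 2)
    S <- assemble_covariance_chol(zeta, L)
    Sigma <- S %*% t(S)
    expect_equal(Sigma, t(Sigma))
    expect_equal(diag(Sigma), zeta^2, tolerance = 1e-12)
    expect_true(all(eigen(Sigma, only.values = TRUE)$values > -1e-12))
  }
  expect_error(assemble_covariance_chol(c(-1, 1), diag(2)), "zeta")
})

test_that("log likelihood matches closed forms and a brute-force loop", {
  obs <- data.frame(pi_id = "A", d = 5, duration_for_next = 2)
  spec <- model_spec()
  eff <- matrix(c(1, 2), 2, 1, dimnames = list(NULL, "A"))  # x'beta = 5
  expect_equal(log_likelihood(obs, spec, eff, 1), -0.5 * log(2 * pi))
  expect_equal(log_likelihood(obs, spec, eff, 2),
               -0.5 * log(2 * pi) - log(2))
  set.seed(2)
  coh <- calib_cohort(n_pis = 5, seed = 2)
  obs2 <- score_change_observations(coh)
  sp2 <- calibration_truth()$spec
  K <- length(coef_names(sp2))
  ids <- unique(as.character(obs2$pi_id))
  eff2 <- matrix(rnorm(K * length(ids)), K, dimnames = list(NULL, ids))
  sig <- 1.7
  X <- build_design_matrix(obs2, sp2)
  naive <- 0
  for (i in seq_len(nrow(obs2))) {
    naive <- naive + dnorm(obs2$d[i],
                           sum(X[i, ] * eff2[, as.character(obs2$pi_id)[i]]),
                           sig, log = TRUE)
  }
  expect_equal(log_likelihood(obs2, sp2, eff2, sig), naive)
  expect_error(log_likelihood(obs2, sp2, eff2, -1), "sigma")
})

test_that("LKJ density matches the bivariate closed form and normalizes", {
  eta <- 4
  for (rho in c(-0.7, 0, 0.4)) {
    L <- matrix(c(1, rho, 0, sqrt(1 - rho^2)), 2, 2)
    expect_equal(dlkj_chol(L, eta),
                 (1 - rho^2)^(eta - 1) / (2^(2 * eta - 1) * beta(eta, eta)),
                 tolerance = 1e-12)
  }
  intg <- integrate(function(r) vapply(r, function(ri)
    dlkj_chol(matrix(c(1, ri, 0, sqrt(1 - ri^2)), 2, 2), eta), numeric(1)),
    -1, 1)
  expect_equal(intg$value, 1, tolerance = 1e-6)
  # identity factor in d = 2: density is the normalizing constant alone
  expect_equal(log(dlkj_chol(diag(2), eta)),
               -(2 * eta - 1) * log(2) - lbeta(eta, eta))
})

test_that("prior density covers all blocks with documented truncations", {
  pc <- prior_config()
  h <- hyperparameters(mu = c(0, 0), zeta = c(0.5, 0.5), sigma = 1e-12)
  eff <- matrix(0, 2, 1, dimnames = list(NULL, "A"))
  lp0 <- log_prior(h, eff, pc)
  # the half-normal factor at sigma ~ 0 equals twice the normal density
  h2 <- hyperparameters(h$mu, h$zeta, h$omega_chol, sigma = 50)
  diff_expect <- (log(2) + dnorm(1e-12, 0, 100, log = TRUE)) -
    (log(2) + dnorm(50, 0, 100, log = TRUE))
  expect_equal(lp0 - log_prior(h2, eff, pc), diff_expect)
  # moving one effect away from mu along a covariance eigenvector
  # decreases the prior monotonically
  hh <- hyperparameters(mu = c(1, -1), zeta = c(0.8, 0.3),
                        omega_chol = rlkj_chol(2, 4), sigma = 1)
  Sig <- assemble_covariance_chol(hh$zeta, hh$omega_chol)
  ev <- eigen(Sig %*% t(Sig))$vectors[, 1]
  lps <- vapply(c(0, 0.5, 1, 2, 4), function(a) {
    e <- matrix(hh$mu + a * ev, 2, 1, dimnames = list(NULL, "A"))
    log_prior(hh, e, pc)
  }, numeric(1))
  expect_true(all(diff(lps) < 0))
})

test_that("unconstrained density equals the constrained joint plus Jacobians", {
  set.seed(7)
  spec <- model_spec(c("age", "baseline_score"))
  ct <- hyperparameters(mu = c(1, -0.3, 0.05, -0.1),
                        zeta = c(0.5, 0.1, 0.02, 0.05), sigma = 1.5)
  cc <- cohort_config(n_pis = 5, seed = 11, truth = ct, truth_spec = spec)
  obs <- score_change_observations(generate_cohort(cc))
  hd <- piheal:::hbr_data(obs, spec)
  K <- hd$K; n_pi <- hd$n_pi
  P <- K * (K - 1) / 2
  prior <- prior_config()
  scales <- piheal:::mu_scales(spec, prior)
  th <- rnorm(piheal:::theta_dim(K, n_pi), 0, 0.4)
  lp_cpp <- piheal:::cpp_hbr_lp_grad(th, hd$X, hd$d, hd$gidx, hd$n_pi, scales,
                                     prior$zeta_df, prior$sigma_scale,
                                     prior$lkj_shape)$lp
  nat <- piheal:::theta_to_natural(th, K, n_pi)
  eff <- nat$beta; colnames(eff) <- hd$pi_ids
  lj <- log_joint(obs, spec,
                  hyperparameters(nat$mu, nat$zeta, nat$omega_chol, nat$sigma),
                  eff, prior)
  w <- tanh(th[2 * K + seq_len(P)])
  lz <- th[K + 1:K]; ls <- th[2 * K + P + 1]
  det_beta_z <- n_pi * (sum(lz) + sum(log(diag(nat$omega_chol))))
  ldLdw <- 0; p <- 0
  for (i in 2:K) {
    rem <- 1
    for (j in 1:(i - 1)) {
      p <- p + 1
      ldLdw <- ldLdw + 0.5 * log(rem)
      rem <- rem * (1 - w[p]^2)
    }
  }
  expect_equal(lp_cpp,
               lj + det_beta_z + sum(lz) + ls + sum(log(1 - w^2)) + ldLdw,
               tolerance = 1e-8)
})

test_that("analytic gradient agrees with central differences", {
  set.seed(3)
  spec <- calibration_truth()$spec
  obs <- score_change_observations(calib_cohort(n_pis = 4, seed = 3))
  hd <- piheal:::hbr_data(obs, spec)
  prior <- prior_config()
  scales <- piheal:::mu_scales(spec, prior)
  D <- piheal:::theta_dim(hd$K, hd$n_pi)
  f <- function(t) piheal:::cpp_hbr_lp_grad(t, hd$X, hd$d, hd$gidx, hd$n_pi,
                                            scales, prior$zeta_df,
                                            prior$sigma_scale,
                                            prior$lkj_shape)
  th <- rnorm(D, 0, 0.3)
  g <- f(th)$grad
  h <- 1e-6
  for (i in sample.int(D, min(D, 25))) {
    tp <- th; tm <- th
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    expect_equal(g[i], (f(tp)$lp - f(tm)$lp) / (2 * h), tolerance = 1e-4)
  }
})

test_that("with vanishing scales the likelihood degenerates to pooled regression", {
  obs <- score_change_observations(calib_cohort(n_pis = 5, seed = 6))
  spec <- calibration_truth()$spec
  mu <- c(1.5, -0.2, 0.02)
  ids <- unique(as.character(obs$pi_id))
  eff <- matrix(mu, 3, length(ids), dimnames = list(NULL, ids))
  X <- build_design_matrix(obs, spec)
  pooled <- sum(dnorm(obs$d, drop(X %*% mu), 1.3, log = TRUE))
  expect_equal(log_likelihood(obs, spec, eff, 1.3), pooled)
  # and the likelihood is invariant to lesion relabelling
  perm <- rev(ids)
  eff2 <- eff[, perm, drop = FALSE]
  expect_equal(log_likelihood(obs, spec, eff2, 1.3), pooled)
})
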