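test_that("prediction intervals are central empirical quantiles", {
  set.seed(1)
  z <- rnorm(50000)
  ci <- prediction_interval(z, 0.90)
  expect_equal(ci$lower, -1.645, tolerance = 0.03)
  expect_equal(ci$upper, 1.645, tolerance = 0.03)
  expect_true(ci$lower <= ci$point && ci$point <= ci$upper)
  wide <- prediction_interval(z, 1 - 1e-9)
  expect_equal(wide$lower, min(z), tolerance = 1e-4)
  expect_equal(wide$upper, max(z), tolerance = 1e-4)
  const <- prediction_interval(rep(2.5, 200), 0.9)
  expect_equal(const$lower, 2.5)
  expect_equal(const$upper, 2.5)
  expect_error(prediction_interval(rnorm(50), 0.9), "at least 100")
  expect_error(prediction_interval(z, 1.2), "level")
})

test_that("lesion-specific predictive variance dominates population mode", {
  fit <- tiny_fit()
  obs <- list(duration_for_next = 10, age = 80)
  set.seed(2)
  pop <- predictive_distribution(fit, obs, mode = "population")
  set.seed(2)
  les <- predictive_distribution(fit, obs, mode = "pi_specific")
  expect_gt(var(les), var(pop))
  expect_equal(length(pop), dim(fit$draws)[1] * dim(fit$draws)[2])
  expect_error(predictive_distribution(fit, obs, mode = "posterior"),
               "pi_id")
  set.seed(3)
  post <- predictive_distribution(fit, obs, mode = "posterior",
                                  pi_id = fit$data$pi_ids[1])
  expect_true(is.finite(var(post)))
})

test_that("sequential prediction yields one interval per future assessment", {
  fit <- tiny_fit()
  coh <- calib_cohort(n_pis = 3, seed = 99)
  one <- coh[coh$pi_id == "PI001", ]
  set.seed(4)
  rep1 <- sequential_predict(fit, one)
  expect_equal(nrow(rep1), nrow(one) - 1L)
  expect_true(all(rep1$lower <= rep1$upper))
  expect_equal(rep1$actual, one$total[order(one$day)][-1], tolerance = 1e-9)
  dup <- one
  dup$day[2] <- dup$day[1]
  expect_error(sequential_predict(fit, dup), "day indices")
  expect_error(sequential_predict(fit, one[1, ]), "at least 2")
})

test_that("coverage pooling reproduces per-lesion fractions exactly", {
  cov <- coverage_from_counts(c(4, 5, 6, 8), c(6, 6, 7, 10))
  expect_equal(cov$pooled$covered, 23L)
  expect_equal(cov$pooled$assessed, 29L)
  expect_equal(cov$pooled$proportion, 23 / 29)
  expect_equal(cov$per_pi$proportion, c(4 / 6, 5 / 6, 6 / 7, 8 / 10))
  expect_equal(sum(cov$per_pi$covered), cov$pooled$covered)
})

test_that("coverage counts inclusively at interval endpoints", {
  iv <- data.frame(pi_id = c("A", "A", "B"), lower = c(0, 0, -2),
                   upper = c(5, 5, 2))
  cov <- coverage_probability(iv, c(5, 6, -2))   # 5 and -2 on the boundary
  expect_equal(cov$pooled$covered, 2L)
  expect_equal(cov$pooled$assessed, 3L)
  full <- coverage_probability(iv, c(1, 2, 0))
  expect_equal(full$pooled$proportion, 1)
  expect_error(coverage_probability(iv, c(1, 2)), "misaligned")
})
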