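test_that("identical configurations give identical datasets", {
  cc <- cohort_config(n_pis = 6, seed = 9)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("mean follow-up matches the configured study conditions", {
  # 2-4 assessments (mean 3) spaced 14.7 days -> mean follow-up 29.4 days
  cc <- cohort_config(n_pis = 400, seed = 21)
  coh <- generate_cohort(cc)
  fu <- tapply(coh$day, coh$pi_id, max)
  se <- stats::sd(fu) / sqrt(length(fu))
  expect_lt(abs(mean(fu) - 29.4), 3 * se + 0.5)
})

test_that("degenerate truth gives the deterministic mean trajectory", {
  ct <- calibration_truth()
  tr <- hyperparameters(ct$truth$mu, rep(0, 3), sigma = 1e-8)
  cc <- cohort_config(n_pis = 5, assessments_per_pi = 3,
                      integer_scores = FALSE, seed = 4,
                      truth = tr, truth_spec = ct$spec)
  coh <- generate_cohort(cc)
  obs <- score_change_observations(coh)
  X <- build_design_matrix(obs, ct$spec)
  expect_lt(max(abs(obs$d - drop(X %*% tr$mu))), 1e-5)
})

test_that("covariate prevalences converge to their configured values", {
  cc <- cohort_config(n_pis = 2000, assessments_per_pi = 2, seed = 31)
  coh <- generate_cohort(cc)
  one <- coh[!duplicated(coh$pi_id), ]
  prev <- default_prevalences()
  for (nm in names(prev)) {
    se <- sqrt(prev[[nm]] * (1 - prev[[nm]]) / 2000)
    expect_lt(abs(mean(one[[nm]]) - prev[[nm]]), 3 * se + 1e-9)
  }
})

test_that("totals are clipped into the instrument range and clips counted", {
  ct <- calibration_truth()
  tr <- hyperparameters(c(-30, 0, 0), c(0, 0, 0), sigma = 1)
  cc <- cohort_config(n_pis = 10, assessments_per_pi = 3, seed = 2,
                      truth = tr, truth_spec = ct$spec)
  coh <- generate_cohort(cc)
  expect_true(all(coh$total >= 0 & coh$total <= 66))
  expect_gt(attr(coh, "clip_events"), 0)
})

test_that("every simulated total decomposes into permissible subscales within one point", {
  for (tot in 0:66) {
    dec <- decompose_total(tot)
    for (nm in names(dec)) {
      expect_true(dec[[nm]] %in% designr_permissible(nm))
    }
    expect_lte(abs(sum(unlist(dec)) - tot), 1L)
  }
})

test_that("train/test split keeps the longest-followed lesions for testing", {
  coh <- generate_cohort(cohort_config(n_pis = 18, seed = 7))
  sp <- split_train_test(coh, 0.2)
  expect_equal(length(unique(sp$test$pi_id)), 4L)
  expect_equal(length(unique(sp$train$pi_id)), 14L)
  fu <- tapply(coh$day, coh$pi_id, max)
  expect_gte(min(fu[unique(as.character(sp$test$pi_id))]),
             max(fu[unique(as.character(sp$train$pi_id))]) - 1e-9)
  # split is by lesion, never by record
  expect_length(intersect(sp$train$pi_id, sp$test$pi_id), 0)
})

test_that("split tie-breaks deterministically and validates its fraction", {
  rec <- data.frame(pi_id = rep(c("b", "a", "c", "d"), each = 2),
                    day = rep(c(0, 10), 4))
  sp <- split_train_test(rec, 0.25)
  expect_equal(unique(sp$test$pi_id), "a")   # equal follow-up: lexicographic
  expect_error(split_train_test(rec, 0), "test_fraction")
  expect_error(split_train_test(rec, 1.2), "test_fraction")
  expect_error(split_train_test(rec, 0.1), "empty test set")
})

test_that("observation builder derives durations, baselines and dummies", {
  coh <- generate_cohort(cohort_config(n_pis = 4, seed = 13))
  obs <- score_change_observations(coh)
  n_per <- table(coh$pi_id) - 1
  expect_equal(nrow(obs), sum(n_per))
  expect_true(all(obs$duration_for_next > 0))
  expect_true(all(obs$duration_from_day0_sq == obs$duration_from_day0^2))
  one <- coh[coh$pi_id == coh$pi_id[1], ]
  expect_equal(unique(obs$baseline_score[obs$pi_id == one$pi_id[1]]),
               one$total[which.min(one$day)])
  expect_true(all(c("e_large", "e_small", "p_large") %in% names(obs)))
})
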