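test_that("a single selected predictor is returned without a search", {
  obs <- score_change_observations(calib_cohort(n_pis = 4, seed = 1))
  res <- best_combination(obs, "age")
  expect_equal(res$spec$predictors, "age")
  expect_null(res$table)
  expect_error(best_combination(obs, character(0)), "no selected")
})

test_that("screening separates a strong predictor from nulls", {
  spec <- model_spec("malnutrition")
  cn <- coef_names(spec)
  truth <- hyperparameters(mu = stats::setNames(c(2, -0.3, 4), cn),
                           zeta = stats::setNames(c(0.5, 0.05, 0.2), cn),
                           sigma = 2)
  cc <- cohort_config(n_pis = 20, assessments_per_pi = c(3, 5),
                      spacing_mean = 10, spacing_sd = 4,
                      integer_scores = FALSE, seed = 301,
                      truth = truth, truth_spec = spec)
  obs <- score_change_observations(generate_cohort(cc))
  scr <- screen_predictors(obs, c("malnutrition", "dementia"),
                           mcmc = quick_mcmc(seed = 1, warmup = 400,
                                             draws = 600),
                           control = selection_config(n_repetitions = 3))
  expect_gt(scr$screened[["malnutrition"]], 0.95)
  expect_lt(scr$screened[["dementia"]], 0.95)
  expect_equal(scr$selected, "malnutrition")
  expect_true(is.finite(scr$base_log_ml))
})

test_that("the full selection procedure is seeded and self-consistent", {
  spec <- model_spec("malnutrition")
  cn <- coef_names(spec)
  truth <- hyperparameters(mu = stats::setNames(c(2, -0.3, 4), cn),
                           zeta = stats::setNames(c(0.5, 0.05, 0.2), cn),
                           sigma = 2)
  cc <- cohort_config(n_pis = 10, assessments_per_pi = c(3, 4),
                      spacing_mean = 10, spacing_sd = 4,
                      integer_scores = FALSE, seed = 77,
                      truth = truth, truth_spec = spec)
  obs <- score_change_observations(generate_cohort(cc))
  ctrl <- selection_config(n_folds = 2, n_repetitions = 2)
  mc <- quick_mcmc(seed = 4, warmup = 300, draws = 400)
  s1 <- select_final(obs, c("malnutrition", "dementia"), mcmc = mc,
                     control = ctrl, seed = 5)
  s2 <- select_final(obs, c("malnutrition", "dementia"), mcmc = mc,
                     control = ctrl, seed = 5)
  expect_identical(s1$fold_candidates, s2$fold_candidates)
  expect_identical(s1$final_log_ml, s2$final_log_ml)
  expect_identical(coef_names(s1$final), coef_names(s2$final))
  # the final candidate came from the folds and has the top evidence
  expect_true(piheal:::spec_label(s1$final) %in% s1$fold_candidates$candidate)
  expect_equal(s1$final_log_ml, max(s1$all_data_evidence$log_ml, na.rm = TRUE))
  expect_error(select_final(obs[obs$pi_id %in% unique(obs$pi_id)[1], ],
                            "age", control = ctrl), "fewer PIs")
})
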