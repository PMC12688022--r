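# shared fixtures: tiny cohorts and fast MCMC settings used across tests

quick_mcmc <- function(seed = 1, chains = 2, warmup = 300, draws = 400,
                       ...) {
  mcmc_config(n_chains = chains, n_warmup = warmup, n_draws = draws,
              seed = seed, ...)
}

# small continuous-score cohort under the compact calibration truth
calib_cohort <- function(n_pis = 10, seed = 1, assessments = c(3, 4),
                         spacing_mean = 10, spacing_sd = 4) {
  ct <- calibration_truth()
  generate_cohort(cohort_config(
    n_pis = n_pis, assessments_per_pi = assessments,
    spacing_mean = spacing_mean, spacing_sd = spacing_sd,
    integer_scores = FALSE, seed = seed,
    truth = ct$truth, truth_spec = ct$spec))
}

# one small fitted model, computed once and reused across prediction tests
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      obs <- score_change_observations(calib_cohort(n_pis = 8, seed = 42))
      cache <<- sample_posterior(obs, calibration_truth()$spec,
                                 mcmc = quick_mcmc(seed = 5))
    }
    cache
  }
})

ratings_fixture <- function() {
  read_ratings(system.file("extdata", "study1_ratings_synthetic.csv",
                           package = "piheal"))
}
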