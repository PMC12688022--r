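#' Selection procedure configuration
#'
#' @param threshold Posterior-model-probability screening threshold
#'   (predictors are selected when their probability strictly exceeds it;
#'   default 0.95).
#' @param n_folds Number of random training subsets (default 5).
#' @param fold_fraction Fraction of lesions per subset (default 0.8).
#' @param n_repetitions Bridge-sampling repetitions per evidence estimate.
#' @param max_models Cap on the number of predictor combinations searched.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(threshold = 0.95, n_folds = 5,
                             fold_fraction = 0.8, n_repetitions = 5,
                             max_models = 64) {
  stopifnot(threshold > 0, threshold < 1, n_folds >= 1,
            fold_fraction > 0, fold_fraction < 1, n_repetitions >= 1)
  structure(list(threshold = threshold, n_folds = as.integer(n_folds),
                 fold_fraction = fold_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 max_models = as.integer(max_models)),
            class = "selection_config")
}

fit_and_evidence <- function(obs, spec, prior, mcmc, n_reps) {
  fit <- sample_posterior(obs, spec, prior, mcmc)
  if (fit$max_rhat >= 1.1) {
    return(list(fit = fit, ev = NULL, converged = FALSE))
  }
  ev <- suppressWarnings(log_marginal_likelihood(fit, n_repetitions = n_reps))
  list(fit = fit, ev = ev, converged = TRUE)
}

#' Screen single-predictor additions against the base model
#'
#' For each candidate predictor `p`, fits the model with the prediction gap
#' plus `p`, estimates its marginal likelihood, and computes the posterior
#' probability of that model against the base (gap-only) model under equal
#' prior model probabilities. Predictors whose probability strictly exceeds
#' the threshold are selected. Candidates failing the R-hat convergence gate
#' are excluded and reported in `flagged`.
#'
#' @param obs Score-change observations (training data).
#' @param candidates Character vector of candidate predictor names
#'   (`"duration_for_next_sq"` screens the quadratic gap term).
#' @param prior,mcmc Prior and MCMC configurations.
#' @param control A [selection_config()].
#' @return List: `screened` (named probability vector), `selected`,
#'   `flagged`, `base_log_ml`, `evidence` (per-candidate table).
#' @export
screen_predictors <- function(obs, candidates, prior = prior_config(),
                              mcmc = mcmc_config(),
                              control = selection_config()) {
  if (!length(candidates)) stop("no candidate predictors supplied", call. = FALSE)
  base <- fit_and_evidence(obs, model_spec(), prior, mcmc,
                           control$n_repetitions)
  if (!base$converged) stop("base model failed the R-hat gate", call. = FALSE)
  screened <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  logml <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  flagged <- character(0)
  for (p in candidates) {
    res <- fit_and_evidence(obs, model_spec(p), prior, mcmc,
                            control$n_repetitions)
    if (!res$converged) {
      flagged <- c(flagged, p)
      next
    }
    logml[p] <- res$ev$log_ml
    screened[p] <- posterior_model_probability(res$ev$log_ml,
                                               base$ev$log_ml)
  }
  selected <- names(screened)[!is.na(screened) & screened > control$threshold]
  list(screened = screened, selected = selected, flagged = flagged,
       base_log_ml = base$ev$log_ml,
       evidence = data.frame(predictor = candidates, log_ml = logml,
                             probability = screened, row.names = NULL))
}

#' Best combination of selected predictors
#'
#' Fits every non-empty subset of the selected predictors (each on top of
#' the base prediction-gap term) and returns the subset with the highest log
#' marginal likelihood. Combinations whose evidence ties the best within the
#' combined repetition SD resolve to the smaller model, then
#' lexicographically.
#'
#' @inheritParams screen_predictors
#' @param selected Non-empty character vector of selected predictors.
#' @return List: `spec` (the winning [model_spec()]), `table` (per-subset
#'   evidence).
#' @export
best_combination <- function(obs, selected, prior = prior_config(),
                             mcmc = mcmc_config(),
                             control = selection_config()) {
  if (!length(selected)) stop("no selected predictors", call. = FALSE)
  subsets <- unlist(lapply(seq_along(selected), function(k)
    utils::combn(selected, k, simplify = FALSE)), recursive = FALSE)
  if (length(subsets) > control$max_models) {
    stop(sprintf("combination search of %d models exceeds the cap of %d",
                 length(subsets), control$max_models), call. = FALSE)
  }
  if (length(subsets) == 1) {
    return(list(spec = model_spec(subsets[[1]]), table = NULL))
  }
  rows <- lapply(subsets, function(ss) {
    res <- fit_and_evidence(obs, model_spec(ss), prior, mcmc,
                            control$n_repetitions)
    data.frame(label = paste(sort(ss), collapse = "+"),
               size = length(ss),
               log_ml = if (res$converged) res$ev$log_ml else NA_real_,
               sd = if (res$converged) res$ev$sd else NA_real_,
               converged = res$converged, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$log_ml))
  if (!length(ok)) stop("no combination passed the convergence gate", call. = FALSE)
  best_i <- ok[which.max(tab$log_ml[ok])]
  tol <- sqrt(tab$sd[best_i]^2 + tab$sd[ok]^2)
  tied <- ok[tab$log_ml[ok] >= tab$log_ml[best_i] - tol]
  tied <- tied[order(tab$size[tied], tab$label[tied])]
  list(spec = model_spec(subsets[[tied[1]]]), table = tab)
}

#' Full predictor-selection procedure
#'
#' Repeats screen-then-combine on random lesion-level subsets of the
#' training data (the configured fraction, drawn without replacement), then
#' evaluates each distinct candidate's log marginal likelihood on all
#' training data; the candidate with the highest evidence is the best model.
#' Folds with an empty selection fall back to the base model. Ties across
#' candidates resolve to fewer predictors, then lexicographically. Seeded
#' runs are reproducible.
#'
#' @inheritParams screen_predictors
#' @param seed Integer seed for the fold draws.
#' @return An object of class `selection_report`: `fold_candidates`
#'   (per-fold winning spec labels and their subset evidence), `final` (the
#'   best [model_spec()]), `final_log_ml`, `all_data_evidence` (per distinct
#'   candidate), `screens` (per-fold screening output).
#' @export
select_final <- function(obs, candidates, prior = prior_config(),
                         mcmc = mcmc_config(), control = selection_config(),
                         seed = 1L) {
  ids <- unique(as.character(obs$pi_id))
  if (length(ids) < control$n_folds) {
    stop("fewer PIs than folds", call. = FALSE)
  }
  set.seed(seed)
  fold_specs <- vector("list", control$n_folds)
  screens <- vector("list", control$n_folds)
  for (f in seq_len(control$n_folds)) {
    sub_ids <- sample(ids, max(2, round(length(ids) * control$fold_fraction)))
    sub <- obs[obs$pi_id %in% sub_ids, , drop = FALSE]
    scr <- screen_predictors(sub, candidates, prior, mcmc, control)
    screens[[f]] <- scr
    fold_specs[[f]] <- if (length(scr$selected)) {
      best_combination(sub, scr$selected, prior, mcmc, control)$spec
    } else {
      model_spec()
    }
  }
  labels <- vapply(fold_specs, spec_label, character(1))
  distinct <- !duplicated(labels)
  cand_specs <- fold_specs[distinct]
  cand_labels <- labels[distinct]
  ev <- lapply(cand_specs, function(sp)
    fit_and_evidence(obs, sp, prior, mcmc, control$n_repetitions))
  logml <- vapply(ev, function(e) if (e$converged) e$ev$log_ml else NA_real_,
                  numeric(1))
  sds <- vapply(ev, function(e) if (e$converged) e$ev$sd else NA_real_,
                numeric(1))
  ok <- which(!is.na(logml))
  if (!length(ok)) stop("no candidate passed the convergence gate", call. = FALSE)
  best_i <- ok[which.max(logml[ok])]
  sizes <- vapply(cand_specs, function(sp) length(coef_names(sp)), integer(1))
  tol <- sqrt(sds[best_i]^2 + sds[ok]^2)
  tied <- ok[logml[ok] >= logml[best_i] - tol]
  tied <- tied[order(sizes[tied], cand_labels[tied])]
  final_i <- tied[1]
  structure(list(
    fold_candidates = data.frame(fold = seq_len(control$n_folds),
                                 candidate = labels,
                                 stringsAsFactors = FALSE),
    final = cand_specs[[final_i]],
    final_log_ml = logml[final_i],
    all_data_evidence = data.frame(candidate = cand_labels, log_ml = logml,
                                   sd = sds, stringsAsFactors = FALSE),
    screens = screens,
    control = control, seed = seed),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Predictor selection report\n")
  cat("  fold candidates:", paste(x$fold_candidates$candidate, collapse = "; "),
      "\n")
  cat("  best model:", spec_label(x$final),
      sprintf("(log ML %.3f on all training data)\n", x$final_log_ml))
  invisible(x)
}
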