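#' Write / read assessment-record CSV
#'
#' Columns: `pi_id`, `day`, `depth`, the six subscales `e,s,i,g,n,p`
#' (integers in their permissible sets), `age`, and the binary risk-factor
#' and comorbidity flags. Derived quantities (totals, changes, durations,
#' dummies) are always recomputed, never read. On reading, lesions with a
#' single assessment are excluded with a warning (one consultation gives no
#' observable change), and validation failures name the offending rows and
#' columns.
#'
#' @param records Assessment records (e.g. a [generate_cohort()] result).
#' @param path CSV path.
#' @return `write_assessments` returns `path` invisibly; `read_assessments`
#'   returns a validated records data.frame.
#' @export
write_assessments <- function(records, path) {
  keep <- intersect(c("pi_id", "day", "depth", .designr_subscales, "age",
                      risk_factor_names(), comorbidity_names()),
                    names(records))
  utils::write.csv(as.data.frame(records)[, keep], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_assessments
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pi_id", "day", .designr_subscales)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("assessment file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  known <- c("pi_id", "day", "depth", .designr_subscales, "age",
             risk_factor_names(), comorbidity_names())
  unknown <- setdiff(names(df), known)
  if (length(unknown)) stop("unknown column(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  problems <- character(0)
  for (nm in .designr_subscales) {
    ok <- df[[nm]] %in% designr_permissible(nm)
    if (!all(ok)) problems <- c(problems, sprintf(
      "column '%s': impermissible value(s) in row(s) %s", nm,
      paste(which(!ok), collapse = ",")))
  }
  for (nm in intersect(c(risk_factor_names(), comorbidity_names()), names(df))) {
    ok <- df[[nm]] %in% c(0L, 1L)
    if (!all(ok)) problems <- c(problems, sprintf(
      "column '%s': non-binary value(s) in row(s) %s", nm,
      paste(which(!ok), collapse = ",")))
  }
  if (any(df$day != round(df$day))) {
    problems <- c(problems, "column 'day': non-integer day index")
  }
  for (id in unique(df$pi_id)) {
    days <- df$day[df$pi_id == id]
    if (any(diff(sort(days)) == 0) || is.unsorted(days)) {
      problems <- c(problems, sprintf(
        "PI '%s': day indices must strictly increase", id))
    }
  }
  if (length(problems)) {
    stop("assessment validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  counts <- table(df$pi_id)
  singles <- names(counts)[counts < 2]
  if (length(singles)) {
    warning("excluding single-assessment PI(s): ",
            paste(singles, collapse = ", "))
    df <- df[!(df$pi_id %in% singles), , drop = FALSE]
  }
  df$total <- vapply(seq_len(nrow(df)), function(j) total_score(df[j, ]),
                     numeric(1))
  df
}

#' Run a pipeline stage
#'
#' Composable stages reproducing the full modelling workflow on disk:
#' `simulate` writes an assessment CSV (plus provenance), `fit` samples the
#' posterior of a given spec on the training split, `select` runs the
#' predictor-selection procedure, `predict` produces the sequential
#' prediction report and pooled coverage on the test split, and `evaluate`
#' computes the expert-vignette metrics from a ratings CSV. Every stage
#' writes a provenance JSON (seed, configuration) next to its artifact.
#'
#' @param cfg A list: `output_dir`; optionally `records` (CSV path; defaults
#'   to the simulate artifact), `cohort` (a [cohort_config()]), `spec`
#'   predictors, `candidates`, `prior`, `mcmc`, `selection`
#'   ([selection_config()]), `level`, `test_fraction`, `ratings` (CSV path),
#'   `seed`.
#' @param command One of `simulate`, `fit`, `select`, `predict`, `evaluate`.
#' @return The stage's main artifact, invisibly (also written to disk).
#' @export
run_pipeline <- function(cfg, command = c("simulate", "fit", "select",
                                          "predict", "evaluate")) {
  command <- match.arg(command)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  prov <- function(stage, extra = list()) {
    jsonlite::write_json(
      c(list(stage = stage, seed = cfg$seed %||% 1L,
             package_version = as.character(utils::packageVersion("piheal")),
             timestamp = format(Sys.time(), tz = "UTC")), extra),
      out(paste0(stage, "_provenance.json")), auto_unbox = TRUE, digits = NA)
  }
  records_path <- cfg$records %||% out("assessments.csv")

  if (command == "simulate") {
    cc <- cfg$cohort %||% cohort_config(seed = cfg$seed %||% 1L)
    cohort <- generate_cohort(cc)
    write_assessments(cohort, records_path)
    prov("simulate", list(n_pis = cc$n_pis, cohort_seed = cc$seed,
                          clip_events = attr(cohort, "clip_events")))
    return(invisible(cohort))
  }
  if (command == "evaluate") {
    ratings <- read_ratings(cfg$ratings)
    rounds <- sort(unique(ratings$round))
    tabs <- lapply(rounds, function(r)
      vignette_metrics(ratings[ratings$round == r, ]))
    res <- do.call(rbind, lapply(seq_along(rounds), function(i) {
      p <- tabs[[i]]$pooled
      data.frame(round = rounds[i],
                 agreement = p$agreement$proportion,
                 agreement_counts = sprintf("%d/%d", p$agreement$numerator,
                                            p$agreement$denominator),
                 improvement = if (is.null(p$improvement)) NA_real_ else
                   p$improvement$proportion,
                 improvement_counts = if (is.null(p$improvement)) "NULL" else
                   sprintf("%d/%d", p$improvement$numerator,
                           p$improvement$denominator))
    }))
    utils::write.csv(res, out("vignette_metrics.csv"), row.names = FALSE)
    prov("evaluate")
    return(invisible(res))
  }

  if (!file.exists(records_path)) {
    stop("missing assessment records at ", records_path,
         "; run the 'simulate' command first (or point cfg$records at a CSV)",
         call. = FALSE)
  }
  records <- read_assessments(records_path)
  split <- split_train_test(records, cfg$test_fraction %||% 0.2)
  train_obs <- score_change_observations(split$train)
  prior <- cfg$prior %||% prior_config()
  mcmc <- cfg$mcmc %||% mcmc_config(seed = cfg$seed %||% 1L)

  if (command == "fit") {
    spec <- model_spec(cfg$spec %||% character(0))
    fit <- sample_posterior(train_obs, spec, prior, mcmc)
    message(sprintf("R-hat gate: max %.3f (%s)", fit$max_rhat,
                    if (fit$max_rhat < 1.1) "passed" else "FAILED"))
    utils::write.csv(summary(fit), out("posterior_summary.csv"),
                     row.names = FALSE)
    saveRDS(fit, out("fit.rds"))
    prov("fit", list(spec = coef_names(spec), max_rhat = fit$max_rhat,
                     divergences = fit$divergences))
    return(invisible(fit))
  }
  if (command == "select") {
    sel <- select_final(train_obs, cfg$candidates %||% c(
      "age", "baseline_score", "duration_from_day0", "duration_for_next_sq"),
      prior, mcmc, cfg$selection %||% selection_config(),
      seed = cfg$seed %||% 1L)
    jsonlite::write_json(list(
      fold_candidates = sel$fold_candidates,
      final = spec_label(sel$final),
      final_log_ml = sel$final_log_ml,
      all_data_evidence = sel$all_data_evidence),
      out("selection_report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    utils::write.csv(sel$all_data_evidence, out("evidence_table.csv"),
                     row.names = FALSE)
    prov("select")
    return(invisible(sel))
  }
  if (command == "predict") {
    fit_path <- out("fit.rds")
    if (!file.exists(fit_path)) {
      stop("missing fitted model at ", fit_path,
           "; run the 'fit' command first", call. = FALSE)
    }
    fit <- readRDS(fit_path)
    reports <- lapply(unique(split$test$pi_id), function(id)
      sequential_predict(fit, split$test[split$test$pi_id == id, ],
                         level = cfg$level %||% 0.90))
    report <- do.call(rbind, reports)
    cov <- coverage_probability(report, report$actual)
    utils::write.csv(report, out("prediction_report.csv"), row.names = FALSE)
    utils::write.csv(cov$per_pi, out("coverage.csv"), row.names = FALSE)
    prov("predict", list(pooled_coverage = cov$pooled$proportion,
                         level = cfg$level %||% 0.90))
    return(invisible(cov))
  }
}
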