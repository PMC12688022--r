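#' Synthetic cohort configuration
#'
#' Defines a longitudinal pressure-injury cohort with the statistical
#' structure the hierarchical model assumes: per-lesion coefficient vectors
#' drawn from the multivariate normal population distribution, successive
#' score changes drawn from the Gaussian likelihood, covariates drawn from
#' configured prevalences. The defaults emulate the training cohort of the
#' home-care consultation study: 14 lesions followed for a mean of about 29
#' days (3 assessments about 15 days apart), patients aged 79.4 (SD 8.4)
#' years, risk-factor and comorbidity prevalences at the published cohort
#' frequencies, and generating hyperparameters at the published posterior
#' means of the best model (residual SD 2 score points: not published,
#' chosen as a realistic assessment-to-assessment fluctuation).
#'
#' @param n_pis Number of pressure injuries (>= 1); lesions are treated as
#'   independent units.
#' @param assessments_per_pi Integer range `c(min, max)` (or single count) of
#'   assessments per lesion; every lesion has at least 2.
#' @param spacing_mean,spacing_sd Mean/SD (days) of the positive gap between
#'   consecutive assessments (truncated-normal, rounded to whole days >= 1).
#' @param covariate_prevalences Named probabilities for the binary
#'   risk-factor and comorbidity flags.
#' @param age_mean,age_sd Age distribution (years).
#' @param baseline_mean,baseline_sd Distribution of the initial DESIGN-R
#'   2020 total (truncated to the permissible 0-66 range).
#' @param truth An [hyperparameters()] object: the generating population
#'   parameters, in the coefficient order of `truth_spec`.
#' @param truth_spec The [model_spec()] whose design the truth refers to.
#' @param integer_scores Round simulated changes to whole score points and
#'   decompose totals into permissible subscale values (the instrument's
#'   behaviour). `FALSE` keeps continuous totals for pure model checks.
#' @param subscale_weights Proportional allocation of a total over the six
#'   subscales used when decomposing simulated totals.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_pis = 14,
                          assessments_per_pi = c(2, 4),
                          spacing_mean = 14.7, spacing_sd = 8,
                          covariate_prevalences = default_prevalences(),
                          age_mean = 79.4, age_sd = 8.4,
                          baseline_mean = 19, baseline_sd = 6,
                          truth = default_truth(),
                          truth_spec = best_model_spec(),
                          integer_scores = TRUE,
                          subscale_weights = default_subscale_weights(),
                          seed = 1L) {
  if (n_pis < 1) stop("n_pis must be >= 1", call. = FALSE)
  if (length(assessments_per_pi) == 1) {
    assessments_per_pi <- rep(assessments_per_pi, 2)
  }
  if (assessments_per_pi[1] < 2) stop("every PI needs >= 2 assessments",
                                      call. = FALSE)
  if (spacing_mean <= 0 || spacing_sd < 0) {
    stop("assessment spacing must be strictly positive", call. = FALSE)
  }
  if (any(covariate_prevalences < 0 | covariate_prevalences > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(truth, "hbr_hyperparameters"),
            inherits(truth_spec, "hbr_model_spec"))
  if (length(truth$mu) != length(coef_names(truth_spec))) {
    stop("truth dimension does not match truth_spec", call. = FALSE)
  }
  structure(list(n_pis = as.integer(n_pis),
                 assessments_per_pi = as.integer(assessments_per_pi),
                 spacing_mean = spacing_mean, spacing_sd = spacing_sd,
                 covariate_prevalences = covariate_prevalences,
                 age_mean = age_mean, age_sd = age_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 truth = truth, truth_spec = truth_spec,
                 integer_scores = isTRUE(integer_scores),
                 subscale_weights = subscale_weights,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_prevalences <- function() {
  stats::setNames(
    c(0.64, 0.64, 0.43, 0.36, 0.57, 0.43, 0.29, 0.43,
      0.36, 0.21, 0.14, 0.14, 0.36, 0.14, 0.14),
    c(risk_factor_names(), comorbidity_names()))
}

#' @rdname cohort_config
#' @export
default_subscale_weights <- function() {
  c(e = 0.10, s = 0.35, i = 0.08, g = 0.17, n = 0.12, p = 0.18)
}

#' Generating hyperparameters at the published best-model posterior means
#'
#' Coefficient order of [best_model_spec()]: intercept, prediction gap and
#' its square, age, elapsed duration and its square, baseline total.
#' The correlation Cholesky factor defaults to the identity.
#' @return An [hyperparameters()] object.
#' @export
default_truth <- function() {
  cn <- coef_names(best_model_spec())
  hyperparameters(
    mu = stats::setNames(
      c(3.91, -0.55, 0.02, 0.05, -0.52, 0.02, -0.10), cn),
    zeta = stats::setNames(
      c(0.97, 0.17, 0.01, 0.04, 0.26, 0.01, 0.13), cn),
    sigma = 2)
}

#' Moderate-heterogeneity truth for calibration experiments
#'
#' A compact generating truth (intercept, prediction gap, age) in which each
#' coefficient contributes about one score point of between-lesion
#' dispersion at typical design values, balanced against a residual SD of 2.
#' Calibration and recovery simulations use this regime because a cohort of
#' a few dozen lesions actually identifies its covariance: the full
#' best-model structure has lesion-constant covariates whose random effects
#' are collinear within lesion, so its 7x7 covariance is unidentifiable at
#' study-scale sample sizes and predictive intervals stay conservative.
#'
#' @return List with `spec` (the [model_spec()]) and `truth`
#'   ([hyperparameters()]).
#' @export
calibration_truth <- function() {
  spec <- model_spec("age")
  cn <- coef_names(spec)
  list(spec = spec,
       truth = hyperparameters(
         mu = stats::setNames(c(2, -0.3, 0.03), cn),
         zeta = stats::setNames(c(0.5, 0.05, 0.01), cn),
         sigma = 2))
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws covariates, per-lesion effect vectors from `MultiNormal(mu, Sigma)`,
#' assessment days, and successive totals from the Gaussian change
#' likelihood. Totals are clipped to the permissible 0-66 range (clipping
#' events are counted in the `clip_events` attribute) and, when
#' `integer_scores`, decomposed into permissible subscale values preserving
#' the total within one point. Identical configurations (including seed)
#' give identical datasets.
#'
#' @param config A [cohort_config()].
#' @return A data.frame of assessment records (class `pi_cohort`): `pi_id`,
#'   `day`, `depth`, subscales `e,s,i,g,n,p`, `total`, `age` and the binary
#'   flags; attributes `config`, `truth`, `clip_events`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- config$truth
  K <- length(truth$mu)
  Sig_chol <- assemble_covariance_chol(truth$zeta, truth$omega_chol)
  if (any(!is.finite(Sig_chol))) stop("degenerate covariance in truth",
                                      call. = FALSE)
  spec <- config$truth_spec
  set.seed(config$seed)
  prev <- config$covariate_prevalences
  rows <- list()
  clip_events <- 0L
  for (pi in seq_len(config$n_pis)) {
    id <- sprintf("PI%03d", pi)
    age <- stats::rnorm(1, config$age_mean, config$age_sd)
    flags <- stats::setNames(as.integer(stats::runif(length(prev)) < prev),
                             names(prev))
    beta <- truth$mu + drop(Sig_chol %*% stats::rnorm(K))
    n_assess <- sample(seq(config$assessments_per_pi[1],
                           config$assessments_per_pi[2]), 1)
    gaps <- pmax(1, round(stats::rnorm(n_assess - 1, config$spacing_mean,
                                       config$spacing_sd)))
    days <- c(0, cumsum(gaps))
    y0 <- stats::rnorm(1, config$baseline_mean, config$baseline_sd)
    y0 <- min(max(y0, 0), 66)
    if (config$integer_scores) y0 <- round(y0)
    totals <- numeric(n_assess)
    totals[1] <- y0
    depth <- sample(2:5, 1)                       # d2-or-deeper lesions
    sub <- vector("list", n_assess)
    sub[[1]] <- decompose_total(if (config$integer_scores) totals[1] else
      round(totals[1]), config$subscale_weights)
    if (config$integer_scores) totals[1] <- sum(unlist(sub[[1]]))
    for (j in seq_len(n_assess)[-1]) {
      state <- list(duration_for_next = days[j] - days[j - 1],
                    duration_from_day0 = days[j - 1],
                    duration_from_day0_sq = days[j - 1]^2,
                    baseline_score = totals[1],
                    latest_score = totals[j - 1],
                    age = age)
      state <- c(state, as.list(flags), subscale_dummies(sub[[j - 1]]))
      x <- build_design_row(state, spec)
      dchg <- sum(x * beta) + stats::rnorm(1, 0, truth$sigma)
      if (config$integer_scores) dchg <- round(dchg)
      yj <- totals[j - 1] + dchg
      if (yj < 0 || yj > 66) {
        clip_events <- clip_events + 1L
        yj <- min(max(yj, 0), 66)
      }
      if (config$integer_scores) {
        sub[[j]] <- decompose_total(yj, config$subscale_weights)
        yj <- sum(unlist(sub[[j]]))
      } else {
        sub[[j]] <- sub[[j - 1]]
      }
      totals[j] <- yj
    }
    for (j in seq_len(n_assess)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pi_id = id, day = days[j], depth = depth,
        as.data.frame(sub[[j]]), total = totals[j],
        age = age, as.data.frame(as.list(flags)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "truth") <- truth
  attr(out, "clip_events") <- clip_events
  class(out) <- c("pi_cohort", "data.frame")
  out
}

subscale_dummies <- function(sub) {
  out <- list()
  for (nm in .designr_subscales) {
    dm <- binarize_subscale(nm, sub[[nm]])
    out[[paste0(nm, "_large")]] <- dm[["large"]]
    out[[paste0(nm, "_small")]] <- dm[["small"]]
  }
  out
}

#' Decompose a total score into permissible subscale values
#'
#' Allocates a target total over the six scored subscales proportionally to
#' `weights`, stepping each subscale through its permissible value set; the
#' result sums to the target within one point (exactly, whenever the target
#' is attainable by unit steps).
#'
#' @param total Target total (integer, 0-66).
#' @param weights Named proportional allocation over `e,s,i,g,n,p`.
#' @return Named list of subscale scores.
#' @export
decompose_total <- function(total, weights = default_subscale_weights()) {
  total <- as.integer(round(total))
  if (total < 0 || total > 66) stop("total must lie in 0..66", call. = FALSE)
  g <- designr_value_grid()
  dev <- abs(g$sums - total)
  best <- which(dev == min(dev))
  if (length(best) > 1) {
    w <- weights[.designr_subscales] / sum(weights)
    target <- matrix(total * w, length(best), 6, byrow = TRUE)
    score <- rowSums((g$grid[best, , drop = FALSE] - target)^2)
    best <- best[order(score, best)[1]]   # deterministic tie-break
  }
  as.list(g$grid[best, ])
}

# cached enumeration of all permissible subscale combinations
designr_value_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- as.matrix(expand.grid(
        lapply(stats::setNames(nm = .designr_subscales), designr_permissible),
        KEEP.OUT.ATTRS = FALSE))
      storage.mode(grid) <- "integer"
      cache <<- list(grid = grid, sums = rowSums(grid))
    }
    cache
  }
})

#' Train/test split by follow-up length
#'
#' Splits a cohort by lesion (never by record): the configured fraction of
#' lesions with the longest follow-up form the test set, demonstrating the
#' time robustness of the model; ties break lexicographically by lesion id.
#'
#' @param data A cohort data.frame (`pi_id`, `day`, ...).
#' @param test_fraction Proportion in (0, 1); the test count is
#'   `round(n_pis * test_fraction)` and must be >= 1.
#' @return List with `train` and `test` data.frames.
#' @export
split_train_test <- function(data, test_fraction = 0.2) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  ids <- unique(as.character(data$pi_id))
  if (length(ids) < 2) stop("need at least 2 PIs to split", call. = FALSE)
  fu <- vapply(ids, function(id) {
    dd <- data$day[data$pi_id == id]
    max(dd) - min(dd)
  }, numeric(1))
  n_test <- round(length(ids) * test_fraction)
  if (n_test < 1) stop("test_fraction yields an empty test set", call. = FALSE)
  ord <- ids[order(-fu, ids)]
  test_ids <- ord[seq_len(n_test)]
  list(train = data[!(data$pi_id %in% test_ids), , drop = FALSE],
       test = data[data$pi_id %in% test_ids, , drop = FALSE])
}

#' Score-change observations from assessment records
#'
#' Builds the modelled units: one row per consecutive assessment pair of one
#' lesion, with the signed change `d` of the total score, the prediction gap
#' and elapsed duration (and squares), the baseline and latest totals, the
#' large/small subscale dummies of the latest assessment, and the patient
#' covariates.
#'
#' @param records Assessment records (cohort data.frame or validated CSV
#'   import); days must strictly increase within each lesion.
#' @return data.frame of observations, one per change.
#' @export
score_change_observations <- function(records) {
  records <- as.data.frame(records)
  obs <- list()
  flags <- intersect(c(risk_factor_names(), comorbidity_names()),
                     names(records))
  has_sub <- all(.designr_subscales %in% names(records))
  for (id in unique(as.character(records$pi_id))) {
    rr <- records[records$pi_id == id, , drop = FALSE]
    rr <- rr[order(rr$day), , drop = FALSE]
    if (nrow(rr) < 2) next
    if (any(diff(rr$day) <= 0)) {
      stop("non-monotone or duplicated day indices for PI ", id, call. = FALSE)
    }
    tot <- if ("total" %in% names(records)) rr$total else
      vapply(seq_len(nrow(rr)), function(j) total_score(rr[j, ]), numeric(1))
    for (j in seq_len(nrow(rr))[-1]) {
      row <- data.frame(
        pi_id = id,
        t = rr$day[j - 1],
        duration_for_next = rr$day[j] - rr$day[j - 1],
        duration_from_day0 = rr$day[j - 1] - rr$day[1],
        duration_from_day0_sq = (rr$day[j - 1] - rr$day[1])^2,
        d = tot[j] - tot[j - 1],
        baseline_score = tot[1],
        latest_score = tot[j - 1],
        stringsAsFactors = FALSE)
      if (has_sub) {
        row <- cbind(row, as.data.frame(
          subscale_dummies(as.list(rr[j - 1, .designr_subscales]))))
      }
      for (f in c("age", flags)) if (f %in% names(rr)) row[[f]] <- rr[[f]][j - 1]
      obs[[length(obs) + 1L]] <- row
    }
  }
  if (!length(obs)) stop("no score-change observations (all PIs have a single assessment)",
                         call. = FALSE)
  do.call(rbind, obs)
}
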