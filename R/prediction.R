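#' Posterior predictive draws of a future score change
#'
#' For each posterior draw, a coefficient vector is formed and a change is
#' drawn from the Gaussian likelihood. In `"population"` mode the coefficient
#' vector is the hierarchical mean of the draw (the between-lesion scales are
#' set to zero, the rule applied to a lesion with no prediction history); in
#' `"pi_specific"` mode a fresh coefficient vector is drawn from
#' `MultiNormal(mu, Sigma)` per posterior draw, propagating between-lesion
#' variability into the predictive distribution.
#'
#' In `"posterior"` mode the lesion's own fitted coefficient draws are used
#' (posterior-updating: the coefficient vector conditioned on the lesion's
#' accumulated observed changes), which requires `pi_id` to name a lesion
#' present in the fitted data.
#'
#' @param fit An `hbr_fit`.
#' @param obs Named list / one-row data.frame with `duration_for_next` and
#'   the fitted spec's predictors.
#' @param mode `"population"`, `"pi_specific"` or `"posterior"`.
#' @param pi_id Lesion id, required for `"posterior"` mode.
#' @return Numeric vector of predictive draws of the change `d`.
#' @export
predictive_distribution <- function(fit, obs,
                                    mode = c("population", "pi_specific",
                                             "posterior"),
                                    pi_id = NULL) {
  stopifnot(inherits(fit, "hbr_fit"))
  mode <- match.arg(mode)
  x <- build_design_row(obs, fit$spec)
  hp <- hyper_draws(fit)
  n <- nrow(hp$mu)
  lin <- drop(hp$mu %*% x)
  if (mode == "posterior") {
    if (is.null(pi_id) || !(pi_id %in% fit$data$pi_ids)) {
      stop("posterior mode requires a pi_id present in the fitted data",
           call. = FALSE)
    }
    dm <- as_draws_matrix(fit)
    cols <- paste0("beta[", pi_id, ",", coef_names(fit$spec), "]")
    lin <- drop(dm[, cols, drop = FALSE] %*% x)
  }
  if (mode == "pi_specific") {
    K <- length(x)
    # x' Sigma_chol(draw) per draw: Sigma_chol = diag(zeta) L
    zz <- matrix(stats::rnorm(n * K), n, K)
    xs <- hp$zeta * matrix(x, n, K, byrow = TRUE)   # row: x * zeta
    # (x*zeta)' L z: compute row-wise using stored L draws
    lin <- lin + vapply(seq_len(n), function(i) {
      sum((xs[i, ] %*% hp$L[[i]]) * zz[i, ])
    }, numeric(1))
  }
  stats::rnorm(n, lin, hp$sigma)
}

# extract mu (n x K), zeta (n x K), sigma (n), and Omega chol factors per draw
hyper_draws <- function(fit) {
  cache <- attr(fit, "hyper_cache")
  if (!is.null(cache)) return(cache)
  K <- fit$data$K; n_pi <- fit$data$n_pi
  uc <- do.call(rbind, fit$uc_draws)
  n <- nrow(uc)
  P <- K * (K - 1) / 2
  mu <- uc[, 1:K, drop = FALSE]
  zeta <- exp(uc[, K + 1:K, drop = FALSE])
  sigma <- exp(uc[, 2 * K + P + 1])
  L <- lapply(seq_len(n), function(i)
    cpc_to_chol(tanh(uc[i, 2 * K + seq_len(P)]), K))
  list(mu = mu, zeta = zeta, sigma = sigma, L = L)
}

#' Central prediction interval from predictive draws
#'
#' @param draws Numeric vector of predictive draws (>= 100).
#' @param level Nominal coverage in (0, 1), default 0.90.
#' @return An object of class `prediction_interval` with `lower`, `upper`,
#'   `point` (predictive median) and `level`.
#' @export
prediction_interval <- function(draws, level = 0.90) {
  if (length(draws) < 100) stop("need at least 100 predictive draws",
                                call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  q <- stats::quantile(draws, c((1 - level) / 2, 0.5, 1 - (1 - level) / 2),
                       names = FALSE)
  structure(list(lower = q[1], point = q[2], upper = q[3], level = level),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("%g%% prediction interval: [%.2f, %.2f] (median %.2f)\n",
              100 * x$level, x$lower, x$upper, x$point))
  invisible(x)
}

#' Sequential next-assessment predictions for one held-out lesion
#'
#' For each assessment after the first, covariates are built from the
#' preceding assessment (prediction gap = days to the next assessment,
#' elapsed duration = days since the lesion's first assessment, baseline
#' total from the first assessment) and a prediction interval for the next
#' total is formed as the last observed total plus the predicted change.
#' Totals are not clipped when checking coverage; interval endpoints are
#' inclusive (scores are integers and ties occur).
#'
#' @param fit An `hbr_fit`.
#' @param records Assessment records of one lesion (>= 2 rows, strictly
#'   increasing days; needs `total` or the six subscales, plus the spec's
#'   patient covariates).
#' @param level Nominal interval level.
#' @param mode Predictive mode, see [predictive_distribution()]; the default
#'   population mode is the zero-between-lesion-scale rule used for a lesion
#'   with no history.
#' @return data.frame: `pi_id`, `from_day`, `to_day`, `lower`, `upper`,
#'   `point` (all on the total-score scale), `actual`, `covered`.
#' @export
sequential_predict <- function(fit, records, level = 0.90,
                               mode = c("population", "pi_specific",
                                        "posterior")) {
  mode <- match.arg(mode)
  records <- as.data.frame(records)
  records <- records[order(records$day), , drop = FALSE]
  if (nrow(records) < 2) stop("need at least 2 assessments", call. = FALSE)
  if (any(diff(records$day) <= 0)) {
    stop("non-monotone or duplicated day indices", call. = FALSE)
  }
  obs <- score_change_observations(records)
  out <- lapply(seq_len(nrow(obs)), function(j) {
    dr <- predictive_distribution(fit, obs[j, , drop = FALSE], mode = mode,
                                  pi_id = obs$pi_id[j])
    ci <- prediction_interval(dr, level)
    base <- obs$latest_score[j]
    actual <- base + obs$d[j]
    data.frame(pi_id = obs$pi_id[j],
               from_day = obs$t[j],
               to_day = obs$t[j] + obs$duration_for_next[j],
               lower = base + ci$lower, upper = base + ci$upper,
               point = base + ci$point,
               actual = actual,
               covered = actual >= base + ci$lower & actual <= base + ci$upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Coverage probability of prediction intervals
#'
#' The fail-safe validation statistic: the fraction of observed
#' next-assessment totals falling inside their nominal-level prediction
#' intervals, per lesion and pooled (sum of covered over sum of assessed).
#' Interval bounds are inclusive.
#'
#' @param intervals data.frame with `pi_id`, `lower`, `upper` (one row per
#'   predicted assessment), e.g. from [sequential_predict()].
#' @param actual Observed totals, aligned one-to-one with `intervals`.
#' @return An object of class `coverage_result`: `per_pi` (data.frame with
#'   covered/assessed counts and fraction) and `pooled`.
#' @export
coverage_probability <- function(intervals, actual) {
  if (nrow(intervals) != length(actual)) {
    stop("intervals and actual values are misaligned", call. = FALSE)
  }
  covered <- actual >= intervals$lower & actual <= intervals$upper
  ids <- as.character(intervals$pi_id)
  per <- do.call(rbind, lapply(unique(ids), function(id) {
    sel <- ids == id
    data.frame(pi_id = id, covered = sum(covered[sel]),
               assessed = sum(sel),
               proportion = mean(covered[sel]),
               stringsAsFactors = FALSE)
  }))
  coverage_from_counts(per$covered, per$assessed, per$pi_id)
}

#' @rdname coverage_probability
#' @param covered,assessed Per-lesion counts of covered and assessed
#'   predictions.
#' @param pi_ids Optional lesion ids.
#' @export
coverage_from_counts <- function(covered, assessed, pi_ids = NULL) {
  stopifnot(length(covered) == length(assessed), all(covered <= assessed),
            all(covered >= 0), all(assessed >= 1))
  if (is.null(pi_ids)) pi_ids <- sprintf("PI%03d", seq_along(covered))
  per <- data.frame(pi_id = as.character(pi_ids),
                    covered = as.integer(covered),
                    assessed = as.integer(assessed),
                    proportion = covered / assessed,
                    stringsAsFactors = FALSE)
  structure(list(per_pi = per,
                 pooled = list(covered = sum(per$covered),
                               assessed = sum(per$assessed),
                               proportion = sum(per$covered) / sum(per$assessed))),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("Pooled coverage %.2f (%d/%d) over %d lesion(s)\n",
              p$proportion, p$covered, p$assessed, nrow(x$per_pi)))
  invisible(x)
}
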