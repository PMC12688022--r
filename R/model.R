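#' Known candidate predictors
#'
#' Covariate names understood by [model_spec()]: the patient's age in years,
#' the DESIGN-R 2020 total at the first (`baseline_score`) and latest
#' (`latest_score`) assessment, elapsed days since the first assessment
#' (`duration_from_day0`) and its square, the squared prediction gap
#' (`duration_for_next_sq`), the large/small subscale dummies of the latest
#' assessment, the pressure-injury risk-factor flags, and comorbidity flags.
#' The linear prediction gap `duration_for_next` (days from the latest to the
#' next assessment) is always in the model and is not a candidate.
#'
#' @return Character vector of predictor names.
#' @export
known_predictors <- function() {
  c("age", "baseline_score", "latest_score",
    "duration_from_day0", "duration_from_day0_sq", "duration_for_next_sq",
    as.vector(t(outer(.designr_subscales, c("large", "small"), paste, sep = "_"))),
    risk_factor_names(), comorbidity_names())
}

#' @rdname known_predictors
#' @export
risk_factor_names <- function() {
  c("posture_bed", "posture_chair", "bony_prominence", "joint_contracture",
    "malnutrition", "wet_skin", "edema", "skin_tear")
}

#' @rdname known_predictors
#' @export
comorbidity_names <- function() {
  c("dementia", "diabetes", "liver_disease", "cardiovascular_disease",
    "cerebrovascular_disease", "respiratory_disease", "cancer")
}

#' Candidate model specification
#'
#' A model is defined by the predictors added to the base model. The base
#' model predicts the score change with the prediction gap
#' (`duration_for_next`, days) only; its square is an optional model-level
#' term that may also be screened as a candidate (supplying
#' `"duration_for_next_sq"` among `predictors` sets the flag).
#'
#' @param predictors Character vector of covariate names among
#'   [known_predictors()] (may be empty: the base model).
#' @param include_quadratic_duration Add the squared prediction gap term.
#' @return An object of class `hbr_model_spec`.
#' @examples
#' model_spec()                     # base model
#' best_model_spec()                # the published best-model structure
#' @export
model_spec <- function(predictors = character(),
                       include_quadratic_duration = FALSE) {
  predictors <- as.character(predictors)
  if ("duration_for_next_sq" %in% predictors) {
    include_quadratic_duration <- TRUE
    predictors <- setdiff(predictors, "duration_for_next_sq")
  }
  if (anyDuplicated(predictors)) stop("duplicate predictor names", call. = FALSE)
  unknown <- setdiff(predictors, known_predictors())
  if (length(unknown)) stop("unknown predictor(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(predictors = predictors,
                 include_quadratic_duration = isTRUE(include_quadratic_duration)),
            class = "hbr_model_spec")
}

#' The published best-model predictor structure
#'
#' Age, both durations with their squares, and the baseline total score.
#' @return An `hbr_model_spec`.
#' @export
best_model_spec <- function() {
  model_spec(c("age", "duration_for_next_sq",
               "duration_from_day0", "duration_from_day0_sq",
               "baseline_score"))
}

#' Coefficient names of a model specification
#'
#' Order: intercept, prediction gap, its square (if included), then the
#' remaining predictors in specification order. This is the order of design
#' row entries and of all hierarchical parameter vectors.
#'
#' @param spec An `hbr_model_spec`.
#' @return Character vector.
#' @export
coef_names <- function(spec) {
  stopifnot(inherits(spec, "hbr_model_spec"))
  c("intercept", "duration_for_next",
    if (spec$include_quadratic_duration) "duration_for_next_sq",
    spec$predictors)
}

#' @export
print.hbr_model_spec <- function(x, ...) {
  cat("HBR model spec: d ~", paste(coef_names(x)[-1], collapse = " + "), "\n")
  invisible(x)
}

spec_label <- function(spec) {
  cn <- coef_names(spec)[-(1:2)]
  if (!length(cn)) "base" else paste(cn, collapse = "+")
}

#' Prior configuration
#'
#' Scales and shapes of the prior distributions: half-normal on the residual
#' SD, normal on the hierarchical means (wider for the intercept), positive
#' Student-t on the hierarchical scales, LKJ on the correlation Cholesky
#' factor.
#'
#' @param sigma_scale Half-normal scale for the residual SD (default 100).
#' @param mu_slope_scale Normal scale for non-intercept means (default 1).
#' @param mu_intercept_scale Normal scale for the intercept mean (default 10).
#' @param zeta_df Degrees of freedom of the positive Student-t on each
#'   hierarchical scale (default 4, scale 1).
#' @param lkj_shape LKJ concentration (default 4).
#' @return An object of class `hbr_prior_config`.
#' @export
prior_config <- function(sigma_scale = 100, mu_slope_scale = 1,
                         mu_intercept_scale = 10, zeta_df = 4,
                         lkj_shape = 4) {
  stopifnot(sigma_scale > 0, mu_slope_scale > 0, mu_intercept_scale > 0,
            zeta_df > 0, lkj_shape > 0)
  structure(list(sigma_scale = sigma_scale, mu_slope_scale = mu_slope_scale,
                 mu_intercept_scale = mu_intercept_scale, zeta_df = zeta_df,
                 lkj_shape = lkj_shape),
            class = "hbr_prior_config")
}

mu_scales <- function(spec, prior) {
  K <- length(coef_names(spec))
  c(prior$mu_intercept_scale, rep(prior$mu_slope_scale, K - 1))
}

#' Design row / design matrix for score-change observations
#'
#' Builds `[1, s, s^2 (if included), x_1, ..., x_k]` in [coef_names()] order,
#' with the prediction gap `s` in days.
#'
#' @param obs A list or single-row data.frame with `duration_for_next` and
#'   every predictor named in the spec.
#' @param spec An `hbr_model_spec`.
#' @return Numeric vector (row) for `build_design_row`; numeric matrix with
#'   one row per observation for `build_design_matrix`.
#' @export
build_design_row <- function(obs, spec) {
  drop(build_design_matrix(as.data.frame(obs[!vapply(obs, is.null, TRUE)]), spec))
}

#' @rdname build_design_row
#' @param data A data.frame of score-change observations, as from
#'   [score_change_observations()].
#' @export
build_design_matrix <- function(data, spec) {
  stopifnot(inherits(spec, "hbr_model_spec"))
  need <- c("duration_for_next", spec$predictors)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing covariate(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  s <- as.numeric(data$duration_for_next)
  cols <- c(list(intercept = rep(1, nrow(data)), duration_for_next = s),
            if (spec$include_quadratic_duration) list(duration_for_next_sq = s^2),
            lapply(stats::setNames(spec$predictors, spec$predictors),
                   function(p) {
                     v <- as.numeric(data[[p]])
                     if (anyNA(v)) stop("missing covariate values: ", p, call. = FALSE)
                     v
                   }))
  X <- do.call(cbind, cols)
  colnames(X) <- coef_names(spec)
  X
}

#' Hierarchical (population) parameters
#'
#' The multivariate-normal population distribution of the per-lesion
#' coefficient vectors: mean vector `mu`, scale vector `zeta`, correlation
#' Cholesky factor `omega_chol`, and the residual SD `sigma`.
#'
#' @param mu Numeric vector of hierarchical means (intercept first).
#' @param zeta Non-negative scale vector, same length as `mu`.
#' @param omega_chol Lower-triangular correlation Cholesky factor with
#'   unit-norm rows; defaults to the identity.
#' @param sigma Residual SD (> 0).
#' @return An object of class `hbr_hyperparameters`.
#' @export
hyperparameters <- function(mu, zeta, omega_chol = diag(length(mu)), sigma) {
  mu <- as.numeric(mu); zeta <- as.numeric(zeta)
  K <- length(mu)
  if (length(zeta) != K) stop("mu and zeta must have equal length", call. = FALSE)
  if (any(zeta < 0)) stop("zeta entries must be >= 0", call. = FALSE)
  if (length(sigma) != 1 || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  omega_chol <- as.matrix(omega_chol)
  check_corr_chol(omega_chol, K)
  structure(list(mu = mu, zeta = zeta, omega_chol = omega_chol,
                 sigma = as.numeric(sigma)),
            class = "hbr_hyperparameters")
}

check_corr_chol <- function(L, K) {
  if (!all(dim(L) == c(K, K))) stop("omega_chol has wrong dimension", call. = FALSE)
  if (any(abs(L[upper.tri(L)]) > 1e-8)) stop("omega_chol must be lower triangular", call. = FALSE)
  if (any(abs(rowSums(L^2) - 1) > 1e-6)) stop("omega_chol rows must have unit norm", call. = FALSE)
  if (any(diag(L) <= 0)) stop("omega_chol diagonal must be positive", call. = FALSE)
  invisible(L)
}

#' @export
print.hbr_hyperparameters <- function(x, ...) {
  cat("HBR hyperparameters (K =", length(x$mu), ")\n")
  cat("  mu:   ", paste(signif(x$mu, 3), collapse = " "), "\n")
  cat("  zeta: ", paste(signif(x$zeta, 3), collapse = " "), "\n")
  cat("  sigma:", signif(x$sigma, 3), "\n")
  invisible(x)
}

#' Covariance Cholesky factor from scales and correlation factor
#'
#' `Sigma_chol = diag(zeta) %*% omega_chol`; the implied covariance of the
#' per-lesion coefficients is `Sigma_chol %*% t(Sigma_chol)`.
#'
#' @param zeta Non-negative scale vector.
#' @param omega_chol Lower-triangular correlation Cholesky factor.
#' @return Lower-triangular covariance Cholesky factor.
#' @export
assemble_covariance_chol <- function(zeta, omega_chol) {
  if (any(zeta < 0)) stop("zeta entries must be >= 0", call. = FALSE)
  check_corr_chol(as.matrix(omega_chol), length(zeta))
  diag(zeta, length(zeta)) %*% omega_chol
}

#' Gaussian likelihood of score-change observations
#'
#' Sum over observations of the Normal log density of the observed change
#' about the lesion's linear predictor.
#'
#' @param data A data.frame of score-change observations (needs `pi_id`, `d`
#'   and the spec's covariates).
#' @param spec An `hbr_model_spec`.
#' @param effects Matrix of per-lesion coefficient vectors, one column per
#'   lesion, columns named by `pi_id` (or a named list of vectors).
#' @param sigma Residual SD (> 0).
#' @return Log density (scalar).
#' @export
log_likelihood <- function(data, spec, effects, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  X <- build_design_matrix(data, spec)
  if (is.list(effects) && !is.matrix(effects)) {
    effects <- do.call(cbind, effects)
  }
  ids <- as.character(data$pi_id)
  miss <- setdiff(unique(ids), colnames(effects))
  if (length(miss)) stop("no effect vector for PI(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  mu_hat <- rowSums(X * t(effects[, ids, drop = FALSE]))
  sum(stats::dnorm(data$d, mu_hat, sigma, log = TRUE))
}

#' Joint prior log density (constrained scale)
#'
#' Sums the normalized prior terms: half-normal on `sigma`, normals on the
#' hierarchical means, positive Student-t on each hierarchical scale, LKJ on
#' the correlation Cholesky factor, and the multivariate normal population
#' density of each per-lesion coefficient vector.
#'
#' @param h An [hyperparameters()] object.
#' @param effects Matrix (or named list) of per-lesion coefficient vectors.
#' @param prior An [prior_config()].
#' @return Log density (scalar).
#' @export
log_prior <- function(h, effects, prior = prior_config()) {
  stopifnot(inherits(h, "hbr_hyperparameters"))
  if (is.list(effects) && !is.matrix(effects)) effects <- do.call(cbind, effects)
  K <- length(h$mu)
  scales <- c(prior$mu_intercept_scale, rep(prior$mu_slope_scale, K - 1))
  lp <- sum(stats::dnorm(h$mu, 0, scales, log = TRUE))
  lp <- lp + sum(log(2) + stats::dt(h$zeta, df = prior$zeta_df, log = TRUE))
  lp <- lp + log(2) + stats::dnorm(h$sigma, 0, prior$sigma_scale, log = TRUE)
  lp <- lp + dlkj_chol(h$omega_chol, prior$lkj_shape, log = TRUE)
  Sig_chol <- assemble_covariance_chol(h$zeta, h$omega_chol)
  lp + sum(apply(effects, 2, dmvnorm_chol, mu = h$mu, chol_lower = Sig_chol))
}

# log MVN density given lower Cholesky of the covariance
dmvnorm_chol <- function(x, mu, chol_lower) {
  K <- length(mu)
  v <- forwardsolve(chol_lower, x - mu)
  -0.5 * K * log(2 * pi) - sum(log(diag(chol_lower))) - 0.5 * sum(v^2)
}

#' LKJ density of a correlation Cholesky factor
#'
#' Normalized density of the Lewandowski-Kurowicka-Joe distribution with
#' shape `eta`, evaluated on the lower Cholesky factor of the correlation
#' matrix. Computed through the canonical-partial-correlation factorization,
#' under which the partial correlations are independent shifted Beta
#' variates; in dimension 2 this reduces to
#' `(1 - rho^2)^(eta - 1) / (2^(2 eta - 1) * Beta(eta, eta))`.
#'
#' @param L Lower-triangular correlation Cholesky factor.
#' @param eta Shape parameter (> 0).
#' @param log Return the log density.
#' @return Density or log density of `L`.
#' @export
dlkj_chol <- function(L, eta, log = FALSE) {
  L <- as.matrix(L)
  K <- nrow(L)
  check_corr_chol(L, K)
  lp <- 0
  for (i in seq_len(K)[-1]) {
    rem <- 1
    for (j in seq_len(i - 1)) {
      w <- L[i, j] / sqrt(rem)
      b <- eta + (K - 1 - j) / 2
      # Beta density of w on (-1, 1) minus the Jacobian sqrt(rem) of w -> L
      lp <- lp + (b - 1) * log1p(-w^2) - (2 * b - 1) * log(2) - lbeta(b, b) -
        0.5 * log(rem)
      rem <- rem * (1 - w^2)
    }
  }
  if (log) lp else exp(lp)
}

#' Sample a correlation Cholesky factor from the LKJ distribution
#' @param K Dimension.
#' @param eta Shape parameter.
#' @return Lower-triangular `K x K` correlation Cholesky factor.
#' @export
rlkj_chol <- function(K, eta) {
  L <- diag(K)
  for (i in seq_len(K)[-1]) {
    rem <- 1
    for (j in seq_len(i - 1)) {
      b <- eta + (K - 1 - j) / 2
      w <- 2 * stats::rbeta(1, b, b) - 1
      L[i, j] <- w * sqrt(rem)
      rem <- rem * (1 - w^2)
    }
    L[i, i] <- sqrt(rem)
  }
  L
}

#' Joint log density (likelihood + prior)
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return Log density (scalar), `-Inf` outside the valid parameter region.
#' @export
log_joint <- function(data, spec, h, effects, prior = prior_config()) {
  ll <- tryCatch(log_likelihood(data, spec, effects, h$sigma),
                 error = function(e) stop(e))
  ll + log_prior(h, effects, prior)
}

# ---- internal fitting data ---------------------------------------------

hbr_data <- function(data, spec) {
  stopifnot(is.data.frame(data), "pi_id" %in% names(data), "d" %in% names(data))
  X <- build_design_matrix(data, spec)
  ids <- as.character(data$pi_id)
  pi_ids <- sort(unique(ids))
  list(X = X, d = as.numeric(data$d),
       gidx = match(ids, pi_ids) - 1L,
       pi_ids = pi_ids, n_pi = length(pi_ids),
       K = ncol(X), spec = spec)
}

theta_dim <- function(K, n_pi) 2L * K + (K * (K - 1L)) %/% 2L + 1L + K * n_pi

# unconstrained parameter names, in theta order
theta_names <- function(cn, pi_ids) {
  K <- length(cn)
  pr <- character(0)
  for (i in seq_len(K)[-1]) for (j in seq_len(i - 1))
    pr <- c(pr, sprintf("y[%d,%d]", i, j))
  c(paste0("mu[", cn, "]"), paste0("log_zeta[", cn, "]"), pr, "log_sigma",
    as.vector(outer(cn, pi_ids, function(a, b) paste0("z[", b, ",", a, "]"))))
}

# map an unconstrained draw to natural parameters
theta_to_natural <- function(theta, K, n_pi) {
  P <- K * (K - 1) / 2
  mu <- theta[1:K]
  zeta <- exp(theta[K + 1:K])
  y <- theta[2 * K + seq_len(P)]
  sigma <- exp(theta[2 * K + P + 1])
  z <- matrix(theta[(2 * K + P + 1) + seq_len(K * n_pi)], K, n_pi)
  L <- cpc_to_chol(tanh(y), K)
  beta <- mu + zeta * (L %*% z)
  list(mu = mu, zeta = zeta, omega_chol = L, sigma = sigma, z = z, beta = beta)
}

cpc_to_chol <- function(w, K) {
  L <- diag(K)
  p <- 0
  for (i in seq_len(K)[-1]) {
    rem <- 1
    for (j in seq_len(i - 1)) {
      p <- p + 1
      L[i, j] <- w[p] * sqrt(rem)
      rem <- rem * (1 - w[p]^2)
    }
    L[i, i] <- sqrt(rem)
  }
  L
}

chol_to_cpc <- function(L) {
  K <- nrow(L)
  w <- numeric(K * (K - 1) / 2)
  p <- 0
  for (i in seq_len(K)[-1]) {
    rem <- 1
    for (j in seq_len(i - 1)) {
      p <- p + 1
      w[p] <- L[i, j] / sqrt(rem)
      rem <- rem * (1 - w[p]^2)
    }
  }
  w
}

natural_to_theta <- function(mu, zeta, omega_chol, sigma, z) {
  c(mu, log(zeta), atanh(chol_to_cpc(omega_chol)), log(sigma), as.vector(z))
}
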