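#' MCMC configuration
#'
#' The `"desk"` profile (default) uses 4 chains of 2000 retained draws after
#' 1000 warmup iterations, which is ample for the data sizes this model is
#' applied to; the `"replication"` profile uses 3 chains of 40,000 draws after
#' 10,000 warmup.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_warmup Warmup (adaptation) iterations per chain.
#' @param n_draws Retained draws per chain.
#' @param seed Integer seed; fixes the entire run.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param max_treedepth Maximum NUTS doubling depth.
#' @param profile Optional `"desk"` or `"replication"` preset; explicit arguments
#'   override the preset.
#' @return An object of class `hbr_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = NULL, n_warmup = NULL, n_draws = NULL,
                        seed = 1L, target_accept = 0.95, max_treedepth = 10L,
                        profile = c("desk", "replication")) {
  profile <- match.arg(profile)
  preset <- switch(profile,
                   desk = list(n_chains = 4L, n_warmup = 1000L, n_draws = 2000L),
                   replication = list(n_chains = 3L, n_warmup = 10000L, n_draws = 40000L))
  cfg <- list(n_chains = as.integer(n_chains %||% preset$n_chains),
              n_warmup = as.integer(n_warmup %||% preset$n_warmup),
              n_draws = as.integer(n_draws %||% preset$n_draws),
              seed = as.integer(seed), target_accept = target_accept,
              max_treedepth = as.integer(max_treedepth), profile = profile)
  stopifnot(cfg$n_chains >= 1, cfg$n_warmup >= 1, cfg$n_draws >= 1,
            cfg$target_accept > 0, cfg$target_accept < 1)
  structure(cfg, class = "hbr_mcmc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- No-U-Turn sampler with dual averaging and diagonal mass ------------

nuts_chain <- function(lp_grad, theta0, n_warmup, n_iter, target_accept = 0.8,
                       max_treedepth = 10L) {
  D <- length(theta0)
  minv <- rep(1, D)                      # inverse mass (variance of position)
  state <- lp_grad(theta0)
  if (!is.finite(state$lp)) {
    stop("non-finite log joint density at initialization", call. = FALSE)
  }
  theta <- theta0; lp <- state$lp; grad <- state$grad

  leapfrog <- function(theta, r, grad, eps) {
    r <- r + 0.5 * eps * grad
    theta <- theta + eps * minv * r
    st <- lp_grad(theta)
    r <- r + 0.5 * eps * st$grad
    list(theta = theta, r = r, lp = st$lp, grad = st$grad)
  }

  joint_of <- function(lp, r) {
    h <- lp - 0.5 * sum(minv * r * r)
    if (!is.finite(h)) -Inf else h
  }

  find_eps <- function(theta, lp, grad) {
    eps <- 0.1
    r <- stats::rnorm(D) / sqrt(minv)
    h0 <- joint_of(lp, r)
    st <- leapfrog(theta, r, grad, eps)
    h1 <- joint_of(st$lp, st$r)
    if (!is.finite(h1)) {
      while (!is.finite(h1) && eps > 1e-10) {
        eps <- eps / 2
        st <- leapfrog(theta, r, grad, eps)
        h1 <- joint_of(st$lp, st$r)
      }
      return(eps)
    }
    a <- if (h1 - h0 > log(0.5)) 1 else -1
    while (a * (joint_of(st$lp, st$r) - h0) > -a * log(2)) {
      eps <- eps * 2^a
      if (eps > 1e7 || eps < 1e-10) break
      st <- leapfrog(theta, r, grad, eps)
      if (!is.finite(st$lp)) { eps <- eps * 0.5; break }
    }
    eps
  }

  delta_max <- 1000
  divergences <- 0L

  build_tree <- function(theta, r, grad, lu, v, j, eps, h0) {
    if (j == 0L) {
      st <- leapfrog(theta, r, grad, v * eps)
      joint <- joint_of(st$lp, st$r)
      if (!is.finite(joint)) joint <- -Inf
      n1 <- as.integer(lu <= joint)
      s1 <- as.integer(lu < joint + delta_max)
      list(tm = st$theta, rm = st$r, gm = st$grad,
           tp = st$theta, rp = st$r, gp = st$grad,
           tprime = st$theta, lpprime = st$lp,
           n = n1, s = s1, alpha = min(1, exp(joint - h0)), nalpha = 1L,
           div = (s1 == 0L))
    } else {
      t1 <- build_tree(theta, r, grad, lu, v, j - 1L, eps, h0)
      if (t1$s == 1L) {
        if (v == -1) {
          t2 <- build_tree(t1$tm, t1$rm, t1$gm, lu, v, j - 1L, eps, h0)
          t1$tm <- t2$tm; t1$rm <- t2$rm; t1$gm <- t2$gm
        } else {
          t2 <- build_tree(t1$tp, t1$rp, t1$gp, lu, v, j - 1L, eps, h0)
          t1$tp <- t2$tp; t1$rp <- t2$rp; t1$gp <- t2$gp
        }
        if (t2$n > 0L && stats::runif(1) < t2$n / max(1L, t1$n + t2$n)) {
          t1$tprime <- t2$tprime; t1$lpprime <- t2$lpprime
        }
        dtheta <- t1$tp - t1$tm
        t1$s <- t2$s *
          as.integer(sum(dtheta * minv * t1$rm) >= 0) *
          as.integer(sum(dtheta * minv * t1$rp) >= 0)
        t1$n <- t1$n + t2$n
        t1$alpha <- t1$alpha + t2$alpha
        t1$nalpha <- t1$nalpha + t2$nalpha
        t1$div <- t1$div || t2$div
      }
      t1
    }
  }

  # dual-averaging state
  eps <- find_eps(theta, lp, grad)
  da_mu <- log(10 * eps); da_h <- 0; da_logeps_bar <- 0; da_count <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  da_reset <- function(eps) {
    da_mu <<- log(10 * eps); da_h <<- 0; da_logeps_bar <<- log(eps)
    da_count <<- 0
  }
  da_update <- function(alpha_stat) {
    da_count <<- da_count + 1
    da_h <<- (1 - 1 / (da_count + t0)) * da_h +
      (target_accept - alpha_stat) / (da_count + t0)
    logeps <- da_mu - sqrt(da_count) / gamma * da_h
    w <- da_count^(-kappa)
    da_logeps_bar <<- w * logeps + (1 - w) * da_logeps_bar
    exp(logeps)
  }

  w1 <- max(1L, floor(0.25 * n_warmup)); w2 <- floor(0.75 * n_warmup)
  window_draws <- matrix(NA_real_, max(0L, w2 - w1), D)

  total <- n_warmup + n_iter
  draws <- matrix(NA_real_, n_iter, D)
  lps <- numeric(n_iter)

  for (it in seq_len(total)) {
    r0 <- stats::rnorm(D) / sqrt(minv)
    h0 <- joint_of(lp, r0)
    lu <- h0 - stats::rexp(1)
    tm <- theta; tp <- theta; rm <- r0; rp <- r0; gm <- grad; gp <- grad
    tsel <- theta; lpsel <- lp
    n <- 1L; s <- 1L; j <- 0L
    alpha <- 1; nalpha <- 1L; diverged <- FALSE
    while (s == 1L && j < max_treedepth) {
      v <- if (stats::runif(1) < 0.5) -1 else 1
      if (v == -1) {
        tr <- build_tree(tm, rm, gm, lu, v, j, eps, h0)
        tm <- tr$tm; rm <- tr$rm; gm <- tr$gm
      } else {
        tr <- build_tree(tp, rp, gp, lu, v, j, eps, h0)
        tp <- tr$tp; rp <- tr$rp; gp <- tr$gp
      }
      if (tr$s == 1L && stats::runif(1) < tr$n / n) {
        tsel <- tr$tprime; lpsel <- tr$lpprime
      }
      n <- n + tr$n
      dtheta <- tp - tm
      s <- tr$s *
        as.integer(sum(dtheta * minv * rm) >= 0) *
        as.integer(sum(dtheta * minv * rp) >= 0)
      alpha <- tr$alpha; nalpha <- tr$nalpha
      diverged <- diverged || tr$div
      j <- j + 1L
    }
    theta <- tsel; lp <- lpsel
    grad <- lp_grad(theta)$grad

    if (it <= n_warmup) {
      eps <- da_update(alpha / nalpha)
      if (it > w1 && it <= w2) window_draws[it - w1, ] <- theta
      if (it == w2 && w2 > w1 + 10L) {
        v <- apply(window_draws, 2, stats::var)
        nw <- nrow(window_draws)
        minv <- v * nw / (nw + 5) + 1e-3 * 5 / (nw + 5)
        da_reset(max(eps, 1e-6))
      }
      if (it == n_warmup) eps <- exp(da_logeps_bar)
    } else {
      draws[it - n_warmup, ] <- theta
      lps[it - n_warmup] <- lp
      if (diverged) divergences <- divergences + 1L
    }
  }
  list(draws = draws, lp = lps, divergences = divergences,
       step_size = eps, inv_mass = minv)
}

#' Sample the posterior of the hierarchical model
#'
#' Runs the No-U-Turn sampler on the joint posterior of the hierarchical
#' means, scales, correlation Cholesky factor, residual SD and the
#' (non-centered) per-lesion effects, with dual-averaging step-size and
#' diagonal mass-matrix adaptation during warmup. Identical seeds give
#' identical draws.
#'
#' @param data Score-change observation data.frame (see
#'   [score_change_observations()]): columns `pi_id`, `d`,
#'   `duration_for_next` and the spec's predictors.
#' @param spec An [model_spec()].
#' @param prior An [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @return An object of class `hbr_fit`: natural-scale draws, per-parameter
#'   split R-hat, divergence count, and provenance (spec, prior, mcmc
#'   configuration, data fingerprint).
#' @export
sample_posterior <- function(data, spec, prior = prior_config(),
                             mcmc = mcmc_config()) {
  hd <- hbr_data(data, spec)
  if (any(tabulate(hd$gidx + 1L, hd$n_pi) == 0L)) {
    stop("every included PI needs at least one score-change observation",
         call. = FALSE)
  }
  scales <- mu_scales(spec, prior)
  lpg <- function(theta) {
    cpp_hbr_lp_grad(theta, hd$X, hd$d, hd$gidx, hd$n_pi, scales,
                    prior$zeta_df, prior$sigma_scale, prior$lkj_shape)
  }
  K <- hd$K; n_pi <- hd$n_pi; P <- K * (K - 1) / 2
  D <- theta_dim(K, n_pi)

  set.seed(mcmc$seed)
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    theta0 <- c(stats::rnorm(1, mean(hd$d), 1), stats::rnorm(K - 1, 0, 0.5),
                stats::rnorm(K, log(0.5), 0.3),
                stats::rnorm(P, 0, 0.1),
                log(max(stats::sd(hd$d), 0.5)) + stats::rnorm(1, 0, 0.3),
                stats::rnorm(K * n_pi, 0, 0.5))
    if (!is.finite(lpg(theta0)$lp)) {
      stop("non-finite log joint at initialization; theta0 = ",
           paste(signif(theta0, 3), collapse = ","), call. = FALSE)
    }
    chains[[ch]] <- cpp_nuts_hbr(theta0, mcmc$n_warmup, mcmc$n_draws,
                                 mcmc$target_accept, mcmc$max_treedepth,
                                 hd$X, hd$d, hd$gidx, hd$n_pi, scales,
                                 prior$zeta_df, prior$sigma_scale,
                                 prior$lkj_shape)
  }

  cn <- coef_names(spec)
  pnames <- natural_names(cn, hd$pi_ids)
  nat <- array(NA_real_, c(mcmc$n_draws, mcmc$n_chains, length(pnames)),
               dimnames = list(NULL, NULL, pnames))
  for (ch in seq_len(mcmc$n_chains)) {
    nat[, ch, ] <- natural_draws_matrix(chains[[ch]]$draws, K, n_pi)
  }

  rh <- apply(nat, 3, function(m) split_rhat(m))
  fit <- structure(list(
    draws = nat,
    uc_draws = lapply(chains, `[[`, "draws"),
    lp = lapply(chains, `[[`, "lp"),
    rhat = rh,
    max_rhat = max(rh, na.rm = TRUE),
    divergences = sum(vapply(chains, `[[`, integer(1), "divergences")),
    step_sizes = vapply(chains, `[[`, numeric(1), "step_size"),
    spec = spec, prior = prior, mcmc = mcmc,
    data = hd,
    fingerprint = data_fingerprint(hd)
  ), class = "hbr_fit")
  fit
}

natural_names <- function(cn, pi_ids) {
  K <- length(cn)
  om <- character(0)
  for (i in seq_len(K)[-1]) for (j in seq_len(i - 1))
    om <- c(om, sprintf("Omega[%d,%d]", i, j))
  c(paste0("mu[", cn, "]"), paste0("zeta[", cn, "]"), "sigma", om,
    as.vector(outer(cn, pi_ids, function(a, b) paste0("beta[", b, ",", a, "]"))))
}

# rows: draws (unconstrained); returns natural-scale matrix in natural_names order
natural_draws_matrix <- function(uc, K, n_pi) {
  P <- K * (K - 1) / 2
  n <- nrow(uc)
  out <- matrix(NA_real_, n, 2 * K + 1 + P + K * n_pi)
  for (i in seq_len(n)) {
    na <- theta_to_natural(uc[i, ], K, n_pi)
    om <- na$omega_chol %*% t(na$omega_chol)
    out[i, ] <- c(na$mu, na$zeta, na$sigma, om[lower.tri(om)][order_lowertri(K)],
                  as.vector(na$beta))
  }
  out
}

# lower.tri() extracts column-major; reorder to row-major (i,j) pairs
order_lowertri <- function(K) {
  idx <- which(lower.tri(matrix(0, K, K)), arr.ind = TRUE)
  order(idx[, "row"], idx[, "col"])
}

data_fingerprint <- function(hd) {
  v <- c(dim(hd$X), hd$d, hd$gidx)
  sprintf("%d-%d-%.6f", nrow(hd$X), ncol(hd$X), sum(v * seq_along(v)))
}

#' @export
print.hbr_fit <- function(x, ...) {
  cat("Hierarchical Bayesian fit:", spec_label(x$spec), "\n")
  cat(sprintf("  %d chains x %d draws (after %d warmup)\n",
              x$mcmc$n_chains, x$mcmc$n_draws, x$mcmc$n_warmup))
  cat(sprintf("  max split R-hat %.3f; divergences %d\n",
              x$max_rhat, x$divergences))
  invisible(x)
}

#' Posterior draws as a matrix
#' @param fit An `hbr_fit`.
#' @return Matrix (all chains pooled) with named natural-scale columns.
#' @export
as_draws_matrix <- function(fit) {
  stopifnot(inherits(fit, "hbr_fit"))
  d <- fit$draws
  matrix(d, prod(dim(d)[1:2]), dim(d)[3],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

#' Posterior summary of the hierarchical parameters
#' @param object An `hbr_fit`.
#' @param ... Unused.
#' @return data.frame with posterior mean, SD, central 90% interval and
#'   split R-hat for mu, zeta, sigma and the correlation entries.
#' @export
summary.hbr_fit <- function(object, ...) {
  m <- as_draws_matrix(object)
  keep <- !grepl("^beta\\[", colnames(m))
  m <- m[, keep, drop = FALSE]
  data.frame(parameter = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             q5 = apply(m, 2, stats::quantile, 0.05),
             q95 = apply(m, 2, stats::quantile, 0.95),
             rhat = object$rhat[keep],
             row.names = NULL)
}

# ---- convergence diagnostics -------------------------------------------

#' Split Gelman-Rubin statistic
#'
#' The split potential scale reduction factor: each chain is split in half
#' and the ratio of pooled to within-sequence variance is computed. Values
#' below 1.1 for every parameter are taken as evidence of convergence.
#'
#' @param x An `hbr_fit`, or a draws matrix (iterations x chains) for a
#'   single parameter.
#' @param ... Unused.
#' @return Named vector of per-parameter statistics (for a fit), or a single
#'   value (for a matrix).
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @export
rhat.hbr_fit <- function(x, ...) x$rhat

#' @export
rhat.matrix <- function(x, ...) split_rhat(x)

#' @export
rhat.default <- function(x, ...) stop("no rhat method for this object",
                                      call. = FALSE)

split_rhat <- function(mat) {
  if (ncol(mat) < 2) stop("R-hat requires at least 2 chains", call. = FALSE)
  n <- nrow(mat)
  half <- n %/% 2
  seqs <- c(lapply(seq_len(ncol(mat)), function(j) mat[seq_len(half), j]),
            lapply(seq_len(ncol(mat)), function(j) mat[(n - half + 1):n, j]))
  m <- length(seqs); nn <- half
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
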