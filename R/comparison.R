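# ---------------------------------------------------------------------------
# Generalized Pareto fit (Zhang & Stephens 2009 profile-posterior method)
# for exceedances x > 0; returns shape k and scale sigma in the
# parameterization F(x) = 1 - (1 + k x / sigma)^(-1/k).
# ---------------------------------------------------------------------------
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) stop("need at least 5 exceedances for the tail fit")
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  kfun <- function(th) -mean(log1p(-th * x))
  k <- vapply(theta, kfun, numeric(1))
  l <- n * (log(theta / k) + k - 1)
  w <- exp(l - max(l))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  kz <- kfun(theta_hat)
  sigma <- kz / theta_hat
  # convert to the F(x) = 1 - (1 + k x / sigma)^(-1/k) convention and apply
  # the standard weakly-informative shape regularization
  k_hat <- (n * (-kz) + 5) / (n + 10)
  list(k = k_hat, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Pareto-smooth one observation's log importance ratios (log weights)
psis_smooth <- function(lw, tail_frac = 0.2) {
  S <- length(lw)
  M <- ceiling(tail_frac * S)
  ord <- order(lw)
  cutpos <- S - M
  u <- lw[ord[cutpos]]                  # log threshold
  tail_idx <- ord[(cutpos + 1):S]
  exc <- exp(lw[tail_idx] - u) - 1      # exceedances on the ratio scale / e^u
  k <- NA_real_
  if (M >= 5 && stats::sd(exc) > 0) {
    fit <- gpd_fit(exc)
    k <- fit$k
    qq <- qgpd((seq_len(M) - 0.5) / M, fit$k, fit$sigma)
    lw_new <- u + log1p(qq)
    lw_new <- pmin(lw_new, max(lw))     # truncate at the largest raw weight
    lw[tail_idx[order(lw[tail_idx])]] <- sort(lw_new)
  }
  list(lw = lw - logsumexp(lw), k = k)
}

#' PSIS-LOO: Pareto-smoothed importance-sampling leave-one-out CV
#'
#' Approximates exact leave-one-out cross-validation from a pointwise
#' log-likelihood matrix (observations x posterior draws).  Importance
#' ratios `1/p(y_i | theta_s)` are stabilized per observation by fitting a
#' generalized Pareto distribution to the top 20\% of weights and replacing
#' them with expected order statistics.  Reports the LOO information
#' criterion (deviance scale, lower is better), its SE from the pointwise
#' variance, the pointwise elpd contributions and the Pareto-k diagnostic
#' per observation.
#'
#' @param log_lik matrix of pointwise log-likelihoods, `n_obs x n_draws`,
#'   with at least 100 draws
#' @param tail_frac fraction of weights treated as the tail (default 0.2)
#' @return a list of class `psis_loo`: `elpd_loo`, `looic`, `se_looic`,
#'   `pointwise` (elpd per observation), `pareto_k`
#' @export
psis_loo <- function(log_lik, tail_frac = 0.2) {
  if (!is.matrix(log_lik)) log_lik <- as.matrix(log_lik)
  if (ncol(log_lik) < 100) {
    stop("psis_loo needs at least 100 posterior draws", call. = FALSE)
  }
  if (any(!is.finite(log_lik))) {
    stop("non-finite pointwise log-likelihood entries", call. = FALSE)
  }
  n <- nrow(log_lik)
  S <- ncol(log_lik)
  pointwise <- numeric(n)
  kvals <- numeric(n)
  for (i in seq_len(n)) {
    lw_raw <- -log_lik[i, ]
    sm <- psis_smooth(lw_raw - max(lw_raw), tail_frac)
    pointwise[i] <- logsumexp(sm$lw + log_lik[i, ])
    kvals[i] <- sm$k
  }
  elpd <- sum(pointwise)
  se_elpd <- sqrt(n * var(pointwise))
  structure(list(elpd_loo = elpd, looic = -2 * elpd,
                 se_elpd = se_elpd, se_looic = 2 * se_elpd,
                 pointwise = pointwise, pareto_k = kvals,
                 n_obs = n, n_draws = S), class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd %.1f, LOOIC %.1f (SE %.1f), max Pareto-k %.2f\n",
              x$elpd_loo, x$looic, x$se_looic,
              max(x$pareto_k, na.rm = TRUE)))
  invisible(x)
}

#' Compare fitted models
#'
#' Ranks a set of [fit_mle()]/[fit_bayes()] results fitted to the identical
#' filtered trial table.  Bayesian fits are compared by LOOIC (deviance
#' scale) with the SE of the pairwise pointwise differences vs the best
#' model; maximum-likelihood fits are compared by AIC/BIC (the criterion is
#' labelled).  Differences larger than 4 that also exceed several SEs are
#' flagged as interpretable improvements.
#'
#' @param fits a (optionally named) list of `fit_result` objects on the same
#'   trials
#' @param se_factor how many difference-SEs a >4 LOOIC difference must
#'   exceed to be flagged (default 2)
#' @param mle_criterion ranking criterion for the MLE backend: `"AIC"`
#'   (default; like LOOIC it approximates cross-validated deviance) or
#'   `"BIC"` — both are reported
#' @return a `comparison_table` data.frame: one row per model with the
#'   criterion, delta vs best, difference SE, rank and flag
#' @export
compare <- function(fits, se_factor = 2,
                    mle_criterion = c("AIC", "BIC")) {
  mle_criterion <- match.arg(mle_criterion)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "fit_result")))
  keys <- lapply(fits, `[[`, "trial_key")
  if (length(fits) > 1 &&
      !all(vapply(keys[-1], identical, logical(1), keys[[1]]))) {
    stop("fits were not computed on the identical trial set", call. = FALSE)
  }
  backend <- unique(vapply(fits, `[[`, character(1), "backend"))
  if (length(backend) > 1) {
    stop("cannot mix MLE and Bayesian fits in one comparison", call. = FALSE)
  }
  ids <- vapply(fits, `[[`, character(1), "model_id")
  if (backend == "bayes") {
    loos <- lapply(fits, function(f) psis_loo(f$pointwise))
    crit <- vapply(loos, `[[`, numeric(1), "looic")
    criterion <- "LOOIC"
    best <- which.min(crit)
    dse <- vapply(seq_along(fits), function(j) {
      if (j == best) return(0)
      dpt <- loos[[j]]$pointwise - loos[[best]]$pointwise
      2 * sqrt(length(dpt) * var(dpt))
    }, numeric(1))
  } else {
    k <- vapply(fits, `[[`, numeric(1), "n_params")
    ll <- vapply(fits, `[[`, numeric(1), "total_loglik")
    n <- fits[[1]]$n_trials
    bic <- -2 * ll + k * log(n)
    aic <- -2 * ll + 2 * k
    crit <- if (mle_criterion == "AIC") aic else bic
    criterion <- mle_criterion
    best <- which.min(crit)
    dse <- rep(NA_real_, length(fits))
  }
  delta <- crit - crit[best]
  out <- data.frame(model = ids, criterion = criterion, value = crit,
                    delta = delta, delta_se = dse,
                    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
                    rank = rank(crit, ties.method = "min"),
                    interpretable = delta > 4 &
                      (is.na(dse) | delta > se_factor * dse))
  if (backend == "mle") { out$aic <- aic; out$bic <- bic }
  out <- out[order(out$value), ]
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Bridge sampling with a moment-matched ("warped") multivariate normal
# proposal: draws are affinely Gaussianized via the posterior mean and
# covariance Cholesky factor, and the iterative optimal-bridge estimator of
# the normalizing constant is run in log space.
# ---------------------------------------------------------------------------
bridge_logml <- function(draws, log_post, n_prop = nrow(draws),
                         maxiter = 500, tol = 1e-10) {
  S1 <- nrow(draws)
  d <- ncol(draws)
  mu <- colMeans(draws)
  V <- var(draws)
  V <- V + diag(1e-10 + 1e-8 * mean(diag(V)), d)
  L <- t(chol(V))
  # log proposal density
  ldet <- sum(log(diag(L)))
  log_g <- function(X) {
    Z <- forwardsolve(L, t(X) - mu)
    -0.5 * colSums(Z^2) - 0.5 * d * log(2 * pi) - ldet
  }
  prop <- t(mu + L %*% matrix(rnorm(n_prop * d), d))
  l1 <- apply(draws, 1, log_post) - log_g(draws)       # posterior draws
  l2 <- apply(prop, 1, log_post) - log_g(prop)         # proposal draws
  if (all(!is.finite(l2))) return(NA_real_)            # no overlap
  s1 <- S1 / (S1 + n_prop)
  s2 <- n_prop / (S1 + n_prop)
  lstar <- median(l1)
  r <- 0   # log of current estimate, relative to lstar
  for (it in seq_len(maxiter)) {
    num <- logsumexp((l2 - lstar) -
                       .log1pexp(log(s1 / s2) + (l2 - lstar) - r)) -
      log(n_prop)
    den <- logsumexp(-.log1pexp(log(s1 / s2) + (l1 - lstar) - r)) - log(S1)
    r_new <- num - den
    if (!is.finite(r_new)) return(NA_real_)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  r + lstar
}

.log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(pmin(x, 35))))

#' Bridge-sampling Bayes factor on the base-3 log scale
#'
#' Estimates both models' log marginal likelihoods by iterative bridge
#' sampling with a warped multivariate-normal proposal, repeats the whole
#' procedure `n_runs` times, and reports the most equivocal run (the
#' `log3` Bayes factor closest to 0) together with the run spread.  Runs in
#' which the proposal and posterior fail to overlap yield an infinite
#' sentinel: `+Inf`/`-Inf` means the bridge could not effectively estimate
#' the relative evidence, with the favored model inferred from the finite
#' side.  A `|log3 BF| > 1` is conventionally "substantial evidence".
#'
#' @param fit_a,fit_b `fit_result` objects from [fit_bayes()] (or any list
#'   with `draws` and `log_post`)
#' @param n_runs bridge-sampling repetitions (default 15)
#' @param seed integer seed
#' @param maxiter,tol iteration cap and convergence tolerance of the
#'   iterative bridge estimator
#' @return a list of class `bridge_bf`: `log3_bf` (reported, most
#'   equivocal), `runs` (all runs), `logml_a`, `logml_b`
#' @export
bridge_log3_bf <- function(fit_a, fit_b, n_runs = 15L, seed = 1L,
                           maxiter = 500, tol = 1e-10) {
  for (f in list(fit_a, fit_b)) {
    if (is.null(f$draws) || is.null(f$log_post)) {
      stop("bridge sampling needs Bayesian fits with stored draws and log_post",
           call. = FALSE)
    }
  }
  .with_seed(seed, {
    runs <- vapply(seq_len(n_runs), function(i) {
      half <- function(f) {
        S <- nrow(f$draws)
        pick <- sample(S, ceiling(S / 2))
        bridge_logml(f$draws[pick, , drop = FALSE], f$log_post)
      }
      la <- half(fit_a)
      lb <- half(fit_b)
      if (is.na(la) && is.na(lb)) return(NA_real_)
      if (is.na(lb)) return(Inf)
      if (is.na(la)) return(-Inf)
      (la - lb) / log(3)
    }, numeric(1))
    if (sum(!is.na(runs)) < 2) {
      stop("fewer than 2 successful bridge-sampling runs", call. = FALSE)
    }
    finite <- runs[is.finite(runs)]
    reported <- if (length(finite)) finite[which.min(abs(finite))]
                else runs[!is.na(runs)][1]
    structure(list(log3_bf = reported, runs = runs,
                   spread = if (length(finite) > 1) stats::sd(finite)
                            else NA_real_,
                   n_failed = sum(is.na(runs))), class = "bridge_bf")
  })
}

#' @export
print.bridge_bf <- function(x, ...) {
  cat(sprintf("Bridge-sampling BF (log3): %.3f (run spread %.3f, %d runs)\n",
              x$log3_bf, x$spread, length(x$runs)))
  invisible(x)
}
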