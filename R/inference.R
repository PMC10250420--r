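#' Apply the RT exclusion rule
#'
#' Excludes trials with RTs strictly below `low` or strictly above `high`
#' seconds (boundary values are retained).  Defaults are the analysis rule:
#' 0.16 s and 2.5 s.
#'
#' @param trials a trial-record data.frame with column `rt_s`
#' @param low,high retention bounds in seconds
#' @return a list with `trials` (the filtered table) and `report` (per
#'   subject counts of retained and excluded trials)
#' @examples
#' tab <- data.frame(subject = 1, rt_s = c(0.10, 0.16, 0.5, 2.5, 2.6))
#' exclude_trials(tab)$report
#' @export
exclude_trials <- function(trials, low = 0.16, high = 2.5) {
  if (!"rt_s" %in% names(trials)) stop("'trials' lacks an rt_s column")
  keep <- trials$rt_s >= low & trials$rt_s <= high
  report <- do.call(rbind, lapply(split(seq_len(nrow(trials)),
                                        trials$subject), function(idx) {
    k <- keep[idx]
    data.frame(subject = trials$subject[idx[1L]],
               n_total = length(idx), n_retained = sum(k),
               n_low = sum(trials$rt_s[idx] < low),
               n_high = sum(trials$rt_s[idx] > high))
  }))
  rownames(report) <- NULL
  if (any(report$n_retained == 0)) {
    warning("exclusion filter removed all trials for subject(s): ",
            paste(report$subject[report$n_retained == 0], collapse = ", "))
  }
  list(trials = trials[keep, , drop = FALSE], report = report)
}

# precomputed covariates for one subject's trials
.trial_cov <- function(spec, trials) {
  c01 <- as.numeric(trials$correct)
  list(day = trials$day, wtrial = trials$trial_in_day,
       ctrial = trials$trial_overall,
       cohc = coherence_covariate(spec, trials$coherence_pct),
       rt = trials$rt_s, correct = trials$correct,
       sgn = 1 - 2 * c01, c01 = c01,
       minrt = min(trials$rt_s))
}

# pointwise log-likelihood for one subject at unconstrained theta;
# accuracy coding: the upper boundary is the correct response, so correct
# trials evaluate the lower-boundary density under (-v, 1-z)
.ll_pointwise_theta <- function(theta, layout, cov) {
  p <- theta_trial_params(theta, layout, cov, cov$minrt)
  vv <- cov$sgn * p$v
  ww <- cov$c01 + cov$sgn * p$z
  wfpt_logdens_cpp(cov$rt - p$t0, vv, rep_len(p$a, length(vv)), ww)
}

#' Negative log-likelihood of a model at given parameters
#'
#' Sums the Wiener first-passage log-density over all trials at the
#' per-trial parameters implied by each subject's [subject_params()].
#' Any trial with zero likelihood (e.g. `rt <= t0`) makes the total `+Inf`
#' (flagged via attribute `n_invalid`).
#'
#' @param model a [model_spec()]
#' @param params a single [subject_params()] (one-subject table) or a list
#'   indexed by subject id
#' @param trials a filtered trial-record data.frame
#' @return a list with `total` (scalar negative log-likelihood) and
#'   `pointwise` (per-trial log-likelihood vector aligned to `trials` rows)
#' @export
negative_log_likelihood <- function(model, params, trials) {
  if (inherits(params, "subject_params")) {
    ids <- unique(trials$subject)
    params <- setNames(rep(list(params), length(ids)), ids)
  }
  pointwise <- numeric(nrow(trials))
  for (s in unique(trials$subject)) {
    idx <- which(trials$subject == s)
    sub <- trials[idx, , drop = FALSE]
    ps <- if (!is.null(names(params))) params[[as.character(s)]]
          else params[[s]]
    p <- per_trial_params(model, ps, sub)
    vv <- ifelse(sub$correct, -p$v, p$v)
    ww <- ifelse(sub$correct, 1 - p$z, p$z)
    pointwise[idx] <- wfpt_logdens_cpp(sub$rt_s - p$t0, vv, p$a, ww)
  }
  total <- if (any(!is.finite(pointwise))) Inf else -sum(pointwise)
  structure(list(total = total, pointwise = pointwise),
            n_invalid = sum(!is.finite(pointwise)))
}

# ---------------------------------------------------------------------------
# EZ-style moment initialization: closed-form constant-DDM estimates from
# accuracy and RT moments, per coherence level (diffusion coefficient 1).
# ---------------------------------------------------------------------------
.ez_point <- function(pc, mrt, vrt) {
  pc <- min(max(pc, 0.52), 0.98)
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / max(vrt, 1e-4)
  v <- sign(pc - 0.5) * abs(x)^0.25
  a <- L / v
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  c(v = v, a = a, t0 = mrt - mdt)
}

.ez_by <- function(sub, idx) {
  grp <- split(seq_len(nrow(sub)), idx)
  t(vapply(grp, function(i) {
    .ez_point(mean(sub$correct[i]), mean(sub$rt_s[i]), var(sub$rt_s[i]))
  }, numeric(3)))
}

# heuristic starting theta for one subject under a model layout
.init_theta <- function(layout, sub, cov) {
  spec <- layout$spec
  ez <- .ez_by(sub, sub$coherence_pct)
  cohc_lvl <- coherence_covariate(spec, as.numeric(rownames(ez)))
  ok <- is.finite(ez[, "v"]) & is.finite(ez[, "a"])
  fit <- if (sum(ok) >= 2) {
    stats::lm.fit(cbind(1, cohc_lvl[ok]), ez[ok, "v"])$coefficients
  } else c(0.7, 0.03)
  v_int <- unname(fit[1]); v_slp <- max(unname(fit[2]), 0.001)
  a_med <- min(max(median(ez[ok, "a"], na.rm = TRUE), 0.4), 3.5)
  t0_guess <- median(ez[ok, "t0"], na.rm = TRUE)
  t0_init <- min(max(t0_guess, 0.08, na.rm = TRUE), 0.95 * cov$minrt)
  theta <- setNames(numeric(length(layout$names)), layout$names)
  fill_traj <- function(prefix, form, start_val, asym_val) {
    nms <- .traj_par_names(prefix, form, spec$n_days)
    if (form == "constant") {
      theta[nms] <<- (start_val + asym_val) / 2
    } else if (form == "flexible") {
      theta[grep("_start_", nms, value = TRUE)] <<- start_val
      theta[grep("_asym_", nms, value = TRUE)] <<- asym_val
    } else {
      theta[nms] <<- c(start_val, asym_val)
    }
  }
  fill_traj("dr_int", spec$dr_form, 0.75 * v_int, 1.2 * v_int)
  fill_traj("dr_slope", spec$dr_form, 0.75 * v_slp, 1.2 * v_slp)
  fill_traj("rb", spec$rb_form, log(a_med) + 0.08, log(a_med) - 0.08)
  if (spec$dr_form != "constant") {
    theta["dr_rate"] <- .rate_prior_center(spec$dr_form, spec$n_days,
                                           spec$trials_per_day)
  }
  if (spec$rb_form != "constant") {
    theta["rb_rate"] <- .rate_prior_center(spec$rb_form, spec$n_days,
                                           spec$trials_per_day)
  }
  theta["bias_logit"] <- 0
  theta["ndt_raw"] <- ndt_to_theta(t0_init, cov$minrt)
  theta
}

.jitter_theta <- function(theta, layout) {
  k <- layout$kinds
  sdv <- c(drift = 0.15, logrb = 0.10, rate_dr = 0.6, rate_rb = 0.6,
           bias = 0.25, ndt = 0.4)
  theta + rnorm(length(theta), 0, sdv[k])
}

# Optimization box: wide sanity bounds, plus an identifiability cap on the
# rates — a time-to-half longer than the relevant timescale's trial count
# leaves the asymptote as unconstrained extrapolation, so rates are kept in
# [0, log2(max_trial)] (T50 between 3 trials and max_trial + 2).
.theta_bounds <- function(layout) {
  spec <- layout$spec
  k <- layout$kinds
  lower <- setNames(rep(-Inf, length(k)), layout$names)
  upper <- setNames(rep(Inf, length(k)), layout$names)
  lower[k == "drift"] <- -25; upper[k == "drift"] <- 25
  lower[k == "logrb"] <- -4;  upper[k == "logrb"] <- 4
  lower[k == "bias"] <- -5;   upper[k == "bias"] <- 5
  lower[k == "ndt"] <- -15;   upper[k == "ndt"] <- 15
  max_tr <- function(form) if (form == "continuous")
    spec$n_days * spec$trials_per_day else spec$trials_per_day
  lower[k == "rate_dr"] <- 0
  upper[k == "rate_dr"] <- log2(max_tr(spec$dr_form))
  lower[k == "rate_rb"] <- 0
  upper[k == "rate_rb"] <- log2(max_tr(spec$rb_form))
  list(lower = lower, upper = upper)
}

#' Fit a model by per-participant maximum likelihood
#'
#' The desk-scale default backend: each participant's parameters are
#' estimated independently by numerical optimization of the Wiener
#' likelihood over an unconstrained transform of the parameter space
#' (drift-scale parameters and rates free; boundary on the log scale; bias
#' on the logit scale; non-decision time mapped by a scaled logit into
#' (0.001, min RT - 1e-4) so the likelihood stays finite).  Each fit is the
#' best of a moment-based start plus `n_restarts - 1` jittered restarts.
#' Deterministic under `seed`.
#'
#' @param model a [model_spec()]
#' @param trials a filtered trial-record data.frame (see [exclude_trials()])
#' @param n_restarts optimizer starts per subject (first is the
#'   moment-based heuristic)
#' @param seed integer seed controlling the restart jitter
#' @param tolerance relative convergence tolerance
#' @param max_iter iteration cap per start
#' @param penalty `"none"` (pure ML) or `"prior"` (maximum a posteriori
#'   with the [prior_spec()] priors — the same priors the Bayesian backend
#'   uses; recommended for the trajectory models, whose asymptotes are
#'   extrapolations when the estimated time-to-half approaches the design
#'   length)
#' @param prior a [prior_spec()] used when `penalty = "prior"`
#' @param shrink optional normal shrinkage toward the group mean
#'   (desk-scale stand-in for the hierarchical random-effects structure):
#'   a named vector of per-parameter-kind SDs, e.g.
#'   `c(rate_dr = 0.3, rate_rb = 0.3)`; after the independent first pass,
#'   every subject is refitted with the named parameters penalized toward
#'   the first-pass group means with the given SD.  `NULL` (default)
#'   disables the second pass.  Kinds: `drift`, `logrb`, `rate_dr`,
#'   `rate_rb`, `bias`, `ndt`
#' @return an object of class `fit_result`: per-subject estimates, total
#'   log-likelihood, pointwise log-likelihood (single-column matrix),
#'   optimizer diagnostics
#' @export
fit_mle <- function(model, trials, n_restarts = 10L, seed = 1L,
                    tolerance = 1e-8, max_iter = 400L,
                    penalty = c("none", "prior"), prior = prior_spec(),
                    shrink = NULL) {
  penalty <- match.arg(penalty)
  layout <- model_layout(model)
  ids <- sort(unique(trials$subject))
  n_small <- sum(table(trials$subject) < 50)
  if (n_small > 0) {
    warning(n_small, " subject(s) have fewer than 50 trials; estimates may be unstable")
  }
  pointwise <- numeric(nrow(trials))
  estimates <- list()
  diagnostics <- list()
  .with_seed(seed, {
    for (s in ids) {
      idx <- which(trials$subject == s)
      sub <- trials[idx, , drop = FALSE]
      cov <- .trial_cov(model, sub)
      obj <- function(theta) {
        ll <- .ll_pointwise_theta(theta, layout, cov)
        if (any(!is.finite(ll))) return(1e10)
        nll <- -sum(ll)
        if (penalty == "prior") {
          nll <- nll - log_prior_theta(theta, layout, prior, cov$minrt)
        }
        nll
      }
      th0 <- .init_theta(layout, sub, cov)
      bnd <- .theta_bounds(layout)
      clamp <- function(th) pmin(pmax(th, bnd$lower), bnd$upper)
      starts <- c(list(clamp(th0)),
                  lapply(seq_len(max(0L, n_restarts - 1L)),
                         function(i) clamp(.jitter_theta(th0, layout))))
      best <- NULL
      conv <- FALSE
      for (st in starts) {
        res <- suppressWarnings(
          nlminb(st, obj, lower = bnd$lower, upper = bnd$upper,
                 control = list(iter.max = max_iter,
                                eval.max = 2L * max_iter,
                                rel.tol = tolerance)))
        if (is.null(best) || res$objective < best$objective) best <- res
        if (res$convergence == 0) conv <- TRUE
      }
      if (!conv && best$objective >= 1e10) {
        stop("no optimizer start converged for subject ", s, call. = FALSE)
      }
      theta <- setNames(best$par, layout$names)
      estimates[[as.character(s)]] <- list(
        theta = theta,
        subject = theta_to_subject(theta, layout, cov$minrt))
      pointwise[idx] <- .ll_pointwise_theta(theta, layout, cov)
      diagnostics[[as.character(s)]] <-
        data.frame(subject = s, converged = conv, nll = best$objective,
                   restarts = length(starts))
    }
    if (!is.null(shrink)) {
      # empirical-Bayes second pass: penalize the selected parameters
      # toward the first-pass group means
      th_mat <- do.call(rbind, lapply(estimates, `[[`, "theta"))
      mu <- colMeans(th_mat)
      sel <- layout$kinds %in% names(shrink) |
        layout$names %in% names(shrink)
      if (!any(sel)) {
        warning("'shrink' names match no parameter kind or name; ignored")
      }
      sd_vec <- rep(Inf, length(layout$names))
      for (nm in names(shrink)) {
        sd_vec[layout$kinds == nm | layout$names == nm] <- shrink[[nm]]
      }
      bnd <- .theta_bounds(layout)
      for (s in ids) {
        idx <- which(trials$subject == s)
        sub <- trials[idx, , drop = FALSE]
        cov <- .trial_cov(model, sub)
        obj2 <- function(theta) {
          ll <- .ll_pointwise_theta(theta, layout, cov)
          if (any(!is.finite(ll))) return(1e10)
          nll <- -sum(ll)
          if (penalty == "prior") {
            nll <- nll - log_prior_theta(theta, layout, prior, cov$minrt)
          }
          nll + sum(((theta - mu)[sel])^2 / (2 * sd_vec[sel]^2))
        }
        res <- suppressWarnings(
          nlminb(estimates[[as.character(s)]]$theta, obj2,
                 lower = bnd$lower, upper = bnd$upper,
                 control = list(iter.max = max_iter,
                                eval.max = 2L * max_iter,
                                rel.tol = tolerance)))
        theta <- setNames(res$par, layout$names)
        estimates[[as.character(s)]]$theta <- theta
        estimates[[as.character(s)]]$subject <-
          theta_to_subject(theta, layout, cov$minrt)
        pointwise[idx] <- .ll_pointwise_theta(theta, layout, cov)
        diagnostics[[as.character(s)]]$nll <- res$objective
      }
    }
  })
  new_fit_result(model = model, backend = "mle",
                 estimates = estimates,
                 pointwise = matrix(pointwise, ncol = 1),
                 trials = trials,
                 diagnostics = do.call(rbind, diagnostics),
                 seed = seed)
}

new_fit_result <- function(model, backend, estimates, pointwise, trials,
                           diagnostics, seed, draws = NULL,
                           log_post = NULL,
                           n_params = parameter_count(model,
                                                      length(estimates))) {
  structure(list(
    model_id = model$model_id, model = model, backend = backend,
    estimates = estimates, pointwise = pointwise,
    total_loglik = sum(pointwise[, ncol(pointwise), drop = TRUE]),
    n_trials = nrow(trials),
    trial_key = paste(trials$subject, trials$trial_overall, sep = ":"),
    n_params = n_params,
    diagnostics = diagnostics, seed = seed,
    draws = draws, log_post = log_post), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model %s (%s backend): %d subjects, %d trials, logLik %.1f\n",
              x$model_id, x$backend, length(x$estimates), x$n_trials,
              x$total_loglik))
  invisible(x)
}

# simple split-half R-hat and initial-sequence ESS for a single chain
.rhat_split <- function(x) {
  n <- floor(length(x) / 2)
  m <- cbind(x[1:n], x[(n + 1):(2 * n)])
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_acf <- function(x) {
  n <- length(x)
  rho <- stats::acf(x, lag.max = min(200, n - 2), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  K <- if (length(pos)) pos[1] else length(rho)
  n / (1 + 2 * sum(rho[seq_len(K)]))
}

#' Fit a model by Bayesian posterior sampling
#'
#' Adaptive random-walk Metropolis over the same unconstrained transform as
#' [fit_mle()], with the [prior_spec()] priors.  Proposal scale adapts to a
#' ~30\% acceptance rate during warmup; the proposal covariance is the
#' empirical covariance of the second half of warmup.  Per-draw pointwise
#' log-likelihoods are retained for PSIS-LOO, and the joint unnormalized
#' log-posterior evaluator for bridge sampling.  R-hat and ESS diagnostics
#' are reported (convergence bar: R-hat < 1.03); breaches are flagged, the
#' result is still returned.
#'
#' @inheritParams fit_mle
#' @param prior a [prior_spec()]
#' @param draws retained posterior draws per chain
#' @param warmup warmup iterations per chain (discarded)
#' @param chains number of chains
#' @param thin thinning interval applied after warmup
#' @return a `fit_result` with `draws` (retained joint draws), pointwise
#'   log-likelihood matrix (trials x draws), and `log_post`
#' @export
fit_bayes <- function(model, trials, prior = prior_spec(), draws = 1000L,
                      warmup = 1000L, chains = 2L, thin = 1L, seed = 1L) {
  layout <- model_layout(model)
  ids <- sort(unique(trials$subject))
  if (!length(ids)) ids <- 1L   # prior-only run: posterior = prior
  d <- length(layout$names)
  S <- draws * chains
  per_subj <- list()
  .with_seed(seed, {
    for (s in ids) {
      idx <- which(trials$subject == s)
      sub <- trials[idx, , drop = FALSE]
      cov <- if (nrow(sub) > 0) .trial_cov(model, sub) else
        list(day = integer(0), wtrial = integer(0), ctrial = integer(0),
             cohc = numeric(0), rt = numeric(0), correct = logical(0),
             sgn = numeric(0), c01 = numeric(0), minrt = 2.5)
      lpost <- function(theta) {
        ll <- .ll_pointwise_theta(theta, layout, cov)
        if (any(!is.finite(ll))) return(-Inf)
        sum(ll) + log_prior_theta(theta, layout, prior, cov$minrt)
      }
      th0 <- if (nrow(sub) > 0) .init_theta(layout, sub, cov) else
        setNames(rnorm(d, 0, 0.5), layout$names)
      chain_draws <- vector("list", chains)
      for (ch in seq_len(chains)) {
        th <- .jitter_theta(th0, layout)
        lp <- lpost(th)
        tries <- 0
        while (!is.finite(lp) && tries < 50) {
          th <- .jitter_theta(th0, layout); lp <- lpost(th); tries <- tries + 1
        }
        scale <- 0.5 / sqrt(d)
        cholS <- diag(d)
        warm <- matrix(NA_real_, warmup, d)
        for (it in seq_len(warmup)) {
          prop <- th + scale * as.vector(cholS %*% rnorm(d))
          lp2 <- lpost(prop)
          accepted <- log(runif(1)) < lp2 - lp
          if (accepted) { th <- prop; lp <- lp2 }
          warm[it, ] <- th
          # Robbins-Monro step toward ~30% acceptance
          scale <- scale * exp((as.numeric(accepted) - 0.3) / (5 + it)^0.6)
          if (it %in% floor(c(0.5, 0.75) * warmup)) {
            win <- seq(floor(it / 2), it)
            cv <- var(warm[win, , drop = FALSE])
            cv <- cv + diag(1e-8 + 1e-4 * mean(diag(cv)), d)
            cholS <- t(chol(cv))
            scale <- 2.38 / sqrt(d)
          }
        }
        keep <- matrix(NA_real_, draws, d)
        for (it in seq_len(draws * thin)) {
          prop <- th + scale * as.vector(cholS %*% rnorm(d))
          lp2 <- lpost(prop)
          if (log(runif(1)) < lp2 - lp) { th <- prop; lp <- lp2 }
          if (it %% thin == 0) keep[it %/% thin, ] <- th
        }
        chain_draws[[ch]] <- keep
      }
      dm <- do.call(rbind, chain_draws)
      colnames(dm) <- layout$names
      # pointwise log-likelihood per retained draw
      pw <- if (nrow(sub) > 0) {
        vapply(seq_len(S), function(j)
          .ll_pointwise_theta(setNames(dm[j, ], layout$names), layout, cov),
          numeric(nrow(sub)))
      } else matrix(numeric(0), 0, S)
      if (nrow(sub) == 1L) pw <- matrix(pw, nrow = 1L)
      rhat <- apply(dm, 2, .rhat_split)
      ess <- apply(dm, 2, .ess_acf)
      per_subj[[as.character(s)]] <- list(draws = dm, pw = pw, idx = idx,
                                          lpost = lpost, cov = cov,
                                          rhat = rhat, ess = ess)
    }
  })
  pointwise <- matrix(0, nrow(trials), S)
  for (ps in per_subj) if (length(ps$idx)) pointwise[ps$idx, ] <- ps$pw
  joint <- do.call(cbind, lapply(per_subj, function(ps) ps$draws))
  colnames(joint) <- unlist(lapply(names(per_subj), function(s)
    paste(s, layout$names, sep = ".")))
  blocks <- lapply(per_subj, function(ps) ps$lpost)
  dsub <- d
  log_post <- function(theta_joint) {
    tot <- 0
    for (k in seq_along(blocks)) {
      th <- theta_joint[((k - 1) * dsub + 1):(k * dsub)]
      names(th) <- layout$names
      tot <- tot + blocks[[k]](th)
      if (!is.finite(tot)) return(-Inf)
    }
    tot
  }
  estimates <- lapply(per_subj, function(ps) {
    theta <- setNames(colMeans(ps$draws), layout$names)
    list(theta = theta,
         subject = theta_to_subject(theta, layout, ps$cov$minrt))
  })
  rhat_max <- max(vapply(per_subj, function(ps) max(ps$rhat), numeric(1)))
  ess_min <- min(vapply(per_subj, function(ps) min(ps$ess), numeric(1)))
  if (rhat_max >= 1.03) {
    warning(sprintf("max R-hat %.3f exceeds the 1.03 convergence bar",
                    rhat_max))
  }
  diagnostics <- data.frame(subject = as.numeric(names(per_subj)),
                            rhat_max = vapply(per_subj, function(ps)
                              max(ps$rhat), numeric(1)),
                            ess_min = vapply(per_subj, function(ps)
                              min(ps$ess), numeric(1)))
  out <- new_fit_result(model = model, backend = "bayes",
                        estimates = estimates, pointwise = pointwise,
                        trials = trials, diagnostics = diagnostics,
                        seed = seed, draws = joint, log_post = log_post)
  out$total_loglik <- mean(colSums(pointwise))
  out$rhat_max <- rhat_max
  out$ess_min <- ess_min
  out
}
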