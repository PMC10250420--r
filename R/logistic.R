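#' Logistic psychometric function with a fixed lapse rate
#'
#' Probability of a rightward response given signed coherence (negative =
#' leftward motion) and the current threshold:
#' `p = lapse/2 + (1 - lapse) * plogis(signed_coherence / threshold)`.
#' The threshold is the inverse slope of the psychometric function;
#' predictions are bounded in `[lapse/2, 1 - lapse/2]` and `p(0) = 0.5`.
#'
#' @param signed_coherence coherence in percent, signed by motion direction
#' @param threshold psychometric threshold (same units, `> 0`)
#' @param lapse stimulus-independent lapse probability (default 0.01)
#' @return probability of responding "right"; vectorized
#' @examples
#' psychometric_p(0, 5)            # 0.5
#' psychometric_p(1e6, 5)          # 0.995 (lapse ceiling)
#' @export
psychometric_p <- function(signed_coherence, threshold, lapse = 0.01) {
  if (any(threshold <= 0)) stop("'threshold' must be > 0", call. = FALSE)
  if (any(lapse < 0 | lapse > 0.05)) {
    stop("'lapse' must lie in [0, 0.05]", call. = FALSE)
  }
  lapse / 2 + (1 - lapse) * plogis(signed_coherence / threshold)
}

.LOGISTIC_DYNAMICS <- c("continuous", "day_resetting", "flexible",
                        "continuous_plus_day_resetting")

#' Accuracy-only logistic baseline specification
#'
#' The comparison analysis that uses choices alone: a logistic psychometric
#' function whose threshold evolves on the log scale under one of four
#' dynamics — `continuous` (cumulative trial), `day_resetting` (within-day,
#' shared endpoints), `flexible` (within-day, day-specific endpoints,
#' shared rate), or `continuous_plus_day_resetting` (a continuous curve
#' plus a day-resetting offset that decays to zero within each day).
#' Z-scored RTs enter as by-participant slopes on the starting and
#' asymptotic log-threshold parameters.
#'
#' @param dynamics one of the four threshold dynamics
#' @param lapse fixed lapse rate (default 0.01)
#' @param n_days,trials_per_day design dimensions
#' @return an object of class `logistic_spec`
#' @export
logistic_spec <- function(dynamics = .LOGISTIC_DYNAMICS, lapse = 0.01,
                          n_days = 4L, trials_per_day = 700L) {
  dynamics <- match.arg(dynamics)
  structure(list(dynamics = dynamics, lapse = lapse,
                 n_days = as.integer(n_days),
                 trials_per_day = as.integer(trials_per_day)),
            class = "logistic_spec")
}

.logistic_par_names <- function(spec) {
  nd <- spec$n_days
  base <- switch(spec$dynamics,
    continuous = c("th_start", "th_asym", "th_rate"),
    day_resetting = c("th_start", "th_asym", "th_rate"),
    flexible = c(paste0("th_start_d", seq_len(nd)),
                 paste0("th_asym_d", seq_len(nd)), "th_rate"),
    continuous_plus_day_resetting =
      c("th_start", "th_asym", "th_rate", "off_amp", "off_rate"))
  c(base, "rt_slope_start", "rt_slope_asym")
}

# per-trial log-threshold implied by theta (z-scored RT enters additively
# on the log scale through the start/asymptote slopes)
logistic_log_threshold <- function(theta, spec, day, wtrial, ctrial, zrt) {
  bs <- theta[["rt_slope_start"]] * zrt
  ba <- theta[["rt_slope_asym"]] * zrt
  switch(spec$dynamics,
    continuous = curve_value(ctrial, theta[["th_start"]] + bs,
                             theta[["th_asym"]] + ba, theta[["th_rate"]]),
    day_resetting = curve_value(wtrial, theta[["th_start"]] + bs,
                                theta[["th_asym"]] + ba,
                                theta[["th_rate"]]),
    flexible = {
      nd <- spec$n_days
      s <- unname(theta[paste0("th_start_d", seq_len(nd))])[day] + bs
      a <- unname(theta[paste0("th_asym_d", seq_len(nd))])[day] + ba
      curve_value(wtrial, s, a, theta[["th_rate"]])
    },
    continuous_plus_day_resetting =
      curve_value(ctrial, theta[["th_start"]] + bs,
                  theta[["th_asym"]] + ba, theta[["th_rate"]]) +
      curve_value(wtrial, theta[["off_amp"]], 0, theta[["off_rate"]]))
}

.logistic_cov <- function(trials) {
  list(day = trials$day, wtrial = trials$trial_in_day,
       ctrial = trials$trial_overall,
       signed = ifelse(trials$stim_dir == "R", 1, -1) * trials$coherence_pct,
       right = trials$resp_dir == "R",
       zrt = as.vector(scale(trials$rt_s)))
}

.logistic_ll <- function(theta, spec, cov) {
  lth <- logistic_log_threshold(theta, spec, cov$day, cov$wtrial,
                                cov$ctrial, cov$zrt)
  # clamp so exp() cannot under/overflow when the optimizer probes
  # extreme parameter values; the likelihood stays finite either way
  lth <- pmin(pmax(lth, -50), 50)
  p <- psychometric_p(cov$signed, exp(lth), spec$lapse)
  ifelse(cov$right, log(p), log1p(-p))
}

#' Fit the time-varying-threshold logistic baseline
#'
#' Per-participant maximum likelihood of the Bernoulli likelihood over
#' choices, with the by-trial threshold given by the spec's dynamics and
#' the RT slopes (RTs are used only as z-scored covariates).  Pointwise
#' log-likelihoods are retained so the four dynamics can be compared with
#' the same criteria as the DDM models.
#'
#' @param trials a filtered trial-record data.frame
#' @param spec a [logistic_spec()]
#' @param n_restarts optimizer starts per subject
#' @param seed integer seed for the restart jitter
#' @return a `fit_result` (backend `"mle"`, `model_id` = the dynamics name)
#' @export
fit_logistic_dynamics <- function(trials, spec, n_restarts = 3L, seed = 1L) {
  stopifnot(inherits(spec, "logistic_spec"))
  nms <- .logistic_par_names(spec)
  ids <- sort(unique(trials$subject))
  pointwise <- numeric(nrow(trials))
  estimates <- list()
  diagnostics <- list()
  .with_seed(seed, {
    for (s in ids) {
      idx <- which(trials$subject == s)
      sub <- trials[idx, , drop = FALSE]
      if (length(unique(sub$resp_dir)) < 2) {
        warning("subject ", s, " gave a single response throughout; ",
                "threshold weakly identified")
      }
      cov <- .logistic_cov(sub)
      obj <- function(theta) {
        names(theta) <- nms
        ll <- .logistic_ll(theta, spec, cov)
        if (any(!is.finite(ll))) return(1e10)
        -sum(ll)
      }
      # crude threshold guess: coherence level nearest 75% accuracy
      acc <- tapply(sub$correct, sub$coherence_pct, mean)
      lv <- as.numeric(names(acc))
      th_guess <- if (any(acc >= 0.75)) lv[which(acc >= 0.75)[1]]
                  else max(lv)
      th0 <- setNames(numeric(length(nms)), nms)
      th0[grepl("^th_start", nms)] <- log(th_guess) + 0.3
      th0[grepl("^th_asym", nms)] <- log(th_guess) - 0.3
      th0["th_rate"] <- log2(0.25 * if (spec$dynamics == "continuous")
        spec$n_days * spec$trials_per_day else spec$trials_per_day)
      if (spec$dynamics == "continuous_plus_day_resetting") {
        th0["off_amp"] <- 0.2
        th0["off_rate"] <- log2(0.1 * spec$trials_per_day)
      }
      starts <- c(list(th0), lapply(seq_len(max(0, n_restarts - 1)),
                                    function(i) th0 + rnorm(length(th0),
                                                            0, 0.3)))
      best <- NULL
      conv <- FALSE
      for (st in starts) {
        res <- suppressWarnings(nlminb(st, obj,
                                       control = list(iter.max = 400,
                                                      eval.max = 800)))
        if (is.null(best) || res$objective < best$objective) best <- res
        if (res$convergence == 0) conv <- TRUE
      }
      theta <- setNames(best$par, nms)
      estimates[[as.character(s)]] <- list(theta = theta)
      pointwise[idx] <- .logistic_ll(theta, spec, cov)
      diagnostics[[as.character(s)]] <-
        data.frame(subject = s, converged = conv, nll = best$objective)
    }
  })
  new_fit_result(model = list(model_id = spec$dynamics, spec = spec),
                 backend = "mle", estimates = estimates,
                 pointwise = matrix(pointwise, ncol = 1), trials = trials,
                 diagnostics = do.call(rbind, diagnostics), seed = seed,
                 n_params = length(nms) * length(ids))
}

#' Fitted per-trial log-threshold trajectory
#'
#' Evaluates a fitted (or true) logistic parameter vector's log-threshold
#' at each trial of a table, at the mean RT (`zRT = 0`).
#'
#' @param theta named parameter vector (layout of [fit_logistic_dynamics()])
#' @param spec the [logistic_spec()]
#' @param trials trial-record rows for one subject
#' @return per-trial log-threshold values
#' @export
logistic_trajectory <- function(theta, spec, trials) {
  logistic_log_threshold(theta, spec, trials$day, trials$trial_in_day,
                         trials$trial_overall, rep(0, nrow(trials)))
}

#' Simulate choice data from a threshold-dynamics ground truth
#'
#' Draws Bernoulli responses from the logistic psychometric function with
#' the per-trial threshold implied by each subject's parameter vector.
#' RTs (needed as z-scored covariates when refitting) are drawn log-normal
#' and carry no signal unless the truth's RT slopes are nonzero.
#'
#' @param design a [generate_design()] table
#' @param truth list of per-subject named parameter vectors (see
#'   [fit_logistic_dynamics()] layout)
#' @param spec the generating [logistic_spec()]
#' @param seed integer seed
#' @return a trial-record data.frame (with `resp_dir`, `correct`, `rt_s`)
#' @export
simulate_logistic_trials <- function(design, truth, spec, seed = NULL) {
  .with_seed(seed, {
    res <- lapply(split(design, design$subject), function(dsub) {
      s <- dsub$subject[1L]
      theta <- truth[[s]]
      rt <- rlnorm(nrow(dsub), log(0.7), 0.3)
      zrt <- as.vector(scale(rt))
      lth <- logistic_log_threshold(theta, spec, dsub$day,
                                    dsub$trial_in_day, dsub$trial_overall,
                                    zrt)
      signed <- ifelse(dsub$stim_dir == "R", 1, -1) * dsub$coherence_pct
      p_right <- psychometric_p(signed, exp(lth), spec$lapse)
      right <- runif(nrow(dsub)) < p_right
      resp <- ifelse(right, "R", "L")
      data.frame(subject = s, group = if (s %% 2 == 0) "AVGP" else "NVGP",
                 day = dsub$day, trial_in_day = dsub$trial_in_day,
                 trial_overall = dsub$trial_overall,
                 coherence_pct = dsub$coherence_pct,
                 stim_dir = dsub$stim_dir, resp_dir = resp,
                 correct = resp == dsub$stim_dir, rt_s = rt)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Default logistic-threshold ground truth
#'
#' Per-subject parameter vectors for [simulate_logistic_trials()]: log
#' thresholds starting near 15\% coherence and asymptoting near 5\%, with
#' between-subject SD 0.15 on the log scale, time-to-half constants scaled
#' to the design, and zero RT slopes.
#'
#' @param n_subjects subjects to draw
#' @param spec the generating [logistic_spec()]
#' @param seed integer seed
#' @return list of named parameter vectors
#' @export
sample_logistic_truth <- function(n_subjects, spec, seed = NULL) {
  nms <- .logistic_par_names(spec)
  nd <- spec$n_days
  total <- nd * spec$trials_per_day
  .with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      th <- setNames(numeric(length(nms)), nms)
      if (spec$dynamics == "flexible") {
        day_start <- log(c(15, 11, 9, 8))[seq_len(nd)]
        day_asym <- log(c(9, 7, 6, 5))[seq_len(nd)]
        th[paste0("th_start_d", seq_len(nd))] <- day_start + rnorm(nd, 0, 0.15)
        th[paste0("th_asym_d", seq_len(nd))] <- day_asym + rnorm(nd, 0, 0.15)
        th["th_rate"] <- rate_for_half_time(0.15 * spec$trials_per_day)
      } else {
        th["th_start"] <- log(15) + rnorm(1, 0, 0.15)
        th["th_asym"] <- log(5) + rnorm(1, 0, 0.15)
        th["th_rate"] <- if (spec$dynamics == "day_resetting")
          rate_for_half_time(0.25 * spec$trials_per_day)
        else rate_for_half_time(0.45 * total)
      }
      if (spec$dynamics == "continuous_plus_day_resetting") {
        th["off_amp"] <- 0.5 + rnorm(1, 0, 0.1)
        th["off_rate"] <- rate_for_half_time(0.08 * spec$trials_per_day)
      }
      th
    })
  })
}
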