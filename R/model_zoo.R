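.MODEL_FORMS <- list(
  A = c(dr = "constant",   rb = "constant"),
  B = c(dr = "continuous", rb = "continuous"),
  C = c(dr = "continuous", rb = "day_resetting"),
  D = c(dr = "continuous", rb = "flexible"),
  E = c(dr = "flexible",   rb = "continuous"),
  F = c(dr = "flexible",   rb = "flexible")
)

#' Candidate model specification (models A-F)
#'
#' The six models compared in the analysis, differing only in which DDM
#' parameters vary over training and on which timescale:
#' A constant DR, constant RB; B continuous DR, continuous RB; C continuous
#' DR, day-resetting RB; D continuous DR, flexible RB; E flexible DR,
#' continuous RB; F flexible DR, flexible RB.  Bias and non-decision time
#' are constant per subject in every model.  Drift rate is a linear (default)
#' or log-transformed, median-centered function of motion coherence, with
#' the coherence slope following the same dynamics as the DR intercept
#' (shared rate).  Response boundary evolves on the log scale.
#'
#' @param model_id one of `"A"`..`"F"`
#' @param coherence_link `"linear"` (default, supported by the model
#'   comparison on these data) or `"log"`
#' @param group_covariate include additive group (e.g. AVGP/NVGP) fixed
#'   shifts on each parameter's intercept
#' @param n_days days of training in the design
#' @param trials_per_day trials per day
#' @param coherence_center value at which the coherence covariate is
#'   centered; the design median 6.4 (\%) by default (log-transformed under
#'   the log link)
#' @return an object of class `model_spec`
#' @examples
#' model_spec("D")
#' @export
model_spec <- function(model_id = c("A", "B", "C", "D", "E", "F"),
                       coherence_link = c("linear", "log"),
                       group_covariate = FALSE,
                       n_days = 4L, trials_per_day = 700L,
                       coherence_center = 6.4) {
  model_id <- match.arg(model_id)
  coherence_link <- match.arg(coherence_link)
  forms <- .MODEL_FORMS[[model_id]]
  structure(list(model_id = model_id,
                 dr_form = forms[["dr"]], rb_form = forms[["rb"]],
                 coherence_link = coherence_link,
                 group_covariate = isTRUE(group_covariate),
                 n_days = as.integer(n_days),
                 trials_per_day = as.integer(trials_per_day),
                 coherence_center = coherence_center),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %s: %s DR, %s RB (%s coherence; %d days x %d trials)\n",
              x$model_id, x$dr_form, x$rb_form, x$coherence_link,
              x$n_days, x$trials_per_day))
  invisible(x)
}

# centered coherence covariate under the model's link
coherence_covariate <- function(spec, coherence_pct) {
  design <- c(0.8, 1.6, 3.2, 6.4, 12.8, 25.6, 51.2)
  if (!all(coherence_pct %in% design)) {
    warning("coherence outside the design levels; evaluated by extrapolation")
  }
  if (spec$coherence_link == "log") {
    log(coherence_pct) - log(spec$coherence_center)
  } else {
    coherence_pct - spec$coherence_center
  }
}

#' Subject-level parameter set
#'
#' Trajectories and scalar parameters for one participant: DR intercept and
#' coherence-slope trajectories (identity scale, shared rate), log-RB
#' trajectory, constant logit bias and non-decision-time offset.  Implied
#' DDM parameters: `a = exp(logRB) > 0`, `z = plogis(bias_logit)`,
#' `t0 = 0.001 + ndt_offset`.
#'
#' @param dr_int [trajectory_spec()] for the DR intercept (value of DR at
#'   the centered coherence)
#' @param dr_slope [trajectory_spec()] for the by-subject coherence slope
#' @param rb [trajectory_spec()] for the log response boundary
#' @param bias_logit starting-point bias on the logit scale
#' @param ndt_offset non-decision time minus the 0.001 s offset (`> 0`)
#' @param group_effects optional named additive shifts (`dr`, `rb`,
#'   `bias`, `ndt`) applied to the respective intercepts
#' @return an object of class `subject_params`
#' @export
subject_params <- function(dr_int, dr_slope, rb, bias_logit, ndt_offset,
                           group_effects = NULL) {
  stopifnot(inherits(dr_int, "trajectory_spec"),
            inherits(dr_slope, "trajectory_spec"),
            inherits(rb, "trajectory_spec"))
  if (ndt_offset <= 0) stop("'ndt_offset' must be > 0", call. = FALSE)
  structure(list(dr_int = dr_int, dr_slope = dr_slope, rb = rb,
                 bias_logit = bias_logit, ndt_offset = ndt_offset,
                 group_effects = group_effects),
            class = "subject_params")
}

#' Per-trial DDM parameters under a model
#'
#' Maps a subject's trajectories and a table of trials to instantaneous
#' Wiener parameters: `v` = DR-intercept trajectory value + coherence-slope
#' trajectory value x centered coherence; `a` = exp(log-RB trajectory
#' value); `z` and `t0` constant per subject.
#'
#' @param spec a [model_spec()]
#' @param subj a [subject_params()]
#' @param trials a data.frame with columns `day`, `trial_in_day`,
#'   `trial_overall`, `coherence_pct`
#' @return a data.frame with columns `v`, `a`, `z`, `t0`, one row per trial
#' @export
per_trial_params <- function(spec, subj, trials) {
  cohc <- coherence_covariate(spec, trials$coherence_pct)
  g <- subj$group_effects
  gs <- function(nm) if (!is.null(g) && !is.null(g[[nm]])) g[[nm]] else 0
  v <- trajectory(subj$dr_int, trials$day, trials$trial_in_day,
                  trials$trial_overall) + gs("dr") +
       trajectory(subj$dr_slope, trials$day, trials$trial_in_day,
                  trials$trial_overall) * cohc
  a <- exp(trajectory(subj$rb, trials$day, trials$trial_in_day,
                      trials$trial_overall) + gs("rb"))
  z <- plogis(subj$bias_logit + gs("bias"))
  t0 <- 0.001 + subj$ndt_offset + gs("ndt")
  data.frame(v = v, a = a, z = rep_len(z, nrow(trials)),
             t0 = rep_len(t0, nrow(trials)))
}

# free parameters per trajectory of a given form
.n_traj_params <- function(form, n_days) {
  switch(form,
         constant = 1L,
         continuous = 3L,
         day_resetting = 3L,
         flexible = 2L * n_days + 1L)
}

#' Free-parameter count of a model
#'
#' Counts per-subject free parameters (DR intercept and coherence-slope
#' trajectories sharing one rate, log-RB trajectory, bias, NDT), times the
#' number of subjects, plus group fixed shifts if enabled.  Used for
#' AIC/BIC under the maximum-likelihood backend.
#'
#' @inheritParams per_trial_params
#' @param n_subjects number of subjects fitted
#' @param n_days number of days (defaults to the spec's)
#' @return integer parameter count
#' @examples
#' parameter_count(model_spec("A"), 1)  # 5
#' @export
parameter_count <- function(spec, n_subjects, n_days = spec$n_days) {
  dr <- .n_traj_params(spec$dr_form, n_days)
  if (spec$dr_form != "constant") {
    dr <- 2L * (dr - 1L) + 1L  # slope shares the rate with the intercept
  } else {
    dr <- 2L                    # intercept + slope
  }
  rb <- .n_traj_params(spec$rb_form, n_days)
  per_subject <- dr + rb + 2L   # + bias + ndt
  total <- as.integer(n_subjects) * per_subject
  if (spec$group_covariate) total <- total + 4L
  total
}

#' Prior specification for the nonlinear DDM parameters
#'
#' Defaults follow the fitted models: `student_t(3, 1, 10)` on drift-scale
#' parameters, `normal(-0.6, 1.3)` on log-boundary parameters, `normal(0,1)`
#' on the logit bias, `normal(log2(0.25 * max_trial), 1)` on rates (centered
#' on 25\% of the maximum trial number of the relevant timescale: within-day
#' for day-resetting/flexible forms, the full experiment for continuous),
#' and an exponential with mean 0.15 s on the non-decision-time offset
#' (`ndt = 0.001 + offset`).
#'
#' @param drift `c(df, location, scale)` of the Student-t prior on
#'   drift-scale parameters
#' @param log_boundary `c(mean, sd)` of the normal prior on log-RB
#' @param bias_logit `c(mean, sd)` of the normal prior on the logit bias
#' @param rate_sd SD of the normal rate priors (the centers are derived from
#'   the design)
#' @param ndt_mean mean (s) of the exponential prior on the NDT offset
#' @return an object of class `prior_spec`
#' @export
prior_spec <- function(drift = c(df = 3, location = 1, scale = 10),
                       log_boundary = c(mean = -0.6, sd = 1.3),
                       bias_logit = c(mean = 0, sd = 1),
                       rate_sd = 1,
                       ndt_mean = 0.15) {
  structure(list(drift = drift, log_boundary = log_boundary,
                 bias_logit = bias_logit, rate_sd = rate_sd,
                 ndt_mean = ndt_mean),
            class = "prior_spec")
}

# prior center of a rate parameter: log2 of 25% of the relevant max trial
.rate_prior_center <- function(form, n_days, trials_per_day) {
  max_trial <- if (form == "continuous") n_days * trials_per_day
               else trials_per_day
  log2(0.25 * max_trial)
}

# ---------------------------------------------------------------------------
# Internal unconstrained parameterization shared by the MLE and Bayesian
# backends.  theta is a flat named vector per subject; each element carries a
# "kind" used for priors and initialization.  The NDT element maps through a
# scaled logit to (0.001, minrt - 1e-4) so that the likelihood is finite on
# the whole unconstrained space boundary-free.
# ---------------------------------------------------------------------------

.traj_par_names <- function(prefix, form, n_days) {
  switch(form,
         constant = prefix,
         continuous = paste0(prefix, c("_start", "_asym")),
         day_resetting = paste0(prefix, c("_start", "_asym")),
         flexible = c(paste0(prefix, "_start_d", seq_len(n_days)),
                      paste0(prefix, "_asym_d", seq_len(n_days))))
}

# layout: names, kinds (drift | logrb | rate_dr | rate_rb | bias | ndt)
model_layout <- function(spec) {
  nd <- spec$n_days
  nm_int <- .traj_par_names("dr_int", spec$dr_form, nd)
  nm_slp <- .traj_par_names("dr_slope", spec$dr_form, nd)
  nm_dr_rate <- if (spec$dr_form == "constant") character(0) else "dr_rate"
  nm_rb <- .traj_par_names("rb", spec$rb_form, nd)
  nm_rb_rate <- if (spec$rb_form == "constant") character(0) else "rb_rate"
  nms <- c(nm_int, nm_slp, nm_dr_rate, nm_rb, nm_rb_rate,
           "bias_logit", "ndt_raw")
  kinds <- c(rep("drift", length(nm_int) + length(nm_slp)),
             rep("rate_dr", length(nm_dr_rate)),
             rep("logrb", length(nm_rb)),
             rep("rate_rb", length(nm_rb_rate)),
             "bias", "ndt")
  list(names = nms, kinds = setNames(kinds, nms), spec = spec)
}

# split a trajectory parameter block into (starts, asyms) on the link scale
.traj_values <- function(theta, prefix, form, n_days) {
  if (form == "constant") {
    val <- theta[[prefix]]
    return(list(starts = val, asyms = val))
  }
  if (form == "flexible") {
    list(starts = unname(theta[paste0(prefix, "_start_d", seq_len(n_days))]),
         asyms = unname(theta[paste0(prefix, "_asym_d", seq_len(n_days))]))
  } else {
    list(starts = theta[[paste0(prefix, "_start")]],
         asyms = theta[[paste0(prefix, "_asym")]])
  }
}

.ndt_cap <- function(minrt) minrt - 1e-4

theta_to_ndt <- function(ndt_raw, minrt) {
  0.001 + (.ndt_cap(minrt) - 0.001) * plogis(ndt_raw)
}

ndt_to_theta <- function(t0, minrt) {
  qlogis((t0 - 0.001) / (.ndt_cap(minrt) - 0.001))
}

# trajectory values for all trials, given covariate vectors; fast path used
# inside the likelihood (no data.frame construction)
.eval_traj <- function(form, starts, asyms, rate, day, wtrial, ctrial) {
  switch(form,
    constant = rep_len(starts, length(day)),
    continuous = curve_value(ctrial, starts, asyms, rate),
    day_resetting = curve_value(wtrial, starts, asyms, rate),
    flexible = curve_value(wtrial, starts[day], asyms[day], rate))
}

# theta -> per-trial (v, a, z, t0) using precomputed covariates
theta_trial_params <- function(theta, layout, cov, minrt) {
  spec <- layout$spec
  di <- .traj_values(theta, "dr_int", spec$dr_form, spec$n_days)
  ds <- .traj_values(theta, "dr_slope", spec$dr_form, spec$n_days)
  rb <- .traj_values(theta, "rb", spec$rb_form, spec$n_days)
  dr_rate <- if (spec$dr_form == "constant") 0 else theta[["dr_rate"]]
  rb_rate <- if (spec$rb_form == "constant") 0 else theta[["rb_rate"]]
  v <- .eval_traj(spec$dr_form, di$starts, di$asyms, dr_rate,
                  cov$day, cov$wtrial, cov$ctrial) +
       .eval_traj(spec$dr_form, ds$starts, ds$asyms, dr_rate,
                  cov$day, cov$wtrial, cov$ctrial) * cov$cohc
  a <- exp(.eval_traj(spec$rb_form, rb$starts, rb$asyms, rb_rate,
                      cov$day, cov$wtrial, cov$ctrial))
  list(v = v, a = a, z = plogis(theta[["bias_logit"]]),
       t0 = theta_to_ndt(theta[["ndt_raw"]], minrt))
}

# theta -> subject_params (public representation)
theta_to_subject <- function(theta, layout, minrt) {
  spec <- layout$spec
  nd <- spec$n_days
  mk <- function(prefix, form, rate) {
    tv <- .traj_values(theta, prefix, form, nd)
    trajectory_spec(form, tv$starts, tv$asyms, rate, n_days = nd)
  }
  dr_rate <- if (spec$dr_form == "constant") 0 else theta[["dr_rate"]]
  rb_rate <- if (spec$rb_form == "constant") 0 else theta[["rb_rate"]]
  subject_params(dr_int = mk("dr_int", spec$dr_form, dr_rate),
                 dr_slope = mk("dr_slope", spec$dr_form, dr_rate),
                 rb = mk("rb", spec$rb_form, rb_rate),
                 bias_logit = theta[["bias_logit"]],
                 ndt_offset = theta_to_ndt(theta[["ndt_raw"]], minrt) - 0.001)
}

# log prior density of theta (includes the Jacobian of the NDT transform)
log_prior_theta <- function(theta, layout, prior, minrt) {
  spec <- layout$spec
  k <- layout$kinds
  lp <- 0
  i <- k == "drift"
  if (any(i)) {
    lp <- lp + sum(dt((theta[i] - prior$drift[["location"]]) /
                        prior$drift[["scale"]],
                      df = prior$drift[["df"]], log = TRUE) -
                     log(prior$drift[["scale"]]))
  }
  i <- k == "logrb"
  if (any(i)) {
    lp <- lp + sum(dnorm(theta[i], prior$log_boundary[["mean"]],
                         prior$log_boundary[["sd"]], log = TRUE))
  }
  i <- k == "rate_dr"
  if (any(i)) {
    lp <- lp + dnorm(theta[i], .rate_prior_center(spec$dr_form, spec$n_days,
                                                  spec$trials_per_day),
                     prior$rate_sd, log = TRUE)
  }
  i <- k == "rate_rb"
  if (any(i)) {
    lp <- lp + dnorm(theta[i], .rate_prior_center(spec$rb_form, spec$n_days,
                                                  spec$trials_per_day),
                     prior$rate_sd, log = TRUE)
  }
  lp <- lp + dnorm(theta[["bias_logit"]], prior$bias_logit[["mean"]],
                   prior$bias_logit[["sd"]], log = TRUE)
  # exponential prior on the offset + log Jacobian of the scaled logit
  off <- theta_to_ndt(theta[["ndt_raw"]], minrt) - 0.001
  pr <- plogis(theta[["ndt_raw"]])
  lp + dexp(off, rate = 1 / prior$ndt_mean, log = TRUE) +
    log(.ndt_cap(minrt) - 0.001) + log(pr) + log1p(-pr)
}
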