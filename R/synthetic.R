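# run code under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's stream afterwards
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.DESIGN_COHERENCES <- c(0.8, 1.6, 3.2, 6.4, 12.8, 25.6, 51.2)

#' Generate the randomized-coherence trial design
#'
#' Builds the trial table of the multi-day dot-motion experiment: for each
#' subject and day, `per_level` trials of each coherence level in seeded
#' random order, with left/right stimulus direction assigned 50/50 at
#' random.  The reference design is 4 days x 700 trials (100 trials of each
#' of 7 coherence levels per day).
#'
#' @param n_subjects number of participants
#' @param n_days training days
#' @param trials_per_day trials per day; must equal
#'   `per_level * length(coherences)`
#' @param coherences coherence levels in percent
#' @param per_level trials per coherence level per day
#' @param seed integer seed (reproducible design); `NULL` uses the current
#'   RNG stream
#' @return a data.frame with columns `subject`, `day`, `trial_in_day`,
#'   `trial_overall`, `coherence_pct`, `stim_dir`
#' @examples
#' d <- generate_design(2, n_days = 2, trials_per_day = 14, per_level = 2,
#'                      seed = 1)
#' table(d$day, d$coherence_pct)
#' @export
generate_design <- function(n_subjects, n_days = 4L, trials_per_day = 700L,
                            coherences = .DESIGN_COHERENCES,
                            per_level = 100L, seed = NULL) {
  if (per_level * length(coherences) != trials_per_day) {
    stop("per_level * number of coherence levels must equal trials_per_day",
         call. = FALSE)
  }
  .with_seed(seed, {
    per_day <- as.integer(trials_per_day)
    out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      do.call(rbind, lapply(seq_len(n_days), function(d) {
        coh <- sample(rep(coherences, each = per_level))
        data.frame(subject = s, day = d,
                   trial_in_day = seq_len(per_day),
                   trial_overall = (d - 1L) * per_day + seq_len(per_day),
                   coherence_pct = coh,
                   stim_dir = sample(c("L", "R"), per_day, replace = TRUE))
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Default population configuration for ground-truth sampling
#'
#' Population means and SDs of the subject-level parameters used by
#' [sample_ground_truth()].  Drift-rate endpoints default to the group-level
#' point estimates of the best-fitting analysis (DR start 0.44, asymptote
#' 0.96 at the median coherence, time-to-half 1261 trials on the 2800-trial
#' reference design; between-subject asymptote SD 0.175 matching the
#' reported spread of DR change).  Time-to-half constants are rescaled in
#' proportion to the design length so that reduced designs express the same
#' relative dynamics.  Boundary values are on the log scale; NDT is
#' log-normal around 0.3 s.
#'
#' @param n_days,trials_per_day design dimensions (drive the rescaling of
#'   the time-to-half constants and per-day boundary endpoints)
#' @return a list of population parameters (class `population_config`)
#' @export
default_population <- function(n_days = 4L, trials_per_day = 700L) {
  total <- n_days * trials_per_day
  structure(list(
    dr_int = list(start = c(mean = 0.44, sd = 0.15),
                  asym = c(mean = 0.96, sd = 0.175),
                  t50 = 1261 * total / 2800),
    dr_slope = list(start = c(mean = 0.02, sd = 0.006),
                    asym = c(mean = 0.05, sd = 0.012)),
    # log-boundary endpoints per day: mild within-day decreases, a clear
    # day-1 -> day-2 drop, then roughly stable
    rb = list(starts = c(mean = log(1.9), rep(log(1.6), n_days - 1L)),
              asyms = c(mean = log(1.5), rep(log(1.4), n_days - 1L)),
              sd = 0.12,
              t50 = 175 * trials_per_day / 700),
    bias_logit = c(mean = 0, sd = 0.25),
    ndt = c(meanlog = log(0.30), sdlog = 0.12),
    contaminant_rate = 0.005,
    n_days = as.integer(n_days),
    trials_per_day = as.integer(trials_per_day)
  ), class = "population_config")
}

# trajectory endpoints for a target form, from the population's continuous
# (DR) or per-day (RB) description
.truth_traj <- function(form, starts, asyms, t50, n_days, trials_per_day,
                        cumulative) {
  rate <- rate_for_half_time(max(t50, 2.5))
  if (form == "constant") {
    return(trajectory_spec("constant", mean(c(starts, asyms)),
                           n_days = n_days))
  }
  if (form == "flexible") {
    if (length(starts) == n_days) {
      return(trajectory_spec("flexible", starts, asyms, rate, n_days))
    }
    # continuous population law evaluated at each day's first/last trial
    first <- (seq_len(n_days) - 1L) * trials_per_day + 1L
    last <- seq_len(n_days) * trials_per_day
    return(trajectory_spec("flexible",
                           curve_value(first, starts, asyms, rate),
                           curve_value(last, starts, asyms, rate),
                           rate_for_half_time(max(t50 / n_days, 2.5)),
                           n_days))
  }
  # scalar forms
  s <- if (length(starts) > 1L) starts[1L] else starts
  a <- if (length(asyms) > 1L) asyms[length(asyms)] else asyms
  if (form == "day_resetting" && cumulative) {
    rate <- rate_for_half_time(max(t50 / n_days, 2.5))
  }
  trajectory_spec(form, s, a, rate, n_days)
}

#' Draw subject-level ground truth from a population
#'
#' Samples per-subject parameters from the population laws in a
#' [default_population()]-style configuration, shaped to the trajectory
#' forms of the target model (e.g. model D: continuous DR, flexible RB).
#' Normal laws on drift endpoints, log-scale boundary endpoints and logit
#' bias; log-normal NDT.  Positivity of `exp(logRB)` and `t0` holds by
#' construction.
#'
#' @param pop a population configuration, see [default_population()]
#' @param n_subjects number of subjects to draw
#' @param model a [model_spec()]; its forms decide the trajectory shapes
#' @param seed integer seed
#' @return an object of class `ground_truth`: a list with `subjects` (list
#'   of [subject_params()]), `contaminant_rate`, `model`
#' @export
sample_ground_truth <- function(pop = default_population(), n_subjects,
                                model = model_spec("D"), seed = NULL) {
  stopifnot(inherits(model, "model_spec"))
  if (pop$contaminant_rate < 0 || pop$contaminant_rate > 0.05) {
    stop("'contaminant_rate' must lie in [0, 0.05]", call. = FALSE)
  }
  nd <- model$n_days
  tpd <- model$trials_per_day
  .with_seed(seed, {
    subjects <- lapply(seq_len(n_subjects), function(s) {
      dr_s <- rnorm(1, pop$dr_int$start[["mean"]], pop$dr_int$start[["sd"]])
      dr_a <- rnorm(1, pop$dr_int$asym[["mean"]], pop$dr_int$asym[["sd"]])
      sl_s <- rnorm(1, pop$dr_slope$start[["mean"]],
                    pop$dr_slope$start[["sd"]])
      sl_a <- rnorm(1, pop$dr_slope$asym[["mean"]],
                    pop$dr_slope$asym[["sd"]])
      rb_s <- pop$rb$starts + rnorm(nd, 0, pop$rb$sd)
      rb_a <- pop$rb$asyms + rnorm(nd, 0, pop$rb$sd)
      subject_params(
        dr_int = .truth_traj(model$dr_form, dr_s, dr_a, pop$dr_int$t50,
                             nd, tpd, cumulative = TRUE),
        dr_slope = .truth_traj(model$dr_form, sl_s, sl_a, pop$dr_int$t50,
                               nd, tpd, cumulative = TRUE),
        rb = .truth_traj(model$rb_form, rb_s, rb_a, pop$rb$t50,
                         nd, tpd, cumulative = FALSE),
        bias_logit = rnorm(1, pop$bias_logit[["mean"]],
                           pop$bias_logit[["sd"]]),
        ndt_offset = rlnorm(1, pop$ndt[["meanlog"]], pop$ndt[["sdlog"]]))
    })
    structure(list(subjects = subjects,
                   contaminant_rate = pop$contaminant_rate,
                   model = model),
              class = "ground_truth")
  })
}

# exact per-trial sampling by inversion of the defective first-passage CDF
# on per-trial sqrt-spaced grids (one call handles heterogeneous parameters)
.sample_fpt_grid <- function(v, a, z, t0, grid_size = 256L) {
  n <- length(v)
  pu <- .p_upper(v * a, z)
  upper <- runif(n) < pu
  vv <- ifelse(upper, -v, v)
  ww <- ifelse(upper, 1 - z, z)
  tmax <- .t_upper_bound(v, a)
  s2 <- seq(0, 1, length.out = grid_size)^2
  tg <- outer(s2, tmax)                             # grid_size x n
  D <- matrix(exp(wfpt_logdens_cpp(as.vector(tg),
                                   rep(vv, each = grid_size),
                                   rep(a, each = grid_size),
                                   rep(ww, each = grid_size))),
              nrow = grid_size)
  mids <- (D[-1, , drop = FALSE] + D[-grid_size, , drop = FALSE]) / 2 *
    (tg[-1, , drop = FALSE] - tg[-grid_size, , drop = FALSE])
  cs <- apply(mids, 2, cumsum)
  u <- runif(n)
  rt <- vapply(seq_len(n), function(i) {
    cdf <- c(0, cs[, i]) / cs[grid_size - 1L, i]
    monotone_inv_interp(cdf, tg[, i], u[i])
  }, numeric(1))
  data.frame(rt = t0 + rt, upper = upper)
}

#' Simulate trial-level data from ground truth
#'
#' Draws each trial's choice and RT from the Wiener first-passage
#' distribution at that trial's [per_trial_params()] (exact inverse-CDF
#' sampling by default; Euler-Maruyama with `dt = 1e-3` as an independent
#' fallback).  Accuracy coding: the upper boundary is the correct response.
#' A small fraction of contaminant trials draw RT uniformly on (0.05, 3.0) s
#' with a random response, exercising the RT exclusion filter downstream.
#'
#' @param design a design table from [generate_design()]
#' @param truth a [sample_ground_truth()] result (its `subjects` must cover
#'   the design's subject ids)
#' @param model a [model_spec()]; defaults to the truth's
#' @param seed integer seed
#' @param method `"inverse_cdf"` (default) or `"euler"`
#' @return a trial-record data.frame: `subject`, `group`, `day`,
#'   `trial_in_day`, `trial_overall`, `coherence_pct`, `stim_dir`,
#'   `resp_dir`, `correct`, `rt_s`
#' @export
simulate_trials <- function(design, truth, model = truth$model, seed = NULL,
                            method = c("inverse_cdf", "euler")) {
  method <- match.arg(method)
  stopifnot(inherits(truth, "ground_truth"), inherits(model, "model_spec"))
  .with_seed(seed, {
    res <- lapply(split(design, design$subject), function(dsub) {
      s <- dsub$subject[1L]
      pars <- per_trial_params(model, truth$subjects[[s]], dsub)
      if (method == "inverse_cdf") {
        draw <- .sample_fpt_grid(pars$v, pars$a, pars$z, pars$t0)
      } else {
        draw <- do.call(rbind, lapply(seq_len(nrow(pars)), function(i) {
          rwiener_fpt(1, list(v = pars$v[i], a = pars$a[i], z = pars$z[i],
                              t0 = pars$t0[i]), method = "euler")
        }))
      }
      contam <- runif(nrow(dsub)) < truth$contaminant_rate
      if (any(contam)) {
        draw$rt[contam] <- runif(sum(contam), 0.05, 3.0)
        draw$upper[contam] <- runif(sum(contam)) < 0.5
      }
      data.frame(subject = s,
                 group = if (s %% 2 == 0) "AVGP" else "NVGP",
                 day = dsub$day, trial_in_day = dsub$trial_in_day,
                 trial_overall = dsub$trial_overall,
                 coherence_pct = dsub$coherence_pct,
                 stim_dir = dsub$stim_dir,
                 resp_dir = ifelse(draw$upper, dsub$stim_dir,
                                   ifelse(dsub$stim_dir == "L", "R", "L")),
                 correct = draw$upper,
                 rt_s = draw$rt)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Read and write the trial-record CSV dialect
#'
#' Plain UTF-8 CSV with a header row, `.` decimal separator, and exactly the
#' trial-record columns produced by [simulate_trials()].
#'
#' @param trials a trial-record data.frame
#' @param path file path
#' @return `read_trials()` returns the trial-record data.frame
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "day", "trial_in_day", "trial_overall",
            "coherence_pct", "stim_dir", "resp_dir", "correct", "rt_s")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$correct <- as.logical(tab$correct)
  tab
}
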