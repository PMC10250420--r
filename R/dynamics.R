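#' Exponential learning curve value at a trial
#'
#' The by-trial learning function used for every time-varying parameter:
#' \deqn{param = asymptote + (start - asymptote) \cdot
#'       2^{(1 - trial) / (2 + 2^{rate})}}
#' `rate` is the binary log of a time-to-50\%-of-change constant; the added
#' constant 2 prevents trajectories from reaching 50\% of change in fewer
#' than 2 trials.  At `trial = 1` the value is exactly `start`; as
#' `trial -> Inf` it approaches `asymptote`; at
#' `trial = 1 + (2 + 2^rate)` it is the midpoint.
#'
#' @param trial_number 1-based trial index (vectorized, `>= 1`)
#' @param start,asymptote curve endpoints, on the parameter's link scale
#' @param rate log2 of (time to 50\% of change minus 2), unitless
#' @return parameter value(s) on the link scale
#' @examples
#' curve_value(1, 0.44, 0.96, 5)            # = start
#' curve_value(3 + 2^5, 0.44, 0.96, 5)      # = midpoint 0.70
#' @export
curve_value <- function(trial_number, start, asymptote, rate) {
  if (any(trial_number < 1)) {
    stop("'trial_number' must be >= 1", call. = FALSE)
  }
  asymptote + (start - asymptote) * 2^((1 - trial_number) / (2 + 2^rate))
}

#' Time to 50% of change implied by a rate parameter
#'
#' Returns `2 + 2^rate` trials; always greater than 2.  The inverse map is
#' [rate_for_half_time()].
#'
#' @param rate rate parameter (finite; vectorized)
#' @return trials to half of the start-to-asymptote change
#' @examples
#' time_to_half(0)               # 3 trials
#' rate_for_half_time(1261)      # rate giving T50 = 1261 trials
#' @export
time_to_half <- function(rate) {
  stopifnot(all(is.finite(rate)))
  2 + 2^rate
}

#' @rdname time_to_half
#' @param t50 time to half of change, trials (`> 2`)
#' @export
rate_for_half_time <- function(t50) {
  if (any(t50 <= 2)) stop("'t50' must exceed 2 trials", call. = FALSE)
  log2(t50 - 2)
}

#' Learning-trajectory specification
#'
#' One of the four candidate dynamics of a DDM parameter over training:
#' \describe{
#'   \item{constant}{no change; `starts == asymptotes`, rate unused.}
#'   \item{continuous}{one exponential curve of cumulative trial number.}
#'   \item{day_resetting}{one exponential curve of within-day trial number,
#'     identical every day (reset to baseline between days).}
#'   \item{flexible}{within-day curves with day-specific starts and
#'     asymptotes and a single shared rate.}
#' }
#'
#' @param form one of `"constant"`, `"continuous"`, `"day_resetting"`,
#'   `"flexible"`
#' @param starts scalar (or length-`n_days` vector for `flexible`) start
#'   value(s), link scale
#' @param asymptotes as `starts`, the asymptotic value(s)
#' @param rate shared rate parameter (ignored for `constant`)
#' @param n_days number of training days the spec applies to
#' @return an object of class `trajectory_spec`
#' @export
trajectory_spec <- function(form = c("constant", "continuous",
                                     "day_resetting", "flexible"),
                            starts, asymptotes = starts, rate = 0,
                            n_days = 4L) {
  form <- match.arg(form)
  if (form == "flexible") {
    if (length(starts) != n_days || length(asymptotes) != n_days) {
      stop("flexible trajectories need per-day starts/asymptotes of length n_days",
           call. = FALSE)
    }
  } else {
    if (length(starts) != 1L || length(asymptotes) != 1L) {
      stop(sprintf("'%s' trajectories take scalar start/asymptote", form),
           call. = FALSE)
    }
    if (form == "constant" && !isTRUE(all.equal(starts, asymptotes))) {
      stop("constant trajectories require start == asymptote", call. = FALSE)
    }
  }
  structure(list(form = form, starts = starts, asymptotes = asymptotes,
                 rate = rate, n_days = as.integer(n_days),
                 timescale = switch(form,
                                    continuous = "cumulative_trial",
                                    constant = "none",
                                    "within_day_trial")),
            class = "trajectory_spec")
}

#' Evaluate a trajectory at given trials
#'
#' Expands a [trajectory_spec()] into per-trial parameter values on the link
#' scale.  `constant` returns the same value everywhere; `continuous`
#' follows the curve in cumulative trial number; `day_resetting` follows it
#' in within-day trial number with shared endpoints; `flexible` uses
#' day-specific endpoints and the shared rate.
#'
#' @param spec a [trajectory_spec()]
#' @param day_index day of each trial (1-based; vectorized)
#' @param within_day_trial within-day trial number (1-based)
#' @param cumulative_trial cumulative trial number across days (1-based)
#' @return numeric vector of link-scale parameter values
#' @export
trajectory <- function(spec, day_index, within_day_trial, cumulative_trial) {
  stopifnot(inherits(spec, "trajectory_spec"))
  switch(spec$form,
    constant = rep_len(spec$starts, length(day_index)),
    continuous = curve_value(cumulative_trial, spec$starts, spec$asymptotes,
                             spec$rate),
    day_resetting = curve_value(within_day_trial, spec$starts,
                                spec$asymptotes, spec$rate),
    flexible = {
      if (any(day_index < 1 | day_index > spec$n_days)) {
        stop("day_index outside the trajectory's n_days", call. = FALSE)
      }
      curve_value(within_day_trial, spec$starts[day_index],
                  spec$asymptotes[day_index], spec$rate)
    })
}
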