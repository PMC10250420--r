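#' Per-subject parameter estimates as a table
#'
#' @param fit a `fit_result`
#' @return data.frame: one row per subject, one column per (transformed)
#'   parameter
#' @export
fit_estimates <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  th <- do.call(rbind, lapply(fit$estimates, function(e) e$theta))
  out <- data.frame(subject = names(fit$estimates), th, row.names = NULL,
                    check.names = FALSE)
  out
}

# partition trials (in table order, per subject) into blocks of `block`
# trials; any remainder joins the last block so the partition is exact and
# the block count is floor(n / block)
.block_index <- function(n, block) {
  as.integer(pmin(ceiling(seq_len(n) / block), max(1L, floor(n / block))))
}

#' Absolute model fit on trial blocks
#'
#' Assesses recovery of the raw data: trials are binned per subject into
#' consecutive `block`-trial blocks (112 per participant under the
#' reference 2800-trial design), observed accuracy and mean RT are averaged
#' within each block for each coherence level, model predictions (choice
#' probability and expected decision time + t0 at the fitted per-trial
#' parameters) are binned identically, and the two zero-order
#' product-moment correlations are returned, pooled across subjects.
#'
#' @param trials the filtered trial table the fit was computed on
#' @param fit a `fit_result` for a DDM model
#' @param block block length in trials (default 25)
#' @return a list: `r_accuracy`, `r_rt`, `blocks` (the block-level summary
#'   table)
#' @export
absolute_fit <- function(trials, fit, block = 25L) {
  stopifnot(inherits(fit, "fit_result"))
  rows <- lapply(split(seq_len(nrow(trials)), trials$subject), function(idx) {
    if (length(idx) < 2 * block) {
      stop("need at least 2 blocks per subject", call. = FALSE)
    }
    sub <- trials[idx, , drop = FALSE]
    subj <- fit$estimates[[as.character(sub$subject[1L])]]$subject
    p <- per_trial_params(fit$model, subj, sub)
    wp <- list(v = p$v, a = p$a, z = p$z, t0 = p$t0)
    pred_acc <- choice_probability(wp)
    pred_rt <- mean_decision_time(wp) + p$t0
    bl <- .block_index(nrow(sub), block)
    agg <- aggregate(cbind(obs_acc = sub$correct, obs_rt = sub$rt_s,
                           pred_acc = pred_acc, pred_rt = pred_rt),
                     by = list(block = bl, coherence_pct = sub$coherence_pct),
                     FUN = mean)
    agg$subject <- sub$subject[1L]
    agg
  })
  blocks <- do.call(rbind, rows)
  rownames(blocks) <- NULL
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      warning("constant values in one side of the correlation; returning NA")
      return(NA_real_)
    }
    cor(x, y)
  }
  list(r_accuracy = safe_cor(blocks$obs_acc, blocks$pred_acc),
       r_rt = safe_cor(blocks$obs_rt, blocks$pred_rt),
       blocks = blocks)
}

#' Day-1 vs last-day change per coherence level
#'
#' Descriptive learning check: per coherence level, each participant's mean
#' RT and accuracy are aggregated for the first and the last day, and the
#' across-participant paired two-sided t test and Wilcoxon signed-rank test
#' are reported.  Change is last day minus day 1 (negative RT change =
#' faster responses).
#'
#' @param trials a trial-record data.frame spanning at least 2 days
#' @return data.frame: one row per coherence level with mean changes and
#'   both tests' p values
#' @export
coherence_level_change <- function(trials) {
  days <- sort(unique(trials$day))
  if (length(days) < 2) stop("need at least 2 days", call. = FALSE)
  d1 <- days[1L]
  dL <- days[length(days)]
  out <- lapply(sort(unique(trials$coherence_pct)), function(coh) {
    sub <- trials[trials$coherence_pct == coh & trials$day %in% c(d1, dL), ]
    m <- aggregate(cbind(rt = sub$rt_s, acc = sub$correct),
                   by = list(subject = sub$subject, day = sub$day),
                   FUN = mean)
    w <- merge(m[m$day == d1, ], m[m$day == dL, ], by = "subject",
               suffixes = c("_d1", "_dL"))
    if (nrow(w) < 2) {
      message("coherence level ", coh,
              " lacks paired data on both days; skipped")
      return(NULL)
    }
    safe_p <- function(test) tryCatch(test$p.value, error = function(e) NA)
    rt_t <- safe_p(t.test(w$rt_dL, w$rt_d1, paired = TRUE))
    rt_w <- safe_p(suppressWarnings(wilcox.test(w$rt_dL, w$rt_d1,
                                                paired = TRUE)))
    ac_t <- safe_p(t.test(w$acc_dL, w$acc_d1, paired = TRUE))
    ac_w <- safe_p(suppressWarnings(wilcox.test(w$acc_dL, w$acc_d1,
                                                paired = TRUE)))
    data.frame(coherence_pct = coh, n_subjects = nrow(w),
               rt_change = mean(w$rt_dL - w$rt_d1),
               rt_p_t = rt_t, rt_p_wilcox = rt_w,
               acc_change = mean(w$acc_dL - w$acc_d1),
               acc_p_t = ac_t, acc_p_wilcox = ac_w)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Default pipeline configuration
#'
#' @param n_subjects,n_days,trials_per_day,per_level design dimensions
#' @param models model ids to fit (subset of A-F)
#' @param backend `"mle"` or `"bayes"`
#' @param truth_model model id generating the synthetic data
#' @param seed master seed (all stage seeds derive from it)
#' @param out_dir artifacts directory
#' @return a named list (class `pipeline_config`)
#' @export
pipeline_config <- function(n_subjects = 4L, n_days = 4L,
                            trials_per_day = 140L, per_level = 20L,
                            models = c("A", "D"), backend = "mle",
                            truth_model = "D", seed = 1L,
                            out_dir = tempfile("ddmlearn_run_")) {
  structure(list(n_subjects = n_subjects, n_days = n_days,
                 trials_per_day = trials_per_day, per_level = per_level,
                 models = models, backend = backend,
                 truth_model = truth_model, seed = seed,
                 out_dir = out_dir), class = "pipeline_config")
}

#' Run the simulate - exclude - fit - compare pipeline
#'
#' Executes the full analysis on synthetic data: generate the design,
#' sample ground truth, simulate trials, apply the RT exclusion filter, fit
#' the requested models, compare them, assess absolute fit of the winner,
#' and write all artifacts (CSV tables and a plain-text report) to the
#' configured directory.  Byte-identical outputs for the same
#' configuration and seed.
#'
#' @param config a [pipeline_config()]
#' @param quiet suppress progress messages
#' @return (invisibly) a list with the in-memory artifacts: `trials`,
#'   `exclusion`, `fits`, `comparison`, `absolute`, `out_dir`
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say("[simulate] %d subjects x %d days x %d trials",
      config$n_subjects, config$n_days, config$trials_per_day)
  truth_spec <- model_spec(config$truth_model, n_days = config$n_days,
                           trials_per_day = config$trials_per_day)
  trials <- stage("simulate", {
    design <- generate_design(config$n_subjects, config$n_days,
                              config$trials_per_day,
                              per_level = config$per_level,
                              seed = config$seed)
    truth <- sample_ground_truth(
      default_population(config$n_days, config$trials_per_day),
      config$n_subjects, truth_spec, seed = config$seed + 1L)
    simulate_trials(design, truth, seed = config$seed + 2L)
  })
  write_trials(trials, file.path(config$out_dir, "trials.csv"))
  excl <- stage("exclude", exclude_trials(trials))
  write.csv(excl$report, file.path(config$out_dir, "exclusion_report.csv"),
            row.names = FALSE)
  say("[exclude] retained %d / %d trials", nrow(excl$trials), nrow(trials))
  fits <- lapply(config$models, function(id) {
    say("[fit] model %s (%s)", id, config$backend)
    spec <- model_spec(id, n_days = config$n_days,
                       trials_per_day = config$trials_per_day)
    stage(paste0("fit_", id), {
      if (config$backend == "bayes") {
        fit_bayes(spec, excl$trials, seed = config$seed + 10L)
      } else {
        fit_mle(spec, excl$trials, n_restarts = 3L,
                seed = config$seed + 10L)
      }
    })
  })
  names(fits) <- config$models
  for (id in config$models) {
    write.csv(fit_estimates(fits[[id]]),
              file.path(config$out_dir, sprintf("estimates_%s.csv", id)),
              row.names = FALSE)
    write.csv(data.frame(loglik = fits[[id]]$pointwise[, 1]),
              file.path(config$out_dir, sprintf("pointwise_%s.csv", id)),
              row.names = FALSE)
  }
  comparison <- stage("compare", compare(fits))
  write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
            row.names = FALSE)
  best_id <- comparison$model[1L]
  absolute <- stage("report", absolute_fit(excl$trials, fits[[best_id]]))
  rep_path <- file.path(config$out_dir, "report.txt")
  lines <- c(
    sprintf("ddmlearn pipeline report (seed %d)", config$seed),
    sprintf("design: %d subjects x %d days x %d trials; truth model %s",
            config$n_subjects, config$n_days, config$trials_per_day,
            config$truth_model),
    sprintf("retained trials: %d / %d", nrow(excl$trials), nrow(trials)),
    "",
    "model comparison:",
    utils::capture.output(print(as.data.frame(comparison))),
    "",
    sprintf("best model %s absolute fit: r_accuracy = %.3f, r_rt = %.3f",
            best_id, absolute$r_accuracy, absolute$r_rt))
  writeLines(lines, rep_path)
  say("[done] artifacts in %s", config$out_dir)
  invisible(list(trials = trials, exclusion = excl, fits = fits,
                 comparison = comparison, absolute = absolute,
                 out_dir = config$out_dir))
}
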