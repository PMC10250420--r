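test_that("the RT exclusion rule retains boundary values", {
  tab <- data.frame(subject = 1,
                    rt_s = c(0.10, 0.16, 0.50, 2.50, 2.60))
  res <- exclude_trials(tab)
  expect_identical(nrow(res$trials), 3L)
  expect_equal(res$trials$rt_s, c(0.16, 0.50, 2.50))
  expect_identical(res$report$n_low, 1L)
  expect_identical(res$report$n_high, 1L)
  # all-in-range input is untouched
  ok <- data.frame(subject = 1, rt_s = c(0.3, 1.2))
  expect_identical(exclude_trials(ok)$trials, ok)
  # a subject losing every trial is flagged
  bad <- data.frame(subject = c(1, 2), rt_s = c(0.5, 3.0))
  expect_warning(exclude_trials(bad), "subject")
})

test_that("exclusion keep-rate matches the analytic contaminant mixture", {
  spec <- model_spec("A", n_days = 1, trials_per_day = 700)
  p <- wiener_params(0.8, 1.5, 0.5, 0.301)
  truth <- structure(list(
    subjects = list(subject_params(
      dr_int = trajectory_spec("constant", p$v),
      dr_slope = trajectory_spec("constant", 0),
      rb = trajectory_spec("constant", log(p$a)),
      bias_logit = 0, ndt_offset = 0.3)),
    contaminant_rate = 0.005, model = spec), class = "ground_truth")
  d <- do.call(rbind, replicate(15, generate_design(1, 1, 700,
                                                    per_level = 100,
                                                    seed = NULL),
                                simplify = FALSE))
  d$trial_in_day <- seq_len(nrow(d))
  d$trial_overall <- seq_len(nrow(d))
  set.seed(61)
  tab <- simulate_trials(d, truth)
  keep_wiener <- (pwiener(2.5, "upper", p) + pwiener(2.5, "lower", p)) -
    (pwiener(0.16, "upper", p) + pwiener(0.16, "lower", p))
  keep_expected <- 0.995 * keep_wiener + 0.005 * (2.5 - 0.16) / (3.0 - 0.05)
  kept <- nrow(exclude_trials(tab)$trials)
  ci <- stats::binom.test(kept, nrow(tab))$conf.int
  expect_true(keep_expected >= ci[1] && keep_expected <= ci[2])
})

test_that("negative log-likelihood reduces to the density kernel", {
  dat <- sim_dataset("A", n_subjects = 1, n_days = 2, trials_per_day = 98,
                     seed = 71, contaminant_rate = 0)
  subj <- dat$truth$subjects[[1]]
  one <- dat$trials[5, , drop = FALSE]
  n1 <- negative_log_likelihood(dat$spec, subj, one)
  expect_identical(length(n1$pointwise), 1L)
  p <- per_trial_params(dat$spec, subj, one)
  ld <- dwiener(one$rt_s, if (one$correct) "upper" else "lower",
                wiener_params(p$v, p$a, p$z, p$t0))
  expect_equal(n1$total, -ld)
  # additivity over concatenated tables
  h1 <- dat$trials[1:50, ]
  h2 <- dat$trials[51:100, ]
  expect_equal(negative_log_likelihood(dat$spec, subj, rbind(h1, h2))$total,
               negative_log_likelihood(dat$spec, subj, h1)$total +
                 negative_log_likelihood(dat$spec, subj, h2)$total)
  # independent oracle: direct sum of wiener_core calls over 100 trials
  tab <- dat$trials[1:100, ]
  oracle <- 0
  for (i in seq_len(nrow(tab))) {
    pi <- per_trial_params(dat$spec, subj, tab[i, , drop = FALSE])
    oracle <- oracle - dwiener(tab$rt_s[i],
                               if (tab$correct[i]) "upper" else "lower",
                               wiener_params(pi$v, pi$a, pi$z, pi$t0))
  }
  expect_equal(negative_log_likelihood(dat$spec, subj, tab)$total, oracle)
  # any impossible trial makes the objective infinite, flagged
  tab2 <- tab
  tab2$rt_s[1] <- 0.01
  n2 <- negative_log_likelihood(dat$spec, subj, tab2)
  expect_identical(n2$total, Inf)
  expect_identical(attr(n2, "n_invalid"), 1L)
})

test_that("objective is invariant to row order", {
  dat <- sim_dataset("A", n_subjects = 2, n_days = 2, trials_per_day = 98,
                     seed = 73, contaminant_rate = 0)
  subjs <- dat$truth$subjects
  fwd <- negative_log_likelihood(dat$spec, subjs, dat$trials)
  perm <- sample(nrow(dat$trials))
  rev <- negative_log_likelihood(dat$spec, subjs, dat$trials[perm, ])
  expect_equal(fwd$total, rev$total)
  expect_equal(fwd$pointwise[perm], rev$pointwise)
})

test_that("MLE is optimal, deterministic, and recovers constant params", {
  dat <- sim_dataset("A", n_subjects = 1, n_days = 2, trials_per_day = 1001,
                     seed = 75, contaminant_rate = 0)
  ex <- exclude_trials(dat$trials)$trials
  fit <- fit_mle(dat$spec, ex, n_restarts = 3, seed = 5)
  # log-likelihood at the MLE is at least that at the generating truth
  ll_truth <- -negative_log_likelihood(dat$spec, dat$truth$subjects[[1]],
                                       ex)$total
  expect_gte(fit$total_loglik, ll_truth)
  # pointwise column sums to the total
  expect_equal(sum(fit$pointwise[, 1]), fit$total_loglik, tolerance = 1e-6)
  # bit-for-bit determinism under the same seed
  fit2 <- fit_mle(dat$spec, ex, n_restarts = 3, seed = 5)
  expect_identical(fit$estimates[["1"]]$theta, fit2$estimates[["1"]]$theta)
  # recovery of v (at the median coherence), a, t0 within 10%
  truth <- dat$truth$subjects[[1]]
  th <- fit$estimates[["1"]]$theta
  expect_lt(abs(th[["dr_int"]] - truth$dr_int$starts) /
              abs(truth$dr_int$starts), 0.10)
  expect_lt(abs(exp(th[["rb"]]) - exp(truth$rb$starts)) /
              exp(truth$rb$starts), 0.10)
  t0_est <- fit$estimates[["1"]]$subject$ndt_offset + 0.001
  t0_true <- truth$ndt_offset + 0.001
  expect_lt(abs(t0_est - t0_true) / t0_true, 0.10)
})

test_that("few-trial subjects trigger a warning", {
  dat <- sim_dataset("A", n_subjects = 1, n_days = 1, trials_per_day = 42,
                     seed = 77, contaminant_rate = 0)
  expect_warning(fit_mle(dat$spec, dat$trials, n_restarts = 1, seed = 1),
                 "fewer than 50")
})

test_that("fitted flexible model never loses to the constant model", {
  dat <- sim_dataset("D", n_subjects = 1, n_days = 2, trials_per_day = 196,
                     seed = 79, contaminant_rate = 0)
  ex <- exclude_trials(dat$trials)$trials
  specA <- model_spec("A", n_days = 2, trials_per_day = 196)
  specF <- model_spec("F", n_days = 2, trials_per_day = 196)
  fA <- fit_mle(specA, ex, n_restarts = 2, seed = 3)
  fF <- fit_mle(specF, ex, n_restarts = 2, seed = 3)
  expect_gte(fF$total_loglik, fA$total_loglik - 1e-6)
})

test_that("Bayesian backend agrees with the MLE and reports diagnostics", {
  dat <- sim_dataset("A", n_subjects = 1, n_days = 2, trials_per_day = 203,
                     seed = 81, contaminant_rate = 0)
  ex <- exclude_trials(dat$trials)$trials
  fb <- fit_bayes(dat$spec, ex, draws = 600, warmup = 1200, chains = 2,
                  thin = 2, seed = 9)
  fm <- fit_mle(dat$spec, ex, n_restarts = 2, seed = 9)
  # with hundreds of trials the posterior mean tracks the MLE
  expect_lt(abs(fb$estimates[["1"]]$theta[["dr_int"]] -
                  fm$estimates[["1"]]$theta[["dr_int"]]), 0.15)
  expect_identical(nrow(fb$pointwise), nrow(ex))
  expect_identical(ncol(fb$pointwise), 600L * 2L)   # draws x chains
  expect_true(all(c("rhat_max", "ess_min") %in% names(fb$diagnostics)))
})

test_that("prior-only sampling reproduces the bias prior quantiles", {
  spec <- model_spec("A", n_days = 2, trials_per_day = 98)
  empty <- data.frame(subject = integer(0), day = integer(0),
                      trial_in_day = integer(0), trial_overall = integer(0),
                      coherence_pct = numeric(0), correct = logical(0),
                      rt_s = numeric(0))
  fp <- suppressWarnings(fit_bayes(spec, empty, draws = 2000,
                                   warmup = 2000, chains = 2, thin = 2,
                                   seed = 11))
  z <- plogis(fp$draws[, grep("bias_logit", colnames(fp$draws))])
  theo <- plogis(qnorm(c(0.25, 0.5, 0.75)))
  expect_lt(max(abs(quantile(z, c(0.25, 0.5, 0.75)) - theo)), 0.05)
  expect_identical(nrow(fp$pointwise), 0L)
})
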