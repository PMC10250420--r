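test_that("parameter counts enumerate the stated parameterization", {
  expect_identical(parameter_count(model_spec("A"), 1), 5L)
  expect_identical(parameter_count(model_spec("B"), 1), 10L)
  expect_identical(parameter_count(model_spec("C"), 1), 10L)
  expect_identical(parameter_count(model_spec("D"), 1), 16L)
  expect_identical(parameter_count(model_spec("E"), 1), 22L)
  expect_identical(parameter_count(model_spec("F"), 1), 28L)
  # nesting order of complexity for any n_days >= 2
  for (nd in 2:5) {
    kC <- parameter_count(model_spec("C", n_days = nd), 3, nd)
    kD <- parameter_count(model_spec("D", n_days = nd), 3, nd)
    kF <- parameter_count(model_spec("F", n_days = nd), 3, nd)
    expect_true(kF >= kD && kD >= kC)
    # model B has no per-day parameters
    expect_identical(parameter_count(model_spec("B", n_days = nd), 1, nd),
                     10L)
  }
})

test_that("per-trial parameters follow the links and covariates", {
  spec <- model_spec("D", n_days = 2, trials_per_day = 14)
  rb <- trajectory_spec("flexible", log(c(1.8, 1.6)), log(c(1.5, 1.4)),
                        rate_for_half_time(5), n_days = 2)
  subj <- subject_params(
    dr_int = trajectory_spec("continuous", 0.4, 1.0,
                             rate_for_half_time(10), n_days = 2),
    dr_slope = trajectory_spec("continuous", 0.02, 0.05,
                               rate_for_half_time(10), n_days = 2),
    rb = rb, bias_logit = 0.2, ndt_offset = 0.25)
  trials <- data.frame(day = c(1L, 1L, 2L), trial_in_day = c(1L, 5L, 1L),
                       trial_overall = c(1L, 5L, 15L),
                       coherence_pct = c(6.4, 51.2, 6.4))
  p <- per_trial_params(spec, subj, trials)
  # at the design median the slope does not contribute
  expect_equal(p$v[1], 0.4)
  # boundary at within-day trial 1 of day d is exp(start_d)
  expect_equal(p$a[1], 1.8)
  expect_equal(p$a[3], 1.6)
  expect_equal(p$z, rep(plogis(0.2), 3))
  expect_equal(p$t0, rep(0.251, 3))
  # slope contribution at 51.2%
  slope5 <- curve_value(5, 0.02, 0.05, rate_for_half_time(10))
  expect_equal(p$v[2], curve_value(5, 0.4, 1.0, rate_for_half_time(10)) +
                 slope5 * (51.2 - 6.4))
})

test_that("model A parameters are constant across all trials", {
  spec <- model_spec("A", n_days = 4, trials_per_day = 700)
  subj <- subject_params(
    dr_int = trajectory_spec("constant", 0.7),
    dr_slope = trajectory_spec("constant", 0.03),
    rb = trajectory_spec("constant", log(1.5)),
    bias_logit = 0, ndt_offset = 0.3)
  trials <- data.frame(day = rep(1:4, each = 700),
                       trial_in_day = rep(1:700, 4),
                       trial_overall = 1:2800,
                       coherence_pct = rep(6.4, 2800))
  p <- per_trial_params(spec, subj, trials)
  expect_identical(length(unique(p$v)), 1L)
  expect_identical(length(unique(p$a)), 1L)
})

test_that("coherence link switch changes only the covariate", {
  lin <- model_spec("A", coherence_link = "linear")
  lg <- model_spec("A", coherence_link = "log")
  expect_equal(ddmlearn:::coherence_covariate(lin, 6.4), 0)
  expect_equal(ddmlearn:::coherence_covariate(lg, 6.4), 0)
  expect_equal(ddmlearn:::coherence_covariate(lin, 51.2), 44.8)
  expect_equal(ddmlearn:::coherence_covariate(lg, 51.2), log(51.2 / 6.4))
  expect_warning(ddmlearn:::coherence_covariate(lin, 10), "design levels")
})

test_that("nesting: flexible with tied values reproduces simpler models", {
  dat <- sim_dataset("A", n_subjects = 1, n_days = 2, trials_per_day = 98,
                     seed = 31, contaminant_rate = 0)
  specA <- model_spec("A", n_days = 2, trials_per_day = 98)
  specF <- model_spec("F", n_days = 2, trials_per_day = 98)
  subjA <- subject_params(
    dr_int = trajectory_spec("constant", 0.7),
    dr_slope = trajectory_spec("constant", 0.03),
    rb = trajectory_spec("constant", log(1.5)),
    bias_logit = 0.1, ndt_offset = 0.25)
  # model F with start = asymptote everywhere implies model A exactly
  subjF <- subject_params(
    dr_int = trajectory_spec("flexible", c(0.7, 0.7), c(0.7, 0.7), 3,
                             n_days = 2),
    dr_slope = trajectory_spec("flexible", c(0.03, 0.03), c(0.03, 0.03), 3,
                               n_days = 2),
    rb = trajectory_spec("flexible", log(c(1.5, 1.5)), log(c(1.5, 1.5)), 3,
                         n_days = 2),
    bias_logit = 0.1, ndt_offset = 0.25)
  nA <- negative_log_likelihood(specA, subjA, dat$trials)
  nF <- negative_log_likelihood(specF, subjF, dat$trials)
  expect_equal(nA$total, nF$total)
  expect_equal(nA$pointwise, nF$pointwise)
})

test_that("group covariate applies additive shifts", {
  spec <- model_spec("A", group_covariate = TRUE)
  base <- subject_params(
    dr_int = trajectory_spec("constant", 0.7),
    dr_slope = trajectory_spec("constant", 0.03),
    rb = trajectory_spec("constant", log(1.5)),
    bias_logit = 0, ndt_offset = 0.3)
  shifted <- base
  shifted$group_effects <- list(dr = 0.1, rb = -0.2)
  trials <- data.frame(day = 1L, trial_in_day = 1L, trial_overall = 1L,
                       coherence_pct = 6.4)
  p0 <- per_trial_params(spec, base, trials)
  p1 <- per_trial_params(spec, shifted, trials)
  expect_equal(p1$v, p0$v + 0.1)
  expect_equal(p1$a, p0$a * exp(-0.2))
  expect_identical(parameter_count(spec, 2),
                   parameter_count(model_spec("A"), 2) + 4L)
})
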