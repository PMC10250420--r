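test_that("the design balances coherences within day and is seeded", {
  d <- generate_design(2, n_days = 4, trials_per_day = 700,
                       per_level = 100, seed = 9)
  expect_identical(nrow(d), 2L * 4L * 700L)
  counts <- table(d$subject, d$day, d$coherence_pct)
  expect_true(all(counts == 100))
  expect_identical(d$trial_overall,
                   (d$day - 1L) * 700L + d$trial_in_day)
  # same seed, identical design; different seed, different order
  expect_identical(d, generate_design(2, 4, 700, per_level = 100, seed = 9))
  d2 <- generate_design(2, 4, 700, per_level = 100, seed = 10)
  expect_false(identical(d$coherence_pct, d2$coherence_pct))
  expect_error(generate_design(1, 4, 700, per_level = 99, seed = 1),
               "per_level")
})

test_that("simulated non-contaminant RTs exceed the subject's t0", {
  dat <- sim_dataset("A", n_subjects = 2, n_days = 2, trials_per_day = 98,
                     seed = 41, contaminant_rate = 0)
  for (s in 1:2) {
    t0 <- 0.001 + dat$truth$subjects[[s]]$ndt_offset
    expect_true(all(dat$trials$rt_s[dat$trials$subject == s] > t0))
  }
  expect_true(all(dat$trials$correct ==
                    (dat$trials$stim_dir == dat$trials$resp_dir)))
})

test_that("zero drift with central bias yields 50/50 choices", {
  spec <- model_spec("A", n_days = 1, trials_per_day = 700)
  truth <- structure(list(
    subjects = list(subject_params(
      dr_int = trajectory_spec("constant", 0),
      dr_slope = trajectory_spec("constant", 0),
      rb = trajectory_spec("constant", log(1.5)),
      bias_logit = 0, ndt_offset = 0.3)),
    contaminant_rate = 0, model = spec), class = "ground_truth")
  d <- do.call(rbind, replicate(15, generate_design(1, 1, 700,
                                                    per_level = 100,
                                                    seed = NULL),
                                simplify = FALSE))
  d$trial_in_day <- seq_len(nrow(d))
  d$trial_overall <- seq_len(nrow(d))
  set.seed(43)
  tab <- simulate_trials(d, truth)
  ci <- stats::binom.test(sum(tab$correct), nrow(tab))$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("simulator matches the closed-form mean decision time", {
  p <- wiener_params(0.8, 1.4, 0.55, 0.28)
  set.seed(47)
  sim <- rwiener_fpt(50000, p)
  dtime <- sim$rt - p$t0
  se <- sd(dtime) / sqrt(length(dtime))
  expect_lt(abs(mean(dtime) - mean_decision_time(p)), 3 * se)
})

test_that("ground truth sampling respects the population config", {
  spec <- model_spec("D")
  pop <- default_population()
  # zero spread: all subjects identical
  pop0 <- pop
  pop0$dr_int$start[["sd"]] <- 0
  pop0$dr_int$asym[["sd"]] <- 0
  pop0$dr_slope$start[["sd"]] <- 0
  pop0$dr_slope$asym[["sd"]] <- 0
  pop0$rb$sd <- 0
  pop0$bias_logit[["sd"]] <- 0
  pop0$ndt[["sdlog"]] <- 0
  g0 <- sample_ground_truth(pop0, 3, spec, seed = 5)
  expect_identical(g0$subjects[[1]], g0$subjects[[2]])
  expect_identical(g0$subjects[[2]], g0$subjects[[3]])
  # default config: mean DR change within 3 SE of the configured 0.52
  g <- sample_ground_truth(pop, 21, spec, seed = 6)
  change <- vapply(g$subjects, function(s)
    s$dr_int$asymptotes - s$dr_int$starts, numeric(1))
  pop_mean <- pop$dr_int$asym[["mean"]] - pop$dr_int$start[["mean"]]
  pop_se <- sqrt(pop$dr_int$asym[["sd"]]^2 +
                   pop$dr_int$start[["sd"]]^2) / sqrt(21)
  expect_lt(abs(mean(change) - pop_mean), 3 * pop_se)
  # positivity by construction
  for (s in g$subjects) {
    expect_true(all(exp(s$rb$starts) > 0))
    expect_gt(0.001 + s$ndt_offset, 0.001)
  }
  # seeded determinism across the whole generation path
  d <- generate_design(2, 2, 98, per_level = 14, seed = 7)
  t1 <- simulate_trials(d, sample_ground_truth(pop, 2, spec, seed = 8),
                        model = model_spec("D", n_days = 2,
                                           trials_per_day = 98),
                        seed = 9)
  t2 <- simulate_trials(d, sample_ground_truth(pop, 2, spec, seed = 8),
                        model = model_spec("D", n_days = 2,
                                           trials_per_day = 98),
                        seed = 9)
  expect_identical(t1, t2)
})

test_that("trial tables round-trip through the CSV dialect", {
  dat <- sim_dataset("A", n_subjects = 1, n_days = 2, trials_per_day = 14,
                     seed = 51)
  path <- tempfile(fileext = ".csv")
  write_trials(dat$trials, path)
  back <- read_trials(path)
  expect_equal(back$rt_s, dat$trials$rt_s, tolerance = 1e-12)
  expect_identical(back$correct, dat$trials$correct)
  expect_error(read_trials(textConnection("a,b\n1,2")), "lacks columns")
})
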