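# Shared fixtures: all data are generated in code, no files.

# small simulated dataset under a given model id
sim_dataset <- function(model_id = "A", n_subjects = 1L, n_days = 2L,
                        trials_per_day = 98L, seed = 1L,
                        contaminant_rate = NULL) {
  spec <- model_spec(model_id, n_days = n_days,
                     trials_per_day = trials_per_day)
  pop <- default_population(n_days, trials_per_day)
  if (!is.null(contaminant_rate)) pop$contaminant_rate <- contaminant_rate
  design <- generate_design(n_subjects, n_days, trials_per_day,
                            per_level = trials_per_day %/% 7L, seed = seed)
  truth <- sample_ground_truth(pop, n_subjects, spec, seed = seed + 1L)
  trials <- simulate_trials(design, truth, seed = seed + 2L)
  list(spec = spec, design = design, truth = truth, trials = trials)
}

# conjugate normal-mean toy: y_i ~ N(mu, 1), mu ~ N(0, tau^2).
# Returns exact posterior draws, the pointwise log-likelihood matrix, the
# analytic log marginal likelihood, and exact LOO elpd via n refits.
conjugate_toy <- function(n = 20L, mu_true = 0.7, tau = 1, S = 4000L,
                          seed = 7L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  y <- rnorm(n, mu_true, 1)
  post <- function(yy) {
    s2 <- 1 / (length(yy) + 1 / tau^2)
    list(m = s2 * sum(yy), s = sqrt(s2))
  }
  p <- post(y)
  draws <- matrix(rnorm(S, p$m, p$s), ncol = 1)
  ll <- t(vapply(seq_len(S), function(j) dnorm(y, draws[j, 1], 1,
                                               log = TRUE), numeric(n)))
  ll <- t(ll)  # n x S
  # exact LOO: refit on y[-i], predictive density of y[i]
  elpd_exact <- sum(vapply(seq_len(n), function(i) {
    pi <- post(y[-i])
    dnorm(y[i], pi$m, sqrt(1 + pi$s^2), log = TRUE)
  }, numeric(1)))
  Sig <- diag(n) + tau^2 * matrix(1, n, n)
  logml <- -0.5 * (n * log(2 * pi) +
                     as.numeric(determinant(Sig)$modulus) +
                     drop(t(y) %*% solve(Sig) %*% y))
  fit <- list(draws = draws,
              log_post = function(th) sum(dnorm(y, th[1], 1, log = TRUE)) +
                dnorm(th[1], 0, tau, log = TRUE))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(y = y, draws = draws, log_lik = ll, elpd_exact = elpd_exact,
       logml = logml, fit = fit, tau = tau, post = post)
}

# a fit_result shell holding known (e.g. generating) subject parameters,
# for assessment functions that only need model + estimates
truth_fit <- function(spec, truth, trials) {
  est <- lapply(seq_along(truth$subjects), function(s)
    list(subject = truth$subjects[[s]]))
  names(est) <- as.character(seq_along(truth$subjects))
  structure(list(model = spec, model_id = spec$model_id, backend = "truth",
                 estimates = est, n_trials = nrow(trials),
                 trial_key = paste(trials$subject, trials$trial_overall,
                                   sep = ":")),
            class = "fit_result")
}
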