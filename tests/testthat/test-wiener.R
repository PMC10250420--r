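test_that("parameter validation rejects out-of-domain values", {
  expect_error(wiener_params(1, -1, 0.5, 0.3), "boundary")
  expect_error(wiener_params(1, 1.5, 1.2, 0.3), "bias")
  expect_error(wiener_params(1, 1.5, 0.5, -0.1), "non-decision")
  expect_error(wiener_params(Inf, 1.5, 0.5, 0.3), "finite")
})

test_that("rt at or below t0 has zero density; error mode raises", {
  p <- wiener_params(1, 1.5, 0.5, 0.30)
  expect_identical(dwiener(0.25, "upper", p), -Inf)
  expect_identical(dwiener(0.30, "lower", p), -Inf)
  expect_error(dwiener(0.25, "upper", p, on_invalid_rt = "error"),
               "rt <= t0")
  expect_true(is.finite(dwiener(0.31, "upper", p)))
})

test_that("defective densities integrate to one over random parameter sets", {
  set.seed(101)
  for (i in 1:5) {
    p <- list(v = runif(1, -3, 3), a = runif(1, 0.5, 2.5),
              z = runif(1, 0.2, 0.8), t0 = runif(1, 0.1, 0.4))
    tot <- stats::integrate(function(t) exp(dwiener(t, "upper", p)),
                            p$t0, p$t0 + 60, rel.tol = 1e-9)$value +
      stats::integrate(function(t) exp(dwiener(t, "lower", p)),
                       p$t0, p$t0 + 60, rel.tol = 1e-9)$value
    expect_lt(abs(tot - 1), 1e-4)
  }
})

test_that("density is numerically stable across the decision-time range", {
  p <- wiener_params(1, 1.5, 0.5, 0)
  ld <- dwiener(c(1e-4, 1e-3, 0.05, 0.5, 5, 10), "upper", p)
  expect_true(all(is.finite(ld) | ld == -Inf))
  expect_true(all(is.finite(ld[3:6])))
})

test_that("upper/lower reflection symmetry is exact", {
  expect_identical(dwiener(0.8, "upper", list(v = 1, a = 1.5, z = 0.4,
                                              t0 = 0.2)),
                   dwiener(0.8, "lower", list(v = -1, a = 1.5, z = 0.6,
                                              t0 = 0.2)))
})

test_that("choice probability has the zero-drift martingale limit", {
  expect_equal(choice_probability(wiener_params(0, 1.5, 0.5, 0.3)), 0.5)
  expect_equal(choice_probability(wiener_params(0, 1.5, 0.3, 0.3)), 0.3)
  # continuity through v = 0
  eps <- choice_probability(wiener_params(1e-8, 1.5, 0.3, 0.3))
  expect_lt(abs(eps - 0.3), 1e-6)
  # extreme drifts do not overflow
  expect_equal(choice_probability(wiener_params(400, 2, 0.5, 0)), 1)
  expect_equal(choice_probability(wiener_params(-400, 2, 0.5, 0)), 0)
})

test_that("choice probability matches an Euler simulation oracle", {
  p <- wiener_params(1, 1.5, 0.5, 0.3)
  set.seed(11)
  sim <- rwiener_fpt(20000, p, method = "euler", dt = 2e-4)
  ci <- stats::binom.test(sum(sim$upper), nrow(sim))$conf.int
  expect_gt(choice_probability(p), ci[1] - 0.01)
  expect_lt(choice_probability(p), ci[2] + 0.01)
})

test_that("mean decision time: zero-drift analytics and diffusive scaling", {
  expect_equal(mean_decision_time(wiener_params(0, 2, 0.5, 0)), 1.0,
               tolerance = 1e-3)
  expect_equal(mean_decision_time(wiener_params(0, 2, 0.3, 0)),
               4 * 0.3 * 0.7, tolerance = 1e-3)
  # doubling a with v = 0 quadruples the mean decision time
  m1 <- mean_decision_time(wiener_params(0, 1, 0.5, 0))
  m2 <- mean_decision_time(wiener_params(0, 2, 0.5, 0))
  expect_equal(m2 / m1, 4, tolerance = 1e-6)
})

test_that("mean decision time matches the exact sampler", {
  p <- wiener_params(1, 1.5, 0.5, 0.3)
  set.seed(13)
  sim <- rwiener_fpt(50000, p)
  dt <- sim$rt - p$t0
  se <- sd(dt) / sqrt(length(dt))
  expect_lt(abs(mean(dt) - mean_decision_time(p)), 3 * se)
})

test_that("defective CDF: limits, monotonicity, density consistency", {
  p <- wiener_params(1, 1.5, 0.5, 0.3)
  expect_equal(pwiener(p$t0, "upper", p), 0)
  expect_equal(pwiener(40, "upper", p), choice_probability(p),
               tolerance = 1e-6)
  p0 <- wiener_params(0, 1.5, 0.4, 0.3)
  expect_equal(pwiener(40, "upper", p0), 0.4, tolerance = 1e-6)
  expect_equal(pwiener(40, "lower", p0), 0.6, tolerance = 1e-6)
  qs <- pwiener(seq(0.31, 3, length.out = 30), "upper", p)
  expect_true(all(diff(qs) >= 0))
  # numerical derivative of the CDF matches the density
  h <- 1e-4
  for (q in c(0.5, 0.8, 1.5)) {
    num <- (pwiener(q + h, "upper", p) - pwiener(q - h, "upper", p)) / (2 * h)
    expect_lt(abs(num - exp(dwiener(q, "upper", p))), 1e-5)
  }
  # mid-range value against independent quadrature of the density
  quad <- stats::integrate(function(t) exp(dwiener(t, "upper", p)),
                           p$t0, 0.9, rel.tol = 1e-10)$value
  expect_equal(pwiener(0.9, "upper", p), quad, tolerance = 1e-7)
})

test_that("series density agrees with Euler-Maruyama histograms", {
  # chi-square goodness of fit of simulated upper-boundary times against
  # quadrature of the series density, on 3 parameter sets
  sets <- list(list(v = 1, a = 1.5, z = 0.5, t0 = 0.3),
               list(v = 0.5, a = 1.0, z = 0.4, t0 = 0.25),
               list(v = 2, a = 2.0, z = 0.6, t0 = 0.2))
  set.seed(5)
  for (p in sets) {
    e <- rwiener_fpt(8000, p, method = "euler", dt = 2e-5)
    eu <- e$rt[e$upper]
    br <- quantile(eu, seq(0, 1, 0.1))
    br[1] <- p$t0
    br[length(br)] <- Inf
    obs <- as.vector(table(cut(eu, br)))
    pu <- choice_probability(p)
    cdfv <- pwiener(br[-c(1, length(br))], "upper", p)
    probs <- diff(c(0, cdfv, pu)) / pu
    cs <- suppressWarnings(chisq.test(obs, p = probs))
    expect_gt(cs$p.value, 0.01)
  }
})
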