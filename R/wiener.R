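#' Wiener diffusion parameter set
#'
#' Bundles the four drift diffusion model (DDM) parameters for a single trial:
#' drift rate `v` (mean evidence-accumulation speed, evidence units/s,
#' signed), boundary separation `a` (response boundary, evidence units),
#' relative starting point `z` (bias, proportion of `a` measured from the
#' lower boundary) and non-decision time `t0` (s).  The diffusion coefficient
#' is fixed at 1; all parameters are expressed in that scale.
#'
#' @param v drift rate (finite, signed)
#' @param a boundary separation, `a > 0`
#' @param z starting bias, `0 < z < 1`
#' @param t0 non-decision time in seconds, `t0 >= 0`
#' @return an object of class `wiener_params` (a named list)
#' @examples
#' wiener_params(v = 1, a = 1.5, z = 0.5, t0 = 0.3)
#' @export
wiener_params <- function(v, a, z, t0) {
  check_wiener_params(v, a, z, t0)
  structure(list(v = v, a = a, z = z, t0 = t0), class = "wiener_params")
}

check_wiener_params <- function(v, a, z, t0) {
  if (!all(is.finite(v)) || !all(is.finite(a)) ||
      !all(is.finite(z)) || !all(is.finite(t0))) {
    stop("wiener parameters must be finite", call. = FALSE)
  }
  if (any(a <= 0)) stop("boundary separation 'a' must be > 0", call. = FALSE)
  if (any(z <= 0 | z >= 1)) stop("bias 'z' must lie in (0, 1)", call. = FALSE)
  if (any(t0 < 0)) stop("non-decision time 't0' must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.wiener_params <- function(x, ...) {
  cat(sprintf("Wiener parameters: v = %.4g, a = %.4g, z = %.4g, t0 = %.4g s\n",
              x$v, x$a, x$z, x$t0))
  invisible(x)
}

# Resolve (bound, v, z) to the lower-boundary canonical form: density of the
# upper boundary equals the lower-boundary density under (-v, 1-z).
.canonical_lower <- function(bound, v, z) {
  bound <- match.arg(bound, c("upper", "lower"))
  if (bound == "upper") list(v = -v, w = 1 - z) else list(v = v, w = z)
}

#' Log density of the Wiener first-passage time at one boundary
#'
#' Evaluates the defective first-passage-time density of the two-boundary
#' Wiener process at decision time `rt - t0`, for absorption at the named
#' boundary, on the log scale.  The density is computed by the standard dual
#' series (small-time and large-time expansions), switching at a truncation
#' error of 1e-7.
#'
#' @param rt response time(s) in seconds (finite, positive); vectorized
#' @param bound `"upper"` or `"lower"`
#' @param p a [wiener_params()] object, or a list with `v`, `a`, `z`, `t0`
#'   (each scalar or of the length of `rt`)
#' @param on_invalid_rt what to do when `rt <= t0`: return `-Inf` (default,
#'   so optimizers can probe infeasible `t0`) or raise an error
#' @return log-density values (log 1/s); `-Inf` where `rt <= t0`
#' @examples
#' p <- wiener_params(1, 1.5, 0.5, 0.3)
#' dwiener(0.8, "upper", p)
#' @export
dwiener <- function(rt, bound = c("upper", "lower"), p,
                    on_invalid_rt = c("neg_inf", "error")) {
  on_invalid_rt <- match.arg(on_invalid_rt)
  check_wiener_params(p$v, p$a, p$z, p$t0)
  if (any(!is.finite(rt)) || any(rt <= 0)) {
    stop("'rt' must be finite and positive", call. = FALSE)
  }
  n <- length(rt)
  can <- .canonical_lower(match.arg(bound), p$v, p$z)
  t_dec <- rt - rep_len(p$t0, n)
  if (on_invalid_rt == "error" && any(t_dec <= 0)) {
    stop("rt <= t0 encountered", call. = FALSE)
  }
  wfpt_logdens_cpp(t_dec, rep_len(can$v, n), rep_len(p$a, n),
                   rep_len(can$w, n))
}

#' Probability of absorption at the upper boundary
#'
#' Closed form for the constant-parameter process,
#' `P = (exp(-2 v a z) - 1) / (exp(-2 v a) - 1)`, with the zero-drift limit
#' `P = z` handled by the expansion at `|v a| -> 0` and large negative drifts
#' routed through the reflection symmetry to avoid overflow.
#'
#' @inheritParams dwiener
#' @return probability in (0, 1); vectorized over the parameter fields
#' @examples
#' choice_probability(wiener_params(0, 1.5, 0.3, 0.3)) # = z = 0.3
#' @export
choice_probability <- function(p) {
  check_wiener_params(p$v, p$a, p$z, p$t0)
  n <- max(length(p$v), length(p$a), length(p$z))
  v <- rep_len(p$v, n); a <- rep_len(p$a, n); z <- rep_len(p$z, n)
  .p_upper(v * a, z)
}

# P(upper) as a function of x = v * a and z, numerically stable on both sides.
.p_upper <- function(x, z) {
  out <- numeric(length(x))
  neg <- x < 0
  # reflection: P_up(x, z) = 1 - P_up(-x, 1 - z)
  xx <- ifelse(neg, -x, x)
  zz <- ifelse(neg, 1 - z, z)
  tiny <- xx < 1e-9
  out[tiny] <- zz[tiny]                     # zero-drift martingale limit
  i <- !tiny
  out[i] <- expm1(-2 * xx[i] * zz[i]) / expm1(-2 * xx[i])
  ifelse(neg, 1 - out, out)
}

#' Expected decision time of the Wiener process
#'
#' Mean first-passage time (either boundary, excluding `t0`).  With lower
#' distance `b = z a` and upper distance `c = (1 - z) a`, optional stopping
#' gives `E[T] = (c P - b (1 - P)) / v` for `v != 0` and `E[T] = b c =
#' a^2 z (1 - z)` in the zero-drift limit.
#'
#' @inheritParams dwiener
#' @return expected decision time in seconds (excluding `t0`)
#' @examples
#' mean_decision_time(wiener_params(0, 2, 0.5, 0)) # a^2 z (1-z) = 1
#' @export
mean_decision_time <- function(p) {
  check_wiener_params(p$v, p$a, p$z, p$t0)
  n <- max(length(p$v), length(p$a), length(p$z))
  v <- rep_len(p$v, n); a <- rep_len(p$a, n); z <- rep_len(p$z, n)
  b <- z * a
  cc <- (1 - z) * a
  pu <- .p_upper(v * a, z)
  ifelse(abs(v) < 1e-6, b * cc, (cc * pu - b * (1 - pu)) / v)
}

#' Defective CDF of the Wiener first-passage time at one boundary
#'
#' `P(RT <= rt, absorbed at bound)`.  Computed by high-order Gauss-Legendre
#' quadrature of the series density (panels refined near `t0` where the
#' density peaks); the limit as `rt -> Inf` is [choice_probability()] for the
#' upper boundary and its complement for the lower.
#'
#' @inheritParams dwiener
#' @param rt response time(s), seconds; vectorized (shared parameters)
#' @return defective CDF values in `[0, P(bound))`
#' @export
pwiener <- function(rt, bound = c("upper", "lower"), p) {
  bound <- match.arg(bound)
  check_wiener_params(p$v, p$a, p$z, p$t0)
  stopifnot(length(p$v) == 1L, length(p$a) == 1L, length(p$z) == 1L,
            length(p$t0) == 1L)
  t_dec <- rt - p$t0
  out <- numeric(length(rt))
  pos <- which(t_dec > 0)
  if (!length(pos)) return(out)
  can <- .canonical_lower(bound, p$v, p$z)
  dens <- function(td) {
    exp(wfpt_logdens_cpp(td, rep_len(can$v, length(td)),
                         rep_len(p$a, length(td)), rep_len(can$w, length(td))))
  }
  td <- t_dec[pos]
  o <- order(td)
  tds <- td[o]
  # cumulative panels: base knots (sqrt-spaced, dense near 0) + query points
  knots <- sort(unique(c(tds, max(tds) * seq(0, 1, length.out = 65)[-1]^2)))
  knots <- knots[knots > 0]
  cdf_at <- cumsum(vapply(seq_along(knots), function(i) {
    lo <- if (i == 1L) 0 else knots[i - 1L]
    gl <- pracma::gaussLegendre(15, lo, knots[i])
    sum(gl$w * dens(gl$x))
  }, numeric(1)))
  vals <- cdf_at[match(tds, knots)]
  out[pos[o]] <- vals
  out
}

# Upper bound on decision times carrying all but ~1e-10 of the mass: the
# survival function decays at rate lambda1 = v^2/2 + pi^2 / (2 a^2).
.t_upper_bound <- function(v, a) {
  lambda1 <- v^2 / 2 + pi^2 / (2 * a^2)
  25 / lambda1 + 0.5
}

#' Sample first-passage times and choices from the Wiener process
#'
#' Exact sampling by numerical inversion of the defective first-passage CDF
#' (choice from the closed-form absorption probability, then the conditional
#' decision time from a dense monotone CDF grid).  An Euler-Maruyama
#' simulator (`method = "euler"`) is retained as an independent check.
#'
#' @inheritParams dwiener
#' @param n number of trials to draw
#' @param method `"inverse_cdf"` (exact, default) or `"euler"`
#' @param dt Euler step size (s), used only by `method = "euler"`
#' @param grid_size number of grid points for the CDF inversion
#' @return a data.frame with columns `rt` (s) and `upper` (logical)
#' @export
rwiener_fpt <- function(n, p, method = c("inverse_cdf", "euler"),
                        dt = 1e-3, grid_size = 4096L) {
  method <- match.arg(method)
  check_wiener_params(p$v, p$a, p$z, p$t0)
  if (method == "euler") {
    m <- wiener_euler_cpp(n, p$v, p$a, p$z, p$t0, dt,
                          .t_upper_bound(p$v, p$a))
    return(data.frame(rt = m[, 1], upper = m[, 2] == 1))
  }
  pu <- .p_upper(p$v * p$a, p$z)
  upper <- stats::runif(n) < pu
  tmax <- .t_upper_bound(p$v, p$a)
  tg <- tmax * seq(0, 1, length.out = grid_size)^2
  rt <- numeric(n)
  for (b in c(TRUE, FALSE)) {
    idx <- which(upper == b)
    if (!length(idx)) next
    can <- .canonical_lower(if (b) "upper" else "lower", p$v, p$z)
    d <- exp(wfpt_logdens_cpp(tg, rep_len(can$v, grid_size),
                              rep_len(p$a, grid_size),
                              rep_len(can$w, grid_size)))
    cdf <- cumtrapz_vec(tg, d)
    cdf <- cdf / cdf[grid_size]
    u <- stats::runif(length(idx))
    rt[idx] <- p$t0 + monotone_inv_interp(cdf, tg, u)
  }
  data.frame(rt = rt, upper = upper)
}

# trapezoid cumulative integral of y over x
cumtrapz_vec <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# invert a nondecreasing tabulated CDF by linear interpolation, guarding ties
monotone_inv_interp <- function(cdf, grid, u) {
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], grid[keep], xout = u, rule = 2)$y
}
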