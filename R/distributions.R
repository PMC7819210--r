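# fitting PSA parameter distributions from printed 95% confidence intervals

#' Fit a beta distribution to a 95% confidence interval
#'
#' Finds shape parameters `(alpha, beta)` whose 2.5th and 97.5th
#' percentiles equal `(low, high)`, by damped Newton iteration on
#' `(log alpha, log beta)` with a finite-difference Jacobian. The
#' initialization is deterministic: method-of-moments shapes from mean
#' `(low + high)/2` and standard deviation `(high - low)/3.92`.
#'
#' @param low,high Target 2.5th / 97.5th percentiles, `0 < low < high < 1`.
#' @param tol Convergence tolerance on the percentile residuals
#'   (default 1e-9, comfortably inside the 1e-6 contract).
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residuals.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
#' @examples
#' sh <- fit_beta_from_ci(0.94, 0.98)
#' qbeta(c(0.025, 0.975), sh["alpha"], sh["beta"])
fit_beta_from_ci <- function(low, high, tol = 1e-9, max_iter = 200L) {
  if (!(low > 0 && high < 1 && low < high)) {
    stop_config("need 0 < low < high < 1, got (%s, %s)", low, high)
  }
  m <- (low + high) / 2
  s <- (high - low) / (2 * stats::qnorm(0.975))
  v <- s^2
  k <- max(m * (1 - m) / v - 1, 0.1)
  theta <- log(c(alpha = m * k, beta = (1 - m) * k))

  resid <- function(th) {
    sh <- exp(th)
    c(stats::qbeta(0.025, sh[1], sh[2]) - low,
      stats::qbeta(0.975, sh[1], sh[2]) - high)
  }
  r <- resid(theta)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    h <- 1e-6
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      thp <- theta; thp[j] <- thp[j] + h
      J[, j] <- (resid(thp) - r) / h
    }
    step <- tryCatch(solve(J, r), error = function(e) r * 0)
    if (all(step == 0)) break
    # damped update: halve until the residual norm does not increase
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      rc <- resid(cand)
      if (sum(rc^2) <= sum(r^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    theta <- cand; r <- rc
  }
  if (max(abs(r)) >= 1e-6) {
    stop_config("beta CI fit did not converge for (%s, %s): residuals (%.3g, %.3g)",
                low, high, r[1], r[2])
  }
  sh <- exp(theta)
  names(sh) <- c("alpha", "beta")
  sh
}

#' Fit a truncated normal to a 95% confidence interval
#'
#' Moment matching on the untruncated scale: `mean = (low + high)/2`,
#' `sd = (high - low)/3.92`. Draws are then restricted to `bounds`
#' (default \[0, 1\], suiting management proportions).
#'
#' @param low,high CI bounds, `low < high` (equal bounds give a point mass).
#' @param bounds Truncation interval (default `c(0, 1)`).
#' @return List with `mean`, `sd`, `bounds`.
#' @export
fit_truncnorm_from_ci <- function(low, high, bounds = c(0, 1)) {
  if (low > high) stop_config("need low <= high, got (%s, %s)", low, high)
  list(mean = (low + high) / 2,
       sd = (high - low) / (2 * stats::qnorm(0.975)),
       bounds = bounds)
}

#' Truncated-normal quantile function
#'
#' Inverse-CDF of a Normal(`mean`, `sd`) restricted to
#' `(lower, upper)` — the exact distribution rejection sampling would
#' produce, obtained with a single uniform per draw (keeps RNG streams
#' aligned across scenarios). `sd = 0` returns the (clamped) mean. A
#' `mode = "clip"` variant clamps unrestricted normal draws to the bounds
#' instead, placing point masses there.
#'
#' @param p Probabilities (e.g. `runif(n)`).
#' @param mean,sd Parameters of the untruncated normal.
#' @param lower,upper Truncation bounds.
#' @param mode `"resample"` (truncation, default) or `"clip"`.
#' @return Numeric vector of draws/quantiles.
#' @export
qtruncnorm <- function(p, mean, sd, lower = 0, upper = 1,
                       mode = c("resample", "clip")) {
  mode <- match.arg(mode)
  if (sd == 0) return(rep(min(max(mean, lower), upper), length(p)))
  if (mode == "clip") {
    return(pmin(pmax(stats::qnorm(p, mean, sd), lower), upper))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}
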