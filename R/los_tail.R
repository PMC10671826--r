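#' Discrete length-of-stay tail distribution
#'
#' A `los_tail` stores the survival function of a case's length of stay (LoS)
#' in whole weeks: `surv[t + 1] = P(S >= t)` for `t = 0, 1, ..., horizon`.
#' Cases last at least one week, so `P(S >= 0) = P(S >= 1) = 1` in tails
#' built from case data. The tail is the carrier of the LoS mean, variance
#' and Gini coefficient that enter the weekly demand model.
#'
#' @param surv numeric vector of survival probabilities `P(S >= t)` starting
#'   at `t = 0`; must begin at 1, be non-increasing and lie in `[0, 1]`.
#' @return an object of class `los_tail`.
#' @export
los_tail <- function(surv) {
  surv <- as.numeric(surv)
  if (length(surv) < 2L) stop("a LoS tail needs at least t = 0 and t = 1")
  if (abs(surv[1L] - 1) > 1e-12) stop("S(0) must equal 1")
  if (any(surv < -1e-12 | surv > 1 + 1e-12)) {
    stop("survival probabilities must lie in [0, 1]")
  }
  if (any(diff(surv) > 1e-12)) stop("survival function must be non-increasing")
  structure(list(surv = pmin(pmax(surv, 0), 1)),
            class = "los_tail")
}

#' @export
print.los_tail <- function(x, ...) {
  cat("Discrete LoS tail: horizon", los_horizon(x), "weeks, mean",
      format(mean_los(x), digits = 4), "weeks, Gini",
      format(gini_from_tail(x), digits = 3), "\n")
  invisible(x)
}

#' @rdname los_tail
#' @param tail a `los_tail` object.
#' @export
los_horizon <- function(tail) length(tail$surv) - 1L

#' Evaluate P(S >= t), returning 0 beyond the stored horizon
#' @inheritParams los_horizon
#' @param t non-negative integer week(s).
#' @export
los_surv <- function(tail, t) {
  t <- as.integer(t)
  if (any(t < 0L)) stop("t must be non-negative")
  out <- numeric(length(t))
  inside <- t <= los_horizon(tail)
  out[inside] <- tail$surv[t[inside] + 1L]
  out
}

#' Mean and variance of the LoS implied by a tail
#'
#' The discrete expectation identity `E[S] = sum_{t>=1} P(S >= t)` and
#' `E[S^2] = sum_{t>=1} (2t - 1) P(S >= t)`, truncated at the tail horizon.
#'
#' @inheritParams los_horizon
#' @export
mean_los <- function(tail) sum(tail$surv[-1L])

#' @rdname mean_los
#' @export
var_los <- function(tail) {
  s <- tail$surv[-1L]
  t <- seq_along(s)
  sum((2 * t - 1) * s) - mean_los(tail)^2
}

#' Gini coefficient of the length of stay
#'
#' Inequality of the LoS across cases, computed from the tail as
#' `G_s = 1 - sum_{k>=0} P(S > k)^2 / sum_{k>=0} P(S > k)`, where
#' `P(S > k) = P(S >= k + 1)`. Equals 0 for a deterministic LoS and
#' approaches 1 as the LoS distribution becomes extremely unequal. For a
#' geometric LoS with `P(S > k) = q^k` the closed form is `q / (1 + q)`.
#'
#' @inheritParams los_horizon
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_from_tail <- function(tail) {
  s <- tail$surv[-1L]  # P(S > k) = S(k + 1), k = 0, 1, ...
  m <- sum(s)
  if (m <= 0) stop("tail has zero implied mean")
  1 - sum(s^2) / m
}

#' Parametric LoS tails
#'
#' `los_tail_geometric()` builds the memoryless discrete tail with
#' `P(S > k) = q^k`, `q = 1 - 1/mean`, so the untruncated mean is `mean`
#' weeks and the Gini coefficient is `q / (1 + q)`.
#' `los_tail_weibull()` discretises a continuous Weibull LoS by rounding up
#' to whole weeks: `P(S >= t) = exp(-((t - 1)/scale)^shape)`.
#'
#' @param mean mean LoS in weeks (> 1).
#' @param horizon tail truncation in weeks.
#' @export
los_tail_geometric <- function(mean, horizon = ceiling(12 * mean)) {
  if (mean <= 1) stop("geometric LoS needs mean > 1 week")
  q <- 1 - 1 / mean
  los_tail(c(1, q^(0:(horizon - 1L))))
}

#' @rdname los_tail_geometric
#' @param shape,scale Weibull parameters of the underlying continuous LoS.
#' @export
los_tail_weibull <- function(shape, scale, horizon = ceiling(12 * scale)) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  t <- 1:horizon
  los_tail(c(1, exp(-(((t - 1) / scale)^shape))))
}

#' Stationary-excess (equilibrium) distribution of the remaining LoS
#'
#' For cases already in service, the default model of the remaining LoS is
#' the discrete equilibrium distribution of `S`:
#' `P(S^r >= t) = sum_{k>=t} P(S >= k) / E[S]` for `t >= 1`, with
#' `P(S^r >= 0) = 1`. This is the distribution of the residual duration of
#' a case picked at a random time in steady state.
#'
#' @inheritParams los_horizon
#' @return a `los_tail` for the remaining LoS.
#' @export
stationary_excess <- function(tail) {
  s <- tail$surv[-1L]
  m <- sum(s)
  if (m <= 0) stop("tail has zero implied mean")
  r <- rev(cumsum(rev(s))) / m
  los_tail(c(1, r))
}
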