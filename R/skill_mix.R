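#' Expected excess of capacity over normal demand
#'
#' For demand `Y ~ N(mu, sigma^2)`, the expected unused capacity at level
#' `C` is `E(C - Y)^+ = (C - mu) * pnorm(d) + sigma * dnorm(d)` with
#' `d = (C - mu)/sigma` (the normal loss function). For `sigma = 0` it is
#' `max(C - mu, 0)`.
#'
#' @param C capacity.
#' @param mu,sigma demand mean and standard deviation (`sigma >= 0`).
#' @return expected surplus, in the units of `C`.
#' @export
expected_excess_normal <- function(C, mu, sigma) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  ifelse(sigma == 0, pmax(C - mu, 0),
         (C - mu) * stats::pnorm((C - mu) / sigma) +
           sigma * stats::dnorm((C - mu) / sigma))
}

#' Hierarchical skill-mix problem
#'
#' Demand arises per qualification level `k = 1..K` and is normally
#' distributed with mean `mu[k]` and standard deviation `sigma[k]`.
#' Capacity of level `k` may also cover the demand of any lower level
#' (hierarchical substitution). Capacities `C_k` cost `cost[k]` per hour
#' (non-decreasing in `k`), must each satisfy
#' `C_k + e_k >= mu_k + eta_alpha * sigma_k` — where `e_k` is the expected
#' excess trickling down from levels above `k` — and, if positive, be at
#' least the minimum contract `min_contract`. The safety factor
#' `eta_alpha` bounds the per-level shortfall probability at
#' `1 - pnorm(eta_alpha)`.
#'
#' @param mu,sigma per-level demand means and standard deviations
#'   (hours/week), lowest level first.
#' @param cost per-hour cost per level, non-decreasing.
#' @param min_contract minimum capacity `l` of a staffed level (hours/week).
#' @param eta_alpha safety factor (>= 0); 2 bounds the weekly shortfall
#'   probability at about 2.3%.
#' @return an object of class `skill_mix_problem`.
#' @export
skill_mix_problem <- function(mu, sigma, cost = seq_along(mu),
                              min_contract = 0, eta_alpha = 2) {
  K <- length(mu)
  if (K < 1L || length(sigma) != K || length(cost) != K) {
    stop("mu, sigma and cost must have equal positive length")
  }
  if (any(mu < 0) || any(sigma < 0)) stop("mu and sigma must be non-negative")
  if (is.unsorted(cost)) stop("cost must be non-decreasing in level")
  if (min_contract < 0 || eta_alpha < 0) {
    stop("min_contract and eta_alpha must be non-negative")
  }
  structure(list(mu = mu, sigma = sigma, cost = cost,
                 min_contract = min_contract, eta_alpha = eta_alpha),
            class = "skill_mix_problem")
}

new_skill_mix_solution <- function(problem, capacity, excess) {
  structure(list(
    capacity = capacity, excess = excess,
    total_cost = sum(problem$cost * capacity),
    ratios = capacity / sum(capacity),
    problem = problem
  ), class = "skill_mix_solution")
}

#' @export
print.skill_mix_solution <- function(x, ...) {
  K <- length(x$capacity)
  cat("Skill-mix solution over", K, "qualification levels\n")
  print(data.frame(level = seq_len(K), capacity = round(x$capacity, 3),
                   excess_from_above = round(x$excess, 3),
                   ratio = round(x$ratios, 4)), row.names = FALSE)
  cat("total cost:", format(x$total_cost, digits = 6), "\n")
  invisible(x)
}

# Backward recursion: given capacities (or their lower-bound rule) compute
# excesses top-down. lifts[k] adds extra capacity at active level k.
skill_mix_chain <- function(p, active, lifts = numeric(length(p$mu))) {
  K <- length(p$mu)
  C <- numeric(K)
  e <- numeric(K)  # e[k] = excess available to level k from levels > k
  ek <- 0
  for (k in K:1) {
    e[k] <- ek
    if (active[k]) {
      C[k] <- max(p$min_contract, p$mu[k] + p$eta_alpha * p$sigma[k] - ek, 0) +
        lifts[k]
    }
    ek <- expected_excess_normal(C[k] + ek, p$mu[k], p$sigma[k])
  }
  list(capacity = C, excess = e)
}

#' Solve the skill-mix problem without a minimum contract
#'
#' With `min_contract = 0` the optimum has a closed form by backward
#' recursion from the top level: `e_K = 0`,
#' `C_k = max(0, mu_k + eta_alpha * sigma_k - e_k)` and
#' `e_{k-1} = E(C_k + e_k - N_k)^+` via [expected_excess_normal()]. Every
#' level is covered exactly to its safety quantile, using surplus from
#' above before buying own capacity; the top level always holds
#' `C_K = mu_K + eta_alpha * sigma_K`, hence relatively high overcapacity
#' in small teams.
#'
#' @param p a [skill_mix_problem] with `min_contract = 0`.
#' @return a `skill_mix_solution` with per-level `capacity`, `excess`
#'   (surplus available from higher levels), `total_cost` and capacity
#'   `ratios`.
#' @export
solve_unconstrained <- function(p) {
  if (p$min_contract != 0) stop("use solve_with_min_contract when l > 0")
  ch <- skill_mix_chain(p, active = rep(TRUE, length(p$mu)))
  new_skill_mix_solution(p, ch$capacity, ch$excess)
}

#' Solve the skill-mix problem with a minimum contract size
#'
#' With a minimum contract `l > 0` each staffed level must have at least
#' `l` hours, so the support of the solution is combinatorial. All `2^K`
#' staffed/unstaffed patterns are enumerated (`K <= 10`); within a pattern,
#' capacities follow the backward recursion at their lower bounds, and when
#' an unstaffed level's requirement is not met by surplus from above, the
#' lowest-indexed (cheapest) staffed higher level is lifted by the minimal
#' amount, found by root finding on the monotone excess chain. The cheapest
#' feasible pattern wins. With `l = 0` the result coincides with
#' [solve_unconstrained()].
#'
#' @param p a [skill_mix_problem].
#' @return a `skill_mix_solution`.
#' @export
solve_with_min_contract <- function(p) {
  K <- length(p$mu)
  if (K > 10L) stop("pattern enumeration is limited to K <= 10 levels")
  if (p$min_contract == 0) return(solve_unconstrained(p))
  best <- NULL
  for (pattern in 0:(2^K - 1)) {
    active <- as.logical(bitwAnd(pattern, 2^(0:(K - 1))))
    sol <- solve_pattern(p, active)
    if (!is.null(sol) && (is.null(best) || sol$total_cost < best$total_cost)) {
      best <- sol
    }
  }
  if (is.null(best)) stop("skill-mix problem infeasible under this contract")
  best
}

solve_pattern <- function(p, active, tol = 1e-9) {
  K <- length(p$mu)
  lifts <- numeric(K)
  need <- p$mu + p$eta_alpha * p$sigma
  for (pass in seq_len(K + 1L)) {
    ch <- skill_mix_chain(p, active, lifts)
    slack <- ch$capacity + ch$excess - need
    viol <- which(slack < -tol)
    if (length(viol) == 0L) {
      return(new_skill_mix_solution(p, ch$capacity, ch$excess))
    }
    k <- max(viol)  # fix the topmost violated level first
    if (active[k]) return(NULL)  # active levels self-cover; cannot happen
    j <- which(active & seq_len(K) > k)
    if (length(j) == 0L) return(NULL)
    j <- min(j)
    gap <- function(delta) {
      l2 <- lifts
      l2[j] <- l2[j] + delta
      ch2 <- skill_mix_chain(p, active, l2)
      ch2$capacity[k] + ch2$excess[k] - need[k]
    }
    hi <- sum(need) + K * p$min_contract + 10
    while (gap(hi) < 0 && hi < 1e12) hi <- hi * 4
    if (gap(hi) < 0) return(NULL)
    delta <- stats::uniroot(gap, c(0, hi), tol = 1e-10)$root
    lifts[j] <- lifts[j] + delta
  }
  NULL
}

#' Per-level shortfall probability of a skill-mix solution
#'
#' `P(N_k > C_k + e_k) = 1 - pnorm((C_k + e_k - mu_k)/sigma_k)`, which the
#' constraints bound by `1 - pnorm(eta_alpha)`.
#'
#' @param sol a `skill_mix_solution`.
#' @return numeric vector of per-level shortfall probabilities.
#' @export
shortfall_probability <- function(sol) {
  p <- sol$problem
  cover <- sol$capacity + sol$excess
  ifelse(p$sigma == 0, as.numeric(cover < p$mu),
         1 - stats::pnorm((cover - p$mu) / p$sigma))
}

#' Capacity ratios as the team scales
#'
#' Scaling demand by a factor `m` (more new cases, same case mix) turns the
#' per-level demand into mean `m * mu_k` and standard deviation
#' `sqrt(m) * sigma_k`. For each scale the problem is re-solved and the
#' capacity shares `C_k / sum(C_j)` reported; as `m` grows they converge to
#' the demand shares `mu_k / sum(mu_j)` — large teams can staff to the
#' average mix, small teams must overweight the top level.
#'
#' @param p a [skill_mix_problem].
#' @param scales positive multipliers of the arrival rate.
#' @return matrix of capacity ratios, one row per scale.
#' @export
ratio_curve <- function(p, scales) {
  if (any(scales <= 0)) stop("scales must be positive")
  K <- length(p$mu)
  out <- vapply(scales, function(m) {
    pm <- skill_mix_problem(mu = m * p$mu, sigma = sqrt(m) * p$sigma,
                            cost = p$cost, min_contract = p$min_contract,
                            eta_alpha = p$eta_alpha)
    solve_with_min_contract(pm)$ratios
  }, numeric(K))
  out <- matrix(out, ncol = K, byrow = TRUE,
                dimnames = list(as.character(scales), NULL))
  out
}
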