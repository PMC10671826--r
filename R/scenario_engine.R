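#' Team profile for scenario analysis
#'
#' Bundles a team's total demand model with an optional per-qualification-
#' level split used by the skill-mix term. When per-level moments are not
#' supplied they are derived by splitting the team totals across levels in
#' fixed proportions (`ql_shares`, defaulting to the aggregate case mix
#' 67% / 9% / 24% of the three-level hierarchy), with each level's standard
#' deviation taken as `sqrt(z * rho_k)` under the shared peakedness.
#'
#' @param demand a [team_demand] model for the team total.
#' @param per_ql optional data frame with columns `mu` and `sigma`
#'   (hours/week per level, lowest level first).
#' @param ql_shares demand shares per level used when `per_ql` is absent.
#' @param team_id optional label (taken from `demand` if present there).
#' @param location optional `c(x, y)` centroid in km.
#' @param team_size optional worker count; derived from demand when needed.
#' @return an object of class `team_profile`.
#' @export
team_profile <- function(demand, per_ql = NULL,
                         ql_shares = c(0.67, 0.09, 0.24),
                         team_id = demand$team_id, location = NULL,
                         team_size = NULL) {
  stopifnot(inherits(demand, c("team_demand", "pooled_demand")))
  rho <- stationary_moments(demand)$mean
  if (is.null(per_ql)) {
    shares <- ql_shares / sum(ql_shares)
    per_ql <- data.frame(mu = rho * shares,
                         sigma = sqrt(peakedness(demand) * rho * shares))
  } else {
    if (!all(c("mu", "sigma") %in% names(per_ql))) {
      stop("per_ql needs mu and sigma columns")
    }
    if (abs(sum(per_ql$mu) - rho) > 0.01 * rho) {
      stop("per-level means must sum to the team total within 1%")
    }
  }
  structure(list(demand = demand, per_ql = per_ql, team_id = team_id,
                 location = location, team_size = team_size),
            class = "team_profile")
}

#' @export
print.team_profile <- function(x, ...) {
  cat("Team profile", if (!is.null(x$team_id)) paste0("(", x$team_id, ")"),
      "\n")
  print(x$demand)
  invisible(x)
}

#' Build profiles from a team-parameter table
#'
#' @param teams a team-parameter data frame (see [load_team_parameters()]).
#' @inheritParams team_profile
#' @return named list of [team_profile] objects.
#' @export
team_profiles_from_parameters <- function(teams,
                                          ql_shares = c(0.67, 0.09, 0.24)) {
  profiles <- lapply(seq_len(nrow(teams)), function(i) {
    team_profile(as_team_demand(teams[i, , drop = FALSE]),
                 ql_shares = ql_shares)
  })
  names(profiles) <- teams$team_id
  profiles
}

#' Team size implied by demand
#'
#' `M = ceiling(rho / hours_per_worker)`: the number of care workers needed
#' when each delivers `hours_per_worker` hours of direct care per week
#' (estimated at 20 h in practice).
#'
#' @param rho mean weekly demand in hours.
#' @param hours_per_worker direct care hours per worker per week.
#' @export
team_size_from_demand <- function(rho, hours_per_worker = 20) {
  if (any(rho <= 0)) stop("rho must be positive")
  ceiling(rho / hours_per_worker)
}

#' Merge a cluster of teams into one profile
#'
#' Demand pools under independence (means and variances add, see
#' [pool_teams()]); per-level means add and per-level variances add. The
#' merged team's size is recomputed from the pooled demand. Merging is
#' associative: merging incrementally or all at once gives identical
#' metrics.
#'
#' @param profiles list of [team_profile] objects (length >= 1).
#' @param hours_per_worker passed to [team_size_from_demand()].
#' @return a [team_profile] for the merged cluster.
#' @export
merge_cluster <- function(profiles, hours_per_worker = 20) {
  if (length(profiles) == 0L) stop("nothing to merge")
  if (length(profiles) == 1L) return(profiles[[1L]])
  pooled <- pool_teams(lapply(profiles, `[[`, "demand"))
  demand <- pooled_demand(pooled$rho, pooled$z,
                          team_id = paste(vapply(profiles, function(p)
                            as.character(p$team_id), character(1)),
                            collapse = "+"))
  mu <- Reduce(`+`, lapply(profiles, function(p) p$per_ql$mu))
  sig2 <- Reduce(`+`, lapply(profiles, function(p) p$per_ql$sigma^2))
  team_profile(demand, per_ql = data.frame(mu = mu, sigma = sqrt(sig2)),
               team_id = demand$team_id)
}

#' Objective weights for merging decisions
#'
#' @param lambda1,lambda3,lambda4,lambda6 non-negative weights of the
#'   utilization, availability, skill-mix deviation and interaction terms.
#'   `lambda6` doubles as the scaling of the raw interaction count against
#'   the three fraction-valued terms.
#' @param l_threshold effective-capacity threshold `l` in the availability
#'   term.
#' @export
objective_weights <- function(lambda1 = 1, lambda3 = 1, lambda4 = 1,
                              lambda6 = 1e-3, l_threshold = 0.6) {
  if (any(c(lambda1, lambda3, lambda4, lambda6) < 0)) {
    stop("weights must be non-negative")
  }
  if (l_threshold < 0 || l_threshold > 1) stop("l_threshold must be in [0,1]")
  list(lambda1 = lambda1, lambda3 = lambda3, lambda4 = lambda4,
       lambda6 = lambda6, l_threshold = l_threshold)
}

#' Evaluate a team (or merged cluster) on the four scenario metrics
#'
#' Computes, for one profile: capacity utilization under square-root
#' staffing; availability `P(P > l)` of the effective capacity at the
#' implied team size; the skill-mix deviation
#' `sum_k (C_k/sum C - mu_k/sum mu)^+` from an unconstrained skill-mix
#' solution; and the pairwise interaction count.
#'
#' @param profile a [team_profile].
#' @param gamma grade of service for the utilization term.
#' @param p_present worker presence probability.
#' @param eta_alpha skill-mix safety factor.
#' @param hours_per_worker direct care hours per worker per week.
#' @param weights an [objective_weights()] list (supplies `l_threshold`).
#' @return list of class `scenario_metrics` with `rho`, `z`, `team_size`,
#'   `utilization`, `availability`, `ql_deviation`, `interactions`.
#' @export
evaluate_scenario <- function(profile, gamma = 1, p_present = 0.79,
                              eta_alpha = 2, hours_per_worker = 20,
                              weights = objective_weights()) {
  rho <- stationary_moments(profile$demand)$mean
  z <- peakedness(profile$demand)
  M <- if (!is.null(profile$team_size)) profile$team_size else {
    team_size_from_demand(rho, hours_per_worker)
  }
  avail <- 1 - prob_effective_capacity_below(
    availability_model(M, p_present), weights$l_threshold)
  sol <- solve_unconstrained(skill_mix_problem(
    mu = profile$per_ql$mu, sigma = profile$per_ql$sigma,
    eta_alpha = eta_alpha))
  dev <- sum(pmax(sol$ratios - profile$per_ql$mu / sum(profile$per_ql$mu), 0))
  structure(list(team_id = profile$team_id, rho = rho, z = z, team_size = M,
                 utilization = utilization(rho, z, gamma),
                 availability = avail, ql_deviation = dev,
                 interactions = interactions_complete(M)),
            class = "scenario_metrics")
}

#' @export
print.scenario_metrics <- function(x, ...) {
  cat(sprintf(
    "Scenario %s: rho = %.4g, z = %.3g, M = %d\n  utilization %.3f | availability %.3f | QL deviation %.4f | interactions %d\n",
    if (is.null(x$team_id)) "" else x$team_id, x$rho, x$z,
    as.integer(x$team_size), x$utilization, x$availability,
    x$ql_deviation, as.integer(x$interactions)))
  invisible(x)
}

#' Weighted merging objective
#'
#' `lambda1 * utilization + lambda3 * availability -
#'  lambda4 * ql_deviation - lambda6 * interactions`, to be maximized over
#' merge steps: efficiency terms grow with scale while the interaction
#' penalty grows quadratically, so intermediate cluster sizes win for
#' moderate `lambda6`.
#'
#' @param metrics a `scenario_metrics` list from [evaluate_scenario()].
#' @param weights an [objective_weights()] list.
#' @return scalar objective value.
#' @export
objective_score <- function(metrics, weights = objective_weights()) {
  weights$lambda1 * metrics$utilization +
    weights$lambda3 * metrics$availability -
    weights$lambda4 * metrics$ql_deviation -
    weights$lambda6 * metrics$interactions
}

#' Scan a merging sequence
#'
#' Starting from the first team in `order`, teams are merged one at a time;
#' at each step the cumulative cluster is evaluated on the four metrics and
#' the weighted objective. The merge order is caller-supplied (in practice
#' driven by geographic adjacency).
#'
#' @param profiles named list of [team_profile] objects.
#' @param order character vector of team ids giving the merge order;
#'   defaults to the order of `profiles`.
#' @inheritParams evaluate_scenario
#' @return a data frame of class `merge_scan`, one row per step, with the
#'   cluster composition, `rho`, `z`, `team_size`, the four metrics and
#'   `objective`.
#' @export
scan_merge_sequence <- function(profiles, order = names(profiles),
                                gamma = 1, p_present = 0.79, eta_alpha = 2,
                                hours_per_worker = 20,
                                weights = objective_weights()) {
  order <- as.character(order)
  if (anyDuplicated(order)) stop("duplicate team ids in merge order")
  if (!all(order %in% names(profiles))) {
    stop("unknown team id(s): ",
         paste(setdiff(order, names(profiles)), collapse = ", "))
  }
  rows <- lapply(seq_along(order), function(j) {
    cluster <- merge_cluster(profiles[order[seq_len(j)]],
                             hours_per_worker = hours_per_worker)
    m <- evaluate_scenario(cluster, gamma = gamma, p_present = p_present,
                           eta_alpha = eta_alpha,
                           hours_per_worker = hours_per_worker,
                           weights = weights)
    data.frame(step = j, cluster = paste(order[seq_len(j)], collapse = "+"),
               rho = m$rho, z = m$z, team_size = m$team_size,
               utilization = m$utilization, availability = m$availability,
               ql_deviation = m$ql_deviation, interactions = m$interactions,
               objective = objective_score(m, weights),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("merge_scan", "data.frame")
  out
}

#' @export
print.merge_scan <- function(x, digits = 4, ...) {
  cat("Merge scan over", nrow(x), "steps\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot the four metric curves of a merge scan
#'
#' @param x a `merge_scan` data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.merge_scan <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  curves <- list(utilization = "Utilization E[N]/C",
                 availability = "P(P > l)",
                 ql_deviation = "Skill-mix deviation",
                 interactions = "Interactions")
  for (nm in names(curves)) {
    graphics::plot(x$step, x[[nm]], type = "b", xlab = "merge step",
                   ylab = curves[[nm]], ...)
  }
  invisible(x)
}
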