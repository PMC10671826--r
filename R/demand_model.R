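#' Weekly care-demand model for one team
#'
#' The demand for home care is modelled as a discrete-time infinite-server
#' queue with batch arrivals: each week a random number of new cases starts
#' (mean `m_a`, variance `var_a`), each case stays a random number of weeks
#' `S` (the LoS, with tail `los`), and requires a random number of care
#' hours per week `B` (mean `m_g`, variance `var_g`), all mutually
#' independent. The weekly demand in hours is the sum of the hours of all
#' active cases.
#'
#' A model can be built either from a full LoS tail or directly from a
#' team-parameter row (mean LoS and Gini only) — the stationary moments
#' depend on the tail only through `m_s` and `G_s`.
#'
#' @param m_a mean number of new cases per week (> 0).
#' @param m_g mean case demand in hours per week (> 0).
#' @param vmr_a,vmr_g variance-to-mean ratios of the weekly arrival count
#'   and the case weekly hours.
#' @param los optional [los_tail] of the LoS; supplies `m_s` and `gini_s`.
#' @param m_s,gini_s mean LoS (weeks) and LoS Gini coefficient, required if
#'   `los` is not given.
#' @param team_id optional label.
#' @return an object of class `team_demand`.
#' @seealso [stationary_moments()], [peakedness()], [required_capacity()],
#'   [simulate.team_demand()], [predict.team_demand()]
#' @export
team_demand <- function(m_a, m_g, vmr_a = 1, vmr_g = 1, los = NULL,
                        m_s = NULL, gini_s = NULL, team_id = NULL) {
  if (m_a <= 0 || m_g <= 0) stop("m_a and m_g must be positive")
  if (vmr_a < 0 || vmr_g < 0) stop("VMRs must be non-negative")
  if (!is.null(los)) {
    stopifnot(inherits(los, "los_tail"))
    m_s <- mean_los(los)
    gini_s <- gini_from_tail(los)
  }
  if (is.null(m_s) || is.null(gini_s)) {
    stop("supply either a LoS tail or both m_s and gini_s")
  }
  if (m_s <= 0) stop("m_s must be positive")
  if (gini_s < 0 || gini_s >= 1) stop("gini_s must lie in [0, 1)")
  structure(
    list(m_a = m_a, var_a = vmr_a * m_a, m_g = m_g, var_g = vmr_g * m_g,
         m_s = m_s, gini_s = gini_s, los = los, team_id = team_id),
    class = "team_demand"
  )
}

#' @rdname team_demand
#' @param params one row of a team-parameter data frame
#'   (see [load_team_parameters()]).
#' @export
as_team_demand <- function(params) {
  stopifnot(nrow(params) == 1L)
  team_demand(m_a = params$m_a, m_g = params$m_g, vmr_a = params$vmr_a,
              vmr_g = params$vmr_g, m_s = params$m_s_implied,
              gini_s = params$gini_s, team_id = params$team_id)
}

#' Stationary mean and variance of weekly demand
#'
#' In stationarity the mean weekly demand is `rho = m_a * m_s * m_g` and the
#' variance is `z * rho` with `z` the peakedness, so the standard deviation
#' grows only with the square root of the offered load.
#'
#' @param model a [team_demand] or [pooled_demand] model.
#' @return list with `mean` (rho, hours/week) and `variance` (hours^2).
#' @export
stationary_moments <- function(model) UseMethod("stationary_moments")

#' @export
stationary_moments.team_demand <- function(model) {
  rho <- model$m_a * model$m_s * model$m_g
  list(mean = rho, variance = peakedness(model) * rho)
}

#' @export
stationary_moments.pooled_demand <- function(model) {
  list(mean = model$rho, variance = model$z * model$rho)
}

#' Peakedness of weekly demand
#'
#' The variance-to-mean ratio of stationary weekly demand,
#' `z = var_g/m_g + m_g + m_g * (1 - G_s) * (var_a/m_a - 1)`.
#' It aggregates the three sources of variability: case-demand dispersion,
#' batch size in hours, and arrival over/under-dispersion damped by the LoS
#' inequality `G_s`. With unit deterministic case demand (`m_g = 1`,
#' `var_g = 0`) it reduces to the classical `1 + (1 - G_s)(var_a/m_a - 1)`.
#'
#' @inheritParams stationary_moments
#' @return peakedness `z` (dimensionless, > 0).
#' @export
peakedness <- function(model) UseMethod("peakedness")

#' @export
peakedness.team_demand <- function(model) {
  with(model, var_g / m_g + m_g + m_g * (1 - gini_s) * (var_a / m_a - 1))
}

#' @export
peakedness.pooled_demand <- function(model) model$z

#' Demand model specified directly by mean and peakedness
#'
#' A reduced demand model carrying only the stationary mean `rho` and
#' peakedness `z`, as produced by pooling several teams: under independence
#' the component structure (arrivals, LoS, case demand) of the pool is not
#' retained, but every downstream staffing quantity depends on the demand
#' distribution only through `(rho, z)` and the normal approximation.
#'
#' @param rho stationary mean demand, hours/week (> 0).
#' @param z peakedness (> 0).
#' @param team_id optional label.
#' @export
pooled_demand <- function(rho, z, team_id = NULL) {
  if (rho <= 0 || z <= 0) stop("rho and z must be positive")
  structure(list(rho = rho, z = z, team_id = team_id),
            class = "pooled_demand")
}

#' @export
print.pooled_demand <- function(x, ...) {
  cat(sprintf("Pooled demand model%s: rho = %.4g h/week, z = %.4g\n",
              if (is.null(x$team_id)) "" else paste0(" (", x$team_id, ")"),
              x$rho, x$z))
  invisible(x)
}

#' Square-root staffing and utilization
#'
#' `required_capacity()` is the square-root staffing rule
#' `C = rho + gamma * sqrt(z * rho)`: base capacity for the mean plus a
#' safety buffer proportional to the demand standard deviation, with the
#' grade of service `gamma` (typically 0.5–2) controlling the probability
#' `1 - pnorm(gamma)` that demand exceeds capacity under the normal
#' approximation. `utilization()` is the resulting mean utilization
#' `rho / C = 1 / (1 + gamma * sqrt(z / rho))`, increasing in scale `rho`
#' and decreasing in variability `z` — economies of scale with diminishing
#' returns.
#'
#' @param rho mean weekly demand in hours (or a [team_demand] model, from
#'   which `rho` and `z` are taken).
#' @param z peakedness; ignored when `rho` is a model.
#' @param gamma grade-of-service multiplier (>= 0).
#' @return capacity in hours/week, or a utilization fraction in (0, 1].
#' @export
required_capacity <- function(rho, z = NULL, gamma = 1) {
  rz <- resolve_rho_z(rho, z)
  if (gamma < 0) stop("gamma must be non-negative")
  rz$rho + gamma * sqrt(rz$z * rz$rho)
}

#' @rdname required_capacity
#' @export
utilization <- function(rho, z = NULL, gamma = 1) {
  rz <- resolve_rho_z(rho, z)
  1 / (1 + gamma * sqrt(rz$z / rz$rho))
}

resolve_rho_z <- function(rho, z) {
  if (inherits(rho, c("team_demand", "pooled_demand"))) {
    list(rho = stationary_moments(rho)$mean, z = peakedness(rho))
  } else {
    if (is.null(z)) stop("supply z alongside a numeric rho")
    if (any(rho <= 0) || any(z <= 0)) stop("rho and z must be positive")
    list(rho = rho, z = z)
  }
}

#' Current workload for transient forecasts
#'
#' @param case_hours positive vector of weekly hours of the currently
#'   active cases.
#' @param remaining_tail optional [los_tail] of the remaining LoS shared by
#'   all current cases; defaults (in [transient_moments()]) to the
#'   stationary-excess distribution of the model's LoS tail.
#' @return an object of class `current_load`.
#' @export
current_load <- function(case_hours, remaining_tail = NULL) {
  case_hours <- as.numeric(case_hours)
  if (any(case_hours <= 0)) stop("case hours must be positive")
  if (!is.null(remaining_tail)) stopifnot(inherits(remaining_tail, "los_tail"))
  structure(list(case_hours = case_hours, remaining_tail = remaining_tail),
            class = "current_load")
}

#' Transient mean and variance of weekly demand
#'
#' Forecast of the demand `t` weeks ahead given the currently active cases:
#' `E[N_t] = N_0 * S^r(t) + m_a * m_g * sum_{u=1}^{t} S(u)`, where `N_0` is
#' the current total weekly hours, `S^r` the remaining-LoS tail of current
#' cases and `S` the LoS tail of future arrivals. The variance combines the
#' Bernoulli thinning of current case hours with the compound variability
#' of future arrivals. As `t` grows both converge to the stationary
#' moments. Requires the model to carry a full LoS tail.
#'
#' @inheritParams stationary_moments
#' @param load a [current_load()]; `NULL` means an empty system.
#' @param t forecast horizon(s) in whole weeks (>= 0).
#' @return data frame with columns `t`, `mean` and `variance`.
#' @export
transient_moments <- function(model, load = NULL, t) {
  if (is.null(model$los)) {
    stop("transient moments need a model built from a full LoS tail")
  }
  t <- as.integer(t)
  if (any(t < 0L)) stop("t must be non-negative")
  s_tail <- model$los
  b_hat <- if (is.null(load)) numeric(0) else load$case_hours
  r_tail <- if (!is.null(load) && !is.null(load$remaining_tail)) {
    load$remaining_tail
  } else {
    stationary_excess(s_tail)
  }
  n0 <- sum(b_hat)
  out <- lapply(t, function(tt) {
    sr <- los_surv(r_tail, tt)
    su <- if (tt >= 1L) los_surv(s_tail, 1:tt) else numeric(0)
    mean_t <- n0 * sr + model$m_a * model$m_g * sum(su)
    var_t <- sr * (1 - sr) * sum(b_hat^2) +
      model$m_a * (model$var_g + model$m_g^2) * sum(su) +
      model$m_g^2 * (model$var_a - model$m_a) * sum(su^2)
    c(t = tt, mean = mean_t, variance = var_t)
  })
  as.data.frame(do.call(rbind, out))
}

#' Pool the demand of several teams
#'
#' Under independence the pooled mean demand is the sum of the per-team
#' means and the pooled variance the sum of the per-team variances, so the
#' pooled peakedness is the demand-weighted average
#' `z = sum(z_i * rho_i) / sum(rho_i)`. Pooling raises utilization at any
#' fixed grade of service — the pooling principle behind team merging.
#'
#' @param models a list of [team_demand] models.
#' @return list with `rho` (pooled mean, hours/week) and `z` (pooled
#'   peakedness).
#' @export
pool_teams <- function(models) {
  if (length(models) == 0L) stop("nothing to pool")
  rho <- vapply(models, function(m) stationary_moments(m)$mean, numeric(1))
  z <- vapply(models, peakedness, numeric(1))
  list(rho = sum(rho), z = sum(z * rho) / sum(rho))
}

#' @export
print.team_demand <- function(x, ...) {
  sm <- stationary_moments(x)
  cat("Weekly care-demand model",
      if (!is.null(x$team_id)) paste0("(team ", x$team_id, ")"), "\n")
  cat(sprintf("  arrivals: %.3g cases/week (VMR %.3g)\n",
              x$m_a, x$var_a / x$m_a))
  cat(sprintf("  LoS: mean %.3g weeks, Gini %.3g%s\n", x$m_s, x$gini_s,
              if (is.null(x$los)) " (implied)" else ""))
  cat(sprintf("  case demand: %.3g h/week (VMR %.3g)\n",
              x$m_g, x$var_g / x$m_g))
  cat(sprintf("  stationary demand: rho = %.4g h/week, peakedness z = %.4g\n",
              sm$mean, peakedness(x)))
  invisible(x)
}

#' Summarise a demand model under square-root staffing
#'
#' @param object a [team_demand] model.
#' @param gamma grade of service.
#' @param ... ignored.
#' @return list of class `summary.team_demand` with `rho`, `z`, `capacity`
#'   and `utilization`.
#' @export
summary.team_demand <- function(object, gamma = 1, ...) {
  sm <- stationary_moments(object)
  z <- peakedness(object)
  structure(list(team_id = object$team_id, rho = sm$mean, z = z,
                 gamma = gamma,
                 capacity = required_capacity(sm$mean, z, gamma),
                 utilization = utilization(sm$mean, z, gamma)),
            class = "summary.team_demand")
}

#' @export
print.summary.team_demand <- function(x, ...) {
  cat(sprintf(
    "rho = %.4g h/week, z = %.4g, C(gamma=%.3g) = %.4g h/week, utilization = %.3f\n",
    x$rho, x$z, x$gamma, x$capacity, x$utilization))
  invisible(x)
}

#' Simulate stationary weekly demand from a model
#'
#' Monte-Carlo draws of the stationary weekly demand by direct simulation
#' of the infinite-server sum (the oracle for the closed-form moments);
#' see [simulate_stationary_demand()].
#'
#' @param object a [team_demand] model (must carry a LoS tail, or one is
#'   reconstructed as geometric with the model's mean LoS).
#' @param nsim number of replications.
#' @param seed optional RNG seed.
#' @param ... ignored.
#' @return numeric vector of `nsim` weekly demand draws.
#' @export
simulate.team_demand <- function(object, nsim = 1000, seed = NULL, ...) {
  simulate_stationary_demand(object, reps = nsim, seed = seed)
}

#' Forecast demand moments t weeks ahead
#'
#' @inheritParams simulate.team_demand
#' @param t forecast horizons in weeks.
#' @param load optional [current_load()].
#' @param ... ignored.
#' @return the [transient_moments()] data frame.
#' @export
predict.team_demand <- function(object, t = 0:12, load = NULL, ...) {
  transient_moments(object, load = load, t = t)
}
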