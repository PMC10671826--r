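#' Specification for the synthetic visit generator
#'
#' The generator emulates the statistical structure of planned HHC visit
#' records: weekly case starts with chosen mean and dispersion, a
#' parametric LoS per case, a gamma-distributed per-case weekly care
#' demand held constant over the case's weeks, a qualification-level mix,
#' and an intra-week profile over day parts and weekdays/weekend. Defaults
#' are the observed aggregates of a 55-team Dutch HHC provider: 3.6 new
#' cases/week with VMR 1.4, mean LoS around 20 weeks, 3.3 h per case-week
#' with VMR 4, case mix 67/9/24% over the three levels, day-part mix
#' 68.6/7.3/24.2% and a 19.3% weekend dip.
#'
#' @param weeks observation horizon in weeks.
#' @param m_a,vmr_a mean and VMR of weekly new-case counts.
#' @param los LoS distribution: `list(family = "geometric", mean = )` or
#'   `list(family = "weibull", shape = , scale = )` (in weeks).
#' @param m_g,vmr_g mean and VMR of per-case weekly hours.
#' @param ql_mix probabilities over qualification levels.
#' @param daypart_mix probabilities for morning/afternoon/evening.
#' @param weekend_factor demand level of a weekend day relative to a
#'   weekday.
#' @param team_id team label stamped on the records.
#' @param origin a Monday `Date` anchoring week 0.
#' @param warmup weeks of arrivals generated before the observation window
#'   so that it opens in steady state; cases straddling week 0 appear
#'   left-open, exactly as in real observation windows. Defaults to eight
#'   mean LoS durations.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(weeks = 300L, m_a = 3.6, vmr_a = 1.4,
                           los = list(family = "geometric", mean = 20),
                           m_g = 3.3, vmr_g = 4,
                           ql_mix = c(0.67, 0.09, 0.24),
                           daypart_mix = c(morning = 0.686,
                                           afternoon = 0.073,
                                           evening = 0.242),
                           weekend_factor = 1 - 0.193,
                           team_id = "T1",
                           origin = as.Date("2020-01-06"),
                           warmup = NULL) {
  if (weeks < 1) stop("weeks must be positive")
  if (is.null(warmup)) {
    warmup <- ceiling(8 * switch(los$family, geometric = los$mean,
                                 weibull = los$scale * gamma(1 + 1 / los$shape)))
  }
  if (warmup < 0) stop("warmup must be non-negative")
  if (m_a < 0 || vmr_a < 0 || m_g <= 0 || vmr_g < 0) {
    stop("negative generator moments")
  }
  # printed mixes are rounded (the default day-part mix sums to 100.1%);
  # accept small rounding slack and renormalise
  if (abs(sum(ql_mix) - 1) > 0.01 || abs(sum(daypart_mix) - 1) > 0.01) {
    stop("ql_mix and daypart_mix must sum to 1")
  }
  ql_mix <- ql_mix / sum(ql_mix)
  daypart_mix <- daypart_mix / sum(daypart_mix)
  if (weekend_factor < 0) stop("weekend_factor must be non-negative")
  stopifnot(los$family %in% c("geometric", "weibull"))
  structure(list(weeks = as.integer(weeks), m_a = m_a, vmr_a = vmr_a,
                 los = los, m_g = m_g, vmr_g = vmr_g, ql_mix = ql_mix,
                 daypart_mix = daypart_mix, weekend_factor = weekend_factor,
                 team_id = team_id, origin = origin,
                 warmup = as.integer(warmup)),
            class = "generator_spec")
}

# Weekly arrival counts with mean m and VMR v: the count family is picked
# by the dispersion (negative binomial > 1, Poisson = 1, binomial < 1);
# the demand model depends on arrivals only through these two moments.
draw_arrival_counts <- function(n, m, v) {
  if (m == 0) return(integer(n))
  if (v > 1) {
    size <- m / (v - 1)
    stats::rnbinom(n, size = size, mu = m)
  } else if (v == 1) {
    stats::rpois(n, m)
  } else {
    trials <- max(1L, round(m / (1 - v)))
    stats::rbinom(n, trials, m / trials)
  }
}

draw_los <- function(n, los) {
  if (los$family == "geometric") {
    1L + stats::rgeom(n, 1 / los$mean)
  } else {
    as.integer(ceiling(stats::rweibull(n, shape = los$shape,
                                       scale = los$scale)))
  }
}

draw_case_hours <- function(n, m_g, vmr_g) {
  if (vmr_g == 0) return(rep(m_g, n))
  stats::rgamma(n, shape = m_g / vmr_g, scale = vmr_g)
}

#' Generate synthetic visit records
#'
#' Draws weekly case starts, assigns each case a qualification level, an
#' LoS and a constant weekly demand, and materialises one visit record per
#' (case, active week, day part), with the day within the week sampled
#' under the weekday/weekend profile. Output is truncated at the horizon,
#' so late-starting cases appear right-censored exactly as in real
#' observation windows. Fully reproducible: the same spec and seed give
#' identical records.
#'
#' @param spec a [generator_spec()].
#' @param seed RNG seed.
#' @return a visit data frame in the [read_visits()] schema.
#' @export
generate_visits <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed)
  n_weeks_total <- spec$warmup + spec$weeks
  starts_per_week <- draw_arrival_counts(n_weeks_total, spec$m_a, spec$vmr_a)
  n_cases <- sum(starts_per_week)
  if (n_cases == 0L) {
    return(validate_visits(build_visit_frame(data.frame(
      client_id = character(0), team_id = character(0), date = character(0),
      day_part = character(0), duration_hours = character(0),
      qualification_level = character(0)))))
  }
  start_week <- rep(seq_len(n_weeks_total) - 1L - spec$warmup,
                    starts_per_week)
  los <- draw_los(n_cases, spec$los)
  hours <- draw_case_hours(n_cases, spec$m_g, spec$vmr_g)
  ql <- sample.int(length(spec$ql_mix), n_cases, replace = TRUE,
                   prob = spec$ql_mix)
  dayparts <- c("morning", "afternoon", "evening")
  wf <- spec$weekend_factor
  day_prob <- c(rep(1, 5), wf, wf)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    last <- min(start_week[i] + los[i] - 1L, spec$weeks - 1L)
    if (last < 0L) next  # warm-up case expired before the window opened
    active <- max(start_week[i], 0L):last
    n_active <- length(active)
    part <- rep(dayparts, n_active)
    week <- rep(active, each = 3L)
    day <- sample.int(7L, 3L * n_active, replace = TRUE, prob = day_prob) - 1L
    rows[[i]] <- data.frame(
      client_id = sprintf("c%05d", i),
      team_id = spec$team_id,
      date = spec$origin + week * 7L + day,
      day_part = part,
      duration_hours = hours[i] * rep(as.numeric(spec$daypart_mix),
                                      n_active),
      qualification_level = ql[i],
      x_km = NA_real_, y_km = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(generate_visits(generator_spec(weeks = 1L, m_a = 0,
                                          team_id = spec$team_id,
                                          warmup = 0L), seed = seed))
  }
  out <- out[out$duration_hours > 0, , drop = FALSE]
  validate_visits(out, n_levels = length(spec$ql_mix))
}

#' Monte-Carlo simulation of stationary weekly demand
#'
#' Direct simulation of the infinite-server demand sum: for each lag
#' `u = 1..horizon`, a batch of new cases arrives with the model's count
#' distribution, each survives `u` weeks with probability `S(u)` and, if
#' active, contributes an independent gamma-distributed weekly demand with
#' mean `m_g` and variance `var_g`. Summing over lags gives one stationary
#' draw per replication. This is the independent oracle for the
#' closed-form stationary moments; the lag horizon is the model's LoS tail
#' horizon, with a warning when mass `> 1e-3` survives past it.
#'
#' @param model a [team_demand] with a LoS tail (a geometric tail with the
#'   model's implied mean is substituted otherwise).
#' @param reps number of replications.
#' @param seed RNG seed.
#' @return numeric vector of `reps` weekly demand draws (hours).
#' @export
simulate_stationary_demand <- function(model, reps = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tail <- model$los
  if (is.null(tail)) tail <- los_tail_geometric(model$m_s)
  horizon <- los_horizon(tail)
  if (los_surv(tail, horizon) > 1e-3) {
    warning("LoS tail mass beyond the horizon exceeds 1e-3; ",
            "stationary draws will be biased low")
  }
  vmr_a <- model$var_a / model$m_a
  vmr_g <- if (model$m_g > 0) model$var_g / model$m_g else 0
  shape0 <- if (vmr_g > 0) model$m_g / vmr_g else NA_real_
  total <- numeric(reps)
  for (u in seq_len(horizon)) {
    s_u <- los_surv(tail, u)
    if (s_u == 0) break
    arrivals <- draw_arrival_counts(reps, model$m_a, vmr_a)
    survivors <- stats::rbinom(reps, arrivals, s_u)
    total <- total + if (vmr_g > 0) {
      # sum of k iid Gamma(shape0, scale) draws is Gamma(k * shape0, scale)
      stats::rgamma(reps, shape = shape0 * survivors, scale = vmr_g)
    } else {
      survivors * model$m_g
    }
  }
  total
}

#' Monte-Carlo simulation of demand t weeks ahead
#'
#' Oracle for the transient moments: each replication thins the current
#' cases by the remaining-LoS tail at `t` and adds the surviving demand of
#' the arrival batches of the intervening weeks.
#'
#' @inheritParams simulate_stationary_demand
#' @param load a [current_load()] (or `NULL` for an empty system).
#' @param t forecast horizon in whole weeks.
#' @return numeric vector of `reps` demand draws at week `t`.
#' @export
simulate_transient_demand <- function(model, load = NULL, t, reps = 5000,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- as.integer(t)
  if (t < 0L) stop("t must be non-negative")
  tail <- model$los
  if (is.null(tail)) tail <- los_tail_geometric(model$m_s)
  b_hat <- if (is.null(load)) numeric(0) else load$case_hours
  r_tail <- if (!is.null(load) && !is.null(load$remaining_tail)) {
    load$remaining_tail
  } else {
    stationary_excess(tail)
  }
  vmr_a <- model$var_a / model$m_a
  vmr_g <- if (model$m_g > 0) model$var_g / model$m_g else 0
  shape0 <- if (vmr_g > 0) model$m_g / vmr_g else NA_real_
  total <- numeric(reps)
  if (length(b_hat) > 0L) {
    sr <- los_surv(r_tail, t)
    keep <- matrix(stats::rbinom(reps * length(b_hat), 1L, sr),
                   nrow = reps)
    total <- total + as.numeric(keep %*% b_hat)
  }
  for (u in seq_len(t)) {
    s_u <- los_surv(tail, u)
    arrivals <- draw_arrival_counts(reps, model$m_a, vmr_a)
    survivors <- stats::rbinom(reps, arrivals, s_u)
    total <- total + if (vmr_g > 0) {
      stats::rgamma(reps, shape = shape0 * survivors, scale = vmr_g)
    } else {
      survivors * model$m_g
    }
  }
  total
}
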