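#' Week indices for calendar dates
#'
#' Weeks run Monday to Sunday; the index is 0-based from the week containing
#' the earliest date of the observation window.
#'
#' @param dates a `Date` vector.
#' @param origin optional `Date` defining week 0; defaults to the Monday of
#'   the week containing `min(dates)`.
#' @keywords internal
week_index <- function(dates, origin = NULL) {
  if (is.null(origin)) origin <- week_origin(dates)
  as.integer(floor(as.numeric(dates - origin) / 7))
}

week_origin <- function(dates) {
  d0 <- min(dates)
  # as.POSIXlt wday: 0 = Sunday; shift to Monday-start weeks
  d0 - ((as.POSIXlt(d0)$wday + 6L) %% 7L)
}

#' Build cases from visit records
#'
#' A case is a period of regular care for one client at one qualification
#' level; consecutive visits of the same (client, level) pair belong to the
#' same case as long as the gap between them does not exceed `gap_days`
#' (default 30). One client can hold several simultaneous cases at different
#' levels. Cases active in the first observed week are flagged `left_open`
#' (their true start is unknown); cases active in the last observed week are
#' flagged `right_censored`.
#'
#' @param visits a visit data frame from [read_visits()] or
#'   [generate_visits()].
#' @param gap_days maximum gap in days between visits of one case.
#' @return a data frame with one row per case: identifiers, `start_week`,
#'   `end_week`, `los` (in weeks, `end_week - start_week + 1`), `left_open`,
#'   `right_censored`, `total_hours`, and a `weekly_hours` list column of
#'   hours per active week. The observation window (number of weeks) is
#'   attached as attribute `n_weeks`.
#' @export
build_cases <- function(visits, gap_days = 30) {
  empty <- data.frame(client_id = character(0), team_id = character(0),
                      qualification_level = integer(0),
                      start_week = integer(0), end_week = integer(0),
                      los = integer(0), left_open = logical(0),
                      right_censored = logical(0), total_hours = numeric(0))
  if (nrow(visits) == 0L) {
    empty$weekly_hours <- list()
    attr(empty, "n_weeks") <- 0L
    return(empty)
  }
  origin <- week_origin(visits$date)
  week <- week_index(visits$date, origin)
  n_weeks <- max(week) + 1L
  key <- paste(visits$client_id, visits$qualification_level, sep = "\r")
  rows <- lapply(split(seq_len(nrow(visits)), key), function(idx) {
    v <- visits[idx, , drop = FALSE]
    ord <- order(v$date)
    v <- v[ord, , drop = FALSE]
    w <- week[idx][ord]
    gap <- c(0, as.numeric(diff(v$date)))
    case_id <- cumsum(gap > gap_days)
    lapply(split(seq_len(nrow(v)), case_id), function(i) {
      vi <- v[i, , drop = FALSE]
      wi <- w[i]
      span <- min(wi):max(wi)
      hours <- vapply(span, function(s) sum(vi$duration_hours[wi == s]),
                      numeric(1))
      list(client_id = vi$client_id[1L], team_id = vi$team_id[1L],
           qualification_level = vi$qualification_level[1L],
           start_week = min(wi), end_week = max(wi),
           hours = hours)
    })
  })
  rows <- unlist(rows, recursive = FALSE)
  cases <- data.frame(
    client_id = vapply(rows, `[[`, character(1), "client_id"),
    team_id = vapply(rows, `[[`, character(1), "team_id"),
    qualification_level = vapply(rows, `[[`, integer(1),
                                 "qualification_level"),
    start_week = vapply(rows, `[[`, integer(1), "start_week"),
    end_week = vapply(rows, `[[`, integer(1), "end_week"),
    stringsAsFactors = FALSE
  )
  cases$los <- cases$end_week - cases$start_week + 1L
  cases$left_open <- cases$start_week == 0L
  cases$right_censored <- cases$end_week == n_weeks - 1L
  cases$total_hours <- vapply(rows, function(r) sum(r$hours), numeric(1))
  cases$weekly_hours <- I(lapply(rows, `[[`, "hours"))
  rownames(cases) <- NULL
  attr(cases, "n_weeks") <- n_weeks
  cases
}

#' Weekly demand series for one team
#'
#' @inheritParams build_cases
#' @param team_id team identifier.
#' @return numeric vector of total visit hours per week spanning the
#'   observation window of `visits` (weeks without visits contribute 0).
#' @export
weekly_demand_series <- function(visits, team_id) {
  if (nrow(visits) == 0L) return(numeric(0))
  week <- week_index(visits$date)
  n_weeks <- max(week) + 1L
  sel <- visits$team_id == team_id
  if (!any(sel)) {
    warning("no visits for team ", team_id)
    return(numeric(0))
  }
  series <- numeric(n_weeks)
  agg <- tapply(visits$duration_hours[sel], week[sel], sum)
  series[as.integer(names(agg)) + 1L] <- agg
  series
}

moment_summary <- function(x) {
  m <- mean(x)
  v <- stats::var(x)
  list(mean = m, variance = v, vmr = if (m > 0) v / m else NA_real_)
}

#' Arrival moments: weekly counts of new cases
#'
#' Left-open cases are excluded from start counts (their start week is not
#' observed). The variance is the unbiased sample variance over the weekly
#' counts of the observation window.
#'
#' @param cases case data frame from [build_cases()].
#' @return list with `mean`, `variance` and `vmr` of new cases per week.
#' @export
arrival_stats <- function(cases) {
  n_weeks <- attr(cases, "n_weeks")
  if (is.null(n_weeks) || n_weeks < 2L) {
    stop("observation window must span at least 2 weeks")
  }
  starts <- cases$start_week[!cases$left_open]
  counts <- tabulate(starts + 1L, nbins = n_weeks)
  moment_summary(counts)
}

#' Case-demand moments: hours per active case-week
#'
#' Moments are taken over all (case, active week) observations, i.e. each
#' week a case is active contributes one observation of its hours that week.
#'
#' @inheritParams arrival_stats
#' @export
case_demand_stats <- function(cases) {
  hours <- unlist(cases$weekly_hours)
  if (length(hours) == 0L) stop("no active case-weeks")
  moment_summary(hours)
}

#' Kaplan-Meier survival of the length of stay
#'
#' The LoS of a case is `end_week - start_week + 1` weeks (a case observed in
#' one week has LoS 1). Right-censored cases (still active in the last
#' observed week) enter as censored at their observed duration; cases with
#' an unobserved start (`left_open`) are dropped by default since their
#' duration is unknown. The product-limit estimator is computed with
#' [survival::survfit()] and returned as a [los_tail], together with the
#' at-risk/event table as attribute `km_table`.
#'
#' @inheritParams arrival_stats
#' @param drop_left_open drop cases whose start precedes the window.
#' @return a [los_tail] with `P(S >= t)` on `t = 0..max(LoS)`.
#' @export
km_survival <- function(cases, drop_left_open = TRUE) {
  if (drop_left_open) cases <- cases[!cases$left_open, , drop = FALSE]
  if (nrow(cases) == 0L) stop("no usable cases for LoS estimation")
  time <- cases$los
  event <- as.integer(!cases$right_censored)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  horizon <- max(time)
  # survfit gives P(S > t) at t; the tail needs P(S >= t) = P(S > t - 1)
  step <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  tail <- los_tail(c(1, step((1:horizon) - 1)))
  attr(tail, "km_table") <- data.frame(
    t = fit$time, surv = fit$surv, at_risk = fit$n.risk, events = fit$n.event
  )
  tail
}

#' Weibull fit to a Kaplan-Meier tail
#'
#' Fits a Weibull survival curve `S(t) = exp(-(t/scale)^shape)` to the
#' non-parametric tail by (weighted) least squares on the linearising
#' transform `log(-log S(t)) = shape * log t - shape * log scale`, a curve
#' fit to the estimated survival points rather than a likelihood fit to the
#' raw durations. Weights default to the at-risk counts when the tail was
#' produced by [km_survival()], so well-supported early points dominate.
#'
#' @param tail a [los_tail].
#' @param weights optional per-point weights on `t = 1..horizon`.
#' @return list with `shape`, `scale`, and the fitted `sse`.
#' @export
weibull_fit <- function(tail, weights = NULL) {
  t <- seq_len(los_horizon(tail))
  s <- tail$surv[-1L]
  keep <- s > 0 & s < 1
  if (sum(keep) < 3L) stop("need at least 3 tail points with 0 < S < 1")
  if (is.null(weights)) {
    km <- attr(tail, "km_table")
    weights <- if (!is.null(km)) {
      stats::approx(c(0, km$t), c(km$at_risk[1L], km$at_risk), xout = t,
                    method = "constant", rule = 2)$y
    } else rep(1, length(t))
  }
  x <- log(t[keep])
  y <- log(-log(s[keep]))
  if (stats::var(x) == 0) stop("degenerate tail: all mass at one duration")
  fit <- stats::lm.wfit(cbind(1, x), y, w = weights[keep])
  shape <- unname(fit$coefficients[2L])
  scale <- exp(-unname(fit$coefficients[1L]) / shape)
  if (!is.finite(shape) || shape <= 0 || !is.finite(scale) || scale <= 0) {
    stop("Weibull fit failed: non-positive shape or scale")
  }
  pred <- exp(-((t[keep] / scale)^shape))
  list(shape = shape, scale = scale, sse = sum((pred - s[keep])^2))
}

#' Implied mean length of stay
#'
#' In stationarity the mean weekly demand factorises as
#' `rho = m_a * m_s * m_g`, so the mean LoS implied by observed demand is
#' `m_s = mean_demand / (m_a * m_g)`. This sidesteps the unreliable direct
#' estimation of the LoS tail beyond the observation horizon.
#'
#' @param mean_demand mean weekly demand in hours.
#' @param m_a mean new cases per week.
#' @param m_g mean hours per case-week.
#' @return implied mean LoS in weeks.
#' @export
implied_ms <- function(mean_demand, m_a, m_g) {
  if (any(m_a * m_g <= 0)) stop("m_a * m_g must be positive")
  mean_demand / (m_a * m_g)
}

#' Day-part and weekend demand profile
#'
#' @inheritParams build_cases
#' @return list with duration-weighted fractions `morning`, `afternoon`,
#'   `evening` (summing to 1) and `weekend_ratio`, the mean demand on a
#'   weekend day divided by the mean demand on a weekday.
#' @export
daypart_fractions <- function(visits) {
  if (nrow(visits) == 0L) stop("no visits")
  total <- sum(visits$duration_hours)
  frac <- function(part) {
    sum(visits$duration_hours[visits$day_part == part]) / total
  }
  wday <- (as.POSIXlt(visits$date)$wday + 6L) %% 7L  # 0 = Monday
  weekend <- wday >= 5L
  days <- as.numeric(max(visits$date) - min(visits$date)) + 1
  # per-day means over the window, assuming ~5/7 weekdays and 2/7 weekend days
  wk_mean <- sum(visits$duration_hours[!weekend]) / (days * 5 / 7)
  we_mean <- sum(visits$duration_hours[weekend]) / (days * 2 / 7)
  list(morning = frac("morning"), afternoon = frac("afternoon"),
       evening = frac("evening"),
       weekend_ratio = if (wk_mean > 0) we_mean / wk_mean else NA_real_)
}

#' Estimate team parameters from visit records
#'
#' Composes the estimators above into one row per team: mean weekly demand
#' from the weekly series, arrival moments from case starts, case-demand
#' moments from active case-weeks, the LoS Gini from the Kaplan-Meier tail,
#' and the implied mean LoS.
#'
#' @inheritParams build_cases
#' @param drop_left_open passed to [km_survival()].
#' @return a team-parameter data frame in the [load_team_parameters()]
#'   schema.
#' @export
team_parameter_table <- function(visits, gap_days = 30,
                                 drop_left_open = TRUE) {
  if (nrow(visits) == 0L) stop("no visits")
  teams <- sort(unique(visits$team_id))
  rows <- lapply(teams, function(id) {
    v <- visits[visits$team_id == id, , drop = FALSE]
    cases <- build_cases(v, gap_days = gap_days)
    series <- weekly_demand_series(v, id)
    arr <- arrival_stats(cases)
    dem <- case_demand_stats(cases)
    tail <- if (drop_left_open && any(!cases$left_open)) {
      km_survival(cases, drop_left_open = TRUE)
    } else {
      # degenerate window: every case is left-open, fall back to treating
      # observed durations as complete (biased, but keeps the row usable)
      if (drop_left_open) {
        warning("team ", id, ": all cases are left-open; ",
                "LoS estimated from observed durations")
      }
      km_survival(cases, drop_left_open = FALSE)
    }
    data.frame(
      team_id = id,
      mean_demand = mean(series),
      m_a = arr$mean, vmr_a = arr$vmr,
      m_g = dem$mean, vmr_g = dem$vmr,
      gini_s = gini_from_tail(tail),
      m_s_implied = if (arr$mean > 0) {
        implied_ms(mean(series), arr$mean, dem$mean)
      } else NA_real_,  # no observed starts: degenerate but well-formed
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
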