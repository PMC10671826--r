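#' Read a visit-record CSV
#'
#' The canonical visit format is a UTF-8 CSV with a header row and columns
#' `client_id, team_id, date, day_part, duration_hours, qualification_level`
#' and optional planar coordinates `x_km, y_km`. Dates are ISO 8601 calendar
#' dates; durations are hours; `day_part` is one of `morning`, `afternoon`,
#' `evening`; qualification levels are integer ranks (1 = PV niveau 2+,
#' 2 = PV niveau 3, 3 = VP niveau 3 in the three-level Dutch HHC hierarchy).
#'
#' @param path path to the CSV file.
#' @param n_levels number of qualification levels declared for validation.
#' @return a data frame of visit records sorted by
#'   (`client_id`, `qualification_level`, `date`).
#' @export
read_visits <- function(path, n_levels = 3L) {
  if (!file.exists(path)) stop("visit file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("client_id", "team_id", "date", "day_part",
                "duration_hours", "qualification_level")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("visit file is missing column(s): ", paste(missing, collapse = ", "))
  }
  validate_visits(build_visit_frame(raw), n_levels = n_levels)
}

build_visit_frame <- function(raw) {
  data.frame(
    client_id = raw$client_id,
    team_id = raw$team_id,
    date = as.Date(raw$date, format = "%Y-%m-%d"),
    day_part = raw$day_part,
    duration_hours = suppressWarnings(as.numeric(raw$duration_hours)),
    qualification_level = suppressWarnings(as.integer(raw$qualification_level)),
    x_km = if ("x_km" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$x_km))
    } else rep(NA_real_, nrow(raw)),
    y_km = if ("y_km" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$y_km))
    } else rep(NA_real_, nrow(raw)),
    stringsAsFactors = FALSE
  )
}

#' Validate and sort a visit data frame
#'
#' Collects row-level problems (unparseable dates or durations, non-positive
#' durations, unknown day parts, qualification levels outside `1..n_levels`)
#' and reports them with their line numbers (header = line 1).
#'
#' @param visits data frame in the [read_visits()] schema.
#' @inheritParams read_visits
#' @export
validate_visits <- function(visits, n_levels = 3L) {
  dayparts <- c("morning", "afternoon", "evening")
  problems <- character(0)
  bad <- function(which, what) {
    if (any(which)) {
      sprintf("line %d: %s", which(which) + 1L, what)
    } else character(0)
  }
  problems <- c(
    bad(is.na(visits$date), "unparseable date"),
    bad(is.na(visits$duration_hours), "unparseable duration"),
    bad(!is.na(visits$duration_hours) & visits$duration_hours <= 0,
        "duration must be positive"),
    bad(!visits$day_part %in% dayparts,
        "day_part must be morning/afternoon/evening"),
    bad(is.na(visits$qualification_level) |
          !visits$qualification_level %in% seq_len(n_levels),
        sprintf("qualification_level must be an integer in 1..%d", n_levels))
  )
  if (length(problems)) {
    stop("invalid visit rows:\n  ", paste(problems, collapse = "\n  "))
  }
  visits <- visits[order(visits$client_id, visits$qualification_level,
                         visits$date), , drop = FALSE]
  rownames(visits) <- NULL
  visits
}

#' @rdname read_visits
#' @param visits a visit data frame.
#' @export
write_visits <- function(visits, path) {
  out <- visits
  out$date <- format(out$date, "%Y-%m-%d")
  if (all(is.na(out$x_km))) out$x_km <- out$y_km <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Reference parameter set: nine anonymized HHC teams from a Dutch provider,
# selected for merging analysis. mean_demand in hours/week; m_a new
# cases/week; vmr_a the variance-to-mean ratio of weekly case arrivals;
# m_g mean hours/week per case; vmr_g its VMR; gini_s the LoS Gini;
# m_s_implied = mean_demand / (m_a * m_g) in weeks.
builtin_teams <- function() {
  data.frame(
    team_id = c("2", "5", "9", "11", "15", "38", "39", "40", "41"),
    mean_demand = c(183.46, 132.30, 206.06, 125.41, 211.13, 268.71, 159.07,
                    265.53, 290.75),
    m_a = c(1.99, 1.58, 3.69, 2.43, 3.06, 3.64, 3.49, 3.04, 5.33),
    vmr_a = c(1.10, 1.30, 1.12, 1.64, 1.28, 1.78, 1.68, 1.19, 0.90),
    m_g = c(3.61, 3.00, 3.24, 3.06, 2.78, 3.82, 2.68, 3.60, 3.31),
    vmr_g = c(3.18, 3.72, 3.13, 1.97, 2.15, 3.23, 2.51, 3.50, 3.44),
    gini_s = c(0.79, 0.74, 0.78, 0.79, 0.77, 0.81, 0.78, 0.75, 0.82),
    m_s_implied = c(25.50, 27.93, 17.25, 16.85, 24.81, 19.32, 17.03, 24.29,
                    16.49),
    stringsAsFactors = FALSE
  )
}

#' Load team-parameter tables
#'
#' Team parameters summarise one team's weekly demand process: mean demand
#' (hours/week), case arrival mean `m_a` and VMR, per-case weekly hours
#' `m_g` and VMR, the LoS Gini coefficient and the implied mean LoS
#' `m_s = mean_demand / (m_a * m_g)`. With `path = "builtin"` (the default)
#' the bundled nine-team reference set is returned.
#'
#' @param path path to a teams CSV in the schema
#'   `team_id, mean_demand, m_a, vmr_a, m_g, vmr_g, gini_s, m_s_implied`,
#'   or `"builtin"`.
#' @return a validated team-parameter data frame.
#' @export
load_team_parameters <- function(path = "builtin") {
  if (identical(path, "builtin")) {
    return(validate_team_parameters(builtin_teams()))
  }
  if (!file.exists(path)) stop("team parameter file not found: ", path)
  validate_team_parameters(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(team_id = "character"))
  )
}

#' @rdname load_team_parameters
#' @param teams a team-parameter data frame.
#' @export
validate_team_parameters <- function(teams) {
  required <- c("team_id", "mean_demand", "m_a", "vmr_a", "m_g", "vmr_g",
                "gini_s", "m_s_implied")
  missing <- setdiff(required, names(teams))
  if (length(missing)) {
    stop("team parameter table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  num <- teams[, setdiff(required, "team_id")]
  if (any(!vapply(num, is.numeric, logical(1))) || any(is.na(num))) {
    stop("team parameters must all be numeric and non-missing")
  }
  if (any(num <= 0)) stop("team parameters must all be positive")
  if (any(teams$gini_s >= 1)) stop("gini_s must lie in (0, 1)")
  rownames(teams) <- NULL
  teams
}

#' @rdname load_team_parameters
#' @export
write_team_parameters <- function(teams, path) {
  utils::write.csv(teams, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Policy configuration
#'
#' Reads a YAML config of the policy constants used across the models, or
#' returns the defaults: grade of service `gamma = 1`, presence probability
#' `p_present = 0.79`, skill-mix safety factor `eta_alpha = 2`, 20 direct
#' care hours per worker per week, contract shape `a = 1.5`, `b_ft = 8`,
#' `b_pt = 5` (4 h short shifts, 6 h long shifts, 32 h full-time and 20 h
#' part-time weeks), travel constants `k_l = 0.5`, `k_c = 2`, and objective
#' weights `lambda1 = lambda3 = lambda4 = 1`, `lambda6 = 1e-3` with
#' effective-capacity threshold `l_threshold = 0.6`.
#'
#' @param path optional YAML file; entries override the defaults.
#' @return a named list of policy constants.
#' @export
read_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    config <- utils::modifyList(config, user)
  }
  config
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(
    gamma = 1,
    p_present = 0.79,
    eta_alpha = 2,
    hours_per_worker = 20,
    contract = list(a = 1.5, b_ft = 8, b_pt = 5),
    travel = list(k_l = 0.5, k_c = 2),
    objective = list(lambda1 = 1, lambda3 = 1, lambda4 = 1, lambda6 = 1e-3,
                     l_threshold = 0.6)
  )
}
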