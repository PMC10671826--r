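#' Effective-capacity (availability) model
#'
#' Of `M` scheduled care workers, each is present in the planning period
#' independently with probability `p` (the complement covering sick leave
#' and holidays; the default 0.79 corresponds to 12.5% holiday/leave plus
#' 8.5% sick leave). The number present is Binomial(`M`, `p`) and the
#' effective capacity is the fraction present, `P = Mtilde / M`. Non-integer
#' `M` is allowed: the distribution is then evaluated through the
#' incomplete-beta representation of the binomial CDF.
#'
#' @param team_size number of scheduled workers `M` (> 0, non-integer
#'   allowed).
#' @param p_present per-worker presence probability in (0, 1).
#' @param weekly_hours optional per-worker contracted hours, for the
#'   hours-weighted variance of Remark-style heterogeneous teams.
#' @return an object of class `availability_model`.
#' @export
availability_model <- function(team_size, p_present = 0.79,
                               weekly_hours = NULL) {
  if (team_size <= 0) stop("team_size must be positive")
  if (p_present <= 0 || p_present >= 1) stop("p_present must be in (0, 1)")
  if (!is.null(weekly_hours) && any(weekly_hours <= 0)) {
    stop("weekly_hours must be positive")
  }
  structure(list(team_size = team_size, p_present = p_present,
                 weekly_hours = weekly_hours),
            class = "availability_model")
}

#' Mean and variance of the effective capacity
#'
#' `E[P] = p` and `Var(P) = p(1-p)/M`; with heterogeneous contracted hours
#' `w_i` the hours-weighted capacity has variance
#' `p(1-p) * sum(w_i^2) / (sum w_i)^2`. The standard deviation shrinks as
#' `1/sqrt(M)`: small teams are far more exposed to availability dips.
#'
#' @param m an [availability_model].
#' @return list with `mean` and `variance` of `P`.
#' @export
effective_capacity_moments <- function(m) {
  p <- m$p_present
  v <- if (is.null(m$weekly_hours)) {
    p * (1 - p) / m$team_size
  } else {
    p * (1 - p) * sum(m$weekly_hours^2) / sum(m$weekly_hours)^2
  }
  list(mean = p, variance = v)
}

#' Probability that effective capacity falls below a threshold
#'
#' `P(P <= l) = P(Mtilde <= l * M)`, evaluated through the regularized
#' incomplete beta function, which extends the binomial CDF continuously to
#' non-integer team sizes:
#' `P(P <= l) = B(lM + 1, (1 - l)M, p) / B(lM + 1, (1 - l)M)` with
#' `B(x, y, p)` the beta integral over `[p, 1]`. At integer `l * M` this is
#' exactly the binomial CDF.
#'
#' @inheritParams effective_capacity_moments
#' @param l capacity threshold as a fraction in `[0, 1]`.
#' @return probability in `[0, 1]`.
#' @export
prob_effective_capacity_below <- function(m, l) {
  if (any(l < 0 | l > 1)) stop("l must lie in [0, 1]")
  M <- m$team_size
  stats::pbeta(m$p_present, l * M + 1, (1 - l) * M, lower.tail = FALSE)
}

#' Contract-mix model for avoiding split shifts
#'
#' Shifts are either short (one day part — morning, afternoon or evening,
#' the time unit) or long (a short shift extended into the afternoon, of
#' relative length `a > 1`). A full-time week is worth `b_ft >= 5` short
#' shifts, a part-time week `b_pt` in (0, 5]; nobody works more than 5 days
#' a week. `f2` is the fraction of work fixed in the afternoon and `f0` the
#' fraction schedulable at any time (e.g. administration). Defaults
#' (`a = 1.5`, `b_ft = 8`, `b_pt = 5`) correspond to 4 h short shifts, 6 h
#' long shifts, 32 h full-time and 20 h part-time contracts.
#'
#' @param a long-to-short shift length ratio (> 1).
#' @param b_ft short-shift equivalents of a full-time week (>= 5).
#' @param b_pt short-shift equivalents of a part-time week, in (0, 5].
#' @param f0 fraction of work schedulable at any moment.
#' @param f2 fraction of work fixed in the afternoon.
#' @return an object of class `contract_model`.
#' @export
contract_model <- function(a = 1.5, b_ft = 8, b_pt = 5, f0 = 0, f2 = 0.073) {
  if (a <= 1) stop("a must exceed 1")
  if (b_ft < 5) stop("b_ft must be at least 5")
  if (b_pt <= 0 || b_pt > 5) stop("b_pt must lie in (0, 5]")
  if (f0 < 0 || f2 < 0 || f0 + f2 > 1) stop("need f0, f2 >= 0, f0 + f2 <= 1")
  structure(list(a = a, b_ft = b_ft, b_pt = b_pt, f0 = f0, f2 = f2),
            class = "contract_model")
}

#' Can every contract be full time without split shifts?
#'
#' All contracts can be full time when enough work is schedulable in the
#' afternoon or at any time:
#' `f0 + f2 >= min((b_ft - 5) / (b_ft - b_pt), 1 - 1/a)`. When `b_ft` equals
#' `b_pt` the first branch is vacuous and only `1 - 1/a` applies.
#'
#' @param c a [contract_model].
#' @return logical.
#' @export
full_time_all_feasible <- function(c) {
  thr <- if (c$b_ft > c$b_pt) {
    min((c$b_ft - 5) / (c$b_ft - c$b_pt), 1 - 1 / c$a)
  } else {
    1 - 1 / c$a
  }
  c$f0 + c$f2 >= thr
}

#' Maximum fraction of full-time contracts avoiding split shifts
#'
#' When not all contracts can be full time, the binding bound is
#' `p_FT <= (f0 + f2) * b_pt / (b_ft - 5 + (b_pt - b_ft)(f0 + f2))`,
#' obtained by balancing the work that must land in short shifts against
#' the short shifts the contract mix can supply. The result is clamped to
#' `[0, 1]`; a non-positive denominator means the constraint is vacuous and
#' 1 is returned.
#'
#' @inheritParams full_time_all_feasible
#' @return upper bound on the full-time fraction, in `[0, 1]`.
#' @export
max_full_time_fraction <- function(c) {
  if (full_time_all_feasible(c)) return(1)
  f <- c$f0 + c$f2
  den <- c$b_ft - 5 + (c$b_pt - c$b_ft) * f
  if (den <= 0) return(1)
  min(max(f * c$b_pt / den, 0), 1)
}

#' Afternoon/flexible work needed for a target full-time fraction
#'
#' Closed-form inversion of the full-time bound: the smallest `f0 + f2`
#' such that [max_full_time_fraction()] reaches `target_p_ft`:
#' `f = target * (b_ft - 5) / (b_pt + target * (b_ft - b_pt))`, capped at
#' the full-feasibility threshold of [full_time_all_feasible()] (beyond it
#' every contract can already be full time).
#'
#' @inheritParams full_time_all_feasible
#' @param target_p_ft desired full-time fraction in (0, 1].
#' @return required `f0 + f2` fraction.
#' @export
required_afternoon_fraction <- function(c, target_p_ft) {
  if (target_p_ft < 0 || target_p_ft > 1) stop("target must lie in [0, 1]")
  if (target_p_ft == 0) return(0)
  f <- target_p_ft * (c$b_ft - 5) /
    (c$b_pt + target_p_ft * (c$b_ft - c$b_pt))
  thr <- if (c$b_ft > c$b_pt) {
    min((c$b_ft - 5) / (c$b_ft - c$b_pt), 1 - 1 / c$a)
  } else {
    1 - 1 / c$a
  }
  min(f, thr)
}

#' Interaction counts: team manageability
#'
#' With every pair of team members able to communicate, a team of `M`
#' members has `M(M-1)/2` lines of communication — complexity grows
#' quadratically with team size.
#'
#' @param M team size (positive integer).
#' @return number of pairwise interactions.
#' @export
interactions_complete <- function(M) {
  if (any(M < 1 | M != round(M))) stop("M must be a positive integer")
  M * (M - 1) / 2
}

#' Sub-team structure with a mediator
#'
#' @param subteam_sizes sizes `M_j` of the sub-teams (each >= 1).
#' @param mediator whether a central mediator connects the sub-teams
#'   (required by the interaction count below).
#' @return an object of class `team_structure`.
#' @export
team_structure <- function(subteam_sizes, mediator = TRUE) {
  if (length(subteam_sizes) == 0L) stop("empty team structure")
  if (any(subteam_sizes < 1)) stop("sub-team sizes must be at least 1")
  structure(list(subteam_sizes = subteam_sizes, mediator = mediator),
            class = "team_structure")
}

#' Interactions under a mediated sub-team split
#'
#' Splitting `M` members into sub-teams that only communicate internally,
#' plus one mediator linked to everyone, gives
#' `M + sum_j M_j (M_j - 1) / 2` interactions. For an equal split into `k`
#' parts this is `M/2 + M^2/(2k)` (fractional sub-team sizes allowed in
#' that form, see [interactions_equal_split()]), so the quadratic term —
#' and asymptotically the whole count — shrinks by a factor `k`.
#'
#' @param ts a [team_structure] with `mediator = TRUE`.
#' @return number of interactions.
#' @export
interactions_subteams <- function(ts) {
  if (!isTRUE(ts$mediator)) {
    stop("the sub-team interaction count assumes a mediator")
  }
  M <- sum(ts$subteam_sizes)
  M + sum(ts$subteam_sizes * (ts$subteam_sizes - 1) / 2)
}

#' @rdname interactions_subteams
#' @param M total team size (fractional allowed).
#' @param k number of equal sub-teams.
#' @export
interactions_equal_split <- function(M, k) {
  if (M <= 0 || k < 1) stop("need M > 0 and k >= 1")
  M / 2 + M^2 / (2 * k)
}
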