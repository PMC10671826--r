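# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Product-limit survival from a hand-rolled at-risk table.
# Returns P(S >= t) for integer t, given durations and event indicators.
km_oracle <- function(time, event, t) {
  event_times <- sort(unique(time[event == 1]))
  vapply(t, function(tt) {
    surv <- 1
    for (u in event_times[event_times <= tt - 1]) {
      n_u <- sum(time >= u)
      d_u <- sum(time == u & event == 1)
      surv <- surv * (1 - d_u / n_u)
    }
    surv
  }, numeric(1))
}

# Exact binomial CDF P(Binomial(M, p) <= k) by direct summation.
binom_cdf_oracle <- function(k, M, p) {
  sum(choose(M, 0:k) * p^(0:k) * (1 - p)^(M - (0:k)))
}

# Brute-force skill-mix optimum for small K: enumerate staffed/unstaffed
# patterns; per pattern place capacities at their backward-recursion lower
# bounds and, if unstaffed levels are uncovered, search the single lift
# (over every candidate staffed higher level) that restores feasibility at
# minimum cost. Cost landscape per pattern is piecewise 1-D by the
# dominance of lifting low-cost levels, so this is exact for K <= 3.
skill_mix_oracle <- function(mu, sigma, cost, ell, eta) {
  K <- length(mu)
  need <- mu + eta * sigma
  excess_norm <- function(C, m, s) {
    if (s == 0) return(max(C - m, 0))
    (C - m) * pnorm((C - m) / s) + s * dnorm((C - m) / s)
  }
  chain <- function(active, lift_level = 0, delta = 0) {
    C <- numeric(K); e <- numeric(K); ek <- 0
    for (k in K:1) {
      e[k] <- ek
      if (active[k]) {
        C[k] <- max(ell, need[k] - ek, 0) +
          if (k == lift_level) delta else 0
      }
      ek <- excess_norm(C[k] + ek, mu[k], sigma[k])
    }
    list(C = C, e = e)
  }
  best_cost <- Inf; best <- NULL
  for (pattern in 0:(2^K - 1)) {
    active <- as.logical(bitwAnd(pattern, 2^(0:(K - 1))))
    base <- chain(active)
    slack <- base$C + base$e - need
    if (all(slack > -1e-9)) {
      cst <- sum(cost * base$C)
      if (cst < best_cost) { best_cost <- cst; best <- base }
      next
    }
    viol <- which(slack < -1e-9)
    for (j in which(active)) {
      if (j <= max(viol)) next  # lifts only reach levels below j
      worst <- function(delta) {
        ch <- chain(active, j, delta)
        min((ch$C + ch$e - need)[viol])
      }
      hi <- sum(need) + K * ell + 10
      while (worst(hi) < 0 && hi < 1e12) hi <- hi * 4
      if (worst(hi) < 0) next
      delta <- uniroot(worst, c(0, hi), tol = 1e-11)$root
      ch <- chain(active, j, delta)
      cst <- sum(cost * ch$C)
      if (cst < best_cost) { best_cost <- cst; best <- ch }
    }
  }
  list(cost = best_cost, capacity = if (is.null(best)) NULL else best$C)
}

# Bootstrap standard error of a statistic over resampled units.
boot_se <- function(units, stat, B = 120, seed = 99) {
  set.seed(seed)
  n <- length(units)
  reps <- vapply(seq_len(B), function(b) {
    stat(units[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  stats::sd(reps)
}

# Small well-formed visit CSV written to a temp file.
write_visit_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("client_id,team_id,date,day_part,duration_hours,qualification_level",
               lines), path)
  path
}
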