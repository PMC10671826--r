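test_that("the generator is deterministic under a seed and respects m_a = 0", {
  spec <- generator_spec(weeks = 30, warmup = 40)
  a <- generate_visits(spec, seed = 3)
  b <- generate_visits(spec, seed = 3)
  expect_identical(a, b)
  expect_gt(nrow(a), 0)
  c <- generate_visits(spec, seed = 4)
  expect_false(identical(a, c))

  empty <- generate_visits(generator_spec(weeks = 5, m_a = 0, warmup = 0),
                           seed = 1)
  expect_equal(nrow(empty), 0L)

  # byte-identical CSV round trip under the same seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_visits(generate_visits(spec, seed = 3), f1)
  write_visits(generate_visits(spec, seed = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("estimators recover the generator's parameters within 3 SE", {
  spec <- generator_spec(weeks = 300)
  visits <- generate_visits(spec, seed = 2026)
  cases <- build_cases(visits)

  # weekly demand mean: rho = m_a * m_s * m_g, accounting for serial
  # correlation of length ~ m_s weeks in the weekly series
  series <- weekly_demand_series(visits, "T1")
  rho_true <- 3.6 * 20 * 3.3
  n_eff <- length(series) / 20
  se_rho <- sd(series) / sqrt(n_eff)
  expect_lt(abs(mean(series) - rho_true), 3 * se_rho)

  # arrival moments over weekly start counts
  starts <- tabulate(cases$start_week[!cases$left_open] + 1L,
                     nbins = attr(cases, "n_weeks"))
  arr <- arrival_stats(cases)
  expect_lt(abs(arr$mean - 3.6), 3 * sd(starts) / sqrt(length(starts)))
  se_vmr_a <- boot_se(starts, function(x) var(x) / mean(x))
  expect_lt(abs(arr$vmr - 1.4), 3 * se_vmr_a)

  # case-demand moments (per case-week; B is constant within a case, so
  # bootstrap over cases, not case-weeks)
  cd <- case_demand_stats(cases)
  case_idx <- seq_len(nrow(cases))
  se_mg <- boot_se(case_idx, function(idx) {
    mean(unlist(cases$weekly_hours[idx]))
  })
  expect_lt(abs(cd$mean - 3.3), 3 * se_mg)
  se_vmr_g <- boot_se(case_idx, function(idx) {
    h <- unlist(cases$weekly_hours[idx]); var(h) / mean(h)
  })
  expect_lt(abs(cd$vmr - 4.0), 3 * se_vmr_g)

  # LoS Gini: geometric mean-20 truth is q/(1+q), q = 0.95
  tail <- km_survival(cases)
  q <- 1 - 1 / 20
  g_true <- q / (1 + q)
  usable <- which(!cases$left_open)
  se_g <- boot_se(usable, function(idx) {
    gini_from_tail(km_survival(cases[idx, , drop = FALSE]))
  }, B = 60)
  expect_lt(abs(gini_from_tail(tail) - g_true), 3 * se_g)

  # day-part and weekend profile (multinomial standard errors)
  dp <- daypart_fractions(visits)
  n <- nrow(visits)
  for (part in c("morning", "afternoon", "evening")) {
    truth <- c(morning = 0.686, afternoon = 0.073, evening = 0.242)[[part]] /
      1.001
    expect_lt(abs(dp[[part]] - truth), 3 * sqrt(truth * (1 - truth) / n) + 0.01)
  }
  expect_equal(dp$weekend_ratio, 0.807, tolerance = 0.05)

  # composed table: the implied mean LoS lands near the generator truth
  tab <- team_parameter_table(visits)
  expect_equal(tab$m_s_implied, 20, tolerance = 0.1)
})

test_that("simulated stationary demand matches the closed-form moments", {
  teams <- load_team_parameters()
  m5 <- as_team_demand(teams[teams$team_id == "5", ])
  m5$los <- los_tail_geometric(m5$m_s, horizon = 400)
  draws <- simulate_stationary_demand(m5, reps = 5000, seed = 31)
  sm <- stationary_moments(m5)
  se_mean <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - sm$mean), 3 * se_mean)
  expect_equal(sm$mean, 132.30, tolerance = 0.001)
  se_var <- sd((draws - mean(draws))^2) / sqrt(length(draws))
  expect_lt(abs(var(draws) - sm$variance), 3 * se_var)
  expect_equal(sm$variance, 6.954 * 132.38, tolerance = 0.01)

  # underdispersed arrivals (reference team 41 has VMR 0.90)
  m41 <- as_team_demand(teams[teams$team_id == "41", ])
  m41$los <- los_tail_geometric(m41$m_s, horizon = 400)
  d41 <- simulate_stationary_demand(m41, reps = 5000, seed = 32)
  sm41 <- stationary_moments(m41)
  expect_lt(abs(mean(d41) - sm41$mean), 3 * sd(d41) / sqrt(length(d41)))
  se41 <- sd((d41 - mean(d41))^2) / sqrt(length(d41))
  expect_lt(abs(var(d41) - sm41$variance), 3 * se41)

  # no randomness at all: N = m_a * L * m_g exactly
  det <- team_demand(m_a = 3, m_g = 2, vmr_a = 0, vmr_g = 0,
                     los = los_tail(c(1, rep(1, 5), 0)))
  dd <- simulate_stationary_demand(det, reps = 50, seed = 33)
  expect_true(all(dd == 3 * 5 * 2))

  # Poisson arrivals with unit demand: variance equals the mean
  pois <- team_demand(m_a = 6, m_g = 1, vmr_a = 1, vmr_g = 0,
                      los = los_tail_geometric(8, horizon = 300))
  dp <- simulate_stationary_demand(pois, reps = 5000, seed = 34)
  expect_equal(var(dp) / mean(dp), 1, tolerance = 0.1)

  short <- team_demand(m_a = 2, m_g = 1, vmr_a = 1, vmr_g = 0,
                       los = los_tail_geometric(50, horizon = 20))
  expect_warning(simulate_stationary_demand(short, reps = 10, seed = 1),
                 "biased")
})

test_that("simulated transient demand matches the transient moments", {
  tail <- los_tail_geometric(8, horizon = 250)
  m <- team_demand(m_a = 2.5, m_g = 3, vmr_a = 1.4, vmr_g = 4, los = tail)
  load <- current_load(c(4, 2, 6, 3))

  # t = 0: every current case survives, no arrivals yet
  d0 <- simulate_transient_demand(m, load, t = 0, reps = 200, seed = 41)
  expect_true(all(d0 == 15))

  for (t in c(3, 12)) {
    d <- simulate_transient_demand(m, load, t = t, reps = 10000, seed = 42 + t)
    tm <- transient_moments(m, load, t = t)
    se_mean <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - tm$mean), 3 * se_mean)
    se_var <- sd((d - mean(d))^2) / sqrt(length(d))
    expect_lt(abs(var(d) - tm$variance), 3 * se_var)
  }

  # empty load reduces to the arrivals-only term
  d <- simulate_transient_demand(m, NULL, t = 5, reps = 8000, seed = 51)
  tm <- transient_moments(m, NULL, t = 5)
  expect_lt(abs(mean(d) - tm$mean), 3 * sd(d) / sqrt(length(d)))
})
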