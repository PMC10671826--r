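make_visits <- function(dates, client = "a", ql = 1L, hours = 1,
                        team = "T1", part = "morning") {
  n <- length(dates)
  validate_visits(data.frame(
    client_id = rep_len(client, n), team_id = rep_len(team, n),
    date = as.Date(dates), day_part = rep_len(part, n),
    duration_hours = rep_len(hours, n),
    qualification_level = rep_len(ql, n),
    x_km = rep_len(NA_real_, n), y_km = rep_len(NA_real_, n),
    stringsAsFactors = FALSE))
}

test_that("the 30-day gap rule splits and joins cases as specified", {
  base <- as.Date("2021-03-01")
  v <- make_visits(base + c(0, 20, 60))
  cases <- build_cases(v)
  expect_equal(nrow(cases), 2L)

  v <- make_visits(base + c(0, 29, 58))
  expect_equal(nrow(build_cases(v)), 1L)

  # one client, two levels interleaved: one case per level
  v <- rbind(make_visits(base + c(0, 7), ql = 1L),
             make_visits(base + c(3, 10), ql = 3L))
  cases <- build_cases(validate_visits(v))
  expect_equal(nrow(cases), 2L)
  expect_setequal(cases$qualification_level, c(1L, 3L))

  expect_equal(nrow(build_cases(make_visits(as.Date(character(0))))), 0L)
})

test_that("censoring flags come from the observation window", {
  base <- as.Date("2021-03-01")  # a Monday
  v <- rbind(make_visits(base + c(0, 7), client = "early"),
             make_visits(base + c(21, 28), client = "late"),
             make_visits(base + 14, client = "mid"))
  cases <- build_cases(validate_visits(v))
  cases <- cases[order(cases$client_id), ]
  expect_equal(cases$left_open, c(TRUE, FALSE, FALSE))
  expect_equal(cases$right_censored, c(FALSE, TRUE, FALSE))
  expect_equal(cases$los, c(2L, 2L, 1L))
})

test_that("weekly series sums durations by week with explicit zeros", {
  base <- as.Date("2021-03-01")
  v <- rbind(make_visits(base, hours = 1.5),
             make_visits(base + 2, hours = 2.0, client = "b"),
             make_visits(base + 14, hours = 1.0, client = "c"),
             make_visits(base + 28, hours = 4.0, client = "d"))
  s <- weekly_demand_series(validate_visits(v), "T1")
  expect_equal(s, c(3.5, 0, 1.0, 0, 4.0))
  expect_warning(out <- weekly_demand_series(v, "nope"), "no visits")
  expect_length(out, 0L)
})

test_that("arrival and case-demand moments match hand arithmetic", {
  base <- as.Date("2021-03-01")
  v <- do.call(rbind, lapply(0:9, function(w) {
    make_visits(base + 7 * w, client = sprintf("c%d", w))
  }))
  cases <- build_cases(validate_visits(v))
  arr <- arrival_stats(cases)
  # the week-0 start is left-open by construction; 9 observed starts in 10 weeks
  expect_equal(arr$mean, 0.9)
  expect_equal(arr$vmr, var(c(0, rep(1, 9))) / 0.9)

  v2 <- rbind(make_visits(base + c(0, 7, 14), hours = 3),
              make_visits(base + 7, hours = 2, client = "b"),
              make_visits(base + 7, hours = 4, client = "c"))
  cd <- case_demand_stats(build_cases(validate_visits(v2)))
  expect_equal(cd$mean, 3)
  expect_equal(cd$variance, var(c(3, 3, 3, 2, 4)))
  expect_error(case_demand_stats(build_cases(make_visits(as.Date(character(0))))),
               "active")
})

test_that("Kaplan-Meier tail matches hand computation and brute force", {
  # complete durations {2, 3, 3, 5}
  cases <- data.frame(los = c(2L, 3L, 3L, 5L), left_open = FALSE,
                      right_censored = FALSE)
  tail <- km_survival(cases)
  expect_equal(los_surv(tail, 3), 3 / 4)
  expect_equal(los_surv(tail, 4), 1 / 4)
  # no censoring: KM equals the empirical survival everywhere
  emp <- vapply(0:6, function(t) mean(cases$los >= t), numeric(1))
  expect_equal(los_surv(tail, 0:6), emp)

  # censored at 3: cross-check against the hand-rolled at-risk table
  cases2 <- data.frame(los = c(2L, 3L, 4L), left_open = FALSE,
                       right_censored = c(FALSE, TRUE, FALSE))
  tail2 <- km_survival(cases2)
  expect_equal(los_surv(tail2, 0:5),
               km_oracle(cases2$los, c(1, 0, 1), 0:5))
  expect_equal(los_surv(tail2, 4), 2 / 3)

  # random censoring patterns against the oracle
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    los <- sample.int(12, n, replace = TRUE)
    cens <- runif(n) < 0.3
    cs <- data.frame(los = los, left_open = FALSE, right_censored = cens)
    tl <- km_survival(cs)
    expect_equal(los_surv(tl, 0:max(los)),
                 km_oracle(los, as.integer(!cens), 0:max(los)),
                 tolerance = 1e-12)
  }

  expect_error(km_survival(data.frame(los = 3L, left_open = TRUE,
                                      right_censored = FALSE)),
               "no usable cases")
})

test_that("Weibull curve fit recovers exact and exponential tails", {
  tail <- los_tail(c(1, exp(-((1:60) / 20)^1.3)))
  fit <- weibull_fit(tail)
  expect_equal(fit$shape, 1.3, tolerance = 0.01)
  expect_equal(fit$scale, 20, tolerance = 0.01)

  expo <- los_tail(c(1, exp(-(1:60) / 15)))
  fit_e <- weibull_fit(expo)
  expect_equal(fit_e$shape, 1, tolerance = 0.01)

  # geometric LoS: the two-parameter Weibull can only do as well or better
  # than the best exponential (its shape = 1 submodel)
  geom_tail <- los_tail_geometric(8, horizon = 60)
  fit_g <- weibull_fit(geom_tail)
  best_exp_sse <- optimize(function(lam) {
    sum((exp(-(1:60) / lam) - geom_tail$surv[-1])^2)
  }, c(0.1, 100))$objective
  expect_lte(fit_g$sse, best_exp_sse + 1e-8)

  expect_error(weibull_fit(los_tail(c(1, 1, 1, 0, 0))), "degenerate|points")
})

test_that("Gini coefficient has its closed forms and stays in [0, 1)", {
  # deterministic LoS of c weeks: perfect equality
  for (c_weeks in c(1, 4, 9)) {
    tail <- los_tail(c(1, rep(1, c_weeks), 0)[1:(c_weeks + 2)])
    expect_equal(gini_from_tail(tail), 0)
  }
  # geometric: G = q / (1 + q)
  expect_equal(gini_from_tail(los_tail_geometric(2, 600)), 1 / 3,
               tolerance = 1e-9)
  for (q in c(0.2, 0.8, 0.95)) {
    tail <- los_tail_geometric(1 / (1 - q), horizon = 3000)
    expect_equal(gini_from_tail(tail), q / (1 + q), tolerance = 1e-6)
  }
  expect_gte(gini_from_tail(los_tail_weibull(0.8, 10)), 0)
  expect_lt(gini_from_tail(los_tail_weibull(0.8, 10)), 1)
})

test_that("tail mean identity and implied mean LoS", {
  tail <- los_tail_weibull(1.4, 12)
  s <- vapply(1:los_horizon(tail), function(t) los_surv(tail, t), numeric(1))
  expect_equal(mean_los(tail), sum(s))

  expect_equal(implied_ms(132.30, 1.58, 3.00), 27.91139, tolerance = 1e-6)
  expect_equal(implied_ms(132.30, 1.58, 3.00), 27.93, tolerance = 0.005)
  expect_equal(implied_ms(290.75, 5.33, 3.31), 16.49, tolerance = 0.005)
  expect_equal(implied_ms(6, 2, 3), 1)
  expect_error(implied_ms(10, 0, 3), "positive")
})

test_that("day-part fractions are duration-weighted and weekend-aware", {
  base <- as.Date("2021-03-01")
  v <- make_visits(base + 0:13, part = "morning")
  f <- daypart_fractions(v)
  expect_equal(f$morning, 1)
  expect_equal(f$afternoon, 0)
  expect_equal(f$weekend_ratio, 1)  # equal demand every day

  v2 <- rbind(make_visits(base, part = "morning", hours = 3),
              make_visits(base, part = "evening", hours = 1))
  f2 <- daypart_fractions(validate_visits(v2))
  expect_equal(f2$morning, 0.75)
  expect_equal(f2$evening, 0.25)
})

test_that("single-case and multi-team parameter tables are well-formed", {
  base <- as.Date("2021-03-01")
  v <- rbind(make_visits(base + c(0, 7, 14), team = "A"),
             make_visits(base + c(0, 7), team = "B", client = "z"))
  # every case opens the window, so the LoS fallback warns per team
  tab <- suppressWarnings(team_parameter_table(validate_visits(v)))
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$team_id, c("A", "B"))
  expect_true(all(tab$mean_demand > 0))
})
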