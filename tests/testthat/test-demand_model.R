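team5 <- function() {
  teams <- load_team_parameters()
  as_team_demand(teams[teams$team_id == "5", ])
}

test_that("stationary moments factorise as rho = m_a m_s m_g with Var = z rho", {
  m41 <- as_team_demand(load_team_parameters()["41" ==
                          load_team_parameters()$team_id, ])
  sm <- stationary_moments(m41)
  expect_equal(sm$mean, 5.33 * 16.49 * 3.31, tolerance = 1e-12)
  expect_equal(sm$mean, 290.75, tolerance = 0.002)
  expect_equal(sm$variance, peakedness(m41) * sm$mean)

  # unit deterministic case demand + Poisson arrivals: pure infinite-server,
  # variance equals the mean whatever the LoS
  m <- team_demand(m_a = 4, m_g = 1, vmr_a = 1, vmr_g = 0,
                   los = los_tail_weibull(1.7, 9))
  expect_equal(peakedness(m), 1)
  expect_equal(stationary_moments(m)$variance, stationary_moments(m)$mean)
})

test_that("peakedness evaluates the reference teams as printed", {
  expect_equal(peakedness(team5()), 3.72 + 3.00 + 3.00 * 0.26 * 0.30)
  expect_equal(peakedness(team5()), 6.99, tolerance = 0.01)
  teams <- load_team_parameters()
  m2 <- as_team_demand(teams[teams$team_id == "2", ])
  expect_equal(peakedness(m2), 3.18 + 3.61 + 3.61 * 0.21 * 0.10,
               tolerance = 1e-12)
  # unit deterministic case demand reduces to the classical G/G/inf form
  m <- team_demand(m_a = 2, m_g = 1, vmr_a = 1.6, vmr_g = 0,
                   m_s = 10, gini_s = 0.3)
  expect_equal(peakedness(m), 1 + (1 - 0.3) * (1.6 - 1))
})

test_that("square-root staffing and utilization behave as the scaling law", {
  rho <- 132.30; z <- 6.954
  expect_equal(required_capacity(rho, z, gamma = 1), rho + sqrt(z * rho))
  expect_equal(required_capacity(rho, z, gamma = 0), rho)
  # safety margin grows by sqrt(2) when demand doubles at fixed z
  margin <- function(r) required_capacity(r, z, 1) - r
  expect_equal(margin(2 * rho) / margin(rho), sqrt(2))

  expect_equal(utilization(rho, z, 1), 1 / (1 + sqrt(z / rho)))
  expect_equal(utilization(team5(), gamma = 1), 0.813, tolerance = 0.001)
  # increasing in rho, decreasing in z and gamma
  rhos <- seq(50, 2000, by = 50)
  expect_true(all(diff(utilization(rhos, z, 1)) > 0))
  expect_true(utilization(rho, 2 * z, 1) < utilization(rho, z, 1))
  expect_true(utilization(rho, z, 2) < utilization(rho, z, 1))
  expect_gt(utilization(1e8, z, 1), 0.999)
  # a team with much higher peakedness can be less efficient despite more
  # demand (reference teams 29 vs 5)
  expect_lt(utilization(231.59, 18.49, 1), utilization(132.30, 6.99, 1))
})

test_that("transient moments interpolate from current load to stationarity", {
  tail <- los_tail_geometric(10, horizon = 600)
  m <- team_demand(m_a = 2, m_g = 3, vmr_a = 1.4, vmr_g = 4, los = tail)

  # empty system, no arrivals possible: moments are zero
  m0 <- team_demand(m_a = 1e-12, m_g = 3, vmr_a = 1, vmr_g = 4, los = tail)
  tm0 <- transient_moments(m0, NULL, t = c(0, 3, 10))
  expect_true(all(abs(tm0$mean) < 1e-9))

  # single current case, B = 4, no future arrivals: Bernoulli thinning
  load1 <- current_load(4, remaining_tail = tail)
  t_half <- which.min(abs(tail$surv - 0.5)) - 1L  # t with S^r(t) ~ 0.5
  sr <- los_surv(tail, t_half)
  tm1 <- transient_moments(m0, load1, t = t_half)
  expect_equal(tm1$mean, 4 * sr, tolerance = 1e-6)
  expect_equal(tm1$variance, sr * (1 - sr) * 16, tolerance = 1e-6)

  # large t converges to the stationary moments regardless of the load
  load <- current_load(c(5, 2, 8))
  tm <- transient_moments(m, load, t = c(0, 400))
  sm <- stationary_moments(m)
  expect_equal(tm$mean[1], 15)  # t = 0 reproduces current demand
  expect_equal(tm$mean[2], sm$mean, tolerance = 1e-6)
  expect_equal(tm$variance[2], sm$variance, tolerance = 1e-6)
  # predict() is the method interface to the same computation
  expect_equal(predict(m, t = c(0, 400), load = load), tm)
})

test_that("pooling sums demand and averages peakedness by load", {
  teams <- load_team_parameters()
  models <- lapply(c("5", "15", "39", "41"), function(id) {
    as_team_demand(teams[teams$team_id == id, ])
  })
  single <- pool_teams(models[1])
  expect_equal(single$rho, stationary_moments(models[[1]])$mean)
  expect_equal(single$z, peakedness(models[[1]]))

  pooled <- pool_teams(models)
  rhos <- vapply(models, function(m) stationary_moments(m)$mean, numeric(1))
  zs <- vapply(models, peakedness, numeric(1))
  expect_equal(pooled$rho, sum(rhos))
  expect_equal(pooled$rho, 793.25, tolerance = 0.001)
  expect_equal(pooled$z, sum(zs * rhos) / sum(rhos))
  expect_equal(pooled$z, 6.09, tolerance = 0.001)

  # two identical teams: z preserved, rho doubled, utilization up
  twin <- pool_teams(models[c(1, 1)])
  expect_equal(twin$z, peakedness(models[[1]]))
  expect_equal(twin$rho, 2 * rhos[1])
  expect_gt(utilization(twin$rho, twin$z), utilization(rhos[1], zs[1]))
  expect_error(pool_teams(list()), "nothing to pool")
})

test_that("moment results depend on arrivals only through two moments", {
  # same (m_a, var_a): negative binomial vs matched-moment model give the
  # same closed-form stationary moments, and simulation agrees for both
  tail <- los_tail_geometric(6, horizon = 200)
  m <- team_demand(m_a = 3, m_g = 2, vmr_a = 1.5, vmr_g = 3, los = tail)
  sm <- stationary_moments(m)
  draws <- simulate_stationary_demand(m, reps = 4000, seed = 11)
  se_mean <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - sm$mean), 3 * se_mean)
  se_var <- sd((draws - mean(draws))^2) / sqrt(length(draws))
  expect_lt(abs(var(draws) - sm$variance), 3 * se_var)
})
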