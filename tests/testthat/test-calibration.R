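test_that("yearly proportions are flow counts over start-of-year alive", {
  world <- quick_world(seed = 3, size = 5e4, years = 6)
  obs <- world$observations
  pts <- yearly_proportions(obs, "50-64", "Fit", "deaths")
  row <- obs[obs$band == "50-64" & obs$state == "Fit", ]
  expect_equal(pts$proportion, row$deaths / row$alive_start)
  expect_equal(pts$t, 0:5)
  # binomial sampling oracle: each yearly proportion within 3 SE of truth
  p_true <- world$ground_truth$death[["50-64|Fit"]]$p
  se <- sqrt(p_true * (1 - p_true) / row$alive_start)
  expect_true(all(abs(pts$proportion - p_true) < 3 * se))
})

test_that("zero-population years are excluded with a warning", {
  g <- tiny_grid()
  df <- expand.grid(year = 2006:2009, band = g$bands, state = g$states,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$alive_start <- ifelse(df$year == 2008 & df$band == "A" & df$state == "S1",
                           0, 100)
  df[c("deaths", "deregs", "entries", "ageing_out", "progression_out")] <- 0
  df$deaths <- ifelse(df$alive_start > 0, 10, 0)
  obs <- cohort_observations(df, grid = g)
  expect_warning(pts <- yearly_proportions(obs, "A", "S1", "deaths"),
                 "zero alive_start")
  expect_equal(nrow(pts), 3)
  expect_equal(pts$proportion, rep(0.1, 3))
})

test_that("degree-0 fit is the arithmetic mean; constants are recovered", {
  pts <- data.frame(t = 0:9, proportion = rep(0.1, 10))
  fit <- fit_flow(pts)
  expect_equal(fit$degree, 0L)
  expect_equal(fit$spec$kind, "constant")
  expect_equal(fit$spec$p, 0.1)
  pts2 <- data.frame(t = 0:9, proportion = c(0.1, 0.12, 0.09, 0.11, 0.1,
                                             0.105, 0.095, 0.1, 0.11, 0.09))
  expect_equal(fit_flow(pts2, max_degree = 0)$spec$p, mean(pts2$proportion))
})

test_that("noiseless polynomials are recovered exactly at the right degree", {
  t <- 0:11
  lin <- data.frame(t = t, proportion = 0.02 + 0.003 * t)
  f1 <- fit_flow(lin)
  expect_equal(f1$degree, 1L)
  expect_equal(f1$spec$beta, c(0.02, 0.003, 0, 0), tolerance = 1e-10)
  expect_equal(f1$spec$t_max, 11)
  cub <- data.frame(t = t, proportion = 0.05 + 0.004 * t - 4e-4 * t^2 + 2e-5 * t^3)
  f3 <- fit_flow(cub)
  expect_equal(f3$degree, 3L)
  expect_equal(f3$spec$beta, c(0.05, 0.004, -4e-4, 2e-5), tolerance = 1e-9)
})

test_that("degree selection finds a noisy cubic and respects max_degree", {
  set.seed(42)
  t <- 0:11
  truth <- 0.10 + 0.02 * t - 5e-3 * t^2 + 4e-4 * t^3
  y <- truth + rnorm(12, sd = 5e-4)
  f <- fit_flow(data.frame(t = t, proportion = y))
  expect_equal(f$degree, 3L)
  expect_lt(max(abs(f$spec$beta - c(0.10, 0.02, -5e-3, 4e-4)) /
                  c(0.10, 0.02, 5e-3, 4e-4)), 0.5)
  f1 <- fit_flow(data.frame(t = t, proportion = y), max_degree = 1)
  expect_lte(f1$degree, 1L)
})

test_that("fitting is invariant to row order and degrades gracefully", {
  set.seed(9)
  pts <- data.frame(t = 0:9, proportion = 0.05 + 0.002 * (0:9) + rnorm(10, sd = 1e-3))
  f_a <- fit_flow(pts)
  f_b <- fit_flow(pts[sample(nrow(pts)), ])
  expect_equal(f_a$degree, f_b$degree)
  expect_equal(f_a$spec, f_b$spec)
  expect_warning(f1 <- fit_flow(pts[1, ]), "fewer than 2 points")
  expect_equal(f1$spec$p, pts$proportion[1])
})

test_that("entry fitting works on counts, not proportions", {
  g <- tiny_grid()
  df <- expand.grid(year = 2006:2017, band = g$bands, state = g$states,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$alive_start <- 1000
  df[c("deaths", "deregs", "ageing_out", "progression_out")] <- 0
  df$entries <- ifelse(df$band == "A" & df$state == "S1",
                       100 + 20 * (df$year - 2006), 500)
  obs <- cohort_observations(df, grid = g)
  f_lin <- fit_entry(obs, "A", "S1")
  expect_equal(f_lin$degree, 1L)
  expect_equal(f_lin$spec$units, "count")
  expect_equal(f_lin$spec$beta[1:2], c(100, 20), tolerance = 1e-9)
  f_const <- fit_entry(obs, "B", "S2")
  expect_equal(f_const$spec$p, 500)
  # Poisson oracle: constant intensity recovered within 3 SE of the mean
  set.seed(5)
  lambda <- 400
  df$entries <- rpois(nrow(df), lambda)
  obs2 <- cohort_observations(df, grid = g)
  f_p <- fit_entry(obs2, "A", "S2", max_degree = 0)
  expect_lt(abs(f_p$spec$p - lambda), 3 * sqrt(lambda / 12))
})

test_that("calibrate fits all 72 flows and initial_state_from copies stocks", {
  world <- quick_world(seed = 21, size = 1e5, years = 8)
  params <- calibrate(world$observations)
  rep <- calibration_report(params)
  expect_equal(nrow(rep), 72)
  expect_equal(sum(rep$flow == "death"), 16)
  expect_equal(sum(rep$flow == "ageing"), 12)
  expect_equal(sum(rep$flow == "progression"), 12)
  init <- initial_state_from(world$observations, 2006)
  obs06 <- world$observations[world$observations$year == 2006, ]
  expect_equal(init$alive, obs06$alive_start)
  expect_equal(attr(init, "start_year"), 2006)
  expect_error(initial_state_from(world$observations, 1999), "not present")
})

test_that("self-consistency: calibrated model reproduces its own cohort", {
  world <- quick_world(seed = 33, size = 1e5, years = 12)
  params <- calibrate(world$observations)
  traj <- simulate_cohort(initial_state_from(world$observations), params, 11)
  mt <- build_mape_table(world$observations, traj)
  stocks <- mt$mape_pct[mt$variable == "Alive"]
  expect_true(all(stocks < 5))
  expect_lt(attr(mt, "overall"), 10)
})

test_that("calibration on noiseless engine output is essentially exact", {
  g <- frailty_grid()
  truth <- constant_parameters(g, p_death = seq(0.01, 0.16, length.out = 16),
                               p_age = 0.05, p_prog = 0.03, entry = 200)
  init <- uniform_state(1e5, start_year = 2006)
  obs <- noiseless_observations(truth, init, 10)
  params <- calibrate(obs)
  for (k in names(truth$death))
    expect_equal(params$death[[k]]$p, truth$death[[k]]$p, tolerance = 1e-8)
  for (k in names(truth$progression))
    expect_equal(params$progression[[k]]$p, truth$progression[[k]]$p,
                 tolerance = 1e-8)
})
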