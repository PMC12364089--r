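test_that("mape matches hand oracles and handles zeros", {
  expect_equal(mape(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(mape(c(100, 200), c(110, 180)), 10)
  expect_warning(m <- mape(c(0, 100), c(5, 100)), "zero observed")
  expect_equal(m, 0)
  expect_error(mape(c(0, 0), c(1, 2)), "all zero")
  expect_error(mape(1:3, 1:2), "differ in length")
})

test_that("mape is scale-invariant, non-negative and zero on identity", {
  set.seed(8)
  for (i in 1:20) {
    o <- runif(12, 1, 100)
    e <- o * runif(12, 0.5, 1.5)
    m <- mape(o, e)
    expect_gte(m, 0)
    c_ <- runif(1, 0.01, 50)
    expect_equal(mape(c_ * o, c_ * e), m)
    expect_equal(mape(o, o), 0)
  }
})

test_that("packaged validation tables load with 88 cells and known means", {
  t2 <- ff_fixture("table2")
  t3 <- ff_fixture("table3")
  expect_s3_class(t2, "ff_mape_table")
  expect_equal(nrow(t2), 88)
  expect_equal(nrow(t3), 88)
  expect_equal(sum(t2$variable == "Ageing"), 12)
  expect_equal(sum(t2$variable == "FrailtyTransition"), 12)
  # overall equals an independent summation of the cells
  expect_equal(attr(t2, "overall"), sum(t2$mape_pct) / 88)
  expect_equal(attr(t3, "overall"), sum(t3$mape_pct) / 88)
  # by-variable weighting gives a different, larger summary on these cells
  expect_gt(mape_overall(t2, "by_variable"), mape_overall(t2, "flat"))
})

test_that("self-fit MAPE table is ~0 everywhere, doubled estimates give 100", {
  g <- frailty_grid()
  truth <- constant_parameters(g, p_death = 0.05, p_age = 0.04, p_prog = 0.03,
                               p_dereg = 0.02, entry = 150)
  init <- uniform_state(1e4, start_year = 2006)
  obs <- noiseless_observations(truth, init, 8)
  params <- calibrate(obs)
  traj <- simulate_cohort(initial_state_from(obs), params, 7)
  mt <- build_mape_table(obs, traj)
  expect_equal(nrow(mt), 88)
  expect_true(all(mt$mape_pct < 1e-6))
  expect_lt(attr(mt, "overall"), 1e-6)
  # doubling every observed value halves nothing: each cell is exactly 100%
  obs2 <- obs
  cols <- c("alive_start", "deaths", "deregs", "entries", "ageing_out",
            "progression_out")
  for (cn in cols) obs2[[cn]] <- obs2[[cn]] * 2
  obs2 <- cohort_observations(as.data.frame(obs2), grid = g)
  mt2 <- build_mape_table(obs2, traj)
  expect_true(all(abs(mt2$mape_pct - 50) < 1e-9))  # estimate = observed/2
})

test_that("misaligned year ranges raise a naming error", {
  g <- frailty_grid()
  truth <- constant_parameters(g, p_death = 0.05)
  obs <- noiseless_observations(truth, uniform_state(1e3, start_year = 2006), 5)
  init_late <- uniform_state(1e3, start_year = 2030)
  traj <- simulate_cohort(init_late, truth, 4)
  expect_error(build_mape_table(obs, traj), "overlap")
})

test_that("rescaling multiplies entry/dereg specs linearly and only those", {
  params <- example_parameters(cohort_size = 1e4)
  same <- rescale_parameters(params, 1, 1)
  expect_equal(same$entry, params$entry)
  expect_equal(same$dereg, params$dereg)
  doubled <- rescale_parameters(params, entry_scale = 2)
  expect_equal(doubled$entry[["50-64|Fit"]]$p, 2 * params$entry[["50-64|Fit"]]$p)
  expect_equal(doubled$death, params$death)
  expect_equal(doubled$progression, params$progression)
  # polynomial coefficients scale through
  params$dereg[["50-64|Fit"]] <- flow_spec("polynomial", beta = c(0.02, 0.001),
                                           t_max = 11)
  halved <- rescale_parameters(params, dereg_scale = 0.5)
  expect_equal(halved$dereg[["50-64|Fit"]]$beta, c(0.01, 0.0005, 0, 0))
  # zero factors produce the closed national flows
  closed <- rescale_parameters(params, 0, 0)
  pr <- annual_proportions(closed, 3)
  expect_equal(pr$dereg, rep(0, 16))
  expect_equal(pr$entry, rep(0, 16))
  expect_error(rescale_parameters(params, entry_scale = -1), "non-negative")
})

test_that("initial prevalence rescaling preserves band totals", {
  st <- table1_initial_state(1e5, "SAIL")
  rcgp <- ff_fixture("table1")
  rcgp <- rcgp[rcgp$cohort == "RCGP", ]
  targets <- data.frame(band = rcgp$band, state = rcgp$state,
                        share = rcgp$share_pct)
  out <- scale_initial_prevalence(st, targets, mode = "band")
  for (b in age_bands())
    expect_equal(sum(out$alive[out$band == b]), sum(st$alive[st$band == b]))
  # hand example: explicit shares on one band
  st2 <- population_state(c(rep(250, 4), rep(0, 12)))
  tg <- data.frame(band = rep(age_bands(), each = 4),
                   state = rep(frailty_states(), 4),
                   share = rep(c(0.7, 0.2, 0.08, 0.02), 4))
  out2 <- suppressWarnings(scale_initial_prevalence(st2, tg, mode = "band"))
  expect_equal(out2$alive[1:4], c(700, 200, 80, 20))
  # identity when targets equal current shares
  tg_id <- data.frame(band = st$band, state = st$state,
                      share = st$alive)
  expect_equal(scale_initial_prevalence(st, tg_id)$alive, st$alive)
  tg_bad <- tg; tg_bad$share[1] <- -1
  expect_error(scale_initial_prevalence(st, tg_bad), "non-negative")
})
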