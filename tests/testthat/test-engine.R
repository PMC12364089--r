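test_that("model structure counts match the combinatorial formula", {
  m <- build_model(constant_parameters())
  expect_equal(m$n_stocks, 48L)
  expect_equal(m$n_flows, 72L)
  m2 <- build_model(constant_parameters(tiny_grid()))
  expect_equal(m2$n_stocks, 12L)
  expect_equal(m2$n_flows, 16L)  # 3*4 + 2*1 + 1*2
})

test_that("built model is structurally irreversible", {
  m <- build_model(constant_parameters())
  fl <- m$flows
  moves <- fl[!is.na(fl$to_band) & fl$flow %in% c("ageing", "progression"), ]
  band_rank <- match(moves$band, age_bands())
  state_rank <- match(moves$state, frailty_states())
  expect_true(all(match(moves$to_band, age_bands()) >= band_rank))
  expect_true(all(match(moves$to_state, frailty_states()) >= state_rank))
  expect_false(any(fl$flow == "ageing" & fl$band == "85+"))
  expect_false(any(fl$flow == "progression" & fl$state == "Severe"))
})

test_that("missing flow specs are a configuration error naming the flow", {
  g <- tiny_grid()
  ok <- constant_parameters(g)
  broken <- ok$death[-1]
  expect_error(
    model_parameters(g, death = broken, dereg = ok$dereg, entry = ok$entry,
                     ageing = ok$ageing, progression = ok$progression),
    "missing death flow spec.*A\\|S1")
})

test_that("annual proportions evaluate, freeze and clamp", {
  g <- tiny_grid()
  p <- constant_parameters(g, p_death = 0.1)
  pr <- annual_proportions(p, 5)
  expect_equal(pr$death, rep(0.1, 4))
  s <- flow_spec("polynomial", beta = c(0.05, 0.01), t_max = 10)
  expect_equal(eval_flow_spec(s, 2), 0.07)
  expect_equal(eval_flow_spec(s, 50), eval_flow_spec(s, 10))  # frozen
  expect_warning(v <- eval_flow_spec(flow_spec("polynomial", beta = c(-0.02),
                                               t_max = 5), 0),
                 "clamped")
  expect_equal(v, 0)
})

test_that("one step does the hand arithmetic", {
  g <- frailty_grid()
  # pure mortality in one subgroup
  p <- constant_parameters(g)
  p$death[["50-64|Fit"]] <- flow_spec("constant", p = 0.1)
  st <- population_state(c(1000, rep(0, 15)), g)
  out <- step_population(st, p)
  expect_equal(out$state$alive[1], 900)
  expect_equal(out$flows$deaths[1], 100)
  expect_equal(out$state$died_cum[1], 100)
  expect_equal(attr(out$state, "t"), 1)
  # progression and ageing route to the right destinations
  p2 <- constant_parameters(g)
  p2$progression[["50-64|Fit"]] <- flow_spec("constant", p = 0.05)
  p2$ageing[["50-64|Fit"]] <- flow_spec("constant", p = 0.02)
  out2 <- step_population(st, p2)
  expect_equal(out2$state$alive[subgroup_of("50-64", "Fit") + 1], 930)
  expect_equal(out2$state$alive[subgroup_of("50-64", "Mild") + 1], 50)
  expect_equal(out2$state$alive[subgroup_of("65-74", "Fit") + 1], 20)
})

test_that("identity step leaves the state unchanged except time", {
  st <- uniform_state()
  out <- step_population(st, constant_parameters())
  expect_equal(out$state$alive, st$alive)
  expect_equal(out$state$died_cum, st$died_cum)
  expect_equal(attr(out$state, "t"), attr(st, "t") + 1)
})

test_that("joint outflows above 1 are rescaled proportionally with warning", {
  g <- tiny_grid()
  p <- constant_parameters(g, p_death = 0.8, p_dereg = 0.6)
  st <- population_state(rep(100, 4), g)
  expect_warning(out <- step_population(st, p), "rescaled")
  expect_equal(out$flows$deaths + out$flows$deregs, rep(100, 4))
  expect_equal(out$flows$deaths / out$flows$deregs, rep(0.8 / 0.6, 4))
  expect_true(all(out$state$alive >= 0))
})

test_that("negative alive input is rejected", {
  expect_error(population_state(c(-1, rep(0, 15))), "negative")
})

test_that("constant mortality matches the closed-form geometric decay", {
  for (p_death in c(0.05, 0.2, 0.5)) {
    p <- constant_parameters(p_death = p_death)
    tr <- simulate_cohort(population_state(rep(1000, 16)), p, 7)
    for (t in 0:7)
      expect_equal(tr$states[[t + 1]]$alive, rep(1000 * (1 - p_death)^t, 16))
  }
})

test_that("conservation holds on randomized parameter sets", {
  set.seed(101)
  for (rep in 1:25) {
    p <- constant_parameters(
      p_death = runif(16, 0, 0.3), p_dereg = runif(16, 0, 0.2),
      p_age = runif(16, 0, 0.2), p_prog = runif(16, 0, 0.2),
      entry = runif(16, 0, 500))
    init <- population_state(runif(16, 0, 1e4))
    tr <- simulate_cohort(init, p, 6)
    expect_lt(conservation_error(tr), 1e-9)
    expect_true(all(unlist(lapply(tr$states, `[[`, "alive")) >= 0))
    expect_true(all(tr$flows$deaths >= 0 & tr$flows$progression_out >= 0))
  }
})

test_that("flow records link consecutive states exactly", {
  set.seed(11)
  p <- constant_parameters(p_death = runif(16, 0, 0.2),
                           p_age = runif(16, 0, 0.1),
                           p_prog = runif(16, 0, 0.1),
                           entry = runif(16, 0, 100))
  tr <- simulate_cohort(uniform_state(5000), p, 5)
  grid <- tr$grid
  ns <- length(grid$states)
  for (y in 1:5) {
    a0 <- tr$states[[y]]$alive
    a1 <- tr$states[[y + 1]]$alive
    fl <- tr$flows[tr$flows$year == y - 1, ]
    prog_in <- c(0, fl$progression_out[-16])
    prog_in[seq(1, 16, by = ns)] <- 0   # nothing enters a band's first state
    age_in <- c(rep(0, ns), fl$ageing_out[1:(16 - ns)])
    expect_equal(a1, a0 - fl$deaths - fl$deregs - fl$ageing_out -
                   fl$progression_out + fl$entries + prog_in + age_in)
  }
})

test_that("sub-annual Euler mode converges on the annual proportions", {
  p <- constant_parameters(p_death = 0.2)
  init <- population_state(rep(1000, 16))
  tr1 <- simulate_cohort(init, p, 3, dt = 1)
  tr4 <- simulate_cohort(init, p, 3, dt = 0.25)
  # per-step proportion 1-(1-p)^dt makes annual survival identical
  expect_equal(tr4$states[[4]]$alive, tr1$states[[4]]$alive, tolerance = 1e-12)
  expect_lt(conservation_error(tr4), 1e-9)
})

test_that("tidy trajectory export has one row per year-subgroup-variable", {
  p <- constant_parameters(p_death = 0.1, entry = 10)
  tr <- simulate_cohort(uniform_state(100, start_year = 2006), p, 2)
  td <- as.data.frame(tr)
  expect_setequal(unique(td$variable),
                  c("alive", "died_cum", "left_cum", "entered_cum",
                    "deaths", "deregs", "entries", "ageing_out",
                    "progression_out"))
  expect_equal(nrow(td), 3 * 16 * 4 + 2 * 16 * 5)
  expect_equal(sort(unique(td$year)), 2006:2008)
})
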