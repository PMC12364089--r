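# Shared fixture builders. All synthetic data is generated in code under
# fixed seeds; nothing is read from disk except the packaged table
# transcriptions.

# A small 2-band x 2-state grid for structural tests.
tiny_grid <- function() model_grid(c("A", "B"), c("S1", "S2"))

# Uniform state over any grid.
uniform_state <- function(n = 1000, grid = frailty_grid(), ...) {
  population_state(rep(n, n_subgroups(grid)), grid = grid, ...)
}

# A stochastic cohort with constant ground-truth rates, sized for quick
# calibration tests.
quick_world <- function(seed = 7, size = 2e5, years = 8) {
  init <- table1_initial_state(size, "RCGP")
  truth <- example_parameters(cohort_size = size)
  gen <- generate_cohort(synthetic_config(years = years, initial = init,
                                          true_params = truth, seed = seed))
  gen
}

# Noise-free observations produced by running the deterministic engine and
# recording its own flows; calibration on these must be (near-)exact.
noiseless_observations <- function(params, initial, years) {
  traj <- simulate_cohort(initial, params, years)
  start_year <- attr(initial, "start_year")
  rows <- lapply(seq_len(years), function(y) {
    st <- traj$states[[y]]
    fl <- traj$flows[traj$flows$year == start_year + y - 1, ]
    data.frame(year = start_year + y - 1, band = st$band, state = st$state,
               alive_start = st$alive, deaths = fl$deaths, deregs = fl$deregs,
               entries = fl$entries, ageing_out = fl$ageing_out,
               progression_out = fl$progression_out, stringsAsFactors = FALSE)
  })
  cohort_observations(do.call(rbind, rows), grid = attr(initial, "grid"))
}
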