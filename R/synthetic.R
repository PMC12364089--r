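#' Configuration of the synthetic-cohort generator
#'
#' The generator emulates the structure of an annual primary-care cohort
#' extract: a known initial distribution over the 16 subgroups, competing
#' annual outcomes (die / de-register / progress frailty / age / stay)
#' drawn from one multinomial per subgroup-year on the start-of-year alive
#' count, and Poisson entries into every subgroup. The true parameters are
#' returned alongside the observations so calibration can be tested
#' against ground truth.
#'
#' @param years number of observation years
#' @param initial an \code{ff_state} giving the initial alive counts
#'   (e.g. from \code{\link{table1_initial_state}})
#' @param true_params an \code{ff_params}; entry specs give the expected
#'   entrants/year per subgroup (Poisson intensity)
#' @param seed integer seed fixing the whole output
#' @param dispersion optional variance inflation of the outcome draws
#'   (Dirichlet-multinomial); 1 = plain multinomial
#' @return An object of class \code{ff_synth_config}.
#' @export
synthetic_config <- function(years = 12, initial, true_params, seed = 1,
                             dispersion = 1) {
  stopifnot(inherits(initial, "ff_state"), inherits(true_params, "ff_params"),
            years >= 1, dispersion >= 1)
  grid <- attr(initial, "grid")
  if (!identical(grid$bands, true_params$grid$bands) ||
      !identical(grid$states, true_params$grid$states))
    stop("initial state and true parameters use different grids")
  structure(list(years = as.integer(years), initial = initial,
                 true_params = true_params, seed = as.integer(seed),
                 dispersion = dispersion),
            class = "ff_synth_config")
}

# Dirichlet-multinomial draw with variance inflation `disp` relative to the
# multinomial; disp = 1 falls back to rmultinom.
ff_rmultinom <- function(n, prob, disp) {
  if (disp <= 1 || n < 2) return(as.vector(stats::rmultinom(1, n, prob)))
  s <- max((n - disp) / (disp - 1), 1e-6)
  w <- stats::rgamma(length(prob), shape = prob * s, rate = 1)
  w[prob == 0] <- 0
  if (sum(w) == 0) w <- prob
  as.vector(stats::rmultinom(1, n, w / sum(w)))
}

#' Generate a synthetic cohort observation table
#'
#' Runs the stochastic aggregate-level data-generating process described in
#' \code{\link{synthetic_config}} and assembles the result in the
#' calibration table schema. The per-year accounting identity
#' alive_start(y+1) = alive_start(y) - outflows + entries + inflows holds
#' exactly by construction.
#'
#' @param config an \code{ff_synth_config}
#' @return A list with \code{observations} (an \code{ff_observations}),
#'   \code{ground_truth} (the true \code{ff_params}) and \code{seed}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ff_synth_config"))
  grid <- attr(config$initial, "grid")
  ns <- length(grid$states)
  n <- n_subgroups(grid)
  params <- config$true_params
  start_year <- attr(config$initial, "start_year")
  if (is.null(start_year)) start_year <- 0

  # fail before any draw if the stated rates are inconsistent
  prop_by_year <- lapply(seq_len(config$years) - 1L, function(t)
    annual_proportions(params, t, warn_clamp = FALSE))
  for (t in seq_along(prop_by_year)) {
    pr <- prop_by_year[[t]]
    tot <- pr$death + pr$dereg + pr$progression + pr$ageing
    if (any(tot > 1 + 1e-12))
      stop("configuration error: outcome proportions sum to ",
           format(max(tot)), " > 1 at t = ", t - 1, " for subgroup ",
           sg_key(pr$band, pr$state)[which.max(tot)])
  }

  set.seed(config$seed)
  alive <- config$initial$alive
  sg <- subgroup_table(grid)
  rows <- vector("list", config$years)
  for (y in seq_len(config$years)) {
    pr <- prop_by_year[[y]]
    deaths <- deregs <- prog_out <- age_out <- entries <- numeric(n)
    for (i in seq_len(n)) {
      p <- c(pr$death[i], pr$dereg[i], pr$progression[i], pr$ageing[i])
      p <- c(p, 1 - sum(p))
      draw <- ff_rmultinom(round(alive[i]), p, config$dispersion)
      deaths[i] <- draw[1]; deregs[i] <- draw[2]
      prog_out[i] <- draw[3]; age_out[i] <- draw[4]
      entries[i] <- stats::rpois(1, pr$entry[i])
    }
    rows[[y]] <- data.frame(year = start_year + y - 1, band = sg$band,
                            state = sg$state, alive_start = alive,
                            deaths = deaths, deregs = deregs,
                            entries = entries, ageing_out = age_out,
                            progression_out = prog_out,
                            stringsAsFactors = FALSE)
    prog_in <- numeric(n); age_in <- numeric(n)
    nz <- which(prog_out > 0)
    if (length(nz)) prog_in[nz + 1L] <- prog_in[nz + 1L] + prog_out[nz]
    nz <- which(age_out > 0)
    if (length(nz)) age_in[nz + ns] <- age_in[nz + ns] + age_out[nz]
    alive <- alive - deaths - deregs - prog_out - age_out +
      prog_in + age_in + entries
  }
  obs <- cohort_observations(do.call(rbind, rows), grid = grid)
  list(observations = obs, ground_truth = params, seed = config$seed)
}

#' Initial population state from the published cohort distributions
#'
#' Distributes a cohort of the given size over the 16 subgroups using the
#' published initial percentage distribution of either source cohort
#' (the English primary-care calibration cohort, "RCGP", or the Welsh
#' validation cohort, "SAIL"). Quotas are share x size, rounded with a
#' largest-remainder correction so the stocks sum exactly to the cohort
#' size; ties are broken towards larger subgroups.
#'
#' @param cohort_size total number of people
#' @param cohort "RCGP" or "SAIL"
#' @return An \code{ff_state} over the 4 x 4 frailty grid with
#'   \code{start_year = 2006}.
#' @export
table1_initial_state <- function(cohort_size, cohort = c("RCGP", "SAIL")) {
  cohort <- match.arg(cohort)
  stopifnot(cohort_size > 0)
  shares <- ff_fixture("table1")
  shares <- shares[shares$cohort == cohort, , drop = FALSE]
  grid <- frailty_grid()
  ord <- order(match(shares$band, grid$bands), match(shares$state, grid$states))
  shares <- shares[ord, , drop = FALSE]
  total <- round(cohort_size)
  quota <- shares$share_pct / 100 * cohort_size
  alloc <- floor(quota)
  r <- total - sum(alloc)
  if (r < 0 || r > length(quota)) {
    # printed shares do not sum to exactly 100%; at large sizes the excess
    # outgrows what fractional rounding can absorb, so renormalise first
    quota <- quota * total / sum(quota)
    alloc <- floor(quota)
    r <- total - sum(alloc)
  }
  if (r > 0) {
    pick <- order(-(quota - alloc), -quota)   # largest remainder, ties to big cells
    alloc[pick[seq_len(r)]] <- alloc[pick[seq_len(r)]] + 1
  }
  population_state(stats::setNames(alloc, sg_key(shares$band, shares$state)),
                   grid = grid, t = 0, start_year = 2006)
}
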