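#' Population state: alive and accounting stocks per subgroup
#'
#' The model tracks, for every age-band x frailty-state subgroup, the number
#' of people alive at the start of the year plus three cumulative
#' accounting stocks: people who have died, who have left (de-registered),
#' and who have entered since the simulation origin.
#'
#' @param alive numeric vector of alive counts in canonical band-major
#'   subgroup order (or a named vector keyed "band|state")
#' @param grid an \code{ff_grid}
#' @param t model time in years since the origin
#' @param start_year calendar year of the origin (optional, used for
#'   alignment with observations)
#' @param died_cum,left_cum,entered_cum cumulative accounting stocks
#' @return A data.frame of class \code{ff_state} with columns \code{band},
#'   \code{state}, \code{alive}, \code{died_cum}, \code{left_cum},
#'   \code{entered_cum} and attributes \code{grid}, \code{t},
#'   \code{start_year}.
#' @export
population_state <- function(alive, grid = frailty_grid(), t = 0,
                             start_year = NULL, died_cum = 0, left_cum = 0,
                             entered_cum = 0) {
  n <- n_subgroups(grid)
  sg <- subgroup_table(grid)
  keys <- sg_key(sg$band, sg$state)
  if (!is.null(names(alive))) {
    missing <- setdiff(keys, names(alive))
    if (length(missing))
      stop("alive vector is missing subgroup(s): ", paste(missing, collapse = ", "))
    alive <- alive[keys]
  }
  if (length(alive) != n) stop("alive must have one value per subgroup (", n, ")")
  if (anyNA(alive) || any(alive < 0)) stop("negative or missing alive count")
  out <- data.frame(band = sg$band, state = sg$state,
                    alive = as.numeric(alive),
                    died_cum = rep_len(as.numeric(died_cum), n),
                    left_cum = rep_len(as.numeric(left_cum), n),
                    entered_cum = rep_len(as.numeric(entered_cum), n),
                    stringsAsFactors = FALSE)
  if (any(out$died_cum < 0) || any(out$left_cum < 0) || any(out$entered_cum < 0))
    stop("accounting stocks must be non-negative")
  structure(out, grid = grid, t = t, start_year = start_year,
            class = c("ff_state", "data.frame"))
}

#' @export
print.ff_state <- function(x, ...) {
  cat(sprintf("population state at t = %g%s: %s alive across %d subgroups\n",
              attr(x, "t"),
              if (!is.null(attr(x, "start_year")))
                sprintf(" (year %g)", attr(x, "start_year") + attr(x, "t")) else "",
              format(round(sum(x$alive))), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Build the stock-flow model and report its structure
#'
#' For nb bands and ns states the model has \code{3*nb*ns} stocks (alive,
#' died, left per subgroup) and \code{3*nb*ns + nb*(ns-1) + (nb-1)*ns}
#' flows (entry, death, de-registration per subgroup; frailty progression
#' except out of the terminal state; ageing except out of the terminal
#' band). The canonical 4 x 4 configuration gives 48 stocks and 72 flows.
#' The returned flow table shows every flow's source and destination, so
#' irreversibility (no flow towards a fitter state or a younger band) can
#' be asserted structurally.
#'
#' @param params an \code{ff_params} (validated for completeness on
#'   construction)
#' @return An object of class \code{ff_model}: list with \code{grid},
#'   \code{params}, \code{n_stocks}, \code{n_flows} and \code{flows}, a
#'   data.frame with columns \code{flow}, \code{band}, \code{state},
#'   \code{to_band}, \code{to_state} (NA for flows into the died/left
#'   accounting stocks or from outside the population).
#' @export
build_model <- function(params) {
  stopifnot(inherits(params, "ff_params"))
  grid <- params$grid
  nb <- length(grid$bands); ns <- length(grid$states)
  sg <- subgroup_table(grid)
  rows <- list(
    data.frame(flow = "entry", band = sg$band, state = sg$state,
               to_band = sg$band, to_state = sg$state, stringsAsFactors = FALSE),
    data.frame(flow = "death", band = sg$band, state = sg$state,
               to_band = NA_character_, to_state = NA_character_, stringsAsFactors = FALSE),
    data.frame(flow = "dereg", band = sg$band, state = sg$state,
               to_band = NA_character_, to_state = NA_character_, stringsAsFactors = FALSE)
  )
  prog <- sg[sg$state != grid$states[ns], , drop = FALSE]
  if (nrow(prog))
    rows <- c(rows, list(data.frame(
      flow = "progression", band = prog$band, state = prog$state,
      to_band = prog$band, to_state = next_state(prog$state, grid),
      stringsAsFactors = FALSE)))
  agei <- sg[sg$band != grid$bands[nb], , drop = FALSE]
  if (nrow(agei))
    rows <- c(rows, list(data.frame(
      flow = "ageing", band = agei$band, state = agei$state,
      to_band = next_band(agei$band, grid), to_state = agei$state,
      stringsAsFactors = FALSE)))
  flows <- do.call(rbind, rows)
  structure(list(grid = grid, params = params,
                 n_stocks = 3L * nb * ns,
                 n_flows = nrow(flows),
                 flows = flows),
            class = "ff_model")
}

#' @export
print.ff_model <- function(x, ...) {
  cat(sprintf("stock-flow model: %d stocks, %d flows (%d x %d grid)\n",
              x$n_stocks, x$n_flows, length(x$grid$bands), length(x$grid$states)))
  invisible(x)
}

#' Evaluate all flow rates at model time t
#'
#' Polynomial rates are evaluated at \code{min(t, t_max)} and clamped to
#' [0, 1] (proportions) or [0, Inf) (entry counts); clamping raises a
#' warning.
#'
#' @param params an \code{ff_params}
#' @param t model time in years
#' @param warn_clamp passed to \code{\link{eval_flow_spec}}
#' @return A data.frame with one row per subgroup in canonical order and
#'   columns \code{band}, \code{state}, \code{death}, \code{dereg},
#'   \code{progression}, \code{ageing} (0 where the flow does not exist)
#'   and \code{entry} (persons/year).
#' @export
annual_proportions <- function(params, t, warn_clamp = TRUE) {
  stopifnot(inherits(params, "ff_params"), length(t) == 1, t >= 0)
  grid <- params$grid
  sg <- subgroup_table(grid)
  keys <- sg_key(sg$band, sg$state)
  ev <- function(flow) {
    v <- stats::setNames(numeric(length(keys)), keys)
    specs <- params[[flow]]
    v[names(specs)] <- vapply(specs, eval_flow_spec, numeric(1), t = t,
                              warn_clamp = warn_clamp)
    unname(v)
  }
  data.frame(band = sg$band, state = sg$state,
             death = ev("death"), dereg = ev("dereg"),
             progression = ev("progression"), ageing = ev("ageing"),
             entry = ev("entry"), stringsAsFactors = FALSE)
}

# One synchronous sub-step of length dt years. Competing outflows are all
# computed from the start-of-step stock; if their joint proportion exceeds 1
# they are rescaled proportionally (with a warning). Returns the updated
# stock vectors and the realised flows.
ff_substep <- function(alive, props, dt, grid) {
  ns <- length(grid$states); nb <- length(grid$bands)
  conv <- function(p) if (dt == 1) p else 1 - (1 - p)^dt
  pd <- conv(props$death); pl <- conv(props$dereg)
  pp <- conv(props$progression); pa <- conv(props$ageing)
  tot <- pd + pl + pp + pa
  over <- tot > 1
  if (any(over)) {
    warning("joint outflow proportion exceeds 1 in subgroup(s) ",
            paste(sg_key(props$band[over], props$state[over]), collapse = ", "),
            "; rescaled to sum to 1")
    f <- ifelse(over, 1 / tot, 1)
    pd <- pd * f; pl <- pl * f; pp <- pp * f; pa <- pa * f
  }
  deaths <- pd * alive; deregs <- pl * alive
  prog_out <- pp * alive; age_out <- pa * alive
  entries <- props$entry * dt

  n <- length(alive)
  prog_in <- numeric(n); age_in <- numeric(n)
  # progression: same band, next state (band-major layout: +1)
  src_p <- which(prog_out > 0 | pp > 0)
  if (length(src_p)) prog_in[src_p + 1L] <- prog_in[src_p + 1L] + prog_out[src_p]
  # ageing: next band, same state (+ns)
  src_a <- which(age_out > 0 | pa > 0)
  if (length(src_a)) age_in[src_a + ns] <- age_in[src_a + ns] + age_out[src_a]

  alive_new <- alive - deaths - deregs - prog_out - age_out +
    prog_in + age_in + entries
  # joint outflows never exceed the stock, so negatives are float noise
  tiny <- alive_new < 0
  if (any(tiny)) {
    if (any(alive_new < -1e-8 * max(alive, 1)))
      stop("internal error: negative stock beyond rounding tolerance")
    alive_new[tiny] <- 0
  }
  list(alive = alive_new, deaths = deaths, deregs = deregs,
       entries = entries, ageing_out = age_out, progression_out = prog_out)
}

#' Advance the population by one year
#'
#' All competing outflows (death, de-registration, frailty progression,
#' ageing) are computed synchronously from the start-of-year stock; people
#' progressing move to the next frailty state within the band, people
#' ageing move to the next band within the frailty state, and exogenous
#' entries are added. If the joint outflow proportion of a subgroup exceeds
#' 1 the four outflows are rescaled proportionally to sum to 1 (with a
#' warning).
#'
#' @param state an \code{ff_state}
#' @param params an \code{ff_params} over the same grid
#' @param dt sub-annual Euler step in years; must divide 1. With dt < 1
#'   each sub-step applies proportion \code{1 - (1 - p)^dt} and entries
#'   \code{E * dt}; flows are accumulated over the year.
#' @return A list with elements \code{state} (the state at t + 1) and
#'   \code{flows}, a data.frame per subgroup of the realised annual flows
#'   (\code{deaths}, \code{deregs}, \code{entries}, \code{ageing_out},
#'   \code{progression_out}).
#' @export
step_population <- function(state, params, dt = 1) {
  stopifnot(inherits(state, "ff_state"), inherits(params, "ff_params"))
  grid <- attr(state, "grid")
  if (!identical(grid$bands, params$grid$bands) ||
      !identical(grid$states, params$grid$states))
    stop("state and parameters are defined over different grids")
  if (any(state$alive < 0)) stop("negative alive input")
  nsteps <- round(1 / dt)
  if (abs(nsteps * dt - 1) > 1e-9) stop("dt must divide 1 year")

  t0 <- attr(state, "t")
  props <- annual_proportions(params, t0)
  alive <- state$alive
  acc <- list(deaths = 0, deregs = 0, entries = 0, ageing_out = 0,
              progression_out = 0)
  for (k in seq_len(nsteps)) {
    sub <- ff_substep(alive, props, dt, grid)
    alive <- sub$alive
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + sub[[nm]]
  }
  flows <- data.frame(band = state$band, state = state$state,
                      deaths = acc$deaths, deregs = acc$deregs,
                      entries = acc$entries, ageing_out = acc$ageing_out,
                      progression_out = acc$progression_out,
                      stringsAsFactors = FALSE)
  new_state <- state
  new_state$alive <- alive
  new_state$died_cum <- state$died_cum + acc$deaths
  new_state$left_cum <- state$left_cum + acc$deregs
  new_state$entered_cum <- state$entered_cum + acc$entries
  attr(new_state, "t") <- t0 + 1
  list(state = new_state, flows = flows)
}

#' Simulate the model over an annual horizon
#'
#' Runs the deterministic difference equations for \code{horizon} years and
#' records the population state at the start of every year together with
#' the realised flows of every elapsed year.
#'
#' @param initial an \code{ff_state} at the simulation origin
#' @param params an \code{ff_params}
#' @param horizon number of years to simulate (>= 1)
#' @param dt optional sub-annual Euler step (see
#'   \code{\link{step_population}})
#' @return An object of class \code{ff_trajectory}: list with
#'   \code{states} (length horizon + 1), \code{flows} (data.frame with a
#'   \code{year} column; calendar years when the initial state carries a
#'   \code{start_year}, else model time), \code{grid}, \code{start_year}.
#' @export
simulate_cohort <- function(initial, params, horizon, dt = 1) {
  stopifnot(horizon >= 1)
  states <- vector("list", horizon + 1)
  states[[1]] <- initial
  flows <- vector("list", horizon)
  start_year <- attr(initial, "start_year")
  t0 <- attr(initial, "t")
  for (h in seq_len(horizon)) {
    stepped <- step_population(states[[h]], params, dt = dt)
    states[[h + 1]] <- stepped$state
    fl <- stepped$flows
    fl <- cbind(year = (if (is.null(start_year)) t0 else start_year + t0) + h - 1,
                fl)
    flows[[h]] <- fl
  }
  structure(list(states = states, flows = do.call(rbind, flows),
                 grid = attr(initial, "grid"), start_year = start_year),
            class = "ff_trajectory")
}

#' @export
print.ff_trajectory <- function(x, ...) {
  h <- length(x$states) - 1
  cat(sprintf("trajectory: %d annual steps, %s -> %s alive\n", h,
              format(round(sum(x$states[[1]]$alive))),
              format(round(sum(x$states[[h + 1]]$alive)))))
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x an \code{ff_trajectory}
#' @param row.names,optional,... ignored (data.frame method signature)
#' @return A long data.frame, one row per (year, band, state, variable),
#'   with variables alive, died_cum, left_cum, entered_cum (start-of-year
#'   stocks) and deaths, deregs, entries, ageing_out, progression_out
#'   (within-year flows).
#' @export
as.data.frame.ff_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  start <- if (is.null(x$start_year)) attr(x$states[[1]], "t") else
    x$start_year + attr(x$states[[1]], "t")
  stock_rows <- do.call(rbind, lapply(seq_along(x$states), function(i) {
    st <- x$states[[i]]
    data.frame(year = start + i - 1, band = st$band, state = st$state,
               alive = st$alive, died_cum = st$died_cum,
               left_cum = st$left_cum, entered_cum = st$entered_cum,
               stringsAsFactors = FALSE)
  }))
  long_stocks <- stats::reshape(
    stock_rows, direction = "long",
    varying = c("alive", "died_cum", "left_cum", "entered_cum"),
    v.names = "value", timevar = "variable",
    times = c("alive", "died_cum", "left_cum", "entered_cum"))
  long_flows <- stats::reshape(
    x$flows, direction = "long",
    varying = c("deaths", "deregs", "entries", "ageing_out", "progression_out"),
    v.names = "value", timevar = "variable",
    times = c("deaths", "deregs", "entries", "ageing_out", "progression_out"))
  out <- rbind(long_stocks[, c("year", "band", "state", "variable", "value")],
               long_flows[, c("year", "band", "state", "variable", "value")])
  rownames(out) <- NULL
  out[order(out$year, match(out$band, x$grid$bands),
            match(out$state, x$grid$states), out$variable), ]
}

#' Maximum relative conservation error along a trajectory
#'
#' For every recorded state the closed-population accounting identity
#' sum(alive + died_cum + left_cum) = sum(initial alive) + sum(entered_cum)
#' must hold; this returns the largest relative violation.
#'
#' @param traj an \code{ff_trajectory}
#' @return Largest relative error across recorded states.
#' @export
conservation_error <- function(traj) {
  init <- traj$states[[1]]
  base <- sum(init$alive) + sum(init$died_cum) + sum(init$left_cum)
  ent0 <- sum(init$entered_cum)
  err <- vapply(traj$states, function(st) {
    lhs <- sum(st$alive) + sum(st$died_cum) + sum(st$left_cum)
    rhs <- base + sum(st$entered_cum) - ent0
    abs(lhs - rhs) / max(abs(rhs), 1)
  }, numeric(1))
  max(err)
}
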