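#' Population projection: people reaching age 50 per calendar year
#'
#' Drives the national scale-up: in the closed national model people enter
#' only by turning 50 and leave only by dying, so the exogenous input is
#' the projected count of people reaching age 50 each year, optionally
#' accompanied by per-band population estimates for initialisation.
#'
#' @param entrants data.frame with columns \code{year} and
#'   \code{entrants_50} (persons reaching age 50 that year); years must be
#'   contiguous
#' @param band_populations optional data.frame with columns \code{year},
#'   \code{band}, \code{population}
#' @return An object of class \code{ff_projection}.
#' @export
population_projection <- function(entrants, band_populations = NULL) {
  stopifnot(all(c("year", "entrants_50") %in% names(entrants)))
  if (any(entrants$entrants_50 < 0) || anyNA(entrants$entrants_50))
    stop("entrants_50 must be non-negative")
  entrants <- entrants[order(entrants$year), c("year", "entrants_50")]
  gaps <- setdiff(seq(min(entrants$year), max(entrants$year)), entrants$year)
  if (length(gaps))
    stop("projection years are not contiguous; missing ",
         paste(gaps, collapse = ", "))
  if (!is.null(band_populations))
    stopifnot(all(c("year", "band", "population") %in% names(band_populations)))
  structure(list(entrants = entrants, band_populations = band_populations),
            class = "ff_projection")
}

#' @export
print.ff_projection <- function(x, ...) {
  cat(sprintf("population projection: %d-%d, %s entrants at age 50 in total\n",
              min(x$entrants$year), max(x$entrants$year),
              format(round(sum(x$entrants$entrants_50)))))
  invisible(x)
}

#' Frailty split of new age-50 entrants
#'
#' The frailty mix of people reaching 50 is not observed directly; it is a
#' configurable model input. \code{entry_split} validates explicit shares;
#' \code{split_from_state} derives them from the youngest band's current
#' composition; \code{all_fit_split} puts every entrant in the fittest
#' state.
#'
#' @param shares numeric vector, one non-negative share per frailty state,
#'   summing to 1 (tolerance 1e-6)
#' @param grid an \code{ff_grid}
#' @return A named numeric vector of shares over the frailty states.
#' @export
entry_split <- function(shares, grid = frailty_grid()) {
  ns <- length(grid$states)
  if (length(shares) != ns) stop("split needs one share per frailty state (", ns, ")")
  if (any(shares < 0) || anyNA(shares)) stop("split shares must be non-negative")
  if (abs(sum(shares) - 1) > 1e-6) stop("split shares must sum to 1")
  stats::setNames(as.numeric(shares), grid$states)
}

#' @rdname entry_split
#' @param state an \code{ff_state} whose youngest band supplies the shares
#' @export
split_from_state <- function(state) {
  grid <- attr(state, "grid")
  idx <- state$band == grid$bands[1]
  tot <- sum(state$alive[idx])
  if (tot <= 0) stop("youngest band is empty; cannot derive an entry split")
  entry_split(state$alive[idx] / tot, grid)
}

#' @rdname entry_split
#' @export
all_fit_split <- function(grid = frailty_grid()) {
  entry_split(c(1, rep(0, length(grid$states) - 1)), grid)
}

#' Close the model for a national population
#'
#' At national scale net migration is assumed negligible: people enter only
#' by reaching age 50 and leave only by dying. This zeroes every entry and
#' de-registration specification and leaves death, ageing and frailty
#' progression untouched. Idempotent.
#'
#' @param params an \code{ff_params}
#' @return The closed \code{ff_params}.
#' @export
national_parameters <- function(params) {
  stopifnot(inherits(params, "ff_params"))
  params$entry <- stats::setNames(lapply(names(params$entry), function(k)
    flow_spec("constant", p = 0, units = "count")), names(params$entry))
  params$dereg <- stats::setNames(lapply(names(params$dereg), function(k)
    flow_spec("constant", p = 0, units = "proportion")), names(params$dereg))
  params
}

#' Run the national model driven by age-50 inflows
#'
#' Each simulated year, that year's projected entrants at age 50 are added
#' to the youngest band (split across frailty states by \code{split})
#' before the synchronous annual step. Polynomial rates freeze at their
#' calibration t_max, so projecting beyond the calibration window assumes
#' transition parameters stay constant.
#'
#' @param initial an \code{ff_state} with a \code{start_year}
#' @param projection an \code{ff_projection} covering every simulated year
#' @param params an \code{ff_params}; normally first passed through
#'   \code{\link{national_parameters}}
#' @param split entrant frailty shares (see \code{\link{entry_split}})
#' @param horizon number of years to project
#' @return An \code{ff_trajectory}; entrants appear in the flow records'
#'   \code{entries} column and in \code{entered_cum}.
#' @export
project_population <- function(initial, projection, params, split, horizon) {
  stopifnot(inherits(initial, "ff_state"), inherits(projection, "ff_projection"),
            inherits(params, "ff_params"), horizon >= 1)
  grid <- attr(initial, "grid")
  split <- entry_split(unname(split), grid)
  start_year <- attr(initial, "start_year")
  if (is.null(start_year)) stop("initial state needs a start_year")
  need <- start_year + seq_len(horizon) - 1
  missing_years <- setdiff(need, projection$entrants$year)
  if (length(missing_years))
    stop("projection does not cover year(s) ", paste(missing_years, collapse = ", "))
  ent <- stats::setNames(projection$entrants$entrants_50, projection$entrants$year)

  states <- vector("list", horizon + 1)
  states[[1]] <- initial
  flows <- vector("list", horizon)
  young <- which(initial$band == grid$bands[1])
  for (h in seq_len(horizon)) {
    yr <- start_year + h - 1
    st <- states[[h]]
    inflow <- ent[[as.character(yr)]] * split
    st$alive[young] <- st$alive[young] + inflow
    st$entered_cum[young] <- st$entered_cum[young] + inflow
    stepped <- step_population(st, params)
    states[[h + 1]] <- stepped$state
    fl <- stepped$flows
    fl$entries[young] <- fl$entries[young] + inflow
    flows[[h]] <- cbind(year = yr, fl)
  }
  structure(list(states = states, flows = do.call(rbind, flows),
                 grid = grid, start_year = start_year),
            class = "ff_trajectory")
}

#' Prevalence summary of a population snapshot
#'
#' Computes, for one year's 16 subgroup counts: the total population aged
#' 50+, each subgroup's share of it, the count and share with any frailty
#' (every state above the fittest), the moderate-plus-severe count, and
#' each age band's share of the frail population.
#'
#' @param counts an \code{ff_state}, or a numeric vector of subgroup counts
#'   in canonical band-major order (optionally named "band|state")
#' @param grid an \code{ff_grid} (ignored when counts is an
#'   \code{ff_state})
#' @return A list of class \code{ff_summary}: \code{total},
#'   \code{subgroups} (data.frame with \code{count} and \code{pct}),
#'   \code{frail_count}, \code{frail_pct}, \code{mod_sev_count},
#'   \code{mod_sev_pct}, \code{band_frail_share} (data.frame, percent of
#'   the frail population per band).
#' @export
summarise_population <- function(counts, grid = frailty_grid()) {
  if (inherits(counts, "ff_state")) {
    grid <- attr(counts, "grid")
    counts <- stats::setNames(counts$alive, sg_key(counts$band, counts$state))
  }
  sg <- subgroup_table(grid)
  keys <- sg_key(sg$band, sg$state)
  if (!is.null(names(counts))) counts <- counts[keys]
  if (length(counts) != nrow(sg) || anyNA(counts) || any(counts < 0))
    stop("counts must be ", nrow(sg), " non-negative values, one per subgroup")
  total <- sum(counts)
  if (total <= 0) stop("all-zero population; nothing to summarise")
  frail_states <- grid$states[-1]
  sev_states <- grid$states[-(1:2)]   # moderate and worse on the 4-state grid
  frail_idx <- sg$state %in% frail_states
  subgroups <- data.frame(band = sg$band, state = sg$state,
                          count = as.numeric(counts),
                          pct = 100 * counts / total,
                          stringsAsFactors = FALSE)
  frail_count <- sum(counts[frail_idx])
  band_frail <- vapply(grid$bands, function(b)
    sum(counts[sg$band == b & frail_idx]), numeric(1))
  structure(list(
    total = total,
    subgroups = subgroups,
    frail_count = frail_count,
    frail_pct = 100 * frail_count / total,
    mod_sev_count = sum(counts[sg$state %in% sev_states]),
    mod_sev_pct = 100 * sum(counts[sg$state %in% sev_states]) / total,
    band_frail_share = data.frame(
      band = grid$bands,
      share_pct = if (frail_count > 0) 100 * band_frail / frail_count else NA_real_,
      stringsAsFactors = FALSE)
  ), class = "ff_summary")
}

#' @export
print.ff_summary <- function(x, ...) {
  cat(sprintf("population 50+: %s (%s thousand)\n",
              format(round(x$total), big.mark = ","),
              format(round(x$total / 1000), big.mark = ",")))
  cat(sprintf("with any frailty: %s (%.1f%%)\n",
              format(round(x$frail_count), big.mark = ","), x$frail_pct))
  cat(sprintf("moderate or severe: %s (%.1f%%)\n",
              format(round(x$mod_sev_count), big.mark = ","), x$mod_sev_pct))
  for (i in seq_len(nrow(x$band_frail_share)))
    cat(sprintf("  band %s: %.1f%% of the frail population\n",
                x$band_frail_share$band[i], x$band_frail_share$share_pct[i]))
  invisible(x)
}
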