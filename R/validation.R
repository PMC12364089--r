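#' Mean absolute percentage error between two annual series
#'
#' \deqn{MAPE = \frac{100}{n}\sum_{i: o_i \ne 0} \frac{|o_i - e_i|}{|o_i|}}
#' Points with a zero observed value are excluded (with a warning) to avoid
#' infinite cells in small subgroups; a series whose observed values are
#' all zero has no defined MAPE and raises an error.
#'
#' @param observed,estimated equal-length numeric series
#' @return The MAPE in percent.
#' @examples
#' mape(c(100, 200), c(110, 180))  # 10
#' @export
mape <- function(observed, estimated) {
  if (length(observed) != length(estimated))
    stop("observed and estimated series differ in length (",
         length(observed), " vs ", length(estimated), ")")
  keep <- observed != 0
  if (!any(keep)) stop("MAPE undefined: observed series is all zero")
  if (!all(keep))
    warning("excluding ", sum(!keep), " point(s) with zero observed value")
  mean(abs(observed[keep] - estimated[keep]) / abs(observed[keep])) * 100
}

ff_cell_variables <- c("Alive", "Entering", "Dying", "Deregistration",
                       "Ageing", "FrailtyTransition")

#' Construct a MAPE table from cell values
#'
#' @param cells data.frame with columns \code{band}, \code{state},
#'   \code{variable} (one of Alive, Entering, Dying, Deregistration,
#'   Ageing, FrailtyTransition) and \code{mape_pct}
#' @param grid an \code{ff_grid}
#' @param weighting "flat" (unweighted mean over all cells, the default)
#'   or "by_variable" (mean of per-variable means)
#' @return An object of class \code{ff_mape_table} (a data.frame) with
#'   attributes \code{overall} and \code{weighting}.
#' @export
mape_table <- function(cells, grid = frailty_grid(),
                       weighting = c("flat", "by_variable")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("band", "state", "variable", "mape_pct") %in% names(cells)))
  if (!all(cells$variable %in% ff_cell_variables))
    stop("unknown MAPE variable(s): ",
         paste(setdiff(cells$variable, ff_cell_variables), collapse = ", "))
  if (any(cells$mape_pct < 0, na.rm = TRUE)) stop("MAPE cells must be non-negative")
  cells <- cells[order(match(cells$band, grid$bands),
                       match(cells$state, grid$states),
                       match(cells$variable, ff_cell_variables)), ]
  rownames(cells) <- NULL
  structure(cells, grid = grid, weighting = weighting,
            overall = mape_overall(cells, weighting),
            class = c("ff_mape_table", "data.frame"))
}

#' Overall MAPE summary of a cell table
#'
#' The published summary weights every variable equally; with "flat"
#' weighting this is the unweighted arithmetic mean over all cells (88 for
#' the 4 x 4 model), which reproduces the published overall statistic from
#' the printed cells. "by_variable" averages the six per-variable means
#' instead.
#'
#' @param cells a data.frame of cells or an \code{ff_mape_table}
#' @param weighting "flat" or "by_variable"
#' @return Overall MAPE in percent.
#' @export
mape_overall <- function(cells, weighting = c("flat", "by_variable")) {
  weighting <- match.arg(weighting)
  v <- cells$mape_pct
  if (anyNA(v)) {
    warning("ignoring ", sum(is.na(v)), " undefined MAPE cell(s)")
  }
  if (weighting == "flat") mean(v, na.rm = TRUE)
  else mean(tapply(v, cells$variable, mean, na.rm = TRUE))
}

#' @export
print.ff_mape_table <- function(x, ...) {
  cat(sprintf("MAPE table: %d cells, overall %.2f%% (%s weighting)\n",
              nrow(x), attr(x, "overall"), attr(x, "weighting")))
  invisible(x)
}

#' Score a simulated trajectory against observed cohort data
#'
#' Builds the per-subgroup error grid: one cell per variable per applicable
#' subgroup (Alive, Entering, Dying, Deregistration for every subgroup;
#' Ageing only where an older band exists; FrailtyTransition only where a
#' more severe state exists), plus an equal-weighted overall summary. For
#' the 4 x 4 model that is 88 cells. Stocks are compared at the start of
#' every overlapping year (including year 0, which contributes 0 when the
#' initial conditions were copied from the observations); flows are
#' compared on within-year totals.
#'
#' @param obs an \code{ff_observations}
#' @param traj an \code{ff_trajectory} whose initial state carries a
#'   \code{start_year}
#' @param weighting overall summary mode, see \code{\link{mape_overall}}
#' @return An \code{ff_mape_table}.
#' @export
build_mape_table <- function(obs, traj, weighting = c("flat", "by_variable")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(obs, "ff_observations"), inherits(traj, "ff_trajectory"))
  grid <- attr(obs, "grid")
  if (is.null(traj$start_year))
    stop("trajectory has no start_year; simulate from a state built with one")
  obs_years <- sort(unique(obs$year))
  t0 <- attr(traj$states[[1]], "t")
  stock_years <- traj$start_year + t0 + seq_along(traj$states) - 1
  flow_years <- sort(unique(traj$flows$year))
  common_stock <- intersect(obs_years, stock_years)
  common_flow <- intersect(obs_years, flow_years)
  if (length(common_stock) < 2)
    stop("observed years (", min(obs_years), "-", max(obs_years),
         ") and simulated years (", min(stock_years), "-", max(stock_years),
         ") overlap in fewer than 2 years")

  sim_stocks <- do.call(rbind, lapply(seq_along(traj$states), function(i) {
    st <- traj$states[[i]]
    data.frame(year = stock_years[i], band = st$band, state = st$state,
               alive = st$alive, stringsAsFactors = FALSE)
  }))
  sg <- subgroup_table(grid)
  last_band <- grid$bands[length(grid$bands)]
  last_state <- grid$states[length(grid$states)]
  flow_map <- c(Entering = "entries", Dying = "deaths",
                Deregistration = "deregs", Ageing = "ageing_out",
                FrailtyTransition = "progression_out")

  cells <- list()
  for (i in seq_len(nrow(sg))) {
    b <- sg$band[i]; s <- sg$state[i]
    o <- obs[obs$band == b & obs$state == s, , drop = FALSE]
    cell <- function(variable, value) {
      cells[[length(cells) + 1]] <<- data.frame(
        band = b, state = s, variable = variable, mape_pct = value,
        stringsAsFactors = FALSE)
    }
    safe_mape <- function(o_series, e_series) {
      tryCatch(mape(o_series, e_series),
               error = function(e) NA_real_)
    }
    ssim <- sim_stocks[sim_stocks$band == b & sim_stocks$state == s, , drop = FALSE]
    cell("Alive", safe_mape(o$alive_start[match(common_stock, o$year)],
                            ssim$alive[match(common_stock, ssim$year)]))
    fsim <- traj$flows[traj$flows$band == b & traj$flows$state == s, , drop = FALSE]
    for (variable in names(flow_map)) {
      if (variable == "Ageing" && b == last_band) next
      if (variable == "FrailtyTransition" && s == last_state) next
      col <- flow_map[[variable]]
      obs_col <- c(entries = "entries", deaths = "deaths", deregs = "deregs",
                   ageing_out = "ageing_out",
                   progression_out = "progression_out")[[col]]
      cell(variable, safe_mape(o[[obs_col]][match(common_flow, o$year)],
                               fsim[[col]][match(common_flow, fsim$year)]))
    }
  }
  mape_table(do.call(rbind, cells), grid = grid, weighting = weighting)
}

scale_one_spec <- function(spec, f) {
  if (spec$kind == "constant") {
    raw <- spec$p * f
    if (spec$units == "proportion" && raw > 1)
      warning("rescaled constant proportion exceeds 1; clamped at evaluation")
    spec$p <- raw
  } else {
    spec$beta <- spec$beta * f
  }
  spec
}

#' Rescale entry and de-registration parameters for another cohort
#'
#' When transferring a model calibrated on one cohort to a population with
#' different coverage, the entry and de-registration rates are multiplied
#' by constant scaling factors (both constant values and polynomial
#' coefficients scale linearly); all other flows are untouched. Factors of
#' 0 remove the flows entirely, which yields the closed national model.
#'
#' @param params an \code{ff_params}
#' @param entry_scale,dereg_scale non-negative multiplier, either a scalar
#'   or a named vector keyed "band|state" (missing keys default to 1)
#' @return The rescaled \code{ff_params}.
#' @export
rescale_parameters <- function(params, entry_scale = 1, dereg_scale = 1) {
  stopifnot(inherits(params, "ff_params"))
  if (any(entry_scale < 0) || any(dereg_scale < 0))
    stop("scaling factors must be non-negative")
  apply_scale <- function(specs, f) {
    if (is.null(names(f))) {
      if (length(f) != 1) stop("unnamed scaling factor must be a scalar")
      fv <- stats::setNames(rep(f, length(specs)), names(specs))
    } else {
      bad <- setdiff(names(f), names(specs))
      if (length(bad)) stop("scaling factor for unknown subgroup(s): ",
                            paste(bad, collapse = ", "))
      fv <- stats::setNames(rep(1, length(specs)), names(specs))
      fv[names(f)] <- f
    }
    stats::setNames(lapply(names(specs), function(k)
      scale_one_spec(specs[[k]], fv[[k]])), names(specs))
  }
  params$entry <- apply_scale(params$entry, entry_scale)
  params$dereg <- apply_scale(params$dereg, dereg_scale)
  params
}

#' Rescale initial frailty prevalence to target shares
#'
#' Replaces the frailty-state composition of the alive stocks by target
#' shares while preserving totals: in "band" mode each age band's total is
#' preserved and split by the band's target shares; in "overall" mode the
#' grand total is preserved and split by 16 subgroup shares. Used to adjust
#' an external cohort's initial prevalence to match the calibration
#' cohort's.
#'
#' @param state an \code{ff_state}
#' @param targets data.frame with columns \code{band}, \code{state},
#'   \code{share} (shares are normalised within each band, or overall)
#' @param mode "band" or "overall"
#' @return The rescaled \code{ff_state}.
#' @export
scale_initial_prevalence <- function(state, targets, mode = c("band", "overall")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "ff_state"),
            all(c("band", "state", "share") %in% names(targets)))
  if (any(targets$share < 0) || anyNA(targets$share))
    stop("target shares must be non-negative")
  grid <- attr(state, "grid")
  key_s <- sg_key(state$band, state$state)
  key_t <- sg_key(targets$band, targets$state)
  share <- stats::setNames(targets$share, key_t)[key_s]
  if (anyNA(share))
    stop("targets missing subgroup(s): ", paste(key_s[is.na(share)], collapse = ", "))
  new <- state
  if (mode == "band") {
    for (b in grid$bands) {
      idx <- state$band == b
      tot_share <- sum(share[idx])
      if (tot_share <= 0) stop("target shares sum to zero in band ", b)
      new$alive[idx] <- sum(state$alive[idx]) * share[idx] / tot_share
    }
  } else {
    tot_share <- sum(share)
    if (tot_share <= 0) stop("target shares sum to zero")
    new$alive <- sum(state$alive) * share / tot_share
  }
  new
}
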