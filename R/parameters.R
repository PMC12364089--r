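#' Flow specification: a constant or time-polynomial rate
#'
#' Every flow in the model is driven either by a constant annual proportion
#' (or entry count) or by a cubic-at-most polynomial in model time t,
#' \eqn{\beta_0 + \beta_1 t + \beta_2 t^2 + \beta_3 t^3}. Polynomial
#' specifications carry a \code{t_max}: beyond the calibration window the
#' rate is frozen at its \code{t_max} value, so projections never
#' extrapolate a cubic.
#'
#' @param kind "constant" or "polynomial"
#' @param p constant value (annual proportion, or persons/year for entry
#'   flows)
#' @param beta numeric coefficients (beta0, beta1, beta2, beta3); shorter
#'   vectors are zero-padded
#' @param t_max final calibration time; polynomial evaluation uses
#'   \code{min(t, t_max)}
#' @param units "proportion" (clamped to [0, 1] at evaluation) or "count"
#'   (clamped below at 0)
#' @return An object of class \code{ff_flow_spec}.
#' @export
flow_spec <- function(kind = c("constant", "polynomial"), p = NULL,
                      beta = NULL, t_max = Inf,
                      units = c("proportion", "count")) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  if (kind == "constant") {
    if (is.null(p) || length(p) != 1 || is.na(p))
      stop("constant flow_spec requires a single value p")
    if (p < 0) stop("constant flow value must be non-negative")
    if (units == "proportion" && p > 1)
      warning("constant proportion ", format(p), " exceeds 1; it will be clamped at evaluation")
    spec <- list(kind = kind, p = as.numeric(p), t_max = Inf, units = units)
  } else {
    if (is.null(beta) || length(beta) < 1 || length(beta) > 4 || anyNA(beta))
      stop("polynomial flow_spec requires 1-4 coefficients beta")
    beta <- c(as.numeric(beta), rep(0, 4 - length(beta)))
    if (!is.finite(t_max)) stop("polynomial flow_spec requires a finite t_max")
    spec <- list(kind = kind, beta = beta, t_max = as.numeric(t_max), units = units)
  }
  structure(spec, class = "ff_flow_spec")
}

#' @export
print.ff_flow_spec <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("flow spec: constant %s (%s)\n", format(x$p), x$units))
  } else {
    cat(sprintf("flow spec: polynomial beta = (%s), frozen at t = %g (%s)\n",
                paste(format(x$beta), collapse = ", "), x$t_max, x$units))
  }
  invisible(x)
}

#' Evaluate a flow specification at model time t
#'
#' Polynomial specs are evaluated at \code{min(t, t_max)} (the freezing
#' rule); proportions are clamped to [0, 1] and counts to [0, Inf). A
#' warning is raised when clamping actually changes the value unless
#' \code{warn_clamp = FALSE}.
#'
#' @param spec an \code{ff_flow_spec}
#' @param t model time(s) in years, >= 0
#' @param warn_clamp warn when the raw value falls outside the admissible
#'   range
#' @return Numeric vector of evaluated rates.
#' @export
eval_flow_spec <- function(spec, t, warn_clamp = TRUE) {
  stopifnot(inherits(spec, "ff_flow_spec"))
  if (any(t < 0)) stop("model time t must be non-negative")
  if (spec$kind == "constant") {
    raw <- rep(spec$p, length(t))
  } else {
    tt <- pmin(t, spec$t_max)
    raw <- spec$beta[1] + spec$beta[2] * tt + spec$beta[3] * tt^2 + spec$beta[4] * tt^3
  }
  hi <- if (spec$units == "proportion") 1 else Inf
  val <- pmin(pmax(raw, 0), hi)
  if (warn_clamp && any(val != raw))
    warning(sprintf("flow value clamped to [0, %s] (raw range %s..%s)",
                    format(hi), format(min(raw)), format(max(raw))))
  val
}

sg_key <- function(band, state) paste(band, state, sep = "|")

#' Required flow keys for a grid
#'
#' Death, de-registration and entry flows exist for every subgroup; ageing
#' for every subgroup except the terminal band; frailty progression for
#' every subgroup except the terminal state.
#' @param grid an \code{ff_grid}
#' @param flow one of "death", "dereg", "entry", "ageing", "progression"
#' @return Character vector of subgroup keys in canonical band-major order.
#' @keywords internal
required_keys <- function(grid, flow) {
  sg <- subgroup_table(grid)
  keep <- switch(flow,
    death = , dereg = , entry = rep(TRUE, nrow(sg)),
    ageing = sg$band != grid$bands[length(grid$bands)],
    progression = sg$state != grid$states[length(grid$states)],
    stop("unknown flow: ", flow)
  )
  sg_key(sg$band[keep], sg$state[keep])
}

#' Model parameters: one flow specification per subgroup per flow
#'
#' For a grid of \code{nb} bands and \code{ns} states the full set is
#' \code{nb*ns} death, de-registration and entry specs, \code{(nb-1)*ns}
#' ageing specs, and \code{nb*(ns-1)} frailty-progression specs (no ageing
#' out of the terminal band; the most severe state is absorbing). For the
#' 4 x 4 frailty grid that is 16 + 16 + 16 + 12 + 12 = 72 flows.
#'
#' @param grid an \code{ff_grid}
#' @param death,dereg,entry,ageing,progression named lists of
#'   \code{\link{flow_spec}} objects, keyed "band|state"
#' @return An object of class \code{ff_params}.
#' @export
model_parameters <- function(grid, death, dereg, entry, ageing, progression) {
  stopifnot(inherits(grid, "ff_grid"))
  flows <- list(death = death, dereg = dereg, entry = entry,
                ageing = ageing, progression = progression)
  for (fl in names(flows)) {
    need <- required_keys(grid, fl)
    have <- names(flows[[fl]])
    missing <- setdiff(need, have)
    if (length(missing))
      stop("configuration error: missing ", fl, " flow spec for subgroup(s) ",
           paste(missing, collapse = ", "))
    extra <- setdiff(have, need)
    if (length(extra))
      stop("configuration error: ", fl, " flow spec given for invalid subgroup(s) ",
           paste(extra, collapse = ", "))
    ok <- vapply(flows[[fl]], inherits, logical(1), what = "ff_flow_spec")
    if (!all(ok))
      stop("configuration error: ", fl, " entries must be flow_spec objects")
    units <- vapply(flows[[fl]], `[[`, character(1), "units")
    want <- if (fl == "entry") "count" else "proportion"
    if (!all(units == want))
      stop("configuration error: ", fl, " flow specs must have units '", want, "'")
    flows[[fl]] <- flows[[fl]][need]  # canonical order
  }
  structure(c(list(grid = grid), flows), class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  nfl <- sum(lengths(x[c("death", "dereg", "entry", "ageing", "progression")]))
  cat("model parameters:", length(x$grid$bands), "x", length(x$grid$states),
      "grid,", nfl, "flow specifications\n")
  invisible(x)
}

#' Uniform constant parameters (convenience constructor)
#'
#' Builds a complete parameter set in which every subgroup shares the same
#' constant rates. Mostly useful for tests, worked examples and as a
#' starting point for hand-edited configurations.
#'
#' @param grid an \code{ff_grid}
#' @param p_death,p_dereg,p_age,p_prog annual proportions, recycled across
#'   subgroups (a scalar or a vector of one value per subgroup in canonical
#'   order)
#' @param entry expected entrants per year per subgroup
#' @return An \code{ff_params} object.
#' @export
constant_parameters <- function(grid = frailty_grid(), p_death = 0,
                                p_dereg = 0, p_age = 0, p_prog = 0,
                                entry = 0) {
  sg <- subgroup_table(grid)
  keys <- sg_key(sg$band, sg$state)
  make <- function(vals, keys_all, keys_need, units) {
    vals <- rep_len(vals, length(keys_all))
    names(vals) <- keys_all
    stats::setNames(
      lapply(vals[keys_need], function(v) flow_spec("constant", p = v, units = units)),
      keys_need)
  }
  model_parameters(
    grid,
    death = make(p_death, keys, required_keys(grid, "death"), "proportion"),
    dereg = make(p_dereg, keys, required_keys(grid, "dereg"), "proportion"),
    entry = make(entry, keys, required_keys(grid, "entry"), "count"),
    ageing = make(p_age, keys, required_keys(grid, "ageing"), "proportion"),
    progression = make(p_prog, keys, required_keys(grid, "progression"), "proportion")
  )
}

#' Example parameter set with age- and frailty-graded rates
#'
#' A plausible stated world for demonstrations and the synthetic-cohort
#' generator: annual death proportions rise with age band and frailty
#' state, ageing rates are the reciprocal of band width, frailty
#' progression is a few percent per year, de-registration is a flat 3%,
#' and entries are proportional to the initial cohort distribution.
#'
#' @param grid an \code{ff_grid} (defaults to the 4 x 4 frailty grid; the
#'   graded values assume this grid)
#' @param cohort_size total cohort size used to scale entry intensities
#' @param entry_rate expected entrants per year as a fraction of the
#'   initial subgroup stock
#' @return An \code{ff_params} object.
#' @export
example_parameters <- function(grid = frailty_grid(), cohort_size = 1e5,
                               entry_rate = 0.05) {
  nb <- length(grid$bands); ns <- length(grid$states)
  band_death <- seq(0.004, 0.11, length.out = nb)
  state_mult <- seq(1, 3.5, length.out = ns)
  widths <- age_band_table()$width
  band_age <- if (identical(grid$bands, age_bands())) 1 / widths[-nb] else
    rep(0.08, nb - 1)
  state_prog <- seq(0.04, 0.06, length.out = max(ns - 1, 1))
  band_prog_mult <- seq(0.7, 1.5, length.out = nb)
  shares <- if (identical(grid, frailty_grid()))
    ff_fixture("table1")$share_pct[seq_len(16)] / 100 else
    rep(1 / (nb * ns), nb * ns)

  sg <- subgroup_table(grid)
  keys <- sg_key(sg$band, sg$state)
  bi <- match(sg$band, grid$bands); si <- match(sg$state, grid$states)
  spec_p <- function(v) flow_spec("constant", p = v, units = "proportion")
  spec_n <- function(v) flow_spec("constant", p = v, units = "count")

  death <- stats::setNames(lapply(band_death[bi] * state_mult[si], spec_p), keys)
  dereg <- stats::setNames(lapply(rep(0.03, nb * ns), spec_p), keys)
  entry <- stats::setNames(lapply(shares * cohort_size * entry_rate, spec_n), keys)
  k_age <- required_keys(grid, "ageing")
  ageing <- stats::setNames(lapply(band_age[bi[match(k_age, keys)]], spec_p), k_age)
  k_prog <- required_keys(grid, "progression")
  progression <- stats::setNames(
    lapply(state_prog[si[match(k_prog, keys)]] * band_prog_mult[bi[match(k_prog, keys)]],
           spec_p), k_prog)
  model_parameters(grid, death, dereg, entry, ageing, progression)
}
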