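#' Cohort observations: annual stocks and flow counts per subgroup
#'
#' The calibration input is a long table with one row per calendar year per
#' subgroup: the start-of-year alive count and the within-year counts of
#' deaths, de-registrations, entries, ageing transitions out and frailty
#' transitions out. This mirrors the structure of annual primary-care
#' cohort extracts.
#'
#' @param df data.frame with columns \code{year}, \code{band}, \code{state},
#'   \code{alive_start}, \code{deaths}, \code{deregs}, \code{entries},
#'   \code{ageing_out}, \code{progression_out}
#' @param grid an \code{ff_grid}; every (year, band, state) combination over
#'   the observed year range must be present
#' @return The validated data.frame with class \code{ff_observations},
#'   ordered by year then canonical subgroup, with attribute \code{grid}.
#' @export
cohort_observations <- function(df, grid = frailty_grid()) {
  req <- c("year", "band", "state", "alive_start", "deaths", "deregs",
           "entries", "ageing_out", "progression_out")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("observations are missing column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), req)
  if (length(extra))
    stop("observations contain unknown column(s): ", paste(extra, collapse = ", "))
  if (!nrow(df)) stop("empty observation set")
  bad_band <- setdiff(unique(df$band), grid$bands)
  if (length(bad_band)) stop("unknown age band in observations: ", paste(bad_band, collapse = ", "))
  bad_state <- setdiff(unique(df$state), grid$states)
  if (length(bad_state)) stop("unknown frailty state in observations: ", paste(bad_state, collapse = ", "))
  sg <- subgroup_table(grid)
  years <- sort(unique(df$year))
  want <- expand.grid(year = years, key = sg_key(sg$band, sg$state),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(df$year, sg_key(df$band, df$state))
  miss <- want[!paste(want$year, want$key) %in% have, , drop = FALSE]
  if (nrow(miss))
    stop("observations are missing row(s): ",
         paste(sprintf("(%s, %s)", miss$year, sub("\\|", ", ", miss$key)),
               collapse = "; "))
  if (anyDuplicated(have)) stop("duplicate (year, band, state) rows in observations")
  num <- c("alive_start", "deaths", "deregs", "entries", "ageing_out", "progression_out")
  for (cn in num) {
    if (anyNA(df[[cn]]) || any(df[[cn]] < 0))
      stop("negative or missing values in column ", cn)
  }
  outsum <- df$deaths + df$deregs + df$ageing_out + df$progression_out
  if (any(outsum > df$alive_start + 1e-9))
    warning("outflow counts exceed start-of-year alive in ",
            sum(outsum > df$alive_start + 1e-9), " row(s); kept as observed")
  df <- df[order(df$year, match(df$band, grid$bands), match(df$state, grid$states)), ]
  rownames(df) <- NULL
  structure(df, grid = grid, class = c("ff_observations", "data.frame"))
}

#' Yearly transition proportions for one subgroup and flow
#'
#' The annual proportion is the within-year flow count divided by the
#' start-of-year alive count; years with an empty subgroup are excluded
#' with a warning.
#'
#' @param obs an \code{ff_observations}
#' @param band,state subgroup labels
#' @param flow one of "deaths", "deregs", "ageing_out", "progression_out"
#' @return A data.frame with columns \code{t} (years since the first
#'   observed year) and \code{proportion}.
#' @export
yearly_proportions <- function(obs, band, state,
                               flow = c("deaths", "deregs", "ageing_out",
                                        "progression_out")) {
  stopifnot(inherits(obs, "ff_observations"))
  flow <- match.arg(flow)
  rows <- obs[obs$band == band & obs$state == state, , drop = FALSE]
  if (!nrow(rows)) stop("no observations for subgroup (", band, ", ", state, ")")
  keep <- rows$alive_start > 0
  if (!all(keep))
    warning("excluding ", sum(!keep), " year(s) with zero alive_start for (",
            band, ", ", state, ")")
  rows <- rows[keep, , drop = FALSE]
  if (!nrow(rows)) stop("empty observation set for (", band, ", ", state,
                        ") after excluding zero-population years")
  data.frame(t = rows$year - min(obs$year),
             proportion = rows[[flow]] / rows$alive_start)
}

# Ordinary least-squares polynomial fits of degree 0..max_degree with
# forward nested F-tests: the degree is raised only while the added term is
# significant at alpha. Noiseless data yield F = Inf (accept) and then NaN
# (stop), so exact polynomials recover their true degree.
ff_fit_poly <- function(t, y, max_degree, alpha, units) {
  n <- length(t)
  if (n < 2) {
    warning("fewer than 2 points; returning constant spec equal to the mean")
    return(list(spec = flow_spec("constant", p = max(mean(y), 0), units = units),
                degree = 0L, rss = 0,
                trace = data.frame(degree = 0L, rss = 0, p_value = NA_real_)))
  }
  max_degree <- min(max_degree, n - 2L)   # need >= degree + 2 points
  max_degree <- max(max_degree, 0L)
  fits <- vector("list", max_degree + 1)
  fits[[1]] <- stats::lm(y ~ 1)
  if (max_degree >= 1)
    for (d in seq_len(max_degree))
      fits[[d + 1]] <- stats::lm(y ~ stats::poly(t, d, raw = TRUE))
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  tss <- sum((y - mean(y))^2)
  exact_tol <- 1e-12 * max(tss, .Machine$double.eps)
  pvals <- rep(NA_real_, max_degree + 1)
  degree <- 0L
  if (max_degree >= 1) {
    for (d in seq_len(max_degree)) {
      if (rss[d] <= exact_tol) break   # current model already exact
      an <- stats::anova(fits[[d]], fits[[d + 1]])
      pv <- an$`Pr(>F)`[2]
      if (rss[d + 1] <= exact_tol) pv <- 0   # exact improvement
      pvals[d + 1] <- pv
      if (!is.na(pv) && pv < alpha) degree <- d else break
    }
  }
  coefs <- unname(stats::coef(fits[[degree + 1]]))
  coefs[is.na(coefs)] <- 0
  spec <- if (degree == 0L) {
    flow_spec("constant", p = max(coefs[1], 0), units = units)
  } else {
    flow_spec("polynomial", beta = coefs, t_max = max(t), units = units)
  }
  list(spec = spec, degree = degree, rss = rss[degree + 1],
       trace = data.frame(degree = 0:max_degree, rss = rss, p_value = pvals))
}

#' Fit a flow specification to yearly proportions
#'
#' Ordinary least squares on the raw proportion scale with polynomial time
#' covariates (t, t^2, t^3 at most). The degree is selected by forward
#' nested F-tests: starting from a constant, a higher degree is accepted
#' only while the added term is significant at \code{alpha}. The returned
#' specification freezes polynomial rates at the last observed time.
#'
#' @param points data.frame with columns \code{t} and \code{proportion}
#'   (as from \code{\link{yearly_proportions}})
#' @param max_degree highest polynomial degree attempted (default 3);
#'   automatically lowered when fewer than degree + 2 points are available
#' @param alpha significance level of the nested F-tests
#' @return A list of class \code{ff_fitted_flow}: \code{spec} (an
#'   \code{ff_flow_spec}), \code{degree}, \code{rss} and \code{trace}
#'   (per-degree RSS and F-test p-values).
#' @export
fit_flow <- function(points, max_degree = 3, alpha = 0.05) {
  stopifnot(is.data.frame(points), all(c("t", "proportion") %in% names(points)))
  out <- ff_fit_poly(points$t, points$proportion, max_degree, alpha, "proportion")
  structure(out, class = "ff_fitted_flow")
}

#' Fit an entry specification to yearly entry counts
#'
#' Entries are an exogenous inflow with no source stock, so they are fitted
#' on raw counts (persons/year), not proportions; otherwise identical to
#' \code{\link{fit_flow}}.
#'
#' @param obs an \code{ff_observations}
#' @param band,state subgroup labels
#' @param max_degree,alpha see \code{\link{fit_flow}}
#' @return An \code{ff_fitted_flow} whose spec has units "count".
#' @export
fit_entry <- function(obs, band, state, max_degree = 3, alpha = 0.05) {
  stopifnot(inherits(obs, "ff_observations"))
  rows <- obs[obs$band == band & obs$state == state, , drop = FALSE]
  if (!nrow(rows)) stop("no observations for subgroup (", band, ", ", state, ")")
  out <- ff_fit_poly(rows$year - min(obs$year), rows$entries, max_degree,
                     alpha, "count")
  structure(out, class = "ff_fitted_flow")
}

#' @export
print.ff_fitted_flow <- function(x, ...) {
  cat(sprintf("fitted flow: degree %d, RSS %.3g\n", x$degree, x$rss))
  print(x$spec)
  invisible(x)
}

#' Calibrate a full parameter set from cohort observations
#'
#' Fits one flow specification per required flow (for the 4 x 4 grid:
#' 16 death + 16 de-registration + 16 entry + 12 ageing + 12 frailty
#' progression = 72) using \code{\link{fit_flow}} / \code{\link{fit_entry}}.
#' The per-flow selection trace is attached as the calibration report
#' (see \code{\link{calibration_report}}), so individual functional forms
#' can be inspected and overridden in configuration.
#'
#' @param obs an \code{ff_observations} covering at least 2 consecutive
#'   years
#' @param max_degree,alpha model-selection controls, see
#'   \code{\link{fit_flow}}
#' @return An \code{ff_params} with attribute \code{calibration_report}.
#' @export
calibrate <- function(obs, max_degree = 3, alpha = 0.05) {
  stopifnot(inherits(obs, "ff_observations"))
  grid <- attr(obs, "grid")
  if (length(unique(obs$year)) < 2)
    stop("calibration requires observations for at least 2 years")
  flow_col <- c(death = "deaths", dereg = "deregs", ageing = "ageing_out",
                progression = "progression_out")
  specs <- list(); report <- list()
  for (fl in c("death", "dereg", "ageing", "progression")) {
    keys <- required_keys(grid, fl)
    specs[[fl]] <- stats::setNames(vector("list", length(keys)), keys)
    for (k in keys) {
      bs <- strsplit(k, "|", fixed = TRUE)[[1]]
      pts <- yearly_proportions(obs, bs[1], bs[2], flow_col[[fl]])
      fit <- fit_flow(pts, max_degree = max_degree, alpha = alpha)
      specs[[fl]][[k]] <- fit$spec
      report[[length(report) + 1]] <- data.frame(
        band = bs[1], state = bs[2], flow = fl, degree = fit$degree,
        rss = fit$rss,
        beta0 = if (fit$spec$kind == "constant") fit$spec$p else fit$spec$beta[1],
        beta1 = if (fit$spec$kind == "constant") 0 else fit$spec$beta[2],
        beta2 = if (fit$spec$kind == "constant") 0 else fit$spec$beta[3],
        beta3 = if (fit$spec$kind == "constant") 0 else fit$spec$beta[4],
        stringsAsFactors = FALSE)
    }
  }
  keys <- required_keys(grid, "entry")
  specs$entry <- stats::setNames(vector("list", length(keys)), keys)
  for (k in keys) {
    bs <- strsplit(k, "|", fixed = TRUE)[[1]]
    fit <- fit_entry(obs, bs[1], bs[2], max_degree = max_degree, alpha = alpha)
    specs$entry[[k]] <- fit$spec
    report[[length(report) + 1]] <- data.frame(
      band = bs[1], state = bs[2], flow = "entry", degree = fit$degree,
      rss = fit$rss,
      beta0 = if (fit$spec$kind == "constant") fit$spec$p else fit$spec$beta[1],
      beta1 = if (fit$spec$kind == "constant") 0 else fit$spec$beta[2],
      beta2 = if (fit$spec$kind == "constant") 0 else fit$spec$beta[3],
      beta3 = if (fit$spec$kind == "constant") 0 else fit$spec$beta[4],
      stringsAsFactors = FALSE)
  }
  params <- model_parameters(grid, death = specs$death, dereg = specs$dereg,
                             entry = specs$entry, ageing = specs$ageing,
                             progression = specs$progression)
  attr(params, "calibration_report") <- do.call(rbind, report)
  params
}

#' Per-flow calibration report
#' @param params an \code{ff_params} produced by \code{\link{calibrate}}
#' @return A data.frame with chosen degree, RSS and coefficients per flow,
#'   or NULL for parameters not produced by calibration.
#' @export
calibration_report <- function(params) attr(params, "calibration_report")

#' Initial population state from an observed year
#'
#' Copies the chosen year's start-of-year alive counts into a fresh
#' population state (accounting stocks zero, model time zero).
#'
#' @param obs an \code{ff_observations}
#' @param year calendar year present in the observations (default: first)
#' @return An \code{ff_state} with \code{start_year = year}.
#' @export
initial_state_from <- function(obs, year = min(obs$year)) {
  stopifnot(inherits(obs, "ff_observations"))
  if (!year %in% obs$year) stop("year ", year, " not present in observations")
  grid <- attr(obs, "grid")
  rows <- obs[obs$year == year, , drop = FALSE]
  alive <- stats::setNames(rows$alive_start, sg_key(rows$band, rows$state))
  population_state(alive, grid = grid, t = 0, start_year = year)
}
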