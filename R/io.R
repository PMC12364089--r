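#' @title File readers and writers
#' @description CSV for tables, JSON for parameter sets. All writers emit a
#'   header; all readers reject files that do not match the documented
#'   schema, naming the file and offending column. Round trips are
#'   lossless at full double precision.
#' @name frailtyflow-io
NULL

ff_read_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required column(s) ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(df), c(required, optional))
  if (length(unknown))
    stop(path, ": unknown column(s) ", paste(unknown, collapse = ", "))
  df
}

#' Read / write cohort observation tables
#'
#' Long-format CSV with columns year, band, state, alive_start, deaths,
#' deregs, entries, ageing_out, progression_out.
#'
#' @param path CSV file path
#' @param grid an \code{ff_grid}
#' @return \code{read_observations}: an \code{ff_observations}.
#' @export
read_observations <- function(path, grid = frailty_grid()) {
  df <- ff_read_csv(path, c("year", "band", "state", "alive_start", "deaths",
                            "deregs", "entries", "ageing_out", "progression_out"))
  tryCatch(cohort_observations(df, grid = grid),
           error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' @rdname read_observations
#' @param obs an \code{ff_observations}
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "ff_observations"))
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

spec_to_list <- function(spec) {
  if (spec$kind == "constant")
    list(kind = "constant", p = spec$p, units = spec$units)
  else
    list(kind = "polynomial", beta = as.list(spec$beta), t_max = spec$t_max,
         units = spec$units)
}

spec_from_list <- function(x, where) {
  if (is.null(x$kind) || !x$kind %in% c("constant", "polynomial"))
    stop("invalid flow spec at ", where, ": kind must be constant or polynomial")
  units <- if (is.null(x$units)) "proportion" else x$units
  if (x$kind == "constant") {
    if (is.null(x$p)) stop("invalid flow spec at ", where, ": constant needs p")
    flow_spec("constant", p = x$p, units = units)
  } else {
    if (is.null(x$beta)) stop("invalid flow spec at ", where, ": polynomial needs beta")
    flow_spec("polynomial", beta = unlist(x$beta),
              t_max = if (is.null(x$t_max)) Inf else x$t_max, units = units)
  }
}

#' Read / write model parameter files (JSON)
#'
#' The schema has a \code{grid} block (bands, states) and a \code{flows}
#' block with one entry per flow type per subgroup key ("band|state"),
#' each either \code{{kind: constant, p, units}} or
#' \code{{kind: polynomial, beta, t_max, units}}. Writing then reading
#' reproduces the parameter object exactly.
#'
#' @param path JSON file path
#' @return \code{read_params}: an \code{ff_params}.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$grid) || is.null(x$flows))
    stop(path, ": parameter file needs 'grid' and 'flows' blocks")
  grid <- model_grid(unlist(x$grid$bands), unlist(x$grid$states))
  flows <- lapply(stats::setNames(nm = c("death", "dereg", "entry", "ageing",
                                         "progression")), function(fl) {
    block <- x$flows[[fl]]
    if (is.null(block)) stop(path, ": missing flow block '", fl, "'")
    stats::setNames(lapply(names(block), function(k)
      spec_from_list(block[[k]], paste0(path, " flows.", fl, ".", k))),
      names(block))
  })
  tryCatch(
    model_parameters(grid, death = flows$death, dereg = flows$dereg,
                     entry = flows$entry, ageing = flows$ageing,
                     progression = flows$progression),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' @rdname read_params
#' @param params an \code{ff_params}
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ff_params"))
  x <- list(
    grid = list(bands = params$grid$bands, states = params$grid$states),
    flows = lapply(params[c("death", "dereg", "entry", "ageing", "progression")],
                   function(specs) lapply(specs, spec_to_list))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write population projections
#'
#' CSV schema: \code{year}, \code{entrants_50}, optionally \code{band} and
#' \code{population} (long per-band population estimates, with
#' \code{entrants_50} repeated within a year).
#'
#' @param path CSV file path
#' @return \code{read_projection}: an \code{ff_projection}.
#' @export
read_projection <- function(path) {
  df <- ff_read_csv(path, c("year", "entrants_50"), c("band", "population"))
  if ("band" %in% names(df)) {
    ent <- unique(df[, c("year", "entrants_50")])
    if (anyDuplicated(ent$year))
      stop(path, ": entrants_50 differs across rows of the same year")
    population_projection(ent, df[, c("year", "band", "population")])
  } else {
    population_projection(df)
  }
}

#' @rdname read_projection
#' @param projection an \code{ff_projection}
#' @export
write_projection <- function(projection, path) {
  stopifnot(inherits(projection, "ff_projection"))
  if (is.null(projection$band_populations)) {
    utils::write.csv(projection$entrants, path, row.names = FALSE, quote = FALSE)
  } else {
    bp <- projection$band_populations
    bp$entrants_50 <- projection$entrants$entrants_50[match(bp$year,
                                                            projection$entrants$year)]
    utils::write.csv(bp[, c("year", "entrants_50", "band", "population")],
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a MAPE table as CSV
#'
#' Wide layout mirroring the published validation tables: one row per
#' subgroup, one column per variable (the frailty-transition cell sits on
#' its source state's row), and a final footer row carrying the overall
#' equal-weighted summary.
#'
#' @param mt an \code{ff_mape_table}
#' @param path CSV file path
#' @export
write_mape_table <- function(mt, path) {
  stopifnot(inherits(mt, "ff_mape_table"))
  grid <- attr(mt, "grid")
  sg <- subgroup_table(grid)
  wide <- data.frame(band = sg$band, state = sg$state, stringsAsFactors = FALSE)
  for (v in ff_cell_variables) {
    m <- match(paste(sg$band, sg$state, v),
               paste(mt$band, mt$state, mt$variable))
    wide[[v]] <- mt$mape_pct[m]
  }
  footer <- wide[1, ]
  footer[1, ] <- NA
  footer$band <- "Overall"
  footer$state <- attr(mt, "weighting")
  footer$Alive <- attr(mt, "overall")
  utils::write.csv(rbind(wide, footer), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged transcriptions of the published tables
#'
#' Plain-CSV transcriptions shipped with the package: "table1" (initial
#' subgroup percentages of both source cohorts), "table2" / "table3"
#' (internal / external validation MAPE cells, returned as
#' \code{ff_mape_table}s of 88 cells each), "table4" (projected subgroup
#' counts and percentages for 2017 and 2027).
#'
#' @param name one of "table1", "table2", "table3", "table4"
#' @return A data.frame, or an \code{ff_mape_table} for the MAPE tables.
#' @export
ff_fixture <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  file <- c(table1 = "table1_initial_shares.csv",
            table2 = "table2_internal_mape.csv",
            table3 = "table3_external_mape.csv",
            table4 = "table4_projection.csv")[[name]]
  path <- system.file("extdata", file, package = "frailtyflow")
  if (path == "") stop("packaged fixture not found: ", file)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (name %in% c("table2", "table3")) mape_table(df) else df
}
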