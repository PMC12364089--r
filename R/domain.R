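#' @title Age bands, frailty states and subgroup indexing
#' @description
#' The model's vocabulary: four age bands (50-64, 65-74, 75-84, 85+), four
#' electronic frailty index (eFI) categories (Fit, Mild, Moderate, Severe),
#' and the 16 subgroups formed by crossing them. Subgroups are indexed 0-15
#' in band-major order: (50-64, Fit) = 0 ... (85+, Severe) = 15.
#' @name frailty-domain
NULL

#' Canonical frailty state labels, in increasing severity
#' @return Character vector of the four ordered state labels.
#' @export
frailty_states <- function() c("Fit", "Mild", "Moderate", "Severe")

#' Canonical age band labels, youngest first
#' @return Character vector of the four ordered band labels.
#' @export
age_bands <- function() c("50-64", "65-74", "75-84", "85+")

#' eFI category boundaries
#'
#' Upper bounds of the Fit/Mild/Moderate intervals on the eFI scale.
#' Intervals are closed above: Fit = [0, 0.12], Mild = (0.12, 0.24],
#' Moderate = (0.24, 0.36], Severe = (0.36, 1]. This convention reproduces
#' the published cut-offs on every score representable as k/36 and leaves
#' no gap for arbitrary fractions.
#' @return Numeric vector of the three internal cut points.
#' @export
efi_breaks <- function() c(0.12, 0.24, 0.36)

#' Age band properties
#'
#' @return A data.frame with one row per band: \code{band}, \code{lower_age},
#'   \code{upper_age} (NA for the open-ended 85+ band) and \code{width} in
#'   years (NA for 85+). The last band has no ageing outflow.
#' @export
age_band_table <- function() {
  data.frame(
    band = age_bands(),
    lower_age = c(50, 65, 75, 85),
    upper_age = c(64, 74, 84, NA),
    width = c(15, 10, 10, NA),
    stringsAsFactors = FALSE
  )
}

#' Model grid: the set of subgroups a model is built over
#'
#' A grid is the cross of ordered band labels with ordered state labels.
#' The default 4 x 4 frailty grid is \code{frailty_grid()}; smaller grids
#' are useful for structural testing.
#'
#' @param bands character vector of ordered age-band labels (youngest first)
#' @param states character vector of ordered frailty-state labels (fittest
#'   first)
#' @return An object of class \code{ff_grid}.
#' @export
model_grid <- function(bands, states) {
  stopifnot(is.character(bands), is.character(states),
            length(bands) >= 1, length(states) >= 1,
            !anyDuplicated(bands), !anyDuplicated(states))
  structure(list(bands = bands, states = states), class = "ff_grid")
}

#' @rdname model_grid
#' @export
frailty_grid <- function() model_grid(age_bands(), frailty_states())

#' @export
print.ff_grid <- function(x, ...) {
  cat("model grid:", length(x$bands), "age bands x", length(x$states),
      "frailty states (", n_subgroups(x), "subgroups )\n")
  invisible(x)
}

#' Number of subgroups in a grid
#' @param grid an \code{ff_grid}
#' @return Integer count of band-state subgroups.
#' @export
n_subgroups <- function(grid = frailty_grid()) {
  length(grid$bands) * length(grid$states)
}

#' Subgroup table for a grid
#'
#' @param grid an \code{ff_grid}
#' @return A data.frame with columns \code{index} (0-based, band-major),
#'   \code{band}, \code{state}, in canonical order.
#' @export
subgroup_table <- function(grid = frailty_grid()) {
  nb <- length(grid$bands); ns <- length(grid$states)
  data.frame(
    index = seq_len(nb * ns) - 1L,
    band = rep(grid$bands, each = ns),
    state = rep(grid$states, times = nb),
    stringsAsFactors = FALSE
  )
}

#' Canonical subgroup index of a (band, state) pair
#'
#' @param band band label
#' @param state state label
#' @param grid an \code{ff_grid}
#' @return Integer index 0..(n_subgroups - 1), band-major.
#' @export
subgroup_of <- function(band, state, grid = frailty_grid()) {
  b <- match(band, grid$bands)
  s <- match(state, grid$states)
  if (anyNA(b)) stop("unknown age band: ", paste(band[is.na(b)], collapse = ", "))
  if (anyNA(s)) stop("unknown frailty state: ", paste(state[is.na(s)], collapse = ", "))
  as.integer((b - 1L) * length(grid$states) + (s - 1L))
}

#' Decompose a subgroup index back into (band, state)
#' @param index integer index 0..(n_subgroups - 1)
#' @param grid an \code{ff_grid}
#' @return A data.frame with columns \code{band} and \code{state}.
#' @export
subgroup_decompose <- function(index, grid = frailty_grid()) {
  ns <- length(grid$states)
  if (any(index < 0 | index >= n_subgroups(grid)))
    stop("subgroup index out of range")
  data.frame(
    band = grid$bands[index %/% ns + 1L],
    state = grid$states[index %% ns + 1L],
    stringsAsFactors = FALSE
  )
}

#' Next older age band
#' @param band band label
#' @param grid an \code{ff_grid}
#' @return The next band label, or \code{NA} for the terminal (open-ended)
#'   band, which has no ageing outflow.
#' @export
next_band <- function(band, grid = frailty_grid()) {
  i <- match(band, grid$bands)
  if (anyNA(i)) stop("unknown age band: ", band)
  ifelse(i < length(grid$bands), grid$bands[pmin(i + 1L, length(grid$bands))], NA_character_)
}

#' Next (more severe) frailty state
#'
#' Frailty is modelled as irreversible and adjacent-state-only; the most
#' severe state is absorbing within the frailty dimension.
#' @param state state label
#' @param grid an \code{ff_grid}
#' @return The next state label, or \code{NA} for the terminal state.
#' @export
next_state <- function(state, grid = frailty_grid()) {
  i <- match(state, grid$states)
  if (anyNA(i)) stop("unknown frailty state: ", state)
  ifelse(i < length(grid$states), grid$states[pmin(i + 1L, length(grid$states))], NA_character_)
}

#' Electronic frailty index score from a deficit count
#'
#' The eFI is a cumulative deficit score: the number of deficits present in
#' an individual as a proportion of the total considered (36 in the standard
#' instrument).
#'
#' @param n_deficits integer count of deficits present
#' @param total_deficits integer size of the deficit list (default 36)
#' @return The score \code{n_deficits / total_deficits} in [0, 1].
#' @examples
#' efi_score(9)          # 0.25
#' efi_score(0)          # 0
#' @export
efi_score <- function(n_deficits, total_deficits = 36L) {
  if (length(total_deficits) != 1 || total_deficits <= 0)
    stop("total_deficits must be a single positive integer")
  if (any(n_deficits != round(n_deficits)))
    stop("n_deficits must be a whole number")
  if (any(n_deficits < 0 | n_deficits > total_deficits))
    stop("n_deficits must lie in [0, ", total_deficits, "]")
  n_deficits / total_deficits
}

#' Categorise an eFI score into a frailty state
#'
#' Uses half-open-above intervals Fit = [0, 0.12], Mild = (0.12, 0.24],
#' Moderate = (0.24, 0.36], Severe = (0.36, 1] (see \code{\link{efi_breaks}}).
#'
#' @param score numeric eFI score(s) in [0, 1]
#' @return Character vector of state labels.
#' @examples
#' categorise_efi(c(0.10, 0.25, 0.40))  # Fit, Moderate, Severe
#' @export
categorise_efi <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("eFI score must lie in [0, 1]")
  # left.open makes each interval closed above, so 0.12 -> Fit, 0.24 -> Mild
  frailty_states()[findInterval(score, efi_breaks(), left.open = TRUE) + 1L]
}
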