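#' Count distinct survey days per individual-year
#'
#' The model's inclusion filter is expressed in survey days: an individual
#' must be seen on at least `min_days` distinct calendar dates within a year.
#' Multiple sightings on one date count as a single survey day here (although
#' all of them enter the encounter counts).
#'
#' @param sightings A sighting table with `individual_id`, `date` and,
#'   optionally, `year` (derived from `date` when absent).
#' @return A tibble with columns `individual_id`, `year`, `survey_days`.
#' @export
count_survey_days <- function(sightings) {
  sightings <- tibble::as_tibble(sightings)
  if (!"year" %in% names(sightings)) {
    sightings <- dplyr::mutate(sightings,
                               year = as.integer(format(as.Date(date), "%Y")))
  }
  sightings |>
    dplyr::distinct(individual_id, year, date) |>
    dplyr::count(individual_id, year, name = "survey_days")
}

#' Build the gridded annual encounter array
#'
#' Aggregates binned sightings into per-individual, per-bin, per-year counts
#' `S[i, l, t]` and daily effort into annual per-bin surveyed areas
#' `e[l, t]`, applying the inclusion filter: an individual is retained if it
#' was seen on at least `min_days` distinct survey days in at least one year.
#' Retained individuals contribute rows for **all** study years (years with
#' no sightings are informative zeros, absorbed by the model's presence
#' indicator); per-year inclusion flags record which individual-years met the
#' criterion on their own.
#'
#' @param sightings A sighting table with `bin_index` already assigned (see
#'   [assign_latitude_bins()]) and `individual_id`, `date` columns.
#' @param effort An effort table with `date` (or `year`), `bin_index`,
#'   `area_km2`.
#' @param grid The [lat_grid()] the sightings were binned on.
#' @param min_days Inclusion threshold in distinct survey days (default 5).
#' @return An object of class `encounter_data`: a list with the count array
#'   `S` (individuals x bins x years), annual effort matrix `effort` (bins x
#'   years), the `inclusion` tibble (`individual_id`, `year`, `survey_days`,
#'   `included`), index vectors `individuals` and `years`, and the `grid`.
#' @export
build_encounter_array <- function(sightings, effort, grid, min_days = 5L) {
  stopifnot(inherits(grid, "lat_grid"))
  sightings <- tibble::as_tibble(sightings)
  if (!"bin_index" %in% names(sightings)) {
    stop("sightings must carry a `bin_index` column; run assign_latitude_bins() first",
         call. = FALSE)
  }
  effort <- tibble::as_tibble(effort)
  if (!"year" %in% names(effort)) {
    effort <- dplyr::mutate(effort, year = as.integer(format(as.Date(date), "%Y")))
  }
  if (!"year" %in% names(sightings)) {
    sightings <- dplyr::mutate(sightings,
                               year = as.integer(format(as.Date(date), "%Y")))
  }

  days <- count_survey_days(sightings)
  qualified <- dplyr::filter(days, survey_days >= min_days)
  if (nrow(qualified) == 0L) {
    stop("no individuals meet the inclusion threshold", call. = FALSE)
  }
  individuals <- sort(unique(qualified$individual_id))
  years <- sort(unique(effort$year))

  e_tbl <- effort |>
    dplyr::group_by(bin_index, year) |>
    dplyr::summarise(area_km2 = sum(area_km2), .groups = "drop")
  e_mat <- matrix(0, grid$n_bins, length(years),
                  dimnames = list(NULL, years))
  e_mat[cbind(e_tbl$bin_index, match(e_tbl$year, years))] <- e_tbl$area_km2

  kept <- sightings |>
    dplyr::filter(individual_id %in% individuals, year %in% years)
  s_tbl <- kept |>
    dplyr::count(individual_id, bin_index, year, name = "count")

  # a sighting where no survey effort was recorded is a data inconsistency
  bad <- s_tbl |>
    dplyr::filter(e_mat[cbind(bin_index, match(year, years))] == 0)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "sightings recorded in zero-effort (bin, year) cells: %s",
      paste(sprintf("%s bin %d year %d", bad$individual_id, bad$bin_index, bad$year),
            collapse = "; ")), call. = FALSE)
  }

  S <- array(0L, dim = c(length(individuals), grid$n_bins, length(years)),
             dimnames = list(individuals, NULL, years))
  S[cbind(match(s_tbl$individual_id, individuals), s_tbl$bin_index,
          match(s_tbl$year, years))] <- s_tbl$count

  inclusion <- tidyr::expand_grid(individual_id = individuals, year = years) |>
    dplyr::left_join(days, by = c("individual_id", "year")) |>
    dplyr::mutate(survey_days = dplyr::coalesce(survey_days, 0L),
                  included = survey_days >= min_days)

  structure(
    list(S = S, effort = e_mat, inclusion = inclusion,
         individuals = individuals, years = years, grid = grid,
         min_days = as.integer(min_days)),
    class = "encounter_data"
  )
}

#' @export
print.encounter_data <- function(x, ...) {
  cat(sprintf(
    "<encounter_data> %d individuals x %d bins x %d years; %d sightings; %d qualifying individual-years (>= %d survey days)\n",
    length(x$individuals), dim(x$S)[2], length(x$years), sum(x$S),
    sum(x$inclusion$included), x$min_days
  ))
  invisible(x)
}

#' Tidy an encounter array into a long tibble
#'
#' @param x An `encounter_data` object.
#' @param ... Unused.
#' @return A tibble with columns `individual_id`, `bin_index`, `year`,
#'   `count`, `area_km2`, one row per individual-bin-year cell.
#' @method tidy encounter_data
#' @export
tidy.encounter_data <- function(x, ...) {
  tidyr::expand_grid(
    individual_id = x$individuals,
    bin_index = seq_len(dim(x$S)[2]),
    year = x$years
  ) |>
    dplyr::mutate(
      count = as.integer(x$S[cbind(match(individual_id, x$individuals),
                                   bin_index, match(year, x$years))]),
      area_km2 = x$effort[cbind(bin_index, match(year, x$years))]
    )
}
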