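#' Read and write the package's delimited table formats
#'
#' Plain-CSV interchange formats: sightings (`individual_id,date,latitude`,
#' ISO-8601 dates, decimal degrees), daily effort (`date,bin_index,area_km2`),
#' ground truth (`individual_id,year,C_true,sigma2_true,R_true,A_true`), and
#' stressor layers (static `bin_index,value`; dynamic
#' `bin_index,year,month,value`).
#'
#' @param x The table (or layer) to write.
#' @param path File path.
#' @return Readers return tibbles (layers as `stressor_layer`); writers
#'   return the input invisibly.
#' @name latsecr-io
NULL

#' @rdname latsecr-io
#' @export
write_sightings <- function(x, path) {
  readr::write_csv(dplyr::select(x, individual_id, date, latitude), path)
  invisible(x)
}

#' @rdname latsecr-io
#' @export
read_sightings <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    date = readr::col_date(),
    latitude = readr::col_double()
  )) |>
    dplyr::mutate(year = as.integer(format(date, "%Y")))
}

#' @rdname latsecr-io
#' @export
write_effort <- function(x, path) {
  readr::write_csv(dplyr::select(x, date, bin_index, area_km2), path)
  invisible(x)
}

#' @rdname latsecr-io
#' @export
read_effort <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(),
    bin_index = readr::col_integer(),
    area_km2 = readr::col_double()
  )) |>
    dplyr::mutate(year = as.integer(format(date, "%Y")))
}

#' @rdname latsecr-io
#' @export
write_truth <- function(x, path) {
  readr::write_csv(
    dplyr::select(x, individual_id, year, C_true, sigma2_true, R_true, A_true),
    path)
  invisible(x)
}

#' @rdname latsecr-io
#' @export
read_truth <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(), year = readr::col_integer(),
    C_true = readr::col_double(), sigma2_true = readr::col_double(),
    R_true = readr::col_double(), A_true = readr::col_integer()
  ))
}

#' @rdname latsecr-io
#' @export
write_layer <- function(x, path) {
  stopifnot(inherits(x, "stressor_layer"))
  cols <- if (layer_kind(x) == "static") c("bin_index", "value") else
    c("bin_index", "year", "month", "value")
  readr::write_csv(dplyr::select(tibble::as_tibble(x),
                                 dplyr::all_of(cols)), path)
  invisible(x)
}

#' @rdname latsecr-io
#' @param name,kind,scaled Layer metadata for [read_layer()]; `kind` is
#'   inferred from the columns when `NULL`.
#' @export
read_layer <- function(path, name = tools::file_path_sans_ext(basename(path)),
                       kind = NULL, scaled = FALSE) {
  tb <- readr::read_csv(path, col_types = readr::cols())
  if (is.null(kind)) kind <- if ("month" %in% names(tb)) "dynamic" else "static"
  new_stressor_layer(tb, name = name, kind = kind, scaled = scaled)
}

#' Write an encounter array as a directory of delimited tables
#'
#' Writes `S.csv` (long format `individual_id,bin_index,year,count`, non-zero
#' cells only), `effort.csv` (`bin_index,year,area_km2`) and `inclusion.csv`
#' (`individual_id,year,survey_days,included`).
#'
#' @param data An [build_encounter_array()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_encounters <- function(data, dir) {
  stopifnot(inherits(data, "encounter_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tidy(data) |>
    dplyr::filter(count > 0) |>
    dplyr::select(individual_id, bin_index, year, count) |>
    readr::write_csv(file.path(dir, "S.csv"))
  tidy(data) |>
    dplyr::distinct(bin_index, year, area_km2) |>
    readr::write_csv(file.path(dir, "effort.csv"))
  readr::write_csv(data$inclusion, file.path(dir, "inclusion.csv"))
  invisible(dir)
}

#' Write posterior draws as a long-format delimited table
#'
#' @param fit A [secr_fit()] object.
#' @param path File path for the `chain,draw,parameter,value` table.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  readr::write_csv(posterior_draws(fit), path)
  invisible(path)
}
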