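#' Define a one-dimensional latitudinal grid
#'
#' The study area is discretised into contiguous latitude bins of equal width.
#' Bins are half-open intervals `[edge_l, edge_{l+1})`, 1-indexed from the
#' southern edge, so a latitude exactly on a shared edge belongs to the
#' northern (higher-index) bin.
#'
#' @param lat_origin Southern edge of bin 1, in decimal degrees latitude.
#' @param bin_width Bin width in degrees latitude (default 0.01, i.e. about
#'   1.1 km at mid latitudes).
#' @param n_bins Number of bins (default 55).
#' @param km_per_degree Kilometres per degree of latitude used when converting
#'   model-scale quantities to distance (default 110, i.e. 1.1 km per 0.01
#'   degree bin).
#'
#' @return An object of class `lat_grid`: a list with `lat_origin`,
#'   `bin_width`, `n_bins`, `km_per_degree`, the vector of `edges` (length
#'   `n_bins + 1`), bin `centroids`, and the grid `extent` (southern and
#'   northern limits).
#' @examples
#' g <- lat_grid(44.33)
#' g$centroids[1] # 44.335
#' @export
lat_grid <- function(lat_origin, bin_width = 0.01, n_bins = 55,
                     km_per_degree = 110) {
  stopifnot(is.numeric(lat_origin), length(lat_origin) == 1L, is.finite(lat_origin))
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be a positive number of degrees", call. = FALSE)
  }
  if (!is.numeric(n_bins) || n_bins < 2 || n_bins != round(n_bins)) {
    stop("`n_bins` must be an integer >= 2", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  edges <- lat_origin + bin_width * (0:n_bins)
  structure(
    list(
      lat_origin = lat_origin,
      bin_width = bin_width,
      n_bins = n_bins,
      km_per_degree = km_per_degree,
      edges = edges,
      centroids = lat_origin + bin_width * (seq_len(n_bins) - 0.5),
      extent = c(south = lat_origin, north = lat_origin + n_bins * bin_width)
    ),
    class = "lat_grid"
  )
}

#' @export
print.lat_grid <- function(x, ...) {
  cat(sprintf(
    "<lat_grid> %d bins of %.4f deg from %.4f to %.4f N\n",
    x$n_bins, x$bin_width, x$extent[["south"]], x$extent[["north"]]
  ))
  invisible(x)
}

#' Assign sightings to latitude bins
#'
#' Adds a `bin_index` column locating each sighting in the half-open bin
#' `[edge_l, edge_{l+1})` that contains its latitude. Sightings outside the
#' grid extent are dropped with a warning reporting how many were removed.
#'
#' @param sightings A data frame with at least a `latitude` column (decimal
#'   degrees); typically also `individual_id` and `date`.
#' @param grid A [lat_grid()].
#'
#' @return A tibble with the in-extent rows of `sightings` plus an integer
#'   `bin_index` column. The number of dropped rows is available as
#'   `attr(, "n_dropped")`.
#' @export
assign_latitude_bins <- function(sightings, grid) {
  stopifnot(inherits(grid, "lat_grid"))
  sightings <- tibble::as_tibble(sightings)
  if (!"latitude" %in% names(sightings)) {
    stop("`sightings` must have a `latitude` column", call. = FALSE)
  }
  lat <- sightings$latitude
  # findInterval with left-closed intervals matches the half-open convention;
  # the northern outer edge itself is out of extent.
  idx <- findInterval(lat, grid$edges, left.open = FALSE)
  in_extent <- idx >= 1L & idx <= grid$n_bins
  n_dropped <- sum(!in_extent)
  if (n_dropped > 0L) {
    warning(sprintf("%d sighting(s) outside the grid extent were dropped", n_dropped),
            call. = FALSE)
  }
  out <- dplyr::mutate(sightings[in_extent, , drop = FALSE],
                       bin_index = as.integer(idx[in_extent]))
  if (nrow(out) == 0L) {
    warning("no sightings fall inside the grid extent", call. = FALSE)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
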