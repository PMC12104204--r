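#' Stressor layers
#'
#' A stressor layer is a tibble of relative intensity values on the latitude
#' grid, either static (columns `bin_index`, `value`) or dynamic (columns
#' `bin_index`, `year`, `month`, `value`), carrying a `name`, a `kind` and a
#' flag recording whether it has been scaled to `[0, 1]`.
#'
#' @param x A data frame with the columns above.
#' @param name Layer name.
#' @param kind `"static"` or `"dynamic"`.
#' @param scaled Whether `value` is already scaled to a maximum of 1.
#' @return A tibble of class `stressor_layer`.
#' @export
new_stressor_layer <- function(x, name, kind = c("static", "dynamic"),
                               scaled = FALSE) {
  kind <- match.arg(kind)
  x <- tibble::as_tibble(x)
  need <- if (kind == "static") c("bin_index", "value") else
    c("bin_index", "year", "month", "value")
  if (!all(need %in% names(x))) {
    stop(sprintf("a %s layer needs columns %s", kind,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(x$value < 0)) stop("stressor values must be non-negative", call. = FALSE)
  structure(x, class = c("stressor_layer", class(x)),
            layer_name = name, kind = kind, scaled = scaled)
}

layer_kind <- function(layer) attr(layer, "kind")
layer_name <- function(layer) attr(layer, "layer_name")
layer_is_scaled <- function(layer) isTRUE(attr(layer, "scaled"))

#' @export
print.stressor_layer <- function(x, ...) {
  cat(sprintf("<stressor_layer '%s'> %s, %s\n", layer_name(x), layer_kind(x),
              if (layer_is_scaled(x)) "scaled to [0, 1]" else "raw"))
  NextMethod()
}

#' Scale a stressor layer to the unit interval
#'
#' Divides all values by the layer maximum so that 1 marks the highest
#' relative intensity and 0 no exposure. Dynamic layers are scaled by their
#' single global maximum across bins, years and months, keeping years
#' comparable.
#'
#' @param layer A [new_stressor_layer()] object with raw values.
#' @return The layer with `value` in `[0, 1]` and max exactly 1.
#' @export
scale_layer <- function(layer) {
  stopifnot(inherits(layer, "stressor_layer"))
  m <- max(layer$value)
  if (m <= 0) stop(sprintf("layer '%s' is all zero and cannot be scaled",
                           layer_name(layer)), call. = FALSE)
  out <- layer
  out$value <- layer$value / m
  attr(out, "scaled") <- TRUE
  out
}

#' Linear proximity proxy for a point-source stressor
#'
#' When only the location of a stressor source is known, exposure is proxied
#' by proximity: `raw_l = max_dist - |centroid_l - point|`, where `max_dist`
#' is the largest centroid-to-source distance on the grid. The proxy is
#' maximal at the source and falls to zero at the farthest bin, encoding
#' "greater proximity, greater exposure" with a linear decay (the default; a
#' reciprocal decay `1 / (dist + bin_width)` is also available since no
#' canonical form exists for such proxies).
#'
#' @param point Source latitude, degrees.
#' @param grid A [lat_grid()].
#' @param name Layer name (defaults to a description of the point).
#' @param decay `"linear"` (default) or `"reciprocal"`.
#' @return A static, unscaled `stressor_layer`.
#' @export
proximity_proxy <- function(point, grid, name = sprintf("proximity_%.3f", point),
                            decay = c("linear", "reciprocal")) {
  stopifnot(inherits(grid, "lat_grid"), is.finite(point))
  decay <- match.arg(decay)
  d <- abs(grid$centroids - point)
  raw <- switch(decay,
    linear = max(d) - d,
    reciprocal = 1 / (d + grid$bin_width)
  )
  new_stressor_layer(
    tibble::tibble(bin_index = seq_len(grid$n_bins), value = raw),
    name = name, kind = "static"
  )
}

#' Annualise a dynamic stressor layer
#'
#' The sighting model works at an annual scale, so monthly dynamic layers are
#' reduced to one value per (bin, year) by averaging over the months present
#' in that year. Every bin must have at least one month per year it appears
#' in; the number of months averaged is recorded in `n_months`.
#'
#' @param layer A dynamic `stressor_layer`.
#' @return A tibble with columns `bin_index`, `year`, `value`, `n_months`,
#'   retaining the layer's name, kind `"dynamic"` and scaling flag.
#' @export
annualize_dynamic <- function(layer) {
  stopifnot(inherits(layer, "stressor_layer"))
  if (layer_kind(layer) != "dynamic") {
    stop("`annualize_dynamic()` expects a dynamic layer", call. = FALSE)
  }
  out <- layer |>
    tibble::as_tibble() |>
    dplyr::group_by(bin_index, year) |>
    dplyr::summarise(value = mean(value), n_months = dplyr::n(), .groups = "drop")
  empty <- dplyr::anti_join(
    tidyr::expand_grid(bin_index = unique(layer$bin_index), year = unique(layer$year)),
    out, by = c("bin_index", "year")
  )
  if (nrow(empty) > 0L) {
    stop(sprintf("layer '%s' has (bin, year) cells with no monthly values: %s",
                 layer_name(layer),
                 paste(sprintf("(%d, %d)", empty$bin_index, empty$year),
                       collapse = ", ")), call. = FALSE)
  }
  structure(out, class = c("stressor_layer", class(out)),
            layer_name = layer_name(layer), kind = "dynamic",
            scaled = attr(layer, "scaled"))
}
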