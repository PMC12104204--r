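# Stack the per-chain draw matrices of a fit into pooled (draws x case)
# matrices.
pooled_draws <- function(fit) {
  stopifnot(inherits(fit, "secr_fit"))
  list(
    C = do.call(rbind, lapply(fit$chains, `[[`, "C")),
    sigma2 = do.call(rbind, lapply(fit$chains, `[[`, "sigma2")),
    R = do.call(rbind, lapply(fit$chains, `[[`, "R")),
    A = do.call(rbind, lapply(fit$chains, `[[`, "A"))
  )
}

#' Relative occurrence of an individual across latitude bins
#'
#' The space use of an individual-year is a normal distribution with mean at
#' its activity center and variance its activity range. The relative
#' occurrence in bin `l` is the normal probability mass between the bin's
#' edges, `pnorm((edge_{l+1} - C)/sigma) - pnorm((edge_l - C)/sigma)`. Mass
#' falling beyond the grid is truncated, not renormalised, so the occurrence
#' vector sums to at most 1.
#'
#' @param C Activity center(s), degrees latitude (scalar or vector).
#' @param sigma2 Activity range(s), degrees squared, positive; recycled
#'   against `C`.
#' @param grid A [lat_grid()].
#' @return For scalar input a vector of per-bin probabilities; for vector
#'   input a matrix with one row per (C, sigma2) pair.
#' @export
relative_occurrence <- function(C, sigma2, grid) {
  stopifnot(inherits(grid, "lat_grid"))
  if (any(sigma2 <= 0)) stop("`sigma2` must be positive", call. = FALSE)
  n <- max(length(C), length(sigma2))
  C <- rep_len(C, n); sigma <- sqrt(rep_len(sigma2, n))
  # P(draws x (n_bins + 1)) of lower-tail masses at each edge
  P <- stats::pnorm((matrix(grid$edges, n, grid$n_bins + 1L, byrow = TRUE) - C) / sigma)
  occ <- P[, -1L, drop = FALSE] - P[, -(grid$n_bins + 1L), drop = FALSE]
  if (n == 1L) drop(occ) else occ
}

#' Rescale residency intercepts to the unit interval
#'
#' Within one posterior iteration, the residency intercepts `R` of all
#' present (`A = 1`) individual-years are min-max rescaled jointly across
#' the dataset so 1 marks the highest residency and 0 complete absence;
#' absent individual-years receive 0. If all present values coincide they
#' map to 1 (a lone observed individual is fully resident, not absent).
#'
#' @param R Residency intercepts: a vector (one iteration) or a matrix with
#'   one row per iteration.
#' @param A Presence indicators, same shape as `R` (default: all present).
#' @return Rescaled values in `[0, 1]`, same shape as `R`.
#' @export
rescale_residency <- function(R, A = NULL) {
  if (is.matrix(R)) {
    if (is.null(A)) A <- matrix(1L, nrow(R), ncol(R))
    out <- matrix(0, nrow(R), ncol(R))
    for (i in seq_len(nrow(R))) out[i, ] <- rescale_residency(R[i, ], A[i, ])
    return(out)
  }
  if (is.null(A)) A <- rep(1L, length(R))
  out <- numeric(length(R))
  pres <- A == 1L
  if (!any(pres)) {
    warning("no present individual-years in this iteration; residency all zero",
            call. = FALSE)
    return(out)
  }
  r <- R[pres]
  rng <- range(r)
  out[pres] <- if (rng[1] == rng[2]) 1 else (r - rng[1]) / (rng[2] - rng[1])
  out
}

#' Posterior mean residency-weighted space use
#'
#' At each retained posterior iteration the per-bin relative occurrence of
#' each present individual-year is weighted by its rescaled residency;
#' iterations in which the individual-year is absent contribute zeros. The
#' mean of these weighted values across all iterations gives one relative
#' space-use distribution per individual-year.
#'
#' @param fit A [secr_fit()] object.
#' @return A tibble of class `secr_space_use` with columns `individual_id`,
#'   `year`, `included`, `bin_index`, `mean_weighted_occurrence`.
#' @export
space_use_distribution <- function(fit) {
  d <- pooled_draws(fit)
  grid <- fit$grid
  N <- nrow(d$C); J <- ncol(d$C)
  Rp <- rescale_residency(d$R, d$A)
  rows <- purrr::map(seq_len(J), function(j) {
    pres <- d$A[, j] == 1L
    field <- numeric(grid$n_bins)
    if (any(pres)) {
      occ <- relative_occurrence(d$C[pres, j], d$sigma2[pres, j], grid)
      if (is.null(dim(occ))) occ <- matrix(occ, nrow = 1L)
      field <- colSums(occ * Rp[pres, j]) / N
    }
    tibble::tibble(
      individual_id = fit$cases$individual_id[j],
      year = fit$cases$year[j],
      included = fit$cases$included[j],
      bin_index = seq_len(grid$n_bins),
      mean_weighted_occurrence = field
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("secr_space_use", class(out))
  attr(out, "grid") <- grid
  out
}

#' Posterior distribution of individual stressor exposure
#'
#' At each retained posterior iteration, exposure of an individual-year is
#' the sum over bins of its relative occurrence times the scaled stressor
#' value for that bin, weighted by the rescaled residency:
#' `E = (sum_l occ_l * s_l) * R'`. Dynamic layers are annualised to the
#' individual-year's year first. With stressor values and residency both in
#' `[0, 1]` and occurrence summing to at most 1, every exposure value lies
#' in `[0, 1]`.
#'
#' @param fit A [secr_fit()] object.
#' @param layer A scaled [new_stressor_layer()] (see [scale_layer()]).
#' @param keep_draws Keep the full draws-by-case exposure matrix (default
#'   FALSE).
#' @return A tibble of class `secr_exposure`: per individual-year the
#'   posterior `median`, `mean`, and central 90% interval (`lo90`, `hi90`)
#'   of exposure, with the layer name attached. Attributes carry the annual
#'   mean-of-medians and overall mean-of-medians reference values (computed
#'   over qualifying individual-years), and optionally the draws.
#' @export
exposure_distribution <- function(fit, layer, keep_draws = FALSE) {
  stopifnot(inherits(fit, "secr_fit"), inherits(layer, "stressor_layer"))
  if (!layer_is_scaled(layer)) {
    stop("`layer` must be scaled to [0, 1] first; see scale_layer()", call. = FALSE)
  }
  grid <- fit$grid
  dynamic <- layer_kind(layer) == "dynamic"
  if (dynamic && "month" %in% names(layer)) layer <- annualize_dynamic(layer)
  svec <- function(yr) {
    tb <- if (dynamic) dplyr::filter(tibble::as_tibble(layer), year == yr)
          else tibble::as_tibble(layer)
    if (nrow(tb) == 0L) {
      stop(sprintf("layer '%s' has no values for year %s", layer_name(layer), yr),
           call. = FALSE)
    }
    s <- numeric(grid$n_bins)
    if (any(tb$bin_index > grid$n_bins)) {
      stop("layer bin indices exceed the grid", call. = FALSE)
    }
    s[tb$bin_index] <- tb$value
    s
  }

  d <- pooled_draws(fit)
  N <- nrow(d$C); J <- ncol(d$C)
  Rp <- rescale_residency(d$R, d$A)
  E <- matrix(0, N, J)
  for (j in seq_len(J)) {
    pres <- d$A[, j] == 1L
    if (!any(pres)) next
    occ <- relative_occurrence(d$C[pres, j], d$sigma2[pres, j], grid)
    if (is.null(dim(occ))) occ <- matrix(occ, nrow = 1L)
    E[pres, j] <- drop(occ %*% svec(fit$cases$year[j])) * Rp[pres, j]
  }

  out <- fit$cases |>
    dplyr::select(individual_id, year, included) |>
    dplyr::mutate(
      stressor = layer_name(layer),
      median = apply(E, 2, stats::median),
      mean = colMeans(E),
      lo90 = apply(E, 2, stats::quantile, probs = 0.05),
      hi90 = apply(E, 2, stats::quantile, probs = 0.95)
    )
  qual <- dplyr::filter(out, included)
  annual <- qual |>
    dplyr::group_by(year) |>
    dplyr::summarise(mean_of_medians = mean(median), .groups = "drop")
  class(out) <- c("secr_exposure", class(out))
  attr(out, "annual_mean_of_medians") <- annual
  attr(out, "overall_mean_of_medians") <- mean(qual$median)
  if (keep_draws) attr(out, "draws") <- E
  out
}
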