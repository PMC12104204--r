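#' Convert an activity-range sigma to kilometres
#'
#' The activity range parameter is the variance of a normal space-use
#' distribution on the degree-latitude scale. To describe the distribution's
#' central 95% span, sigma is multiplied by 4 (two standard deviations each
#' side of the center), and converted from degrees to kilometres with a
#' factor of `km_per_degree` (default 110, i.e. 1.1 km per 0.01-degree bin).
#'
#' @param sigma Standard deviation(s) in degrees latitude, non-negative.
#' @param interval_multiplier Width of the reported interval in sigmas
#'   (default 4).
#' @param km_per_degree Kilometres per degree latitude (default 110).
#' @return Range size(s) in km: `interval_multiplier * sigma * km_per_degree`.
#' @examples
#' sigma_to_km(0.1) # 44 km
#' @export
sigma_to_km <- function(sigma, interval_multiplier = 4, km_per_degree = 110) {
  if (any(sigma < 0)) stop("`sigma` must be non-negative", call. = FALSE)
  interval_multiplier * sigma * km_per_degree
}

#' Posterior summaries of activity-range size in kilometres
#'
#' Applies [sigma_to_km()] to `sqrt(sigma2)` draw by draw, excluding draws
#' in which the individual-year was estimated absent (`A = 0`, whose pinned
#' range is an arbitrary placeholder). Individual-years absent in every
#' retained draw are reported with `NA` summaries.
#'
#' @param fit A [secr_fit()] object.
#' @param km_per_degree Kilometres per degree latitude (default taken from
#'   the fit's grid).
#' @return A tibble with columns `individual_id`, `year`, `included`,
#'   `n_present_draws`, `median_km`, `lo90_km`, `hi90_km`.
#' @export
range_summaries <- function(fit, km_per_degree = NULL) {
  stopifnot(inherits(fit, "secr_fit"))
  if (is.null(km_per_degree)) km_per_degree <- fit$grid$km_per_degree
  d <- pooled_draws(fit)
  rows <- purrr::map(seq_len(ncol(d$C)), function(j) {
    pres <- d$A[, j] == 1L
    km <- sigma_to_km(sqrt(d$sigma2[pres, j]), km_per_degree = km_per_degree)
    tibble::tibble(
      individual_id = fit$cases$individual_id[j],
      year = fit$cases$year[j],
      included = fit$cases$included[j],
      n_present_draws = sum(pres),
      median_km = if (length(km)) stats::median(km) else NA_real_,
      lo90_km = if (length(km)) unname(stats::quantile(km, 0.05)) else NA_real_,
      hi90_km = if (length(km)) unname(stats::quantile(km, 0.95)) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Posterior contrast of group mean activity centers
#'
#' At each retained iteration, the mean activity center of each group is
#' computed over its present (`A = 1`) members, and the difference
#' (group A minus group B) forms a posterior difference distribution. The
#' probability of direction is the fraction of difference draws greater
#' than 0, with draws exactly at 0 counting half towards each direction.
#' Iterations in which either group has no present member are skipped and
#' counted.
#'
#' @param fit A [secr_fit()] object.
#' @param labels A data frame with columns `individual_id`, `year`, `group`
#'   assigning a group label per individual-year (labels may change between
#'   years, e.g. when an individual matures).
#' @param group_a,group_b The two labels to contrast; by default the first
#'   two label levels in sorted order.
#' @return A list of class `secr_contrast`: the difference draws, a one-row
#'   `summary` tibble (`group_a`, `group_b`, `mean_diff_deg`,
#'   `prob_direction`, `n_iterations_used`, `n_iterations_skipped`), and the
#'   per-iteration group means.
#' @export
group_center_contrast <- function(fit, labels, group_a = NULL, group_b = NULL) {
  stopifnot(inherits(fit, "secr_fit"))
  labels <- tibble::as_tibble(labels)
  need <- c("individual_id", "year", "group")
  if (!all(need %in% names(labels))) {
    stop("`labels` needs columns individual_id, year, group", call. = FALSE)
  }
  lv <- sort(unique(labels$group))
  if (is.null(group_a)) group_a <- lv[1]
  if (is.null(group_b)) group_b <- lv[2]
  case_key <- paste(fit$cases$individual_id, fit$cases$year)
  members <- function(g) {
    la <- labels[labels$group %in% g, ]
    idx <- match(paste(la$individual_id, la$year), case_key)
    unique(idx[!is.na(idx)])
  }
  ia <- members(group_a)
  ib <- members(group_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("both groups must contain at least one individual-year", call. = FALSE)
  }
  d <- pooled_draws(fit)
  gmean <- function(idx) {
    Cm <- d$C[, idx, drop = FALSE]
    Am <- d$A[, idx, drop = FALSE]
    n_pres <- rowSums(Am)
    out <- rowSums(Cm * Am) / n_pres
    out[n_pres == 0] <- NA_real_
    out
  }
  ma <- gmean(ia); mb <- gmean(ib)
  ok <- !is.na(ma) & !is.na(mb)
  diff <- ma[ok] - mb[ok]
  n_used <- sum(ok)
  if (n_used == 0L) stop("no iteration has present members in both groups",
                         call. = FALSE)
  prob <- (sum(diff > 0) + 0.5 * sum(diff == 0)) / n_used
  structure(
    list(
      diff_draws = diff,
      group_means = tibble::tibble(iteration = which(ok), mean_a = ma[ok],
                                   mean_b = mb[ok]),
      summary = tibble::tibble(
        group_a = group_a, group_b = group_b,
        mean_diff_deg = mean(diff),
        prob_direction = prob,
        n_iterations_used = n_used,
        n_iterations_skipped = length(ma) - n_used
      )
    ),
    class = "secr_contrast"
  )
}

#' @export
print.secr_contrast <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<secr_contrast> %s vs %s: mean difference %.4f deg, %.1f%% probability that %s is more northerly (%d iterations)\n",
    s$group_a, s$group_b, s$mean_diff_deg, 100 * s$prob_direction, s$group_a,
    s$n_iterations_used
  ))
  invisible(x)
}
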