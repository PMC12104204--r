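#' Describe a synthetic survey scenario
#'
#' Bundles the dimensions and generative parameters for the synthetic-data
#' generator. Defaults emulate the magnitudes of the motivating field study:
#' a 55-bin latitudinal grid of 0.01-degree bins surveyed on about 30 days per
#' season over 8 years, with population-level log activity range `mu_true`
#' chosen so that typical individual ranges are a few tens of kilometres.
#'
#' Ground-truth latent quantities are drawn per individual-year:
#' presence `A_true ~ Bernoulli(presence_prob)`, activity center
#' `C_true ~ Uniform(grid extent)`, log activity range
#' `log(sigma2_true) = mu_true + Normal(0, omega_true^2)`, and residency
#' intercept `R_true ~ Normal(0, 1)`.
#'
#' @param n_bins,bin_width_deg,lat_origin Grid dimensions; see [lat_grid()].
#' @param n_years Number of survey seasons (default 8).
#' @param n_days_per_year Survey days per season (default 30).
#' @param n_individuals Number of marked individuals (default 25).
#' @param mu_true Population mean of log activity range, log degrees squared
#'   (default -5.4, i.e. sigma of about 0.067 degrees, a ~30 km range).
#' @param omega_true Standard deviation of the individual-year log-range
#'   random effect (default 0.75).
#' @param beta_e_true Slope of log baseline sighting rate on scaled effort
#'   (default 0.05 per unit of effort scaled to a 0-10 range).
#' @param presence_prob Probability an individual uses the study area in a
#'   year (default 0.5).
#' @param effort_pattern One of `"uniform"`, `"north-heavy"`, `"patchy"`.
#' @param start_year First calendar year of the study (default 2016).
#' @param seed Integer seed governing all of the scenario's random draws.
#'   Each generator function uses a fixed offset from this seed so stages can
#'   be regenerated independently and reproducibly.
#'
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_bins = 55, bin_width_deg = 0.01, lat_origin = 44.33,
                         n_years = 8, n_days_per_year = 30, n_individuals = 25,
                         mu_true = -5.4, omega_true = 0.75, beta_e_true = 0.05,
                         presence_prob = 0.5,
                         effort_pattern = c("uniform", "north-heavy", "patchy"),
                         start_year = 2016, seed = 1L) {
  effort_pattern <- match.arg(effort_pattern)
  counts <- c(n_bins = n_bins, n_years = n_years,
              n_days_per_year = n_days_per_year, n_individuals = n_individuals)
  if (any(counts < 1) || any(counts != round(counts)) || n_bins < 2) {
    stop("scenario counts must be positive integers (n_bins >= 2)", call. = FALSE)
  }
  if (bin_width_deg <= 0) stop("`bin_width_deg` must be > 0", call. = FALSE)
  if (presence_prob < 0 || presence_prob > 1) {
    stop("`presence_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (omega_true < 0) stop("`omega_true` must be >= 0", call. = FALSE)
  structure(
    list(
      n_bins = as.integer(n_bins), bin_width_deg = bin_width_deg,
      lat_origin = lat_origin, n_years = as.integer(n_years),
      n_days_per_year = as.integer(n_days_per_year),
      n_individuals = as.integer(n_individuals),
      mu_true = mu_true, omega_true = omega_true, beta_e_true = beta_e_true,
      presence_prob = presence_prob, effort_pattern = effort_pattern,
      start_year = as.integer(start_year), seed = as.integer(seed)
    ),
    class = "sim_scenario"
  )
}

#' @rdname sim_scenario
#' @param scenario A `sim_scenario`.
#' @export
scenario_grid <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  lat_grid(scenario$lat_origin, scenario$bin_width_deg, scenario$n_bins)
}

scenario_years <- function(scenario) {
  scenario$start_year + seq_len(scenario$n_years) - 1L
}

# Survey dates for one season: n_days_per_year distinct days sampled from a
# June-to-mid-October window, sorted. Uses the current RNG stream.
season_dates <- function(year, n_days) {
  window <- seq(as.Date(sprintf("%d-06-01", year)),
                as.Date(sprintf("%d-10-15", year)), by = "day")
  n_days <- min(n_days, length(window))
  sort(sample(window, n_days))
}

#' Simulate daily per-bin survey effort
#'
#' Emits one surveyed-area value (km^2) for every (survey day, bin). The
#' `"uniform"` pattern gives every bin-day the same positive effort;
#' `"north-heavy"` ramps effort up linearly towards the northern bins with
#' mild day-to-day noise; `"patchy"` zeroes a random subset of bins on each
#' day and removes one whole bin per year entirely, guaranteeing (bin, year)
#' cells with zero annual effort.
#'
#' @param scenario A [sim_scenario()].
#' @return A tibble with columns `date`, `year`, `bin_index`, `area_km2`,
#'   one row per (survey day, bin). Deterministic for a fixed scenario seed.
#' @export
simulate_effort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed + 101L)
  nb <- scenario$n_bins
  base <- 3.5 # km^2 surveyed per bin per day, matching ~5000 km^2 per season
  rows <- purrr::map(scenario_years(scenario), function(yr) {
    dates <- season_dates(yr, scenario$n_days_per_year)
    dead_bin <- if (scenario$effort_pattern == "patchy") sample.int(nb, 1L) else 0L
    purrr::map(dates, function(d) {
      eff <- switch(scenario$effort_pattern,
        uniform = rep(base, nb),
        `north-heavy` = base * seq(0.25, 1.75, length.out = nb) *
          exp(stats::rnorm(1, 0, 0.2)),
        patchy = {
          e <- base * exp(stats::rnorm(nb, 0, 0.3))
          e[sample.int(nb, size = ceiling(nb / 3))] <- 0
          e
        }
      )
      if (dead_bin > 0L) eff[dead_bin] <- 0
      tibble::tibble(date = d, year = yr, bin_index = seq_len(nb), area_km2 = eff)
    })
  })
  dplyr::bind_rows(rows)
}

#' Simulate ground-truth latent states per individual-year
#'
#' @param scenario A [sim_scenario()].
#' @return A tibble (the truth table) with columns `individual_id`, `year`,
#'   `A_true` (0/1 presence), `C_true` (degrees), `sigma2_true` (degrees^2),
#'   `R_true` (log-rate intercept).
#' @export
simulate_individuals <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed + 202L)
  grid <- scenario_grid(scenario)
  ids <- sprintf("W%03d", seq_len(scenario$n_individuals))
  tidyr::expand_grid(individual_id = ids, year = scenario_years(scenario)) |>
    dplyr::mutate(
      A_true = stats::rbinom(dplyr::n(), 1L, scenario$presence_prob),
      C_true = stats::runif(dplyr::n(), grid$extent[["south"]], grid$extent[["north"]]),
      sigma2_true = exp(scenario$mu_true +
                          stats::rnorm(dplyr::n(), 0, scenario$omega_true)),
      R_true = stats::rnorm(dplyr::n(), 0, 1)
    )
}

#' Simulate dated sighting records from latent truth and effort
#'
#' For each present individual-year the annual expected count in bin `l` is
#' `exp(R_true + beta_e * e_scaled_l) * exp(-d_l^2 / (2 sigma2_true))`, where
#' `e_scaled` is annual effort scaled to a 0-10 range by its global maximum
#' and `d_l` the distance from the bin centroid to the activity center.
#' Annual per-bin counts are drawn Poisson and then apportioned among that
#' bin-year's survey days in proportion to daily effort, so the annual rate
#' is preserved exactly while records carry realistic dates. Within-bin
#' latitudes are uniform. Bins (or whole years) with zero effort, and absent
#' individual-years, yield no sightings.
#'
#' @param truth Truth table from [simulate_individuals()].
#' @param effort Effort table from [simulate_effort()].
#' @param scenario The same [sim_scenario()].
#' @return A tibble with columns `individual_id`, `date`, `year`,
#'   `bin_index`, `latitude`, one row per sighting.
#' @export
simulate_sightings <- function(truth, effort, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!all(truth$year %in% effort$year)) {
    stop("truth and effort tables do not share the same years", call. = FALSE)
  }
  set.seed(scenario$seed + 303L)
  grid <- scenario_grid(scenario)
  annual <- effort |>
    dplyr::group_by(year, bin_index) |>
    dplyr::summarise(area_km2 = sum(area_km2), .groups = "drop")
  esc <- annual |>
    dplyr::mutate(e_scaled = scale_effort(area_km2))

  draws <- truth |>
    dplyr::filter(A_true == 1L) |>
    purrr::pmap(function(individual_id, year, A_true, C_true, sigma2_true, R_true) {
      yr <- year
      ey <- dplyr::filter(esc, year == yr)
      d <- grid$centroids[ey$bin_index] - C_true
      lam <- ifelse(ey$e_scaled > 0,
                    exp(R_true + scenario$beta_e_true * ey$e_scaled -
                          d^2 / (2 * sigma2_true)),
                    0)
      counts <- stats::rpois(length(lam), lam)
      keep <- which(counts > 0L)
      if (length(keep) == 0L) return(NULL)
      purrr::map(keep, function(k) {
        bin <- ey$bin_index[k]
        daily <- dplyr::filter(effort, year == yr, bin_index == bin, area_km2 > 0)
        per_day <- as.vector(stats::rmultinom(1, counts[k],
                                              daily$area_km2 / sum(daily$area_km2)))
        idx <- rep(seq_len(nrow(daily)), per_day)
        tibble::tibble(
          individual_id = individual_id,
          date = daily$date[idx],
          year = yr,
          bin_index = bin,
          latitude = stats::runif(length(idx), grid$edges[bin], grid$edges[bin + 1])
        )
      }) |> dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()
  if (nrow(draws) == 0L) return(draws)
  dplyr::arrange(draws, individual_id, date, bin_index)
}

#' Simulate anthropogenic stressor layers
#'
#' Builds three static layers as linear proximity proxies to fixed point
#' sources (two port-like sources at roughly a quarter and three quarters of
#' the grid, one mid-grid discharge-like source) and two dynamic layers with
#' per-(bin, year, month) intensities: a crab-pot-like layer covering
#' June-August and a recreational-fishing-like layer covering June-October.
#' Dynamic intensities combine a smooth spatial profile whose center drifts
#' between years with multiplicative lognormal noise; all raw values are
#' non-negative and layers are returned unscaled (see [scale_layer()]).
#'
#' @param scenario A [sim_scenario()].
#' @return A named list of `stressor_layer` objects.
#' @export
simulate_stressors <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed + 404L)
  grid <- scenario_grid(scenario)
  years <- scenario_years(scenario)
  south <- grid$extent[["south"]]; width <- diff(grid$extent)

  statics <- list(
    port_north = proximity_proxy(south + 0.75 * width, grid, name = "port_north"),
    port_south = proximity_proxy(south + 0.25 * width, grid, name = "port_south"),
    outfall = proximity_proxy(south + 0.5 * width, grid, name = "outfall")
  )

  dyn_layer <- function(name, months) {
    rows <- tidyr::expand_grid(year = years, month = months) |>
      purrr::pmap(function(year, month) {
        center <- south + stats::runif(1, 0.2, 0.8) * width
        profile <- exp(-((grid$centroids - center) / (0.25 * width))^2)
        tibble::tibble(
          bin_index = seq_len(grid$n_bins), year = year, month = month,
          value = profile * exp(stats::rnorm(grid$n_bins, 0, 0.2))
        )
      }) |>
      dplyr::bind_rows()
    new_stressor_layer(rows, name = name, kind = "dynamic")
  }

  c(statics, list(
    crab_pots = dyn_layer("crab_pots", 6:8),
    rec_fishing = dyn_layer("rec_fishing", 6:10)
  ))
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper producing effort, truth, sightings and stressor layers
#' for one scenario.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with elements `scenario`, `grid`, `effort`, `truth`,
#'   `sightings`, `stressors`.
#' @export
simulate_dataset <- function(scenario = sim_scenario()) {
  effort <- simulate_effort(scenario)
  truth <- simulate_individuals(scenario)
  list(
    scenario = scenario,
    grid = scenario_grid(scenario),
    effort = effort,
    truth = truth,
    sightings = simulate_sightings(truth, effort, scenario),
    stressors = simulate_stressors(scenario)
  )
}
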