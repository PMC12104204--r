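# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

small_scenario <- function(seed = 7, ...) {
  sim_scenario(n_bins = 30, n_years = 3, n_individuals = 15,
               n_days_per_year = 25, seed = seed, ...)
}

small_dataset <- function() {
  memo("small_dataset", function() simulate_dataset(small_scenario()))
}

small_encounters <- function() {
  memo("small_encounters", function() {
    ds <- small_dataset()
    build_encounter_array(assign_latitude_bins(ds$sightings, ds$grid),
                          ds$effort, ds$grid)
  })
}

# A modest 2-chain fit of the small synthetic dataset, shared by the
# space-use, exposure and post hoc tests.
small_fit <- function() {
  memo("small_fit", function() {
    secr_fit(small_encounters(),
             model_config(n_chains = 2, n_iter = 6000, burn_in = 2000,
                          thin = 5, seed = 11))
  })
}

# Hand-constructible secr_fit-like object with prescribed draws, for
# arithmetic-oracle tests of the posterior summaries. Draw matrices are
# (draws x cases).
manual_fit <- function(C, sigma2, R, A, grid, years = NULL, ids = NULL,
                       mu = NULL, n_chains = 2) {
  J <- ncol(C)
  if (is.null(ids)) ids <- sprintf("I%02d", seq_len(J))
  if (is.null(years)) years <- rep(2020L, J)
  half <- nrow(C) %/% n_chains
  idx <- split(seq_len(nrow(C)), rep(seq_len(n_chains), each = half))
  chains <- lapply(idx, function(i) {
    list(C = C[i, , drop = FALSE], sigma2 = sigma2[i, , drop = FALSE],
         R = R[i, , drop = FALSE], A = A[i, , drop = FALSE],
         mu = if (is.null(mu)) rowMeans(log(sigma2[i, , drop = FALSE])) else mu[i],
         omega = rep(0.5, length(i)), beta_e = rep(0, length(i)),
         n_kept = length(i))
  })
  structure(
    list(chains = chains,
         cases = tibble::tibble(individual_id = ids, year = years,
                                survey_days = 5L, included = TRUE,
                                any_sightings = TRUE),
         grid = grid, config = model_config(n_iter = 1000, burn_in = 0,
                                            thin = 1, n_chains = n_chains),
         n_draws = half),
    class = "secr_fit"
  )
}
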