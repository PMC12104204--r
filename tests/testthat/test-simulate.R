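test_that("effort patterns have their stated structure and are seed-deterministic", {
  sc <- small_scenario(effort_pattern = "uniform")
  e <- simulate_effort(sc)
  expect_true(all(e$area_km2 > 0))
  expect_equal(length(unique(e$area_km2)), 1L)
  expect_equal(nrow(e), sc$n_bins * sc$n_years * sc$n_days_per_year)

  sp <- small_scenario(effort_pattern = "patchy")
  ep <- simulate_effort(sp)
  annual <- ep |>
    dplyr::group_by(year, bin_index) |>
    dplyr::summarise(tot = sum(area_km2), .groups = "drop")
  expect_true(any(annual$tot == 0))

  expect_identical(simulate_effort(sp), simulate_effort(sp))
  expect_identical(simulate_individuals(sc), simulate_individuals(sc))
  ds1 <- simulate_dataset(small_scenario())
  ds2 <- simulate_dataset(small_scenario())
  expect_identical(ds1$sightings, ds2$sightings)
  expect_identical(ds1$stressors, ds2$stressors)
})

test_that("latent truth follows its generative distributions", {
  # degenerate Bernoulli
  none <- simulate_individuals(small_scenario(presence_prob = 0))
  expect_true(all(none$A_true == 0L))

  # Monte-Carlo moments at n = 10^4: mean of log sigma2 within 3 SE of
  # mu_true, variance of R within 3 SE of 1
  sc <- sim_scenario(n_individuals = 2500, n_years = 4, presence_prob = 1,
                     mu_true = -5.4, omega_true = 0.75, seed = 42)
  tr <- simulate_individuals(sc)
  n <- nrow(tr)
  expect_equal(n, 10000L)
  se_mu <- sc$omega_true / sqrt(n)
  expect_lt(abs(mean(log(tr$sigma2_true)) - sc$mu_true), 3 * se_mu)
  # SE of the sample variance of N(0,1) is sqrt(2/(n-1))
  expect_lt(abs(stats::var(tr$R_true) - 1), 3 * sqrt(2 / (n - 1)))
  expect_true(all(tr$C_true >= 44.33 & tr$C_true <= 44.33 + 0.55))
})

test_that("sightings obey presence, effort-zero exclusion and the Poisson rate", {
  sc <- small_scenario(effort_pattern = "patchy", seed = 3)
  effort <- simulate_effort(sc)
  truth <- simulate_individuals(sc)
  s <- simulate_sightings(truth, effort, sc)

  absent <- truth$individual_id[truth$A_true == 0L]
  absent_years <- truth[truth$A_true == 0L, c("individual_id", "year")]
  expect_equal(nrow(dplyr::inner_join(s, absent_years,
                                      by = c("individual_id", "year"))), 0L)

  # no sighting in any zero-effort (bin, day)
  joined <- dplyr::left_join(s, effort, by = c("date", "year", "bin_index"))
  expect_true(all(joined$area_km2 > 0))

  # latitudes stay inside their bin
  g <- scenario_grid(sc)
  expect_true(all(s$latitude >= g$edges[s$bin_index] &
                    s$latitude < g$edges[s$bin_index + 1]))
})

test_that("replicate simulations match the analytic Poisson mean in one bin", {
  # one individual, one year, uniform effort: the annual count in a bin is
  # Poisson with rate exp(R + beta_e * e_scaled) * exp(-d^2 / (2 sigma2))
  sc <- sim_scenario(n_bins = 5, n_years = 1, n_days_per_year = 5,
                     n_individuals = 1, presence_prob = 1, mu_true = -6,
                     omega_true = 0, beta_e_true = 0.05, seed = 5)
  effort <- simulate_effort(sc)
  g <- scenario_grid(sc)
  truth <- simulate_individuals(sc)
  annual_e <- effort |>
    dplyr::group_by(bin_index) |>
    dplyr::summarise(e = sum(area_km2), .groups = "drop")
  esc <- scale_effort(annual_e$e) # uniform: all exactly 10
  lam <- exp(truth$R_true + sc$beta_e_true * esc -
               (g$centroids - truth$C_true)^2 / (2 * truth$sigma2_true))

  set.seed(99)
  bin_counts <- matrix(0, 1000, sc$n_bins)
  for (r in seq_len(1000)) {
    sc_r <- sim_scenario(n_bins = 5, n_years = 1, n_days_per_year = 5,
                         n_individuals = 1, presence_prob = 1, mu_true = -6,
                         omega_true = 0, beta_e_true = 0.05, seed = 5 + r)
    # keep the same latent truth, redraw only the counts
    s_r <- simulate_sightings(truth, effort, sc_r)
    if (nrow(s_r)) {
      tab <- table(factor(s_r$bin_index, levels = 1:5))
      bin_counts[r, ] <- as.integer(tab)
    }
  }
  emp <- colMeans(bin_counts)
  se <- sqrt(lam / 1000)
  expect_true(all(abs(emp - lam) <= 3 * se + 1e-9))
})
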