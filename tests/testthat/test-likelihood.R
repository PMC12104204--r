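test_that("effort scaling hits its maximum exactly and preserves zeros", {
  expect_equal(scale_effort(c(0, 50, 100)), c(0, 5, 10))
  expect_equal(max(scale_effort(matrix(runif(20), 4))), 10)
  expect_equal(scale_effort(c(4, 4, 4)), c(10, 10, 10))
  expect_error(scale_effort(c(0, 0)), "all-zero")
  expect_error(scale_effort(c(-1, 2)), "non-negative")
})

test_that("the expected sighting rate follows the half-normal kernel", {
  g <- lat_grid(44, 0.01, 5)
  # zero effort forces rate zero even at the activity center
  lam <- sighting_rate(C = g$centroids[3], sigma2 = 1e-4, R = 0, A = 1,
                       beta_e = 0.5, e_scaled = c(10, 10, 0, 10, 10), g)
  expect_equal(lam[3], 0)
  # identity case: d = 0, R = 0, beta_e = 0 gives exactly 1
  lam <- sighting_rate(C = g$centroids[3], sigma2 = 1e-4, R = 0, A = 1,
                       beta_e = 0, e_scaled = rep(10, 5), g)
  expect_equal(lam[3], 1)
  # at d = sigma the kernel equals exp(-1/2)
  sigma <- 0.02
  lam <- sighting_rate(C = g$centroids[3] - sigma, sigma2 = sigma^2, R = 0,
                       A = 1, beta_e = 0, e_scaled = rep(10, 5), g)
  expect_equal(lam[3], exp(-0.5))
  # absence zeroes the rate everywhere
  expect_equal(sighting_rate(44.02, 1e-4, 0, 0, 0, rep(10, 5), g), rep(0, 5))
  expect_error(sighting_rate(44.02, -1, 0, 1, 0, rep(10, 5), g), "positive")
})

test_that("the kernel is non-increasing in distance", {
  g <- lat_grid(44, 0.01, 41)
  for (s2 in c(1e-5, 1e-3, 0.1)) {
    lam <- sighting_rate(C = g$centroids[21], sigma2 = s2, R = 1, A = 1,
                         beta_e = 0, e_scaled = rep(5, 41), g)
    expect_true(all(diff(lam[21:41]) <= 1e-15))
    expect_true(all(diff(lam[1:21]) >= -1e-15))
  }
})

test_that("single-cell log-likelihood values match the Poisson pmf", {
  g <- lat_grid(44, 0.01, 2)
  # S = 2 at lambda = 1 (second bin unsurveyed): log pmf is -1 - log(2)
  ll <- secr_loglik(S = matrix(c(2L, 0L), 1), e_scaled = matrix(c(10, 0), 1),
                    g, C = g$centroids[1], sigma2 = 1e6, R = 0, A = 1,
                    beta_e = 0)
  # sigma2 large makes the kernel 1 at d = 0; gamma = exp(0) = 1
  expect_equal(ll, -1 - log(2), tolerance = 1e-12)
  # all-zero data with A = 0 everywhere has probability one
  expect_equal(secr_loglik(matrix(0L, 2, 2), matrix(10, 2, 2), g,
                           C = rep(44.005, 2), sigma2 = rep(1, 2),
                           R = rep(0, 2), A = rep(0, 2), beta_e = 0), 0)
  # sightings for an absent individual are impossible
  expect_identical(secr_loglik(matrix(c(3L, 0L), 1), matrix(10, 1, 2), g,
                               44.005, 1, 0, 0, 0), -Inf)
  expect_error(secr_loglik(matrix(-1, 1, 2), matrix(10, 1, 2), g,
                           44.005, 1, 0, 1, 0), "non-negative")
})

# Brute-force reference: naive loops over individuals and bins, scalar
# arithmetic only. Kept deliberately independent of the package's
# vectorised implementation.
naive_loglik <- function(S, E, centroids, C, sigma2, R, A, beta_e) {
  total <- 0
  for (j in seq_len(nrow(S))) {
    for (l in seq_len(ncol(S))) {
      lam <- 0
      if (E[j, l] > 0 && A[j] == 1) {
        d <- centroids[l] - C[j]
        lam <- exp(R[j] + beta_e * E[j, l]) * exp(-d^2 / (2 * sigma2[j]))
      }
      total <- total + dpois(S[j, l], lam, log = TRUE)
    }
  }
  total
}

test_that("vectorised log-likelihood matches brute force on random instances", {
  set.seed(202)
  for (rep in 1:100) {
    J <- sample(1:6, 1); L <- sample(2:12, 1)
    g <- lat_grid(44, 0.01, L)
    E <- matrix(rexp(J * L), J, L)
    E[runif(J * L) < 0.3] <- 0
    if (all(E == 0)) E[1, 1] <- 1
    E <- scale_effort(E)
    A <- rbinom(J, 1, 0.8)
    C <- runif(J, 44, 44 + L * 0.01)
    sigma2 <- exp(rnorm(J, -6, 1))
    R <- rnorm(J)
    beta_e <- rnorm(1, 0, 0.2)
    lam_mat <- t(vapply(seq_len(J), function(j)
      sighting_rate(C[j], sigma2[j], R[j], A[j], beta_e, E[j, ], g),
      numeric(L)))
    S <- matrix(rpois(J * L, lam_mat), J, L)
    S[E == 0] <- 0L
    ll <- secr_loglik(S, E, g, C, sigma2, R, A, beta_e)
    expect_equal(ll, naive_loglik(S, E, g$centroids, C, sigma2, R, A, beta_e),
                 tolerance = 1e-10)
  }
})
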