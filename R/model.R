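#' Prior specification for the SECR model
#'
#' The activity-center prior is continuous Uniform over the grid extent and
#' the presence prior Bernoulli(`presence_prob`); both are structural. The
#' remaining hyperpriors are configurable: `mu ~ Normal(mu_mean, mu_sd^2)` on
#' the log degrees-squared scale (the default is centred near the scale
#' implied by ranges of a few tens of kilometres), `omega ~ half-Normal(0,
#' omega_sd^2)`, and `beta_e ~ Normal(beta_e_mean, beta_e_sd^2)`. The
#' residency intercept prior is fixed at `R ~ Normal(0, 1)`.
#'
#' @param mu_mean,mu_sd Normal prior on the population mean log activity
#'   range (defaults -5, 3).
#' @param omega_sd Scale of the half-normal prior on the log-range
#'   random-effect standard deviation (default 1).
#' @param beta_e_mean,beta_e_sd Normal prior on the effort slope (defaults
#'   0, 10).
#' @param presence_prob Prior presence probability (default 0.5).
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(mu_mean = -5, mu_sd = 3, omega_sd = 1,
                       beta_e_mean = 0, beta_e_sd = 10, presence_prob = 0.5) {
  stopifnot(mu_sd > 0, omega_sd > 0, beta_e_sd > 0,
            presence_prob > 0, presence_prob < 1)
  structure(
    list(mu_mean = mu_mean, mu_sd = mu_sd, omega_sd = omega_sd,
         beta_e_mean = beta_e_mean, beta_e_sd = beta_e_sd,
         presence_prob = presence_prob),
    class = "prior_spec"
  )
}

#' Sampler configuration for the SECR model
#'
#' Defaults follow the full-scale analysis protocol: three chains of 400,000
#' iterations, a 50,000-iteration burn-in, and 1-in-100 thinning. Tests and
#' examples use scaled-down configurations. Individual-years estimated absent
#' (`A = 0`) are reported at the pinned absent state (`absent_center_deg`,
#' `absent_sigma2`), which never enters the likelihood and is excluded from
#' space-use and exposure summaries.
#'
#' @param n_chains Number of chains (default 3; at least 2 for diagnostics).
#' @param n_iter Iterations per chain (default 400000).
#' @param burn_in Burn-in iterations discarded per chain (default 50000).
#'   Random-walk step sizes adapt during burn-in only.
#' @param thin Keep 1 in `thin` post-burn-in iterations (default 100).
#' @param seed Integer seed; chain `k` uses stream `seed + k`.
#' @param priors A [prior_spec()].
#' @param absent_center_deg,absent_sigma2 Pinned state reported when an
#'   individual-year is estimated outside the study area (defaults 52 degrees
#'   N and 0.001 degrees squared).
#' @param effort_scale_factor Effort is scaled to `[0, effort_scale_factor]`
#'   by its global maximum before entering the model (default 10).
#' @param fixed Named list fixing parameters for controlled experiments:
#'   any of `mu`, `omega`, `beta_e` (scalars) and `R` (scalar or one value
#'   per individual-year). Fixed parameters are not updated.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_chains = 3, n_iter = 400000, burn_in = 50000,
                         thin = 100, seed = 1L, priors = prior_spec(),
                         absent_center_deg = 52, absent_sigma2 = 0.001,
                         fixed = list(), effort_scale_factor = 10) {
  stopifnot(inherits(priors, "prior_spec"))
  if (burn_in >= n_iter) stop("`burn_in` must be smaller than `n_iter`", call. = FALSE)
  if (thin < 1) stop("`thin` must be >= 1", call. = FALSE)
  if (n_chains < 2) stop("at least 2 chains are needed for convergence diagnostics",
                         call. = FALSE)
  allowed <- c("mu", "omega", "beta_e", "R")
  if (length(fixed) && !all(names(fixed) %in% allowed)) {
    stop("`fixed` may only name mu, omega, beta_e or R", call. = FALSE)
  }
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         seed = as.integer(seed), priors = priors,
         absent_center_deg = absent_center_deg, absent_sigma2 = absent_sigma2,
         fixed = fixed, effort_scale_factor = effort_scale_factor),
    class = "model_config"
  )
}

#' Scale survey effort for the sighting-rate model
#'
#' Effort enters the baseline sighting rate after dividing by the single
#' maximum over all (bin, year) cells and multiplying by `factor`, so the
#' largest scaled effort is exactly `factor` and zeros are preserved.
#'
#' @param e Non-negative effort values (vector, matrix or array), km^2.
#' @param factor Target maximum (default 10).
#' @return Scaled effort with the same shape as `e`.
#' @export
scale_effort <- function(e, factor = 10) {
  if (any(e < 0)) stop("effort must be non-negative", call. = FALSE)
  m <- max(e)
  if (m <= 0) stop("all-zero effort cannot be scaled", call. = FALSE)
  e * (factor / m)
}

#' Expected sighting rate across latitude bins
#'
#' For one individual-year, the expected annual count in each bin is zero
#' where no effort was deployed and otherwise
#' `A * exp(R + beta_e * e_scaled) * exp(-d^2 / (2 sigma2))`, with `d` the
#' distance in degrees from the bin centroid to the activity center.
#'
#' @param C Activity center, degrees latitude.
#' @param sigma2 Activity range, degrees squared (> 0).
#' @param R Residency (log baseline rate) intercept.
#' @param A Presence indicator, 0 or 1.
#' @param beta_e Effort slope.
#' @param e_scaled Scaled effort per bin (see [scale_effort()]).
#' @param grid A [lat_grid()], or a numeric vector of bin centroids.
#' @return Numeric vector of expected counts, one per bin.
#' @export
sighting_rate <- function(C, sigma2, R, A, beta_e, e_scaled, grid) {
  if (sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  centroids <- if (inherits(grid, "lat_grid")) grid$centroids else grid
  d <- centroids - C
  lam <- A * exp(R + beta_e * e_scaled - d^2 / (2 * sigma2))
  lam[e_scaled <= 0] <- 0
  lam
}

#' Joint log-likelihood of an encounter array
#'
#' Vectorised Poisson log-likelihood over all individual-year-bin cells.
#' Cells with zero effort (or `A = 0`) have rate zero: they contribute
#' nothing when the observed count is zero and drive the log-likelihood to
#' `-Inf` when a count was observed there.
#'
#' @param S Integer count matrix, individual-years by bins.
#' @param e_scaled Scaled effort matrix of the same shape.
#' @param grid A [lat_grid()] (or centroid vector) with as many bins as `S`
#'   has columns.
#' @param C,sigma2,R,A Per-individual-year latent states (vectors of length
#'   `nrow(S)`).
#' @param beta_e Effort slope (scalar).
#' @return The scalar log-likelihood.
#' @export
secr_loglik <- function(S, e_scaled, grid, C, sigma2, R, A, beta_e) {
  if (any(S < 0) || any(S != round(S))) {
    stop("`S` must contain non-negative integer counts", call. = FALSE)
  }
  if (any(sigma2 <= 0)) stop("`sigma2` must be positive", call. = FALSE)
  centroids <- if (inherits(grid, "lat_grid")) grid$centroids else grid
  S <- as.matrix(S); e_scaled <- as.matrix(e_scaled)
  D <- outer(C, centroids, "-")
  loglam <- R + beta_e * e_scaled - D^2 / (2 * sigma2)
  lam <- A * exp(loglam)
  lam[e_scaled <= 0] <- 0
  sum(stats::dpois(S, lam, log = TRUE))
}

# Flatten an encounter_data object into the case-indexed matrices the
# sampler consumes: one row per (individual, year).
build_cases <- function(data, config) {
  J_ind <- length(data$individuals)
  n_years <- length(data$years)
  cases <- tidyr::expand_grid(individual_id = data$individuals,
                              year = data$years) |>
    dplyr::arrange(individual_id, year) |>
    dplyr::left_join(data$inclusion, by = c("individual_id", "year"))
  esc <- scale_effort(data$effort, config$effort_scale_factor)
  L <- dim(data$S)[2]
  S <- matrix(0L, nrow(cases), L)
  E <- matrix(0, nrow(cases), L)
  for (k in seq_len(nrow(cases))) {
    i <- match(cases$individual_id[k], data$individuals)
    t <- match(cases$year[k], data$years)
    S[k, ] <- data$S[i, , t]
    E[k, ] <- esc[, t]
  }
  cases$any_sightings <- rowSums(S) > 0
  list(cases = cases, S = S, E = E)
}

#' Fit the one-dimensional SECR model by MCMC
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler targeting the posterior
#' of the hierarchical model: per individual-year, an activity center `C`
#' (uniform over the grid), presence `A` (Bernoulli), residency intercept
#' `R` (standard normal) and log activity range `log(sigma2) = mu + M` with
#' `M ~ Normal(0, omega^2)`; sightings per bin are Poisson with a half-normal
#' decay of the rate away from `C` and a log-linear effort effect `beta_e`.
#' `C`, `M`, `R` and the population parameters take random-walk Metropolis
#' updates (step sizes adapted during burn-in only); `A` takes an exact
#' Gibbs draw from its two-point full conditional, which forces `A = 1` for
#' any individual-year with sightings. Chains differ only by their seed
#' stream (`seed + chain`).
#'
#' @param data An [build_encounter_array()] object.
#' @param config A [model_config()].
#' @return An object of class `secr_fit`: retained thinned draws per chain
#'   of `C`, `sigma2`, `R`, `A` (draws x individual-years) and `mu`, `omega`,
#'   `beta_e`, plus the case table, grid and configuration echo.
#' @export
secr_fit <- function(data, config = model_config()) {
  stopifnot(inherits(data, "encounter_data"), inherits(config, "model_config"))
  cs <- build_cases(data, config)
  grid <- data$grid
  J <- nrow(cs$cases)

  fixed <- config$fixed
  if (!is.null(fixed$R) && length(fixed$R) == 1L) fixed$R <- rep(fixed$R, J)

  # initial state: C at the sighting-weighted mean latitude (extent midpoint
  # when unseen); A = 1 where sightings exist, else a prior draw
  cent <- grid$centroids
  C0 <- vapply(seq_len(J), function(j) {
    s <- cs$S[j, ]
    if (sum(s) > 0) sum(s * cent) / sum(s) else mean(grid$extent)
  }, numeric(1))
  mu0 <- if (!is.null(fixed$mu)) fixed$mu else config$priors$mu_mean
  omega0 <- if (!is.null(fixed$omega)) fixed$omega else config$priors$omega_sd / 2
  be0 <- if (!is.null(fixed$beta_e)) fixed$beta_e else 0
  R0 <- if (!is.null(fixed$R)) fixed$R else rep(0, J)

  ll0 <- secr_loglik(cs$S, cs$E, grid, C0, rep(exp(mu0), max(J, 1L)), R0,
                     rep(1L, J), be0)
  if (J > 0 && !is.finite(ll0)) {
    stop(sprintf("non-finite log-posterior at initialization (ll = %s; mu0 = %g)",
                 ll0, mu0), call. = FALSE)
  }

  chains <- purrr::map(seq_len(config$n_chains), function(ch) {
    set.seed(config$seed + ch)
    init <- list(C = C0, M = rep(0, J), R = R0,
                 A = as.integer(ifelse(cs$cases$any_sightings, 1L,
                                       stats::rbinom(J, 1L,
                                                     config$priors$presence_prob))),
                 mu = mu0, omega = omega0, beta_e = be0)
    secr_chain_cpp(cs$S, cs$E, cent, grid$extent[["south"]],
                   grid$extent[["north"]], config$n_iter,
                   config$burn_in, config$thin,
                   unclass(config$priors), fixed,
                   config$absent_center_deg, config$absent_sigma2,
                   init)
  })

  structure(
    list(chains = chains, cases = cs$cases, grid = grid, config = config,
         S = cs$S, E = cs$E,
         n_draws = chains[[1]]$n_kept),
    class = "secr_fit"
  )
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf(
    "<secr_fit> %d individual-years, %d chains x %d retained draws (%d iterations, burn-in %d, thin %d)\n",
    nrow(x$cases), length(x$chains), x$n_draws, x$config$n_iter,
    x$config$burn_in, x$config$thin
  ))
  invisible(x)
}

# Per-chain named draw matrices for a fit: population parameters plus the
# per-case C, log(sigma2) and R series.
chain_draw_matrix <- function(fit, chain) {
  ch <- fit$chains[[chain]]
  labs <- sprintf("%s:%s", fit$cases$individual_id, fit$cases$year)
  out <- cbind(mu = ch$mu, omega = ch$omega, beta_e = ch$beta_e,
               ch$C, log(ch$sigma2), ch$R)
  colnames(out) <- c("mu", "omega", "beta_e",
                     paste0("C[", labs, "]"),
                     paste0("log_sigma2[", labs, "]"),
                     paste0("R[", labs, "]"))
  out
}

#' Extract posterior draws in long format
#'
#' @param fit A [secr_fit()] object.
#' @param params Optional character vector restricting to parameter names.
#' @return A tibble with columns `chain`, `draw`, `parameter`, `value`.
#' @export
posterior_draws <- function(fit, params = NULL) {
  stopifnot(inherits(fit, "secr_fit"))
  purrr::map(seq_along(fit$chains), function(k) {
    m <- chain_draw_matrix(fit, k)
    if (!is.null(params)) m <- m[, intersect(colnames(m), params), drop = FALSE]
    tibble::tibble(
      chain = k,
      draw = rep(seq_len(nrow(m)), ncol(m)),
      parameter = rep(colnames(m), each = nrow(m)),
      value = as.vector(m)
    )
  }) |> dplyr::bind_rows()
}
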