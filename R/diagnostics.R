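#' Brooks-Gelman-Rubin potential scale reduction
#'
#' Classic potential-scale-reduction factor from the between- and
#' within-chain variances: with `m` chains of length `n`, `W` the mean of
#' the chain variances and `B/n` the variance of the chain means,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate the
#' chains have mixed; parameters at or above the threshold are flagged.
#' A parameter with zero within-chain variance (e.g. a pinned or fixed
#' quantity) has an undefined factor, reported as `NA` rather than an error.
#'
#' @param fit A [secr_fit()] object, or a list of per-chain numeric matrices
#'   with identical column names (draws in rows).
#' @param threshold Flagging threshold (default 1.1).
#' @return A tibble with columns `parameter`, `rhat`, `flagged`.
#' @export
gelman_rubin <- function(fit, threshold = 1.1) {
  mats <- diagnostic_matrices(fit)
  if (length(mats) < 2L) stop("at least 2 chains are required", call. = FALSE)
  n <- min(vapply(mats, nrow, integer(1)))
  if (n < 2L) stop("at least 2 draws per chain are required", call. = FALSE)
  rhat <- vapply(colnames(mats[[1]]), function(p) {
    draws <- vapply(mats, function(m) m[seq_len(n), p], numeric(n))
    W <- mean(apply(draws, 2, stats::var))
    if (!is.finite(W) || W == 0) return(NA_real_)
    var_plus <- (n - 1) / n * W + stats::var(colMeans(draws))
    sqrt(var_plus / W)
  }, numeric(1))
  tibble::tibble(parameter = colnames(mats[[1]]), rhat = unname(rhat),
                 flagged = !is.na(rhat) & rhat >= threshold)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size per parameter, using Geyer's
#' initial-positive-sequence truncation: within each chain the empirical
#' autocorrelations are summed in adjacent pairs and truncated at the first
#' non-positive pair, giving `ESS = n / (1 + 2 * sum(rho))`; chain ESS values
#' are then added. Constant chains have undefined ESS, reported as `NA`.
#' Parameters at or below the threshold are flagged.
#'
#' @param fit A [secr_fit()] object, or a list of per-chain numeric matrices
#'   with identical column names (draws in rows).
#' @param threshold Flagging threshold (default 400).
#' @return A tibble with columns `parameter`, `ess`, `flagged`.
#' @export
effective_sample_size <- function(fit, threshold = 400) {
  mats <- diagnostic_matrices(fit)
  ess <- vapply(colnames(mats[[1]]), function(p) {
    per_chain <- vapply(mats, function(m) chain_ess(m[, p]), numeric(1))
    if (all(is.na(per_chain))) NA_real_ else sum(per_chain, na.rm = TRUE)
  }, numeric(1))
  tibble::tibble(parameter = colnames(mats[[1]]), ess = unname(ess),
                 flagged = is.na(ess) | ess <= threshold)
}

chain_ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1L, 2000L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  # Geyer initial positive sequence: sum autocorrelations in adjacent pairs,
  # truncate at the first non-positive pair sum
  n_pairs <- floor(length(rho) / 2)
  tail_sum <- 0
  if (n_pairs >= 1L) {
    pair <- rho[seq_len(n_pairs) * 2 - 1] + rho[seq_len(n_pairs) * 2]
    cut <- which(pair <= 0)
    keep <- if (length(cut)) cut[1] - 1L else n_pairs
    if (keep > 0L) tail_sum <- sum(pair[seq_len(keep)])
  }
  n / max(1 + 2 * tail_sum, 1e-8)
}

# Accept either a secr_fit or a bare list of per-chain draw matrices.
diagnostic_matrices <- function(fit) {
  if (inherits(fit, "secr_fit")) {
    lapply(seq_along(fit$chains), function(k) chain_draw_matrix(fit, k))
  } else if (is.list(fit) && all(vapply(fit, is.matrix, logical(1)))) {
    fit
  } else {
    stop("expected a secr_fit or a list of per-chain draw matrices", call. = FALSE)
  }
}

#' Summarise a fitted SECR model
#'
#' `tidy()` returns one row per model parameter with the posterior median,
#' mean, a central credible interval, and convergence diagnostics.
#' `glance()` returns a one-row overview of the fit.
#'
#' @param x A [secr_fit()] object.
#' @param conf_level Width of the central credible interval (default 0.9).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy secr_fit
#' @export
tidy.secr_fit <- function(x, conf_level = 0.9, ...) {
  mats <- diagnostic_matrices(x)
  all_draws <- do.call(rbind, mats)
  a <- (1 - conf_level) / 2
  summ <- tibble::tibble(
    term = colnames(all_draws),
    estimate = apply(all_draws, 2, stats::median),
    mean = colMeans(all_draws),
    conf.low = apply(all_draws, 2, stats::quantile, probs = a),
    conf.high = apply(all_draws, 2, stats::quantile, probs = 1 - a)
  )
  summ |>
    dplyr::left_join(dplyr::select(gelman_rubin(x), term = parameter, rhat),
                     by = "term") |>
    dplyr::left_join(dplyr::select(effective_sample_size(x), term = parameter, ess),
                     by = "term")
}

#' @rdname tidy.secr_fit
#' @method glance secr_fit
#' @export
glance.secr_fit <- function(x, ...) {
  gr <- gelman_rubin(x)
  es <- effective_sample_size(x)
  tibble::tibble(
    n_individuals = length(unique(x$cases$individual_id)),
    n_years = length(unique(x$cases$year)),
    n_individual_years = nrow(x$cases),
    n_chains = length(x$chains),
    n_draws = x$n_draws,
    max_rhat = suppressWarnings(max(gr$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(es$ess, na.rm = TRUE)),
    converged = !any(gr$flagged, na.rm = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
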