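#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted Thurstonian IRT model
#'
#' @param x An `mfc_fit`.
#' @param conf_level Credible interval level (central quantile interval).
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`
#'   (posterior mean), `std.error` (posterior SD), `mcse`, `conf.low`,
#'   `conf.high`, `rhat`, `ess_bulk`.
#' @method tidy mfc_fit
#' @export
tidy.mfc_fit <- function(x, conf_level = 0.95, ...) {
  s <- convergence_diagnostics(x)
  a <- x$draws
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  qs <- t(apply(a, 3L, stats::quantile, probs = probs))
  tibble::tibble(
    term = s$term,
    estimate = s$mean,
    std.error = s$sd,
    mcse = s$mcse,
    conf.low = qs[, 1],
    conf.high = qs[, 2],
    rhat = s$rhat,
    ess_bulk = s$ess_bulk)
}

#' Glance at a fitted Thurstonian IRT model
#'
#' @param x An `mfc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: implementation, chains, kept iterations,
#'   parameter count, max R-hat, min bulk ESS, elpd_waic and wall time.
#' @method glance mfc_fit
#' @export
glance.mfc_fit <- function(x, ...) {
  s <- convergence_diagnostics(x)
  w <- waic(x)
  tibble::tibble(
    impl = x$impl,
    chains = dim(x$draws)[2],
    kept_iter = dim(x$draws)[1],
    n_parameters = dim(x$draws)[3],
    max_rhat = max(s$rhat, na.rm = TRUE),
    min_ess_bulk = min(s$ess_bulk, na.rm = TRUE),
    elpd_waic = w$elpd_waic,
    elapsed = x$time)
}
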