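split_chains <- function(x) {
  # x: iterations x chains -> halves as separate chains
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

rhat_basic <- function(x) {
  # classic potential scale reduction on iterations x chains
  n <- nrow(x); m <- ncol(x)
  chain_means <- colMeans(x)
  chain_vars <- apply(x, 2L, stats::var)
  W <- mean(chain_vars)
  B <- n * stats::var(chain_means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# autocovariances (lags 0..n-1) per column via FFT, biased (1/n) scaling
autocov_fft <- function(x) {
  n <- nrow(x)
  xc <- sweep(x, 2L, colMeans(x))
  npad <- 2^ceiling(log2(2 * n))
  padded <- rbind(xc, matrix(0, npad - n, ncol(x)))
  f <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(f * Conj(f), inverse = TRUE))[seq_len(n), , drop = FALSE]
  ac / (npad * n)
}

ess_basic <- function(x) {
  # Geyer initial positive + monotone sequence estimator on iterations x chains
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  acov <- autocov_fft(x)                    # rows = lags 0..n-1
  chain_means <- colMeans(x)
  mean_var <- mean(acov[1L, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + stats::var(chain_means)
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # paired autocorrelation sums P_k = rho(2k) + rho(2k+1), kept while positive
  ps <- numeric(0)
  for (k in seq_len(floor(n / 2) - 1L)) {
    s <- rho[2L * k - 1L] + rho[2L * k]
    if (s <= 0) break
    ps <- c(ps, s)
  }
  if (length(ps) == 0L) return(n * m)
  ps <- cummin(ps)                          # enforce monotone decrease
  tau <- -1 + 2 * sum(ps)
  tau <- max(tau, 1 / log10(n * m + 10))    # guard for antithetic chains
  n * m / tau
}

#' Convergence diagnostics for MCMC draws
#'
#' Rank-normalized split-chain potential scale reduction (split R-hat), bulk
#' effective sample size via Geyer's initial monotone sequence estimator on
#' rank-normalized split chains, and the Monte Carlo standard error of the
#' posterior mean (`MCSE = sd / sqrt(ESS)`). These are the rank-normalized
#' variants; anti-correlated chains may legitimately report an ESS above the
#' raw draw count.
#'
#' @param draws An `mfc_fit`, or a 3-d array `iterations x chains x
#'   parameters` (dimnames on the third margin name the parameters), or a
#'   matrix `iterations x chains` for a single parameter.
#' @return A tibble with one row per parameter: `term`, `mean`, `sd`,
#'   `mcse`, `rhat`, `ess_bulk`. Scalar summaries (max R-hat, min ESS) are in
#'   attribute `"summary"`.
#' @export
convergence_diagnostics <- function(draws) {
  a <- as_draws_array(draws)
  if (dim(a)[2] < 2L) {
    abort_mfc("split diagnostics require at least 2 chains", "mfcirt_single_chain")
  }
  if (dim(a)[1] < 4L) {
    abort_mfc("too few draws for split diagnostics (need >= 4 per chain)",
              "mfcirt_insufficient_draws")
  }
  terms <- dimnames(a)[[3]]
  if (is.null(terms)) terms <- paste0("par", seq_len(dim(a)[3]))
  res <- purrr::map_dfr(seq_len(dim(a)[3]), function(p) {
    x <- a[, , p]
    sx <- split_chains(x)
    z <- rank_normalize(sx)
    ess <- ess_basic(z)
    sdev <- stats::sd(as.vector(x))
    tibble::tibble(
      term = terms[p],
      mean = mean(x),
      sd = sdev,
      mcse = if (is.na(ess) || ess <= 0) NA_real_ else sdev / sqrt(ess),
      rhat = rhat_basic(z),
      ess_bulk = ess)
  })
  safe <- function(f, x) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  attr(res, "summary") <- tibble::tibble(
    mean_rhat = safe(mean, res$rhat),
    max_rhat = safe(max, res$rhat),
    mean_ess = safe(mean, res$ess_bulk),
    min_ess = safe(min, res$ess_bulk))
  res
}

as_draws_array <- function(draws) {
  if (inherits(draws, "mfc_fit")) return(draws$draws)
  if (is.matrix(draws)) {
    return(array(draws, dim = c(nrow(draws), ncol(draws), 1L)))
  }
  if (is.array(draws) && length(dim(draws)) == 3L) return(draws)
  abort_mfc("draws must be an mfc_fit, a matrix or a 3-d array", "mfcirt_shape_error")
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Widely applicable information criterion (WAIC)
#'
#' Computes `elpd_waic = sum_i [log mean_s exp(ll_si) - var_s(ll_si)]` from a
#' pointwise log-likelihood matrix (posterior draws in rows, observations in
#' columns), with the standard error taken from the observation-wise
#' dispersion. The observation unit here is one respondent-block (the
#' multivariate ranking observation).
#'
#' @param pointwise_loglik Matrix `draws x observations`, a 3-d array
#'   `iterations x chains x observations`, or an `mfc_fit`.
#' @return A list of class `mfc_waic`: `elpd_waic`, `se_elpd_waic`, `p_waic`,
#'   `n_obs` and the pointwise tibble.
#' @export
waic <- function(pointwise_loglik) {
  ll <- pointwise_ll_matrix(pointwise_loglik)
  if (!all(is.finite(ll))) {
    abort_mfc("pointwise log-likelihood contains non-finite values",
              "mfcirt_validation_error")
  }
  lpd <- apply(ll, 2L, log_mean_exp)
  p <- apply(ll, 2L, stats::var)
  pw <- tibble::tibble(obs = seq_len(ncol(ll)), elpd = lpd - p, lpd = lpd, p_waic = p)
  n <- ncol(ll)
  structure(
    list(elpd_waic = sum(pw$elpd),
         se_elpd_waic = sqrt(n * stats::var(pw$elpd)),
         p_waic = sum(p),
         n_obs = n,
         pointwise = pw),
    class = "mfc_waic")
}

pointwise_ll_matrix <- function(x) {
  if (inherits(x, "mfc_fit")) x <- x$pointwise_loglik
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3])
  }
  if (!is.matrix(x)) abort_mfc("expected a draws x observations matrix",
                               "mfcirt_shape_error")
  x
}

#' @export
print.mfc_waic <- function(x, ...) {
  cat(sprintf("WAIC: elpd_waic = %.2f (SE %.2f), p_waic = %.2f, n_obs = %d\n",
              x$elpd_waic, x$se_elpd_waic, x$p_waic, x$n_obs))
  invisible(x)
}

#' Compare models by WAIC
#'
#' Pairwise expected log predictive density differences against the model
#' with the highest `elpd_waic`, with paired standard errors computed from
#' the observation-wise elpd differences. A model compared against itself has
#' difference 0 with SE 0.
#'
#' @param ... Named `mfc_waic` objects (or `mfc_fit`s, which are passed
#'   through [waic()]). Alternatively a single named list.
#' @return A tibble with `model`, `elpd_waic`, `se_elpd_waic`, `p_waic`,
#'   `elpd_diff`, `se_diff`, ordered by decreasing `elpd_waic`.
#' @export
compare_waic <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1]]) && !inherits(objs[[1]], "mfc_waic") &&
      !inherits(objs[[1]], "mfc_fit")) {
    objs <- objs[[1]]
  }
  if (is.null(names(objs)) || any(names(objs) == "")) {
    names(objs) <- paste0("model", seq_along(objs))
  }
  ws <- lapply(objs, function(o) if (inherits(o, "mfc_waic")) o else waic(o))
  n_obs <- vapply(ws, function(w) w$n_obs, integer(1))
  if (length(unique(n_obs)) != 1L) {
    abort_mfc("models must share the same observations for WAIC comparison",
              "mfcirt_comparability_error")
  }
  elpds <- vapply(ws, function(w) w$elpd_waic, numeric(1))
  ref <- which.max(elpds)
  out <- purrr::map_dfr(seq_along(ws), function(i) {
    dvec <- ws[[i]]$pointwise$elpd - ws[[ref]]$pointwise$elpd
    tibble::tibble(
      model = names(ws)[i],
      elpd_waic = ws[[i]]$elpd_waic,
      se_elpd_waic = ws[[i]]$se_elpd_waic,
      p_waic = ws[[i]]$p_waic,
      elpd_diff = sum(dvec),
      se_diff = sqrt(n_obs[1] * stats::var(dvec)))
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$elpd_waic))
  class(out) <- c("mfc_waic_comparison", class(out))
  out
}
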