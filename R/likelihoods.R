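#' Pairwise comparison intercepts
#'
#' Intercepts hold one value per pairwise comparison in lexicographic order.
#' In `free` mode they are unrestricted (the original formulation). In
#' `constrained` mode they are the deterministic transform `gamma = -A mu` of
#' the statement utility means, which enforces the within-block identity
#' `gamma_AB + gamma_BC = gamma_AC` and thereby assigns probability zero to
#' intransitive binary patterns.
#'
#' @param gamma Numeric vector of intercepts.
#' @param mode `"free"` or `"constrained"`.
#' @return `gamma` with class `fc_intercepts` and a `mode` attribute.
#' @export
intercepts <- function(gamma, mode = c("free", "constrained")) {
  mode <- match.arg(mode)
  structure(as.numeric(gamma), class = "fc_intercepts", mode = mode)
}

#' Constrained intercepts derived from utility means
#'
#' @param mu Statement utility means (all statements, block order).
#' @param A Full pairwise design matrix from [full_design_matrix()].
#' @return Constrained [intercepts()], `gamma = -A mu`.
#' @export
constrained_intercepts <- function(mu, A) {
  intercepts(as.numeric(-A %*% mu), mode = "constrained")
}

intercept_mode <- function(gamma) {
  if (inherits(gamma, "fc_intercepts")) attr(gamma, "mode") else "free"
}

#' Probit probability of preferring one statement over another
#'
#' The probability that a respondent with trait scores `theta_i`, `theta_l`
#' (on the traits of statements i and l) prefers statement i over statement l:
#' `pnorm((-gamma + lambda_i * theta_i - lambda_l * theta_l) /
#' sqrt(psi_i + psi_l))`. Invariant to adding a constant to both utilities.
#'
#' @param gamma Comparison intercept.
#' @param lambda_i,lambda_l Loadings of the two statements.
#' @param theta_i Trait score on statement i's trait.
#' @param theta_l Trait score on statement l's trait (defaults to `theta_i`,
#'   the single-trait case).
#' @param psi_i,psi_l Error variances, both positive.
#' @return Preference probability in (0, 1); vectorized over all arguments.
#' @export
pairwise_preference_probability <- function(gamma, lambda_i, lambda_l,
                                            theta_i, theta_l = theta_i,
                                            psi_i = 1, psi_l = 1) {
  if (any(psi_i <= 0) || any(psi_l <= 0)) {
    abort_mfc("error variances must be positive", "mfcirt_domain_error")
  }
  stats::pnorm((-gamma + lambda_i * theta_i - lambda_l * theta_l) /
                 sqrt(psi_i + psi_l))
}

lambda_matrix <- function(design, lambda) {
  n <- nrow(design$statements)
  L <- matrix(0, n, design$n_traits)
  L[cbind(seq_len(n), design$statements$trait)] <- lambda
  L
}

#' Law of the latent utility differences
#'
#' Given a design matrix (full or neighbouring), returns the mean and
#' covariance of the multivariate normal law of the utility differences
#' `y* = A t`: mean `A (mu + Lambda theta)` in constrained mode, or
#' `-gamma + A Lambda theta` with free intercepts; covariance `A Psi A^T`
#' with its eigenvalues and numerical rank. With the full matrix and
#' `n_b >= 3` the covariance is singular (the law is degenerate); with the
#' neighbouring matrix it is positive definite.
#'
#' @param A Design matrix (rows = comparisons, columns = statements).
#' @param mu Utility means per statement.
#' @param Lambda Loading matrix (statements x traits) or per-statement loading
#'   vector together with a `design` to expand it.
#' @param theta Trait score vector for one respondent.
#' @param Psi Per-statement error variances (vector) or diagonal matrix.
#' @param mode `"constrained"` (gamma = -A mu) or `"free"` (supply `gamma`).
#' @param gamma Free intercepts, required when `mode = "free"`.
#' @param design Optional [fc_design()] used to expand a loading vector.
#' @return List of class `utility_difference_law` with `mean`, `cov`,
#'   `eigenvalues` (descending) and `rank`.
#' @export
utility_difference_law <- function(A, mu, Lambda, theta, Psi,
                                   mode = c("constrained", "free"),
                                   gamma = NULL, design = NULL) {
  mode <- match.arg(mode)
  if (is.vector(Lambda)) {
    if (is.null(design)) abort_mfc("supply a design to expand a loading vector",
                                   "mfcirt_shape_error")
    Lambda <- lambda_matrix(design, Lambda)
  }
  if (is.vector(Psi)) Psi <- diag(Psi, nrow = length(Psi))
  if (ncol(A) != length(mu) || ncol(A) != nrow(Lambda) ||
      ncol(Lambda) != length(theta) || nrow(Psi) != ncol(A)) {
    abort_mfc("inconsistent shapes in utility difference law", "mfcirt_shape_error")
  }
  lin <- as.numeric(A %*% (Lambda %*% theta))
  m <- if (mode == "constrained") {
    as.numeric(A %*% mu) + lin
  } else {
    if (is.null(gamma)) abort_mfc("free mode requires gamma", "mfcirt_mode_error")
    -as.numeric(gamma) + lin
  }
  S <- A %*% Psi %*% t(A)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  r <- sum(ev > length(ev) * max(ev, 0) * 1e-12)
  structure(list(mean = m, cov = S, eigenvalues = ev, rank = r),
            class = "utility_difference_law")
}

#' Log-density of a (possibly singular) multivariate normal
#'
#' Density of the degenerate multivariate normal with respect to the
#' Lebesgue measure on its support: with non-zero eigenvalues `v_1..v_r` of
#' the covariance, `(2 pi)^(-r/2) (prod v_i)^(-1/2)
#' exp(-1/2 (x - mean)' cov^+ (x - mean))`, where `cov^+` is the
#' Moore-Penrose pseudo-inverse. The point must lie on the support
#' (`x - mean` in the column space of `cov`); off-support points raise a
#' distinct error rather than returning `-Inf`, because they indicate a
#' coding error, not an unlikely observation.
#'
#' @param x Evaluation point.
#' @param mean Mean vector.
#' @param cov Symmetric positive semi-definite covariance matrix.
#' @param support_tol Relative tolerance on the off-support residual.
#' @param rank_tol Eigenvalue threshold for the numerical rank; defaults to
#'   `length(ev) * max(ev) * 1e-12`.
#' @return The log-density (scalar).
#' @export
singular_normal_logpdf <- function(x, mean, cov, support_tol = 1e-8,
                                   rank_tol = NULL) {
  p <- length(x)
  if (length(mean) != p || !is.matrix(cov) || any(dim(cov) != p)) {
    abort_mfc("x, mean and cov must have matching dimensions", "mfcirt_shape_error")
  }
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  v <- e$values
  if (min(v) < -p * max(v, 0) * 1e-8) {
    abort_mfc("covariance is not positive semi-definite", "mfcirt_domain_error")
  }
  if (is.null(rank_tol)) rank_tol <- p * max(v, 0) * 1e-12
  keep <- v > rank_tol
  r <- sum(keep)
  if (r == 0L) abort_mfc("covariance has numerical rank zero", "mfcirt_rank_error")
  resid <- x - mean
  z <- crossprod(e$vectors, resid)          # coordinates in eigenbasis
  off <- sqrt(sum(z[!keep]^2))
  if (off > support_tol * max(1, sqrt(sum(resid^2)))) {
    abort_mfc(sprintf(
      "point lies off the support of the singular normal (residual %.3e)", off),
      "mfcirt_off_support")
  }
  -(r / 2) * log(2 * pi) - 0.5 * sum(log(v[keep])) -
    0.5 * sum(z[keep]^2 / v[keep])
}

#' Log-likelihood of binary patterns under the original formulation
#'
#' Treats all `n_b (n_b - 1) / 2` comparisons per block as independent
#' Bernoulli outcomes with probit success probabilities and free intercepts.
#' Because the intercepts are unrestricted, this likelihood assigns positive
#' probability to intransitive binary patterns.
#'
#' @param binary 0/1 vector over all comparisons (blocks concatenated,
#'   lexicographic pair order within block).
#' @param gamma Free intercepts, one per comparison (a plain numeric vector
#'   or [intercepts()] in `free` mode; constrained intercepts are rejected).
#' @param design An [fc_design()].
#' @param lambda Per-statement loadings.
#' @param theta Trait score vector (one respondent).
#' @param psi Per-statement error variances.
#' @return Scalar log-likelihood.
#' @export
loglik_original <- function(binary, gamma, design, lambda, theta, psi) {
  if (intercept_mode(gamma) == "constrained") {
    abort_mfc("loglik_original requires free intercepts", "mfcirt_mode_error")
  }
  n_b <- design$block_length; K <- design$n_blocks
  pt <- pair_table(n_b)
  C <- nrow(pt)
  if (length(binary) != K * C || length(gamma) != K * C) {
    abort_mfc("binary pattern and gamma must cover all comparisons",
              "mfcirt_shape_error")
  }
  gi <- rep((seq_len(K) - 1L) * n_b, each = C) + rep(pt[, "i"], K)
  gl <- rep((seq_len(K) - 1L) * n_b, each = C) + rep(pt[, "l"], K)
  tr <- design$statements$trait
  p <- pairwise_preference_probability(
    as.numeric(gamma), lambda[gi], lambda[gl],
    theta[tr[gi]], theta[tr[gl]], psi[gi], psi[gl])
  sum(stats::dbinom(binary, 1, p, log = TRUE))
}

#' Expand neighbouring-rank differences to the full pairwise difference vector
#'
#' Given a block's ranking and the `n_b - 1` positive utility differences
#' between consecutively ranked statements, reconstructs the full
#' `n_b (n_b - 1) / 2` vector of pairwise utility differences (lexicographic
#' statement-pair order). This is the embedding of the reduced representation
#' onto the support of the degenerate full law.
#'
#' @param ranks A permutation of `1..n_b` (one block).
#' @param diffs Positive vector of length `n_b - 1`: utility of rank m minus
#'   utility of rank m + 1.
#' @return Numeric vector of length `n_b (n_b - 1) / 2`.
#' @export
expand_latent_diffs <- function(ranks, diffs) {
  ranks <- check_permutation(ranks)
  n_b <- length(ranks)
  if (length(diffs) != n_b - 1L) {
    abort_mfc("diffs must have length n_b - 1", "mfcirt_shape_error")
  }
  ord <- order(ranks)
  t_util <- numeric(n_b)
  t_util[ord] <- rev(cumsum(rev(c(diffs, 0))))  # utility at rank m
  pt <- pair_table(n_b)
  t_util[pt[, "i"]] - t_util[pt[, "l"]]
}

block_slices <- function(design) {
  n_b <- design$block_length
  lapply(seq_len(design$n_blocks), function(k) (k - 1L) * n_b + seq_len(n_b))
}

#' Log-likelihood of the reduced (stochastic & logical dependencies) model
#'
#' Sum over blocks of the `(n_b - 1)`-dimensional multivariate normal
#' log-density of the positive neighbouring-rank utility differences under
#' the person-specific design matrix `A_j` and constrained intercepts.
#' Marginalizing the latent differences over the positive orthant yields the
#' probability of the observed ranking (see [ranking_probabilities()]).
#'
#' @param ranks Rank vector over all blocks (length `K * n_b`).
#' @param latent_diffs Strictly positive vector of length `K * (n_b - 1)`:
#'   neighbouring-rank utility differences, blocks concatenated.
#' @param design An [fc_design()].
#' @param mu,lambda,psi Per-statement parameters.
#' @param theta Trait score vector (one respondent).
#' @return Scalar log-likelihood.
#' @export
loglik_constrained_reduced <- function(ranks, latent_diffs, design,
                                       mu, lambda, theta, psi) {
  n_b <- design$block_length
  if (any(latent_diffs <= 0)) {
    abort_mfc("latent neighbouring differences must be strictly positive",
              "mfcirt_support_error")
  }
  Lam <- lambda_matrix(design, lambda)
  slices <- block_slices(design)
  ll <- 0
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    A <- neighboring_design_matrix(ranks[s])
    m <- as.numeric(A %*% (mu[s] + Lam[s, , drop = FALSE] %*% theta))
    S <- A %*% diag(psi[s], n_b) %*% t(A)
    d <- latent_diffs[(k - 1L) * (n_b - 1L) + seq_len(n_b - 1L)]
    ll <- ll + mvtnorm::dmvnorm(d, mean = m, sigma = S, log = TRUE)
  }
  ll
}

#' Log-likelihood of the full constrained (stochastic dependencies) model
#'
#' Sum over blocks of the degenerate multivariate normal log-density of the
#' full pairwise utility difference vector under the full design matrix and
#' constrained intercepts `gamma = -A mu`. At corresponding points (full
#' differences equal to the embedding of the reduced ones,
#' [expand_latent_diffs()]) this differs from
#' [loglik_constrained_reduced()] by a parameter-free constant per block.
#'
#' @param ranks Rank vector over all blocks.
#' @param latent_diffs_full Vector of length `K * n_b (n_b - 1) / 2`: full
#'   pairwise utility differences, sign-consistent with the observed ranking
#'   and lying on the singular support.
#' @inheritParams loglik_constrained_reduced
#' @param support_tol Passed to [singular_normal_logpdf()].
#' @return Scalar log-likelihood.
#' @export
loglik_constrained_full <- function(ranks, latent_diffs_full, design,
                                    mu, lambda, theta, psi,
                                    support_tol = 1e-8) {
  n_b <- design$block_length
  C <- n_b * (n_b - 1L) / 2L
  Lam <- lambda_matrix(design, lambda)
  slices <- block_slices(design)
  pt <- pair_table(n_b)
  ll <- 0
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    r <- ranks[s]
    d_full <- latent_diffs_full[(k - 1L) * C + seq_len(C)]
    y <- ranking_to_binary(r)
    if (any(sign(d_full) != ifelse(y == 1, 1, -1))) {
      abort_mfc("latent differences are sign-inconsistent with the observed ranking",
                "mfcirt_support_error")
    }
    A <- full_design_matrix(n_b, 1L)
    m <- as.numeric(A %*% (mu[s] + Lam[s, , drop = FALSE] %*% theta))
    S <- A %*% diag(psi[s], n_b) %*% t(A)
    ll <- ll + singular_normal_logpdf(d_full, m, S, support_tol = support_tol)
  }
  ll
}

#' Joint log-prior of the Thurstonian IRT parameters
#'
#' Weakly informative priors: truncated normal `N(1, 0.5)` on positively keyed
#' loadings and `N(-1, 0.5)` on negatively keyed ones (truncated at zero to
#' the keyed sign), `N(0, 2)` on utility means, positive-truncated `N(1, 0.3)`
#' on error variances, the LKJ distribution with shape `eta = 1` on the trait
#' correlation matrix (uniform over correlation matrices; contributes a
#' constant and is dropped), and standard normals on the whitened trait
#' scores. In `free` intercept mode, `gamma ~ N(0, 4)` (the distribution
#' implied by differences of two independent `N(0, 2)` means). All scale
#' parameters are variances; set `scale = "sd"` to read them as standard
#' deviations instead.
#'
#' @param params List with elements `mu`, `lambda`, `keying`, `psi`,
#'   `trait_corr`, `theta` (J x d matrix or vector) and, in free mode,
#'   `gamma`.
#' @param intercept_mode `"constrained"` or `"free"`.
#' @param scale Interpretation of the prior scale parameters.
#' @return Scalar log-prior; `-Inf` for parameters outside their support.
#' @export
log_prior <- function(params, intercept_mode = c("constrained", "free"),
                      scale = c("variance", "sd")) {
  intercept_mode <- match.arg(intercept_mode)
  scale <- match.arg(scale)
  sc <- function(v) if (scale == "variance") sqrt(v) else v
  lambda <- params$lambda; keying <- params$keying
  psi <- params$psi
  if (any(sign(lambda) * keying < 0) || any(psi <= 0)) return(-Inf)
  # truncated normals, properly normalized
  # mass of N(keying, 0.5) on the keyed side of zero (same constant both signs)
  lnorm <- ifelse(keying > 0,
                  stats::pnorm(0, 1, sc(0.5), lower.tail = FALSE, log.p = TRUE),
                  stats::pnorm(0, -1, sc(0.5), lower.tail = TRUE, log.p = TRUE))
  lp <- sum(stats::dnorm(lambda, mean = keying, sd = sc(0.5), log = TRUE) - lnorm)
  lp <- lp + sum(stats::dnorm(params$mu, 0, sc(2), log = TRUE))
  lp <- lp + sum(stats::dnorm(psi, 1, sc(0.3), log = TRUE) -
                   stats::pnorm(0, 1, sc(0.3), lower.tail = FALSE, log.p = TRUE))
  theta <- params$theta
  if (!is.null(theta)) {
    R <- params$trait_corr
    theta <- rbind(theta)
    Lch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(Lch)) return(-Inf)
    white <- theta %*% backsolve(Lch, diag(ncol(R)))  # theta %*% chol(R)^-1
    lp <- lp + sum(stats::dnorm(white, log = TRUE))
  }
  if (intercept_mode == "free") {
    if (is.null(params$gamma)) {
      abort_mfc("free intercept mode requires gamma in params", "mfcirt_mode_error")
    }
    lp <- lp + sum(stats::dnorm(params$gamma, 0, sc(4), log = TRUE))
  }
  lp
}

#' Exact ranking probabilities for one block (orthant oracle)
#'
#' The probability of each possible ranking of one block, for a respondent
#' with trait scores `theta`, computed as the orthant probability that all
#' neighbouring-rank utility differences are positive under the constrained
#' law. For `n_b <= 4` the integral has dimension <= 3 and is evaluated with
#' a deterministic algorithm, so results are reproducible. The probabilities
#' sum to one over all `n_b!` rankings.
#'
#' @param design An [fc_design()] whose first block is used, or parameters
#'   for a single block.
#' @param block Block index within the design.
#' @param params An `item_parameters` object (or data frame with `mu`,
#'   `lambda`, `psi`).
#' @param theta Trait score vector.
#' @return A tibble with one row per ranking: list-column `ranking` and
#'   column `prob`.
#' @export
ranking_probabilities <- function(design, params, theta, block = 1L) {
  items <- if (inherits(params, "item_parameters")) params$items else params
  n_b <- design$block_length
  s <- (block - 1L) * n_b + seq_len(n_b)
  mu <- items$mu[s]; lambda <- items$lambda[s]; psi <- items$psi[s]
  tr <- design$statements$trait[s]
  perms <- all_rankings(n_b)
  eta <- mu + lambda * theta[tr]
  probs <- apply(perms, 1L, function(r) {
    A <- neighboring_design_matrix(r)
    m <- as.numeric(A %*% eta)
    S <- A %*% diag(psi, n_b) %*% t(A)
    if (n_b == 2L) {
      stats::pnorm(m / sqrt(S[1, 1]))
    } else {
      as.numeric(mvtnorm::pmvnorm(
        lower = rep(0, n_b - 1L), upper = rep(Inf, n_b - 1L),
        mean = m, sigma = S, algorithm = mvtnorm::TVPACK()))
    }
  })
  tibble::tibble(ranking = lapply(seq_len(nrow(perms)), function(i) perms[i, ]),
                 prob = probs)
}
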