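#' Default Big-5-like trait correlation matrix
#'
#' A documented stand-in for the moderate correlations typically reported
#' among the Big Five domains (order: openness, conscientiousness,
#' extraversion, agreeableness, neuroticism). All magnitudes are <= 0.45 and
#' the matrix is checked for positive definiteness. Studies should override
#' it with their own estimates via [sim_config()].
#'
#' @return A 5 x 5 correlation matrix.
#' @export
big5_trait_corr <- function() {
  R <- matrix(c(
    1.00,  0.10,  0.25,  0.15, -0.10,
    0.10,  1.00,  0.15,  0.30, -0.25,
    0.25,  0.15,  1.00,  0.20, -0.30,
    0.15,  0.30,  0.20,  1.00, -0.20,
   -0.10, -0.25, -0.30, -0.20,  1.00), 5, 5, byrow = TRUE)
  dimnames(R) <- list(c("O", "C", "E", "A", "N"), c("O", "C", "E", "A", "N"))
  stopifnot(all(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 0))
  R
}

#' Configuration of a synthetic MFC study
#'
#' Collects the generative settings used by the simulator. Defaults follow
#' the standard simulation conditions for Thurstonian IRT studies: utility
#' means uniform on \[-1, 1\], loading magnitudes uniform on \[0.65, 0.95\]
#' with error variances `psi = 1 - lambda^2` (unit-variance utilities),
#' correlated Big-5-like traits, and two thirds of blocks containing both
#' keying directions.
#'
#' @param n_b Block length (2, 3 or 4 in practice).
#' @param K Number of blocks.
#' @param J Sample size (number of respondents).
#' @param d Number of traits; must satisfy `n_b <= d` so that statements in a
#'   block measure distinct traits.
#' @param mu_range Range of the uniform distribution for utility means.
#' @param lambda_range Range of the uniform distribution for loading
#'   magnitudes; must lie inside (0, 1) because `psi = 1 - lambda^2`.
#' @param mixed_keying_fraction Fraction of blocks containing both positively
#'   and negatively keyed statements.
#' @param trait_corr d x d trait correlation matrix; defaults to
#'   [big5_trait_corr()] when `d = 5`, the identity otherwise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_b = 3, K = 10, J = 50, d = 5,
                       mu_range = c(-1, 1),
                       lambda_range = c(0.65, 0.95),
                       mixed_keying_fraction = 2 / 3,
                       trait_corr = NULL) {
  if (n_b < 2 || K < 1 || J < 1 || d < 1 || n_b > d) {
    abort_mfc("need n_b >= 2, K >= 1, J >= 1 and n_b <= d (distinct traits per block)",
              "mfcirt_invalid_config")
  }
  if (length(mu_range) != 2 || diff(mu_range) < 0 ||
      length(lambda_range) != 2 || diff(lambda_range) < 0) {
    abort_mfc("ranges must be valid intervals", "mfcirt_invalid_config")
  }
  if (lambda_range[1] <= 0 || lambda_range[2] >= 1) {
    abort_mfc("lambda_range must lie inside (0, 1): psi = 1 - lambda^2 must stay positive",
              "mfcirt_invalid_config")
  }
  if (mixed_keying_fraction < 0 || mixed_keying_fraction > 1) {
    abort_mfc("mixed_keying_fraction must be in [0, 1]", "mfcirt_invalid_config")
  }
  if (is.null(trait_corr)) {
    trait_corr <- if (d == 5) big5_trait_corr() else diag(d)
  }
  check_corr_matrix(trait_corr, d)
  structure(
    list(n_b = as.integer(n_b), K = as.integer(K), J = as.integer(J),
         d = as.integer(d), mu_range = mu_range, lambda_range = lambda_range,
         mixed_keying_fraction = mixed_keying_fraction,
         trait_corr = unname(trait_corr)),
    class = "sim_config")
}

check_corr_matrix <- function(R, d) {
  if (!is.matrix(R) || nrow(R) != d || ncol(R) != d ||
      !isTRUE(all.equal(unname(R), unname(t(R)))) ||
      !isTRUE(all.equal(unname(diag(R)), rep(1, d)))) {
    abort_mfc("trait_corr must be a symmetric correlation matrix with unit diagonal",
              "mfcirt_invalid_config")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    abort_mfc("trait_corr must be positive definite", "mfcirt_not_positive_definite")
  }
  invisible(R)
}

#' Draw generative item parameters for a synthetic MFC questionnaire
#'
#' Draws utility means `mu ~ U(mu_range)` and loading magnitudes
#' `|lambda| ~ U(lambda_range)`; the loading sign equals the statement's
#' keying and error variances follow `psi = 1 - lambda^2`. Trait assignment
#' cycles through the traits across blocks so statements within a block
#' measure distinct traits; a seeded draw selects which blocks are mixed-keyed
#' and which of their statements are negatively keyed.
#'
#' @param config A [sim_config()].
#' @param rng_seed Integer seed; the draw is reproducible given the seed.
#' @return A list of class `item_parameters` with elements `design`
#'   (an [fc_design()]), `items` (tibble with `statement`, `block`, `trait`,
#'   `keying`, `mu`, `lambda`, `psi`) and `trait_corr`.
#' @export
draw_item_parameters <- function(config, rng_seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n_b <- config$n_b; K <- config$K; d <- config$d
  n <- n_b * K
  set.seed(rng_seed %% .Machine$integer.max)
  # traits: cycle so each block holds n_b distinct traits
  traits <- ((seq_len(n) - 1L) %% d) + 1L
  # keying: a seeded subset of blocks is mixed (both directions present)
  keying <- rep(1, n)
  n_mixed <- round(config$mixed_keying_fraction * K)
  mixed_blocks <- if (n_mixed > 0) sort(sample.int(K, n_mixed)) else integer(0)
  for (k in mixed_blocks) {
    n_neg <- sample.int(n_b - 1L, 1L)
    neg_pos <- sample.int(n_b, n_neg)
    keying[(k - 1L) * n_b + neg_pos] <- -1
  }
  design <- fc_design(K, n_b, traits, keying, n_traits = d)
  mu <- stats::runif(n, config$mu_range[1], config$mu_range[2])
  lam_abs <- stats::runif(n, config$lambda_range[1], config$lambda_range[2])
  lambda <- keying * lam_abs
  psi <- 1 - lam_abs^2
  items <- dplyr::mutate(design$statements, mu = mu, lambda = lambda, psi = psi)
  structure(list(design = design, items = items,
                 trait_corr = config$trait_corr),
            class = "item_parameters")
}

#' Draw latent trait scores
#'
#' Rows are i.i.d. multivariate normal with zero mean and covariance equal to
#' the trait correlation matrix (standard-normal marginals).
#'
#' @param J Number of respondents.
#' @param trait_corr Positive-definite correlation matrix.
#' @param rng_seed Integer seed.
#' @return A `J x d` numeric matrix.
#' @export
draw_trait_scores <- function(J, trait_corr, rng_seed = 1L) {
  d <- nrow(trait_corr)
  check_corr_matrix(trait_corr, d)
  set.seed(rng_seed %% .Machine$integer.max)
  theta <- mvtnorm::rmvnorm(J, mean = rep(0, d), sigma = trait_corr)
  colnames(theta) <- paste0("trait", seq_len(d))
  theta
}

#' Simulate forced-choice ranking responses
#'
#' For each respondent and block, draws utilities
#' `t = mu + lambda * theta[trait] + eps` with `eps ~ N(0, psi)` independent
#' across statements, and ranks the statements within the block by descending
#' utility (rank 1 = highest utility). Rankings are transitive by
#' construction. Exactly equal utilities (a probability-zero event) raise an
#' error rather than being silently reordered.
#'
#' @param design An [fc_design()].
#' @param params An `item_parameters` object (or a data frame with columns
#'   `mu`, `lambda`, `psi` per statement).
#' @param theta `J x d` matrix of trait scores.
#' @param rng_seed Integer seed.
#' @return A tibble of class `fc_rankings` in wide format: `person_id` plus
#'   one column `b<k>_s<i>` per statement holding its within-block rank.
#' @export
simulate_rankings <- function(design, params, theta, rng_seed = 1L) {
  items <- if (inherits(params, "item_parameters")) params$items else params
  n_b <- design$block_length; K <- design$n_blocks
  n <- n_b * K
  J <- nrow(theta)
  if (nrow(items) != n || ncol(theta) < design$n_traits) {
    abort_mfc("dimension mismatch between design, parameters and trait scores",
              "mfcirt_shape_error")
  }
  set.seed(rng_seed %% .Machine$integer.max)
  mu <- items$mu; lambda <- items$lambda; psi <- items$psi
  tr <- design$statements$trait
  util <- matrix(rep(mu, each = J), J, n) +
    theta[, tr, drop = FALSE] * matrix(rep(lambda, each = J), J, n) +
    matrix(stats::rnorm(J * n, sd = rep(sqrt(psi), each = J)), J, n)
  ranks <- matrix(0L, J, n)
  for (k in seq_len(K)) {
    cols <- (k - 1L) * n_b + seq_len(n_b)
    u <- util[, cols, drop = FALSE]
    if (any(apply(u, 1L, anyDuplicated) > 0)) {
      abort_mfc("tied simulated utilities encountered; refusing to break ties",
                "mfcirt_tied_utilities")
    }
    # rank 1 = highest utility
    ranks[, cols] <- t(apply(-u, 1L, rank))
  }
  as_fc_rankings(ranks, design)
}

as_fc_rankings <- function(ranks, design, person_ids = seq_len(nrow(ranks))) {
  colnames(ranks) <- ranking_column_names(design)
  out <- tibble::as_tibble(as.data.frame(ranks))
  out <- dplyr::mutate(out, person_id = person_ids, .before = 1L)
  class(out) <- c("fc_rankings", class(out))
  out
}

ranking_column_names <- function(design) {
  paste0("b", rep(seq_len(design$n_blocks), each = design$block_length),
         "_s", rep(seq_len(design$block_length), times = design$n_blocks))
}

# strip person_id, return J x (K * n_b) integer matrix, validating permutations
rankings_matrix <- function(rankings, design) {
  cols <- ranking_column_names(design)
  if (!all(cols %in% names(rankings))) {
    abort_mfc("rankings do not match the design's block layout",
              "mfcirt_schema_error")
  }
  m <- as.matrix(rankings[, cols])
  storage.mode(m) <- "integer"
  n_b <- design$block_length
  for (k in seq_len(design$n_blocks)) {
    blk <- m[, (k - 1L) * n_b + seq_len(n_b), drop = FALSE]
    bad <- which(apply(blk, 1L, function(r) {
      anyNA(r) || !setequal(r, seq_len(n_b))
    }))
    if (length(bad)) {
      abort_mfc(sprintf(
        "invalid ranking (tie, gap or missing value) for person %s, block %d",
        paste(utils::head(bad, 3), collapse = ","), k),
        "mfcirt_invalid_ranking")
    }
  }
  m
}

#' Simulate a complete synthetic MFC study
#'
#' Convenience wrapper running [draw_item_parameters()],
#' [draw_trait_scores()] and [simulate_rankings()] on derived sub-seeds of
#' `seed`, so that parameter, person and response streams are reproducible
#' independently.
#'
#' @param config A [sim_config()].
#' @param seed Integer base seed.
#' @return A list with `design`, `params` (`item_parameters`), `theta` and
#'   `rankings`.
#' @export
simulate_mfc <- function(config, seed = 1L) {
  base <- (abs(seed) %% 2147480000L)
  params <- draw_item_parameters(config, rng_seed = base)
  theta <- draw_trait_scores(config$J, params$trait_corr, rng_seed = base + 1L)
  rankings <- simulate_rankings(params$design, params, theta,
                                rng_seed = base + 2L)
  list(design = params$design, params = params, theta = theta,
       rankings = rankings)
}
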