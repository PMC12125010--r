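#' Fit a Thurstonian IRT model to forced-choice ranking data
#'
#' Draws from the posterior of the Thurstonian IRT model by Markov chain
#' Monte Carlo, under one of three implementations:
#'
#' * `"original"`: all pairwise comparisons are modelled as independent
#'   probit outcomes with free intercepts. Intransitive binary patterns have
#'   positive probability under this likelihood.
#' * `"stochastic"`: intercepts are constrained to `gamma = -A mu`, which
#'   respects the stochastic dependencies among comparisons; the likelihood
#'   is the degenerate multivariate normal of the full pairwise utility
#'   difference vector.
#' * `"stochastic_logical"`: as `"stochastic"`, but only the `n_b - 1`
#'   neighbouring-rank comparisons enter, through the person-specific design
#'   matrix; the likelihood is a non-degenerate multivariate normal of
#'   the positive neighbouring utility differences.
#'
#' The two constrained implementations have provably proportional likelihoods
#' (they differ by a parameter-free constant per block), hence identical
#' posteriors; they share the same transition kernel here but run on
#' independent random streams and record different pointwise log-likelihoods.
#' Sampling uses data augmentation with truncated-normal utility draws
#' (constrained implementations) or truncated-normal comparison draws with
#' free intercepts (original implementation), conjugate updates for means,
#' loadings and trait scores, and adaptive Metropolis steps for error
#' variances and the trait correlation matrix. Augmented latent quantities
#' are discarded from the output.
#'
#' Priors (scale parameters are variances): loadings truncated
#' `N(keying, 0.5)` on the keyed side of zero; utility means `N(0, 2)`;
#' error variances positive-truncated `N(1, 0.3)`; trait correlations
#' LKJ(1) (uniform over correlation matrices); trait scores `N(0, Sigma)`;
#' free intercepts `N(0, 4)`.
#'
#' @param rankings An `fc_rankings` tibble (or any data frame with a
#'   `person_id` column and `b<k>_s<i>` rank columns matching the design).
#' @param design An [fc_design()].
#' @param impl Implementation tag.
#' @param chains Number of MCMC chains (>= 2 for split diagnostics).
#' @param iter Iterations per chain, including warm-up.
#' @param warmup Warm-up (adaptation) iterations discarded from the output;
#'   defaults to half of `iter`.
#' @param seed Integer seed; each chain runs on a derived sub-seed, and the
#'   three implementations use distinct sub-streams.
#' @return An object of class `mfc_fit` with elements `draws` (array,
#'   kept iterations x chains x named parameters), `pointwise_loglik`
#'   (array, kept iterations x chains x person-block observations, in
#'   person-major order), `impl`, `config`, `design` and `time` (seconds,
#'   informational only).
#' @examples
#' \donttest{
#' sim <- simulate_mfc(sim_config(n_b = 3, K = 4, J = 20, d = 3), seed = 1)
#' fit <- fit_mfc(sim$rankings, sim$design, impl = "stochastic_logical",
#'                chains = 2, iter = 400, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_mfc <- function(rankings, design,
                    impl = c("stochastic_logical", "stochastic", "original"),
                    chains = 4L, iter = 2000L, warmup = floor(iter / 2),
                    seed = 1L) {
  impl <- match.arg(impl)
  if (chains < 2L) abort_mfc("at least 2 chains are required", "mfcirt_single_chain")
  if (iter < 100L) abort_mfc("iter must be >= 100", "mfcirt_invalid_config")
  if (warmup < 1L || warmup >= iter) {
    abort_mfc("warmup must be in [1, iter)", "mfcirt_invalid_config")
  }
  ranks <- rankings_matrix(rankings, design)
  t0 <- proc.time()[["elapsed"]]
  impl_offset <- c(original = 0L, stochastic = 7L, stochastic_logical = 13L)[[impl]]
  base_seed <- abs(seed) %% 2147000000L
  chain_out <- lapply(seq_len(chains), function(ch) {
    chain_seed <- base_seed + 101L * ch + impl_offset
    if (impl == "original") {
      run_chain_original(ranks, design, iter, warmup, chain_seed)
    } else {
      run_chain_constrained(ranks, design, iter, warmup, chain_seed,
                            full_ll = (impl == "stochastic"))
    }
  })
  kept <- iter - warmup
  par_names <- colnames(chain_out[[1]]$draws)
  draws <- array(NA_real_, dim = c(kept, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  n_obs <- ncol(chain_out[[1]]$pointwise)
  pw <- array(NA_real_, dim = c(kept, chains, n_obs))
  for (ch in seq_len(chains)) {
    draws[, ch, ] <- chain_out[[ch]]$draws
    pw[, ch, ] <- chain_out[[ch]]$pointwise
  }
  structure(
    list(draws = draws,
         pointwise_loglik = pw,
         impl = impl,
         config = list(impl = impl, chains = chains, iter = iter,
                       warmup = warmup, seed = seed),
         design = design,
         time = proc.time()[["elapsed"]] - t0),
    class = "mfc_fit")
}

#' @export
print.mfc_fit <- function(x, ...) {
  cat(sprintf("<mfc_fit> impl = %s, %d chains x %d kept iterations, %d parameters\n",
              x$impl, dim(x$draws)[2], dim(x$draws)[1], dim(x$draws)[3]))
  invisible(x)
}

# ---- shared pieces ---------------------------------------------------------

# parameter naming, shared across implementations
par_labels <- function(design, J, include_mu) {
  n <- nrow(design$statements)
  d <- design$n_traits
  pt <- pair_table(design$block_length)
  K <- design$n_blocks
  gi <- rep((seq_len(K) - 1L) * design$block_length, each = nrow(pt)) + rep(pt[, "i"], K)
  gl <- rep((seq_len(K) - 1L) * design$block_length, each = nrow(pt)) + rep(pt[, "l"], K)
  c(if (include_mu) paste0("mu[", seq_len(n), "]"),
    paste0("lambda[", seq_len(n), "]"),
    paste0("psi[", seq_len(n), "]"),
    paste0("Sigma[", rep(seq_len(d - 1), times = (d - 1):1), ",",
           unlist(lapply(seq_len(d - 1), function(a) (a + 1):d)), "]"),
    paste0("theta[", rep(seq_len(J), d), ",", rep(seq_len(d), each = J), "]"),
    paste0("gamma[", gi, ",", gl, "]"))
}

sigma_pairs <- function(d) {
  cbind(a = rep(seq_len(d - 1), times = (d - 1):1),
        b = unlist(lapply(seq_len(d - 1), function(a) (a + 1):d)))
}

# Metropolis update of the trait correlation matrix, element-wise random walk
# under the LKJ(1) prior (uniform over correlation matrices); several sweeps
# per call since each costs only a d x d Cholesky
update_sigma <- function(Sigma, theta, steps, adapt, it, n_sweeps = 3L) {
  d <- ncol(Sigma)
  J <- nrow(theta)
  S_th <- crossprod(theta)
  pairs <- sigma_pairs(d)
  ch <- chol(Sigma)
  ll_cur <- -J * sum(log(diag(ch))) - 0.5 * sum(chol2inv(ch) * S_th)
  for (sweep_i in seq_len(n_sweeps)) for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    prop <- Sigma
    val <- Sigma[a, b] + steps[p] * stats::rnorm(1)
    acc <- FALSE
    if (abs(val) < 1) {
      prop[a, b] <- prop[b, a] <- val
      chp <- tryCatch(chol(prop), error = function(e) NULL)
      if (!is.null(chp)) {
        ll_prop <- -J * sum(log(diag(chp))) - 0.5 * sum(chol2inv(chp) * S_th)
        if (log(stats::runif(1)) < ll_prop - ll_cur) {
          Sigma <- prop
          ll_cur <- ll_prop
          acc <- TRUE
        }
      }
    }
    if (adapt) {
      steps[p] <- steps[p] * exp((as.numeric(acc) - 0.44) / max(1, it)^0.6)
    }
  }
  list(Sigma = Sigma, steps = steps)
}

# log of the positive-truncated N(1, 0.3) prior density on psi, unnormalized
psi_log_prior <- function(psi) -(psi - 1)^2 / (2 * 0.3)

# determinant of M'M for the embedding of the n_b - 1 neighbouring differences
# into the n_b (n_b - 1)/2 pairwise differences (rank space); parameter-free
embedding_det <- function(n_b) {
  pt <- pair_table(n_b)
  M <- matrix(0, nrow(pt), n_b - 1L)
  for (p in seq_len(nrow(pt))) {
    M[p, pt[p, "i"]:(pt[p, "l"] - 1L)] <- 1
  }
  det(crossprod(M))
}

# ---- constrained implementations (utility augmentation) --------------------

run_chain_constrained <- function(ranks, design, iter, warmup, chain_seed,
                                  full_ll = FALSE) {
  set.seed(chain_seed)
  n_b <- design$block_length; K <- design$n_blocks
  n <- n_b * K; J <- nrow(ranks); d <- design$n_traits
  tr <- design$statements$trait
  keying <- design$statements$keying
  kept <- iter - warmup

  # stmt_idx[[m]]: J x K matrix of global statement index holding rank m;
  # flat[[m]] indexes directly into a J x n matrix
  stmt_idx <- vector("list", n_b)
  for (m in seq_len(n_b)) stmt_idx[[m]] <- matrix(0L, J, K)
  for (k in seq_len(K)) {
    cols <- (k - 1L) * n_b + seq_len(n_b)
    blk <- ranks[, cols, drop = FALSE]
    for (m in seq_len(n_b)) {
      stmt_idx[[m]][, k] <- cols[apply(blk, 1L, function(r) which(r == m))]
    }
  }
  flat <- lapply(stmt_idx, function(s) (as.vector(s) - 1L) * J + rep(seq_len(J), K))

  # person-specific rank neighbours of each statement (fixed by the data):
  # nbr_above[j, i] = statement ranked directly above i by person j, NA at top
  nbr_above <- matrix(NA_integer_, J, n)
  nbr_below <- matrix(NA_integer_, J, n)
  for (k in seq_len(K)) {
    for (m in seq_len(n_b)) {
      cur <- stmt_idx[[m]][, k]
      if (m > 1L) nbr_above[cbind(seq_len(J), cur)] <- stmt_idx[[m - 1L]][, k]
      if (m < n_b) nbr_below[cbind(seq_len(J), cur)] <- stmt_idx[[m + 1L]][, k]
    }
  }

  A_full <- full_design_matrix(n_b, K)
  log_embed_const <- -0.5 * log(embedding_det(n_b)) # full - reduced, per block

  # initial state
  mu <- stats::rnorm(n, 0, 0.3)
  lambda <- keying * stats::runif(n, 0.5, 1.1)
  psi <- stats::runif(n, 0.3, 0.8)
  Sigma <- diag(d)
  theta <- matrix(stats::rnorm(J * d, 0, 0.5), J, d)
  t_mat <- matrix(0, J, n)
  for (m in seq_len(n_b)) t_mat[flat[[m]]] <- n_b - m + stats::rnorm(J * K, 0, 0.1)

  psi_steps <- rep(0.4, n)
  sig_steps <- rep(0.1, d * (d - 1) / 2)
  scale_steps <- rep(0.2, K)

  par_names <- par_labels(design, J, include_mu = TRUE)
  draws <- matrix(NA_real_, kept, length(par_names),
                  dimnames = list(NULL, par_names))
  pointwise <- matrix(NA_real_, kept, J * K)

  # several full Gibbs scans per stored iteration: the augmented utilities
  # dominate the autocorrelation, and extra scans are cheap relative to the
  # per-iteration bookkeeping
  n_scans <- 3L
  for (it in seq_len(iter)) {
    adapt <- it <= warmup
    for (scan in seq_len(n_scans)) {
    lam_rep <- matrix(rep(lambda, each = J), J, n)
    mu_rep <- matrix(rep(mu, each = J), J, n)
    X <- theta[, tr, drop = FALSE]
    cond_mean <- mu_rep + X * lam_rep
    sd_stmt <- sqrt(psi)

    # 1. utilities, rank position by rank position (truncated normals)
    for (m in seq_len(n_b)) {
      hi <- if (m == 1L) rep(Inf, J * K) else t_mat[flat[[m - 1L]]]
      lo <- if (m == n_b) rep(-Inf, J * K) else t_mat[flat[[m + 1L]]]
      idx <- flat[[m]]
      t_mat[idx] <- truncnorm::rtruncnorm(
        1, a = lo, b = hi, mean = cond_mean[idx],
        sd = sd_stmt[as.vector(stmt_idx[[m]])])
    }

    # 2. trait scores (conjugate multivariate normal)
    Lam <- matrix(0, n, d); Lam[cbind(seq_len(n), tr)] <- lambda
    Lp <- Lam / psi
    P <- chol2inv(chol(Sigma)) + crossprod(Lam, Lp)
    V <- chol2inv(chol(P))
    M <- (t_mat - mu_rep) %*% Lp %*% V
    theta <- M + matrix(stats::rnorm(J * d), J, d) %*% chol(V)
    X <- theta[, tr, drop = FALSE]

    # 3. utility means (conjugate, prior N(0, 2))
    r_mu <- t_mat - X * lam_rep
    prec <- J / psi + 1 / 2
    mu <- stats::rnorm(n, (colSums(r_mu) / psi) / prec, sqrt(1 / prec))

    # 3b. block-level location sweep: jointly shifting a block's utilities and
    # its means leaves the likelihood invariant (only differences are
    # identified), so the conditional of the shift comes from the N(0, 2)
    # prior on mu; sampling it directly removes the random walk along this
    # flat direction
    mu_blk <- matrix(mu, n_b, K)
    delta <- stats::rnorm(K, -colMeans(mu_blk), sqrt(2 / n_b))
    delta_full <- rep(delta, each = n_b)
    mu <- mu + delta_full
    t_mat <- t_mat + matrix(rep(delta_full, each = J), J, n)
    mu_rep <- matrix(rep(mu, each = J), J, n)

    # 3c. ancillary interweaving for mu: holding t - mu fixed, the conditional
    # of mu_i is its N(0, 2) prior truncated to the interval that keeps every
    # person's within-block ordering; alternating the two parameterizations
    # breaks the slow coupling between mu and the augmented utilities
    tt <- t_mat - mu_rep
    u <- t_mat
    for (i in seq_len(n)) {
      bi <- nbr_below[, i]; ai <- nbr_above[, i]
      has_b <- !is.na(bi); has_a <- !is.na(ai)
      lo <- if (any(has_b)) {
        max(u[cbind(which(has_b), bi[has_b])] - tt[has_b, i])
      } else -Inf
      hi <- if (any(has_a)) {
        min(u[cbind(which(has_a), ai[has_a])] - tt[has_a, i])
      } else Inf
      mu[i] <- truncnorm::rtruncnorm(1, a = lo, b = hi, mean = 0, sd = sqrt(2))
      u[, i] <- tt[, i] + mu[i]
    }
    t_mat <- u
    mu_rep <- matrix(rep(mu, each = J), J, n)

    # 4. loadings (conjugate truncated normal, prior N(keying, 0.5) keyed side)
    r_lam <- t_mat - mu_rep
    Sxx <- colSums(X^2); Sxy <- colSums(X * r_lam)
    prec <- Sxx / psi + 2
    mn <- (Sxy / psi + 2 * keying) / prec
    lambda <- truncnorm::rtruncnorm(
      1, a = ifelse(keying > 0, 0, -Inf), b = ifelse(keying > 0, Inf, 0),
      mean = mn, sd = sqrt(1 / prec))
    lam_rep <- matrix(rep(lambda, each = J), J, n)

    # 5. error variances (random-walk Metropolis on log psi; the residual sum
    # is free of psi, so extra sweeps cost almost nothing)
    e2 <- colSums((t_mat - mu_rep - X * lam_rep)^2)
    for (sweep_i in 1:2) {
      lpsi <- log(psi)
      lpsi_prop <- lpsi + psi_steps * stats::rnorm(n)
      psi_prop <- exp(lpsi_prop)
      logr <- (-J / 2 * lpsi_prop - e2 / (2 * psi_prop) + psi_log_prior(psi_prop)) -
        (-J / 2 * lpsi - e2 / (2 * psi) + psi_log_prior(psi)) +
        (lpsi_prop - lpsi)
      acc <- log(stats::runif(n)) < logr
      psi[acc] <- psi_prop[acc]
      if (adapt) psi_steps <- psi_steps * exp((as.numeric(acc) - 0.44) / max(1, it)^0.6)
    }

    # 5b. block-scale sweep: multiplying a block's utilities, means, loadings
    # and error SDs by a common c > 0 leaves the ranking likelihood invariant
    # (orderings and standardized differences are unchanged), so the scale is
    # identified through the priors alone; a Metropolis move along this orbit
    # (multiplicative proposal, Jacobian c^(4 n_b)) removes the slow random
    # walk along it
    eps <- scale_steps * stats::rnorm(K)
    cmul <- exp(eps)
    mu_blk <- matrix(mu, n_b, K); lam_blk <- matrix(lambda, n_b, K)
    key_blk <- matrix(keying, n_b, K); psi_blk <- matrix(psi, n_b, K)
    crep <- matrix(rep(cmul, each = n_b), n_b, K)
    logr <- 4 * n_b * eps +
      (colSums(mu_blk^2) - colSums((crep * mu_blk)^2)) / 4 +
      (colSums((lam_blk - key_blk)^2) - colSums((crep * lam_blk - key_blk)^2)) +
      (colSums((psi_blk - 1)^2) - colSums((crep^2 * psi_blk - 1)^2)) / 0.6
    acc_s <- log(stats::runif(K)) < logr
    sc_full <- rep(ifelse(acc_s, cmul, 1), each = n_b)
    mu <- mu * sc_full
    lambda <- lambda * sc_full
    psi <- psi * sc_full^2
    t_mat <- t_mat * matrix(rep(sc_full, each = J), J, n)
    if (adapt) {
      scale_steps <- scale_steps * exp((as.numeric(acc_s) - 0.44) / max(1, it)^0.6)
    }

    # 6. trait correlation matrix
    up <- update_sigma(Sigma, theta, sig_steps, adapt, it)
    Sigma <- up$Sigma; sig_steps <- up$steps
    }  # end scan

    if (it > warmup) {
      row <- it - warmup
      sp <- sigma_pairs(d)
      gamma <- as.numeric(-A_full %*% mu)
      draws[row, ] <- c(mu, lambda, psi, Sigma[sp], as.vector(theta), gamma)
      ll <- pointwise_ll_constrained(t_mat, mu, lambda, psi, theta, tr,
                                     stmt_idx, n_b, K, J)
      if (full_ll) ll <- ll + log_embed_const
      pointwise[row, ] <- as.vector(ll)  # person-major within block, J x K
    }
  }
  list(draws = draws, pointwise = pointwise)
}

# log-density of the neighbouring-rank utility differences per person-block,
# evaluated at the current augmented utilities; tridiagonal covariance
# A_j Psi A_j' handled in closed form for n_b in {2, 3, 4}
pointwise_ll_constrained <- function(t_mat, mu, lambda, psi, theta, tr,
                                     stmt_idx, n_b, K, J) {
  cm <- matrix(rep(mu, each = J), J, length(mu)) +
    theta[, tr, drop = FALSE] * matrix(rep(lambda, each = J), J, length(mu))
  s <- lapply(stmt_idx, function(ix) matrix(psi[ix], J, K))
  tu <- lapply(seq_len(n_b), function(m) {
    matrix(t_mat[(as.vector(stmt_idx[[m]]) - 1L) * J + rep(seq_len(J), K)], J, K)
  })
  mm <- lapply(seq_len(n_b), function(m) {
    matrix(cm[(as.vector(stmt_idx[[m]]) - 1L) * J + rep(seq_len(J), K)], J, K)
  })
  if (n_b == 2L) {
    v <- s[[1]] + s[[2]]
    x <- (tu[[1]] - tu[[2]]) - (mm[[1]] - mm[[2]])
    return(-0.5 * log(2 * pi) - 0.5 * log(v) - 0.5 * x^2 / v)
  }
  if (n_b == 3L) {
    a <- s[[1]] + s[[2]]; b <- s[[2]] + s[[3]]; cc <- -s[[2]]
    x <- (tu[[1]] - tu[[2]]) - (mm[[1]] - mm[[2]])
    y <- (tu[[2]] - tu[[3]]) - (mm[[2]] - mm[[3]])
    dt <- a * b - cc^2
    return(-log(2 * pi) - 0.5 * log(dt) -
             0.5 * (b * x^2 - 2 * cc * x * y + a * y^2) / dt)
  }
  if (n_b == 4L) {
    a <- s[[1]] + s[[2]]; b <- s[[2]] + s[[3]]; cc <- s[[3]] + s[[4]]
    e <- -s[[2]]; f <- -s[[3]]
    x <- (tu[[1]] - tu[[2]]) - (mm[[1]] - mm[[2]])
    y <- (tu[[2]] - tu[[3]]) - (mm[[2]] - mm[[3]])
    z <- (tu[[3]] - tu[[4]]) - (mm[[3]] - mm[[4]])
    dt <- a * b * cc - a * f^2 - cc * e^2
    q <- ((b * cc - f^2) * x^2 + a * cc * y^2 + (a * b - e^2) * z^2 +
            2 * (-e * cc) * x * y + 2 * (e * f) * x * z + 2 * (-a * f) * y * z) / dt
    return(-1.5 * log(2 * pi) - 0.5 * log(dt) - 0.5 * q)
  }
  # general block length: per-block multivariate normal
  out <- matrix(0, J, K)
  for (k in seq_len(K)) {
    for (j in seq_len(J)) {
      dif <- vapply(seq_len(n_b - 1L),
                    function(m) tu[[m]][j, k] - tu[[m + 1L]][j, k], numeric(1))
      mn <- vapply(seq_len(n_b - 1L),
                   function(m) mm[[m]][j, k] - mm[[m + 1L]][j, k], numeric(1))
      ps <- vapply(seq_len(n_b), function(m) s[[m]][j, k], numeric(1))
      S <- diag(ps[-n_b] + ps[-1L])
      for (m in seq_len(n_b - 2L)) S[m, m + 1L] <- S[m + 1L, m] <- -ps[m + 1L]
      out[j, k] <- mvtnorm::dmvnorm(dif, mean = mn, sigma = S, log = TRUE)
    }
  }
  out
}

# ---- original implementation (comparison augmentation, free intercepts) ----

run_chain_original <- function(ranks, design, iter, warmup, chain_seed) {
  set.seed(chain_seed)
  n_b <- design$block_length; K <- design$n_blocks
  n <- n_b * K; J <- nrow(ranks); d <- design$n_traits
  tr <- design$statements$trait
  keying <- design$statements$keying
  kept <- iter - warmup
  pt <- pair_table(n_b)
  C <- nrow(pt)
  P <- K * C
  gi <- rep((seq_len(K) - 1L) * n_b, each = C) + rep(pt[, "i"], K)
  gl <- rep((seq_len(K) - 1L) * n_b, each = C) + rep(pt[, "l"], K)
  blk <- rep(seq_len(K), each = C)
  # observed binary outcomes (J x P)
  y <- matrix(0L, J, P)
  for (p in seq_len(P)) y[, p] <- as.integer(ranks[, gi[p]] < ranks[, gl[p]])
  blk_ind <- matrix(0, P, K); blk_ind[cbind(seq_len(P), blk)] <- 1

  gamma <- stats::rnorm(P, 0, 0.5)
  lambda <- keying * stats::runif(n, 0.5, 1.1)
  psi <- stats::runif(n, 0.3, 0.8)
  Sigma <- diag(d)
  theta <- matrix(stats::rnorm(J * d, 0, 0.5), J, d)
  z <- ifelse(y == 1, 0.5, -0.5) + matrix(stats::rnorm(J * P, 0, 0.1), J, P)

  psi_steps <- rep(0.4, n)
  sig_steps <- rep(0.1, d * (d - 1) / 2)
  pairs_of <- lapply(seq_len(n), function(i) which(gi == i | gl == i))

  par_names <- par_labels(design, J, include_mu = FALSE)
  draws <- matrix(NA_real_, kept, length(par_names),
                  dimnames = list(NULL, par_names))
  pointwise <- matrix(NA_real_, kept, J * K)

  lo <- ifelse(y == 1, 0, -Inf)
  hi <- ifelse(y == 1, Inf, 0)

  n_scans <- 2L
  for (it in seq_len(iter)) {
    adapt <- it <= warmup
    for (scan in seq_len(n_scans)) {
    v <- psi[gi] + psi[gl]
    sdv <- sqrt(v)
    u_part <- theta[, tr[gi], drop = FALSE] * matrix(rep(lambda[gi], each = J), J, P) -
      theta[, tr[gl], drop = FALSE] * matrix(rep(lambda[gl], each = J), J, P)

    # 1. latent comparison variables (truncated normals)
    mz <- sweep(u_part, 2L, gamma)
    z <- matrix(truncnorm::rtruncnorm(
      1, a = as.vector(lo), b = as.vector(hi),
      mean = as.vector(mz), sd = rep(sdv, each = J)), J, P)

    # 2. free intercepts (conjugate, prior N(0, 4))
    prec <- J / v + 0.25
    mn <- (colSums(u_part - z) / v) / prec
    gamma <- stats::rnorm(P, mn, sqrt(1 / prec))

    # 3. trait scores (conjugate)
    G <- matrix(0, P, d)
    for (p in seq_len(P)) {
      G[p, tr[gi[p]]] <- G[p, tr[gi[p]]] + lambda[gi[p]]
      G[p, tr[gl[p]]] <- G[p, tr[gl[p]]] - lambda[gl[p]]
    }
    Gv <- G / v
    Pm <- chol2inv(chol(Sigma)) + crossprod(G, Gv)
    V <- chol2inv(chol(Pm))
    M <- sweep(z, 2L, gamma, "+") %*% Gv %*% V
    theta <- M + matrix(stats::rnorm(J * d), J, d) %*% chol(V)

    # 4. loadings (conjugate truncated normal), statement by statement
    zg <- sweep(z, 2L, gamma, "+")
    for (i in seq_len(n)) {
      ps <- pairs_of[[i]]
      th_i <- theta[, tr[i]]
      num <- 0; den <- 0
      for (p in ps) {
        other <- if (gi[p] == i) gl[p] else gi[p]
        sgn <- if (gi[p] == i) 1 else -1
        resid <- sgn * (zg[, p] -
                          (if (gi[p] == i) -1 else 1) *
                          lambda[other] * theta[, tr[other]])
        num <- num + sum(th_i * resid) / v[p]
        den <- den + sum(th_i^2) / v[p]
      }
      prec_i <- den + 2
      mn_i <- (num + 2 * keying[i]) / prec_i
      lambda[i] <- truncnorm::rtruncnorm(
        1, a = if (keying[i] > 0) 0 else -Inf,
        b = if (keying[i] > 0) Inf else 0,
        mean = mn_i, sd = sqrt(1 / prec_i))
    }

    # 5. error variances (Metropolis on log psi); z-residual sums per pair
    u_part <- theta[, tr[gi], drop = FALSE] * matrix(rep(lambda[gi], each = J), J, P) -
      theta[, tr[gl], drop = FALSE] * matrix(rep(lambda[gl], each = J), J, P)
    q_pair <- colSums((z - sweep(u_part, 2L, gamma))^2)
    for (i in seq_len(n)) {
      ps <- pairs_of[[i]]
      other <- ifelse(gi[ps] == i, gl[ps], gi[ps])
      lp <- log(psi[i])
      lp_prop <- lp + psi_steps[i] * stats::rnorm(1)
      psi_prop <- exp(lp_prop)
      v_cur <- psi[i] + psi[other]
      v_prop <- psi_prop + psi[other]
      logr <- sum(-J / 2 * (log(v_prop) - log(v_cur)) -
                    q_pair[ps] / 2 * (1 / v_prop - 1 / v_cur)) +
        psi_log_prior(psi_prop) - psi_log_prior(psi[i]) + (lp_prop - lp)
      if (log(stats::runif(1)) < logr) {
        psi[i] <- psi_prop
        acc <- TRUE
      } else acc <- FALSE
      if (adapt) psi_steps[i] <- psi_steps[i] * exp((as.numeric(acc) - 0.44) / max(1, it)^0.6)
    }

    # 6. trait correlation matrix
    up <- update_sigma(Sigma, theta, sig_steps, adapt, it)
    Sigma <- up$Sigma; sig_steps <- up$steps
    }  # end scan

    if (it > warmup) {
      row <- it - warmup
      sp <- sigma_pairs(d)
      draws[row, ] <- c(lambda, psi, Sigma[sp], as.vector(theta), gamma)
      # pointwise log-likelihood per person-block: density of the augmented
      # latent comparison variables (a diagonal 3-dimensional normal per
      # block for n_b = 3), matching the latent-density bookkeeping of the
      # constrained implementations so WAIC comparisons share a scale
      v <- psi[gi] + psi[gl]
      sdv <- sqrt(v)
      u_part <- theta[, tr[gi], drop = FALSE] * matrix(rep(lambda[gi], each = J), J, P) -
        theta[, tr[gl], drop = FALSE] * matrix(rep(lambda[gl], each = J), J, P)
      llp <- stats::dnorm(z, mean = sweep(u_part, 2L, gamma),
                          sd = rep(sdv, each = J), log = TRUE)
      pointwise[row, ] <- as.vector(llp %*% blk_ind)
    }
  }
  list(draws = draws, pointwise = pointwise)
}

#' Standardized loadings of a fitted model
#'
#' The ranking likelihood is invariant to rescaling all parameters of a block
#' by a common positive constant, so the absolute scale of `lambda` and `psi`
#' is identified only through the priors. The standardized loading
#' `lambda / sqrt(lambda^2 + psi)` (the loading on the unit-variance latent
#' utility) is scale-invariant and is the quantity on which recovery of
#' generating parameters is meaningfully scored; under the simulator's
#' convention `psi = 1 - lambda^2`, the generating utilities have unit
#' variance, so the generating `lambda` is already standardized.
#'
#' @param fit An `mfc_fit`.
#' @param conf_level Credible interval level.
#' @return A tibble with one row per statement: posterior mean, SD, MCSE and
#'   credible bounds of the standardized loading.
#' @export
standardized_loadings <- function(fit, conf_level = 0.95) {
  a <- fit$draws
  ln <- grep("^lambda\\[", dimnames(a)[[3]])
  pn <- grep("^psi\\[", dimnames(a)[[3]])
  lam <- a[, , ln, drop = FALSE]
  psi <- a[, , pn, drop = FALSE]
  std <- lam / sqrt(lam^2 + psi)
  dimnames(std)[[3]] <- paste0("lambda_std[", seq_along(ln), "]")
  s <- convergence_diagnostics(std)
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  qs <- t(apply(std, 3L, stats::quantile, probs = probs))
  dplyr::mutate(s, conf.low = qs[, 1], conf.high = qs[, 2])
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, standard deviation, Monte Carlo standard
#' error of the mean, rank-normalized split R-hat and bulk effective sample
#' size, ordered by parameter name.
#'
#' @param fit An `mfc_fit` (>= 2 chains).
#' @return A tibble, one row per parameter.
#' @export
summarize_posterior <- function(fit) {
  res <- convergence_diagnostics(fit)
  dplyr::arrange(res, .data$term)
}
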