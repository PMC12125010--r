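test_that("pairwise preference probability follows the probit form", {
  expect_equal(pairwise_preference_probability(0, 1, 1, 0), 0.5)
  # numerator equal to the SD of the difference gives pnorm(1)
  expect_equal(
    pairwise_preference_probability(-sqrt(0.5 + 0.7), 0, 0, 0,
                                    psi_i = 0.5, psi_l = 0.7),
    pnorm(1))
  # monotone in the utility-difference numerator
  p <- pairwise_preference_probability(0, 1, 0.5, seq(-2, 2, 0.5))
  expect_true(all(diff(p) > 0))
  expect_error(pairwise_preference_probability(0, 1, 1, 0, psi_i = -1),
               class = "mfcirt_domain_error")
})

test_that("intercepts are location-invariant contrasts of utility means", {
  A <- full_design_matrix(3, 2)
  mu <- rnorm(6)
  g1 <- constrained_intercepts(mu, A)
  g2 <- constrained_intercepts(mu + 5, A)
  expect_equal(as.numeric(g1), as.numeric(g2))
  # within-block additivity: gamma_AB + gamma_BC = gamma_AC
  expect_equal(g1[1] + g1[3], g1[2], tolerance = 1e-12)
  expect_equal(g1[4] + g1[6], g1[5], tolerance = 1e-12)
})

test_that("utility difference law has the documented degenerate covariance", {
  A <- full_design_matrix(3, 1)
  law <- utility_difference_law(A, rep(0, 3), matrix(0, 3, 1), 0, rep(1, 3))
  expect_equal(unname(law$cov),
               matrix(c(2, 1, -1, 1, 2, 1, -1, 1, 2), 3, 3))
  expect_equal(law$eigenvalues, c(3, 3, 0), tolerance = 1e-10)
  expect_equal(law$rank, 2L)
  An <- neighboring_design_matrix(c(1, 2, 3))
  lawn <- utility_difference_law(An, rep(0, 3), matrix(0, 3, 1), 0, rep(1, 3))
  expect_equal(unname(lawn$cov), matrix(c(2, -1, -1, 2), 2, 2))
  expect_equal(det(lawn$cov), 3)
  expect_equal(lawn$rank, 2L)
})

test_that("singular normal density matches eigenvalue form and guards its support", {
  expect_equal(singular_normal_logpdf(c(0, 0), c(0, 0), diag(2)), -log(2 * pi))
  A <- full_design_matrix(3, 1)
  S <- A %*% t(A)
  expect_equal(singular_normal_logpdf(rep(0, 3), rep(0, 3), S),
               -log(2 * pi) - 0.5 * log(9))
  # full-rank limit agrees with the standard multivariate normal
  set.seed(1)
  V <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  x <- rnorm(3)
  expect_equal(singular_normal_logpdf(x, rep(0, 3), V),
               mvtnorm::dmvnorm(x, sigma = V, log = TRUE))
  # off-support: the null direction of A A' is (1, -1, 1)
  expect_error(singular_normal_logpdf(c(1, -1, 1) * 0.01, rep(0, 3), S),
               class = "mfcirt_off_support")
  # on-support displacement is fine
  expect_silent(singular_normal_logpdf(as.numeric(A %*% rnorm(3)), rep(0, 3), S))
})

test_that("original-model likelihood treats comparisons as independent Bernoullis", {
  d <- one_block_design()
  lambda <- rep(0, 3); psi <- rep(1, 3); theta <- rep(0, 3)
  # all probabilities 1/2: three comparisons contribute 3 log(1/2)
  ll <- loglik_original(c(1, 0, 0), rep(0, 3), d, lambda, theta, psi)
  expect_equal(ll, 3 * log(0.5))
  # intransitive pattern receives positive probability under free intercepts
  ll_intr <- loglik_original(c(1, 0, 1), c(-1, 1, -1), d, lambda, theta, psi)
  expect_true(is.finite(ll_intr) && ll_intr > -Inf)
  # constrained intercepts are rejected
  g <- constrained_intercepts(rnorm(3), full_design_matrix(3, 1))
  expect_error(loglik_original(c(1, 0, 0), g, d, lambda, theta, psi),
               class = "mfcirt_mode_error")
})

test_that("constrained latent-difference law assigns zero mass to intransitive patterns", {
  # under gamma = -A mu the latent differences satisfy d_AC = d_AB + d_BC
  # exactly, so the intransitive pattern (1,0,1) (d_AB > 0, d_AC < 0,
  # d_BC > 0) is impossible; Monte Carlo over the latent difference law
  set.seed(42)
  mu <- rnorm(3); lambda <- runif(3, 0.6, 1); psi <- runif(3, 0.2, 1)
  theta <- rnorm(1)
  A <- full_design_matrix(3, 1)
  mean_vec <- as.numeric(A %*% (mu + lambda * theta))
  eps <- matrix(rnorm(3 * 100000, sd = rep(sqrt(psi), 100000)), ncol = 3,
                byrow = TRUE)
  diffs <- sweep(eps %*% t(A), 2, mean_vec, "+")
  pat <- (diffs > 0) + 0
  intrans <- (pat[, 1] == 1 & pat[, 2] == 0 & pat[, 3] == 1) |
    (pat[, 1] == 0 & pat[, 2] == 1 & pat[, 3] == 0)
  expect_equal(sum(intrans), 0L)
  # with free gamma the inequality gap can be opened
  gam <- c(-2, 2, -2)
  diffs_free <- sweep(eps %*% t(A), 2, -gam + as.numeric(A %*% (lambda * theta)), "+")
  pat_free <- (diffs_free > 0) + 0
  intrans_free <- pat_free[, 1] == 1 & pat_free[, 2] == 0 & pat_free[, 3] == 1
  expect_gt(mean(intrans_free), 0.5)
})

test_that("full and reduced constrained log-likelihoods differ by a parameter-free constant", {
  d <- one_block_design(keying = c(1, 1, -1))
  set.seed(7)
  consts <- replicate(100, {
    mu <- rnorm(3)
    lambda <- c(runif(2, 0.5, 1), -runif(1, 0.5, 1))
    psi <- runif(3, 0.2, 1.2)
    theta <- rnorm(3)
    ranks <- sample(3)
    diffs <- runif(2, 0.05, 2)
    full <- expand_latent_diffs(ranks, diffs)
    loglik_constrained_full(ranks, full, d, mu, lambda, theta, psi) -
      loglik_constrained_reduced(ranks, diffs, d, mu, lambda, theta, psi)
  })
  expect_equal(mean(consts), -0.5 * log(3), tolerance = 1e-10)
  expect_lt(var(consts), 1e-20)
})

test_that("reduced likelihood reduces to the probit probability for n_b = 2", {
  d <- fc_design(1, 2, traits = c(1, 2), keying = c(1, 1), n_traits = 2)
  mu <- c(0.4, -0.2); lambda <- c(0.8, 0.7); psi <- c(0.5, 0.6)
  theta <- c(0.3, -1)
  # orthant-marginal of the univariate latent difference law = Eq-3 probit
  m <- (mu[1] + lambda[1] * theta[1]) - (mu[2] + lambda[2] * theta[2])
  p_orthant <- pnorm(m / sqrt(sum(psi)))
  gamma <- -(mu[1] - mu[2])
  p_probit <- pairwise_preference_probability(gamma, lambda[1], lambda[2],
                                              theta[1], theta[2],
                                              psi[1], psi[2])
  expect_equal(p_orthant, p_probit)
  # and numerical integration of the reduced density over (0, Inf) matches
  f <- function(x) vapply(x, function(xi) {
    exp(loglik_constrained_reduced(c(1, 2), xi, d, mu, lambda, theta, psi))
  }, numeric(1))
  expect_equal(integrate(f, 0, Inf)$value, p_orthant, tolerance = 1e-6)
})

test_that("orthant-marginal ranking probabilities sum to one and match simulation", {
  set.seed(11)
  for (rep in 1:3) {
    cfg <- sim_config(n_b = 3, K = 1, J = 1, d = 3, trait_corr = diag(3))
    p <- draw_item_parameters(cfg, rng_seed = 100 + rep)
    theta <- rnorm(3)
    rp <- ranking_probabilities(p$design, p, theta)
    expect_equal(sum(rp$prob), 1, tolerance = 1e-3)
    freqs <- mc_ranking_freqs(p, theta, 100000, seed = 200 + rep)
    labs <- vapply(rp$ranking, paste, character(1), collapse = "")
    mc <- as.numeric(freqs[labs])
    mc[is.na(mc)] <- 0
    se <- sqrt(rp$prob * (1 - rp$prob) / 100000)
    expect_true(all(abs(rp$prob - mc) <= 3 * se + 1e-8))
  }
})

test_that("log prior respects truncations and modes", {
  d <- 3
  params <- list(mu = rnorm(6), lambda = c(0.8, 0.9, -0.7, 0.6, 0.5, -0.9),
                 keying = c(1, 1, -1, 1, 1, -1), psi = runif(6, 0.2, 1),
                 trait_corr = diag(d), theta = matrix(rnorm(15), 5, 3))
  lp <- log_prior(params, "constrained")
  expect_true(is.finite(lp))
  # wrong-sign loading is outside the truncated support
  bad <- params; bad$lambda[1] <- -0.1
  expect_identical(log_prior(bad, "constrained"), -Inf)
  bad2 <- params; bad2$psi[2] <- -0.5
  expect_identical(log_prior(bad2, "constrained"), -Inf)
  # free mode needs gamma and adds its N(0, 4) term
  expect_error(log_prior(params, "free"), class = "mfcirt_mode_error")
  pf <- params; pf$gamma <- rnorm(9)
  expect_equal(log_prior(pf, "free") - lp,
               sum(dnorm(pf$gamma, 0, 2, log = TRUE)))
  # LKJ(1): the correlation matrix contributes no varying term
  p2 <- params
  p2$trait_corr <- matrix(0.3, d, d); diag(p2$trait_corr) <- 1
  white1 <- sum(dnorm(params$theta %*% solve(chol(params$trait_corr)), log = TRUE))
  white2 <- sum(dnorm(p2$theta %*% solve(chol(p2$trait_corr)), log = TRUE))
  expect_equal(log_prior(p2, "constrained") - lp, white2 - white1)
})

test_that("latent difference supports are validated", {
  d <- one_block_design()
  expect_error(
    loglik_constrained_reduced(c(1, 2, 3), c(0.5, -0.1), d, rep(0, 3),
                               rep(0.8, 3), rep(0, 3), rep(0.5, 3)),
    class = "mfcirt_support_error")
  # sign-inconsistent full differences
  full <- expand_latent_diffs(c(1, 2, 3), c(0.5, 0.5))
  expect_error(
    loglik_constrained_full(c(2, 1, 3), full, d, rep(0, 3), rep(0.8, 3),
                            rep(0, 3), rep(0.5, 3)),
    class = "mfcirt_support_error")
  # off-support full differences (transitive signs but broken additivity)
  expect_error(
    loglik_constrained_full(c(1, 2, 3), c(0.5, 1.5, 0.5), d, rep(0, 3),
                            rep(0.8, 3), rep(0, 3), rep(0.5, 3)),
    class = "mfcirt_off_support")
})
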