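sim_ar1 <- function(n, rho, seed) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- rho * x[i - 1] + sqrt(1 - rho^2) * rnorm(1)
  x
}

test_that("iid chains produce R-hat near one and honest ESS/MCSE", {
  set.seed(3)
  x <- array(rnorm(4 * 1000), dim = c(1000, 4, 1), dimnames = list(NULL, NULL, "a"))
  d <- convergence_diagnostics(x)
  expect_gt(d$rhat, 0.99)
  expect_lt(d$rhat, 1.01)
  expect_gt(d$ess_bulk, 3000)
  # MCSE approximately 1/sqrt(4000) for unit-variance iid draws
  expect_equal(d$mcse, 1 / sqrt(4000), tolerance = 0.2)
  expect_equal(d$mean, 0, tolerance = 4 / sqrt(4000))
})

test_that("non-mixing chains are flagged by split R-hat", {
  set.seed(4)
  x <- array(c(rnorm(1000, 0), rnorm(1000, 3)), dim = c(1000, 2, 1))
  d <- convergence_diagnostics(x)
  expect_gt(d$rhat, 1.5)
})

test_that("ESS matches the AR(1) closed form and may exceed the draw count", {
  # positive autocorrelation: ESS/N ~= (1 - rho) / (1 + rho) = 1/3
  ratios <- vapply(1:10, function(s) {
    x <- array(vapply(1:4, function(ch) sim_ar1(500, 0.5, s * 10 + ch),
                      numeric(500)), dim = c(500, 4, 1))
    convergence_diagnostics(x)$ess_bulk / 2000
  }, numeric(1))
  expect_equal(mean(ratios), 1 / 3, tolerance = 0.15)
  # antithetic chains: ESS above the raw draw count is permitted and reported
  x <- array(vapply(1:4, function(ch) sim_ar1(500, -0.9, 100 + ch),
                    numeric(500)), dim = c(500, 4, 1))
  expect_gt(convergence_diagnostics(x)$ess_bulk, 2000)
})

test_that("ESS is consistent with an established estimator on iid input", {
  skip_if_not_installed("coda")
  set.seed(9)
  x <- matrix(rnorm(4000), 1000, 4)
  mine <- convergence_diagnostics(array(x, c(1000, 4, 1)))$ess_bulk
  theirs <- sum(apply(x, 2, function(v) coda::effectiveSize(v)))
  expect_equal(mine, theirs, tolerance = 0.2)
})

test_that("MCSE decreases at the root-N rate on iid input", {
  set.seed(12)
  m_small <- convergence_diagnostics(array(rnorm(2 * 100), c(100, 2, 1)))$mcse
  m_large <- convergence_diagnostics(array(rnorm(2 * 10000), c(10000, 2, 1)))$mcse
  expect_equal(m_small / m_large, sqrt(100), tolerance = 0.35)
})

test_that("degenerate and undersized inputs are rejected or flagged", {
  expect_error(convergence_diagnostics(array(rnorm(10), c(10, 1, 1))),
               class = "mfcirt_single_chain")
  expect_error(convergence_diagnostics(array(rnorm(6), c(3, 2, 1))),
               class = "mfcirt_insufficient_draws")
  d <- suppressWarnings(convergence_diagnostics(array(1, c(100, 2, 1))))
  expect_equal(d$sd, 0)
  expect_true(is.na(d$rhat) || is.na(d$ess_bulk) || is.na(d$mcse))
})

test_that("WAIC arithmetic: constants, offsets, invariances", {
  set.seed(5)
  ll <- matrix(-2.5, 40, 10)
  w <- waic(ll)
  expect_equal(w$elpd_waic, 10 * -2.5)
  expect_equal(w$p_waic, 0)
  expect_equal(w$se_elpd_waic, 0)
  # adding a per-observation constant k to one model changes elpd_diff by
  # n_obs * k with zero paired SE
  llA <- matrix(rnorm(40 * 10, -2), 40, 10)
  k <- 0.7
  cw <- compare_waic(A = waic(llA), B = waic(llA + k))
  expect_equal(unname(cw$elpd_diff[cw$model == "A"]), -10 * k)
  expect_equal(unname(cw$se_diff[cw$model == "A"]), 0)
  expect_equal(unname(cw$elpd_diff[cw$model == "B"]), 0)  # B is the reference (higher elpd)
  # invariance to permuting draws
  w1 <- waic(llA)
  w2 <- waic(llA[sample(40), ])
  expect_equal(w1$elpd_waic, w2$elpd_waic)
  # antisymmetry of pairwise differences
  llB <- llA + matrix(rnorm(400, 0, 0.1), 40, 10)
  cw2 <- compare_waic(A = waic(llA), B = waic(llB))
  expect_equal(sum(cw2$elpd_diff == 0), 1L)
  expect_error(waic(matrix(c(1, NA), 2, 2)), class = "mfcirt_validation_error")
})

test_that("WAIC favors the generating model in most replicates", {
  # two Gaussian location models, data from model A; pointwise draws built
  # from each model's posterior-ish parameter draws
  set.seed(21)
  wins <- replicate(50, {
    y <- rnorm(60)
    muA <- rnorm(200, 0, 0.05)
    muB <- rnorm(200, 0.6, 0.05)
    llA <- vapply(y, function(yi) dnorm(yi, muA, log = TRUE), numeric(200))
    llB <- vapply(y, function(yi) dnorm(yi, muB, log = TRUE), numeric(200))
    waic(llA)$elpd_waic > waic(llB)$elpd_waic
  })
  expect_gte(mean(wins), 0.9)
})
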