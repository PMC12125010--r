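test_that("full design matrix enumerates lexicographic pairwise contrasts", {
  A <- full_design_matrix(3, 1)
  expect_equal(unclass(A)[1:3, 1:3],
               matrix(c(1, -1, 0, 1, 0, -1, 0, 1, -1), 3, 3, byrow = TRUE))
  expect_equal(unclass(full_design_matrix(2, 1))[1, ], c(1, -1))
  # block-diagonal extension: two identical copies on the diagonal
  A2 <- full_design_matrix(3, 2)
  expect_equal(dim(A2), c(6L, 6L))
  expect_equal(A2[1:3, 1:3], A2[4:6, 4:6])
  expect_true(all(A2[1:3, 4:6] == 0) && all(A2[4:6, 1:3] == 0))
  # rank deficiency: per-block rank n_b - 1, third row = row2 - row1
  expect_equal(qr(A)$rank, 2)
  expect_equal(A[3, ], A[2, ] - A[1, ])
  expect_error(full_design_matrix(1, 1), class = "mfcirt_invalid_design")
  expect_error(full_design_matrix(3, 0), class = "mfcirt_invalid_design")
})

test_that("rankings encode to binary patterns and decode back", {
  expect_equal(ranking_to_binary(c(2, 3, 1)), c(1L, 0L, 0L))
  expect_equal(ranking_to_binary(c(1, 2, 3)), c(1L, 1L, 1L))
  expect_equal(ranking_to_binary(c(3, 2, 1)), c(0L, 0L, 0L))
  expect_equal(binary_to_ranking(c(1, 0, 0)), c(2L, 3L, 1L))
  expect_equal(binary_to_ranking(c(1, 1, 1)), c(1L, 2L, 3L))
  expect_error(ranking_to_binary(c(1, 1, 2)), class = "mfcirt_invalid_ranking")
  expect_error(ranking_to_binary(c(1, 2, 4)), class = "mfcirt_invalid_ranking")
})

test_that("intransitive patterns raise an error naming a violating triple", {
  err <- expect_error(binary_to_ranking(c(1, 0, 1)), class = "mfcirt_intransitive")
  expect_match(conditionMessage(err), "cycle")
})

test_that("encoding/decoding round-trips over every permutation up to n_b = 4", {
  for (n_b in 2:4) {
    perms <- mfcirt:::all_rankings(n_b)
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]
      expect_equal(binary_to_ranking(ranking_to_binary(p)), p)
    }
  }
})

test_that("neighbouring design matrices contrast adjacent ranks", {
  expect_equal(neighboring_design_matrix(c(1, 2, 3)),
               matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(neighboring_design_matrix(c(2, 3, 1)),
               matrix(c(-1, 0, 1, 1, -1, 0), 2, 3, byrow = TRUE),
               ignore_attr = TRUE)
  # structure: one +1 and one -1 per row, full row rank, positive differences
  # for the generating ranking
  set.seed(1)
  for (rep in 1:20) {
    n_b <- sample(2:4, 1)
    r <- sample(n_b)
    A <- neighboring_design_matrix(r)
    expect_true(all(rowSums(A == 1) == 1 & rowSums(A == -1) == 1))
    expect_equal(qr(A)$rank, n_b - 1L)
    u <- (n_b - r)  # utilities consistent with the ranking
    expect_true(all(A %*% u > 0))
  }
})

test_that("identical or exactly opposite rankings share the design matrix up to row sign", {
  r <- c(2, 3, 1)
  A1 <- neighboring_design_matrix(r)
  A2 <- neighboring_design_matrix(4 - r)  # reversed ranking
  # reversed ranking flips and reorders the contrasts
  expect_equal(A1, -unclass(A2)[(nrow(A2)):1, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(A1, neighboring_design_matrix(r), ignore_attr = TRUE)
})

test_that("exactly n_b! of the binary patterns are transitive", {
  expect_equal(nrow(enumerate_transitive_patterns(2)), 2L)
  expect_equal(nrow(enumerate_transitive_patterns(3)), 6L)
  expect_equal(nrow(enumerate_transitive_patterns(4)), 24L)
  expect_error(enumerate_transitive_patterns(5), class = "mfcirt_unsupported")
})

test_that("person design matrix stacks per-block neighbouring contrasts", {
  d <- tiny_design()
  ranks <- c(2, 3, 1, 1, 2, 3)
  A <- person_design_matrix(d, ranks)
  expect_equal(dim(A), c(4L, 6L))
  expect_equal(A[1:2, 1:3], neighboring_design_matrix(c(2, 3, 1)),
               ignore_attr = TRUE)
  expect_equal(A[3:4, 4:6], neighboring_design_matrix(c(1, 2, 3)),
               ignore_attr = TRUE)
  expect_error(person_design_matrix(d, c(1, 2)), class = "mfcirt_invalid_ranking")
})

test_that("design constructor validates its invariants", {
  expect_error(fc_design(2, 3, traits = rep(1, 5), keying = rep(1, 6)),
               class = "mfcirt_invalid_design")
  expect_error(fc_design(2, 3, traits = rep(7, 6), keying = rep(1, 6), n_traits = 5),
               class = "mfcirt_invalid_design")
  expect_error(fc_design(2, 3, traits = rep(1, 6), keying = rep(2, 6)),
               class = "mfcirt_invalid_design")
  d <- tiny_design()
  expect_s3_class(d$statements, "tbl_df")
  expect_equal(nrow(d$statements), 6L)
})
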