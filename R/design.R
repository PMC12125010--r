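#' Questionnaire design for a multidimensional forced-choice test
#'
#' Describes the block structure of an MFC questionnaire: `n_blocks` blocks of
#' `block_length` statements each, a statement-to-trait map and keying signs.
#' Statements are indexed globally `1..n_blocks * block_length` in block order.
#' Simple structure is assumed: every statement measures exactly one trait.
#'
#' @param n_blocks Number of blocks (K), a positive integer.
#' @param block_length Number of statements per block (n_b), an integer >= 2.
#' @param traits Integer vector, one trait index in `1..n_traits` per statement.
#' @param keying Vector of keying signs, `+1` or `-1` per statement.
#' @param n_traits Number of latent traits (d); defaults to `max(traits)`.
#'
#' @return An object of class `fc_design`: a list with the scalar fields above
#'   and `$statements`, a tibble with one row per statement (columns
#'   `statement`, `block`, `position`, `trait`, `keying`).
#' @examples
#' fc_design(n_blocks = 2, block_length = 3,
#'           traits = c(1, 2, 3, 1, 2, 3),
#'           keying = c(1, 1, -1, 1, -1, 1))
#' @export
fc_design <- function(n_blocks, block_length, traits, keying,
                      n_traits = max(traits)) {
  if (length(n_blocks) != 1L || n_blocks < 1 || n_blocks != round(n_blocks) ||
      length(block_length) != 1L || block_length < 2 ||
      block_length != round(block_length)) {
    abort_mfc("`n_blocks` must be >= 1 and `block_length` >= 2.",
              "mfcirt_invalid_design")
  }
  n <- n_blocks * block_length
  traits <- as.integer(traits)
  if (length(traits) != n || anyNA(traits) ||
      any(traits < 1L) || any(traits > n_traits)) {
    abort_mfc("`traits` must give one trait index in 1..n_traits per statement.",
              "mfcirt_invalid_design")
  }
  keying <- as.numeric(keying)
  if (length(keying) != n || !all(keying %in% c(-1, 1))) {
    abort_mfc("`keying` must be +1 or -1 for each statement.",
              "mfcirt_invalid_design")
  }
  statements <- tibble::tibble(
    statement = seq_len(n),
    block = rep(seq_len(n_blocks), each = block_length),
    position = rep(seq_len(block_length), times = n_blocks),
    trait = traits,
    keying = keying
  )
  structure(
    list(n_blocks = as.integer(n_blocks),
         block_length = as.integer(block_length),
         n_traits = as.integer(n_traits),
         statements = statements),
    class = "fc_design"
  )
}

#' @export
print.fc_design <- function(x, ...) {
  cat(sprintf("<fc_design> %d blocks x %d statements, %d traits\n",
              x$n_blocks, x$block_length, x$n_traits))
  print(x$statements, n = 6)
  invisible(x)
}

abort_mfc <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "mfcirt_error"), ...)
}

# lexicographic statement pairs (i, l), i < l, within a block of length n_b
pair_table <- function(n_b) {
  i <- rep(seq_len(n_b - 1L), times = (n_b - 1L):1L)
  l <- unlist(lapply(seq_len(n_b - 1L), function(a) (a + 1L):n_b))
  cbind(i = i, l = l)
}

check_permutation <- function(ranks, n_b = length(ranks)) {
  ranks <- as.numeric(ranks)
  if (length(ranks) != n_b || anyNA(ranks) ||
      !setequal(ranks, seq_len(n_b)) || anyDuplicated(ranks)) {
    abort_mfc(
      sprintf("ranks must be a permutation of 1..%d (no ties, no gaps); got (%s)",
              n_b, paste(ranks, collapse = ",")),
      "mfcirt_invalid_ranking")
  }
  as.integer(ranks)
}

#' Pairwise-comparison design matrix
#'
#' Builds the contrast matrix mapping statement utilities to pairwise utility
#' differences. For one block of length `n_b` the rows enumerate statement
#' pairs (i, l) with i < l lexicographically; row (i, l) has +1 in column i
#' and -1 in column l. For `K` blocks the matrix is block-diagonal. The
#' per-block row rank is `n_b - 1`, so for `n_b >= 3` the matrix is rank
#' deficient and the implied law of the utility differences is degenerate.
#'
#' @param n_b Block length, >= 2.
#' @param K Number of blocks, >= 1.
#' @return A numeric matrix with `K * n_b * (n_b - 1) / 2` rows and
#'   `K * n_b` columns, with attributes `kind = "full"` and `block_index`
#'   (block of each row).
#' @examples
#' full_design_matrix(3, 1)
#' @export
full_design_matrix <- function(n_b, K = 1L) {
  if (length(n_b) != 1L || n_b < 2 || length(K) != 1L || K < 1) {
    abort_mfc("need n_b >= 2 and K >= 1", "mfcirt_invalid_design")
  }
  pt <- pair_table(n_b)
  C <- nrow(pt)
  blk <- matrix(0, C, n_b)
  blk[cbind(seq_len(C), pt[, "i"])] <- 1
  blk[cbind(seq_len(C), pt[, "l"])] <- -1
  A <- matrix(0, K * C, K * n_b)
  for (k in seq_len(K)) {
    A[(k - 1L) * C + seq_len(C), (k - 1L) * n_b + seq_len(n_b)] <- blk
  }
  structure(A, kind = "full", block_index = rep(seq_len(K), each = C))
}

#' Encode a ranking as a binary comparison pattern
#'
#' A block's rank vector (rank 1 = most preferred, i.e. highest latent
#' utility) is recoded into the `n_b * (n_b - 1) / 2` binary outcomes of all
#' pairwise comparisons, in lexicographic pair order (i, l) with i < l. The
#' outcome for pair (i, l) is 1 when statement i is preferred over l.
#'
#' @param ranks A permutation of `1..n_b`.
#' @return Integer 0/1 vector of length `n_b * (n_b - 1) / 2`.
#' @examples
#' ranking_to_binary(c(2, 3, 1))  # (1, 0, 0)
#' @export
ranking_to_binary <- function(ranks) {
  ranks <- check_permutation(ranks)
  pt <- pair_table(length(ranks))
  as.integer(ranks[pt[, "i"]] < ranks[pt[, "l"]])
}

#' Decode a binary comparison pattern into a ranking
#'
#' Inverts [ranking_to_binary()]. Only transitive patterns are decodable: a
#' block of length `n_b` admits `n_b!` rankings but
#' `2^(n_b (n_b - 1) / 2)` binary patterns, so intransitive patterns (such as
#' A > B, B > C, C > A) raise an error identifying a violating triple.
#'
#' @param pattern 0/1 vector of length `n_b * (n_b - 1) / 2`.
#' @return A permutation of `1..n_b`, the unique ranking whose encoding equals
#'   `pattern`.
#' @examples
#' binary_to_ranking(c(1, 0, 0))  # (2, 3, 1)
#' @export
binary_to_ranking <- function(pattern) {
  pattern <- as.numeric(pattern)
  L <- length(pattern)
  n_b <- (1 + sqrt(1 + 8 * L)) / 2
  if (n_b != round(n_b) || anyNA(pattern) || !all(pattern %in% c(0, 1))) {
    abort_mfc("pattern must be a 0/1 vector of length n_b*(n_b-1)/2",
              "mfcirt_invalid_pattern")
  }
  n_b <- as.integer(n_b)
  pt <- pair_table(n_b)
  # number of comparisons each statement wins; a tournament is transitive
  # iff its score sequence is a permutation of 0..n_b-1
  wins <- integer(n_b)
  for (p in seq_len(L)) {
    if (pattern[p] == 1) wins[pt[p, "i"]] <- wins[pt[p, "i"]] + 1L
    else wins[pt[p, "l"]] <- wins[pt[p, "l"]] + 1L
  }
  if (anyDuplicated(wins)) {
    trip <- find_intransitive_triple(pattern, n_b, pt)
    abort_mfc(
      sprintf("pattern (%s) is intransitive: statements (%s) form a preference cycle",
              paste(pattern, collapse = ","), paste(trip, collapse = ",")),
      "mfcirt_intransitive")
  }
  ranks <- n_b - wins
  stopifnot(all(ranking_to_binary(ranks) == pattern))
  ranks
}

find_intransitive_triple <- function(pattern, n_b, pt) {
  pref <- matrix(FALSE, n_b, n_b)
  for (p in seq_len(nrow(pt))) {
    i <- pt[p, "i"]; l <- pt[p, "l"]
    if (pattern[p] == 1) pref[i, l] <- TRUE else pref[l, i] <- TRUE
  }
  for (a in seq_len(n_b)) for (b in seq_len(n_b)) for (c in seq_len(n_b)) {
    if (a != b && b != c && a != c &&
        pref[a, b] && pref[b, c] && pref[c, a]) {
      return(c(a, b, c))
    }
  }
  integer(0)
}

#' Person-specific neighbouring-rank design matrix for one block
#'
#' Contrasts only statements with neighbouring ranks: row m compares the
#' statement holding rank m (+1) against the statement holding rank m + 1
#' (-1). Under the observed ranking all expected latent differences are
#' non-negative, which is the truncated-support parameterization used by the
#' reduced (stochastic & logical dependencies) implementation. The matrix
#' depends on the respondent's ranking; respondents share it exactly when
#' their rankings are identical or exactly reversed (up to row signs/order).
#'
#' @param ranks A permutation of `1..n_b`.
#' @return Numeric matrix with `n_b - 1` rows and `n_b` columns, attribute
#'   `kind = "neighboring"`.
#' @examples
#' neighboring_design_matrix(c(2, 3, 1))
#' @export
neighboring_design_matrix <- function(ranks) {
  ranks <- check_permutation(ranks)
  n_b <- length(ranks)
  ord <- order(ranks)  # ord[m] = statement holding rank m
  A <- matrix(0, n_b - 1L, n_b)
  for (m in seq_len(n_b - 1L)) {
    A[m, ord[m]] <- 1
    A[m, ord[m + 1L]] <- -1
  }
  structure(A, kind = "neighboring")
}

#' Block-diagonal person-specific design matrix across all blocks
#'
#' @param design An [fc_design()].
#' @param ranks Numeric vector of length `n_blocks * block_length`: the
#'   person's rank vectors for all blocks, concatenated in block order.
#' @return Matrix with `n_blocks * (block_length - 1)` rows, attribute
#'   `kind = "neighboring"` and `block_index` per row.
#' @export
person_design_matrix <- function(design, ranks) {
  n_b <- design$block_length
  K <- design$n_blocks
  if (length(ranks) != K * n_b) {
    abort_mfc("ranks must have length n_blocks * block_length",
              "mfcirt_invalid_ranking")
  }
  A <- matrix(0, K * (n_b - 1L), K * n_b)
  for (k in seq_len(K)) {
    blk <- neighboring_design_matrix(ranks[(k - 1L) * n_b + seq_len(n_b)])
    A[(k - 1L) * (n_b - 1L) + seq_len(n_b - 1L),
      (k - 1L) * n_b + seq_len(n_b)] <- blk
  }
  structure(A, kind = "neighboring",
            block_index = rep(seq_len(K), each = n_b - 1L))
}

#' Enumerate all transitive binary comparison patterns
#'
#' Brute-forces all `2^(n_b (n_b - 1)/2)` binary patterns of a block and keeps
#' those decodable into a ranking. Exactly `n_b!` patterns are transitive
#' (2 of 2 for `n_b = 2`, 6 of 8 for `n_b = 3`, 24 of 64 for `n_b = 4`).
#'
#' @param n_b Block length, one of 2, 3, 4 (practical enumeration bound).
#' @return Integer matrix, one transitive pattern per row.
#' @export
enumerate_transitive_patterns <- function(n_b) {
  if (length(n_b) != 1L || !(n_b %in% 2:4)) {
    abort_mfc("enumeration is supported for n_b in {2, 3, 4}",
              "mfcirt_unsupported")
  }
  C <- n_b * (n_b - 1L) / 2L
  grid <- as.matrix(expand.grid(rep(list(0:1), C)))
  colnames(grid) <- NULL
  keep <- apply(grid, 1L, function(p) {
    !inherits(tryCatch(binary_to_ranking(p), error = identity),
              "mfcirt_intransitive")
  })
  grid[keep, , drop = FALSE]
}

# all permutations of 1..n (n small), one per row
all_rankings <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_rankings(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (s in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[s, ], n, after = pos - 1L)
    }
  }
  out
}
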