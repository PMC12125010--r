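#' Factorial grid for the implementation-comparison study
#'
#' Crosses block length, test length (total number of binary comparisons) and
#' sample size; the number of blocks is derived from the test length, so a
#' short test holds 30 comparisons (`K = 10` for `n_b = 3`, `K = 5` for
#' `n_b = 4`) and a medium test 60 (`K = 20` / `K = 10`).
#'
#' @param block_lengths Block lengths to cross (subset of \{3, 4\}).
#' @param test_lengths Named vector of total binary comparison counts.
#' @param sample_sizes Sample sizes to cross.
#' @param replications Replications per cell. The default is desk scale;
#'   larger studies raise it explicitly.
#' @param base_seed Base seed from which per-cell seeds are derived.
#' @return A tibble with one row per cell: `n_b`, `test_length`, `K`, `J`,
#'   `replications`, `base_seed`.
#' @export
study_grid <- function(block_lengths = c(3, 4),
                       test_lengths = c(short = 30, medium = 60),
                       sample_sizes = c(50, 200),
                       replications = 3,
                       base_seed = 1L) {
  g <- tidyr::expand_grid(
    n_b = as.integer(block_lengths),
    test_length = as.integer(test_lengths),
    J = as.integer(sample_sizes))
  g <- dplyr::mutate(
    g,
    C = (.data$n_b * (.data$n_b - 1L)) %/% 2L,
    K = .data$test_length %/% .data$C,
    replications = as.integer(replications),
    base_seed = as.integer(base_seed))
  if (any(g$K * g$C != g$test_length)) {
    abort_mfc("test lengths must be divisible by the per-block comparison count",
              "mfcirt_invalid_config")
  }
  dplyr::select(g, -"C")
}

param_group <- function(term) {
  dplyr::case_when(
    grepl("^lambda\\[", term) ~ "lambda",
    grepl("^gamma\\[", term) ~ "gamma",
    grepl("^psi\\[", term) ~ "psi",
    grepl("^theta\\[", term) ~ "theta",
    grepl("^mu\\[", term) ~ "mu",
    grepl("^Sigma\\[", term) ~ "Sigma",
    TRUE ~ "other")
}

#' Compare posterior estimates across implementations
#'
#' For each pair of fits (on the same data and design) and each parameter
#' group (`lambda`, `gamma`, `psi`, `theta`, plus `mu` where both fits carry
#' it), computes the mean absolute difference between posterior means and the
#' mean combined Monte Carlo standard error
#' `sqrt(MCSE_1^2 + MCSE_2^2)`, flagging whether the differences fall within
#' it. For the constrained implementations, `gamma` is the deterministic
#' transform `-A mu` recomputed per draw, so its definition differs from the
#' free intercepts of the original implementation; the comparison still
#' reports it, as the tabled quantity.
#'
#' @param fits Named list of `mfc_fit` objects sharing data and design.
#' @param truth Optional `item_parameters` object; adds bias and RMSE of the
#'   posterior means against the generating values per group.
#' @return A tibble with one row per implementation pair and parameter group.
#' @export
compare_implementations <- function(fits, truth = NULL) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$impl, character(1))
  }
  designs_equal <- vapply(fits[-1], function(f) {
    identical(f$design$statements, fits[[1]]$design$statements)
  }, logical(1))
  if (!all(designs_equal)) {
    abort_mfc("fits must share the same questionnaire design",
              "mfcirt_comparability_error")
  }
  summ <- lapply(fits, function(f) {
    s <- convergence_diagnostics(f)
    s$group <- param_group(s$term)
    s
  })
  combos <- utils::combn(names(fits), 2L, simplify = FALSE)
  rows <- purrr::map_dfr(combos, function(pr) {
    s1 <- summ[[pr[1]]]; s2 <- summ[[pr[2]]]
    joined <- dplyr::inner_join(s1, s2, by = c("term", "group"),
                                suffix = c("_1", "_2"))
    joined <- dplyr::filter(joined, .data$group %in%
                              c("lambda", "gamma", "psi", "theta", "mu"))
    out <- dplyr::summarise(
      dplyr::group_by(joined, .data$group),
      mean_abs_diff = mean(abs(.data$mean_1 - .data$mean_2)),
      mean_mcse = mean(sqrt(.data$mcse_1^2 + .data$mcse_2^2)),
      n_params = dplyr::n(),
      prop_within_2mcse = mean(abs(.data$mean_1 - .data$mean_2) <=
                                 2 * sqrt(.data$mcse_1^2 + .data$mcse_2^2)),
      .groups = "drop")
    dplyr::mutate(out, impl_1 = pr[1], impl_2 = pr[2],
                  within_mcse = .data$mean_abs_diff <= .data$mean_mcse,
                  .before = 1L)
  })
  if (!is.null(truth)) {
    tv <- truth_vector(truth)
    rec <- purrr::map_dfr(names(fits), function(nm) {
      s <- summ[[nm]]
      j <- dplyr::inner_join(s, tv, by = "term")
      dplyr::mutate(
        dplyr::summarise(
          dplyr::group_by(j, .data$group),
          bias = mean(.data$mean - .data$true),
          rmse = sqrt(mean((.data$mean - .data$true)^2)),
          .groups = "drop"),
        impl = nm, .before = 1L)
    })
    attr(rows, "recovery") <- rec
  }
  class(rows) <- c("mfc_comparison", class(rows))
  rows
}

truth_vector <- function(truth) {
  items <- truth$items
  n <- nrow(items)
  tibble::tibble(
    term = c(paste0("mu[", seq_len(n), "]"),
             paste0("lambda[", seq_len(n), "]"),
             paste0("psi[", seq_len(n), "]")),
    true = c(items$mu, items$lambda, items$psi))
}

#' Run the implementation-comparison simulation study
#'
#' For each grid cell and replication: simulates a dataset, fits the three
#' implementations on it (common data, distinct seeded chains), and scores
#' pairwise agreement of the posterior means against Monte Carlo standard
#' errors. Results are optionally streamed to one CSV per cell so a partial
#' run can resume (existing cell files are loaded, not recomputed).
#'
#' @param grid A [study_grid()] (possibly filtered).
#' @param chains,iter MCMC settings per fit.
#' @param out_dir Optional directory for per-cell CSV streaming.
#' @param trait_corr Optional trait correlation override for the simulator.
#' @return A tibble of class `mfc_comparison_table`: grid columns plus
#'   `replication` and the [compare_implementations()] columns.
#' @export
run_simulation_study <- function(grid, chains = 2L, iter = 600L,
                                 out_dir = NULL, trait_corr = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  impls <- c("original", "stochastic", "stochastic_logical")
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    cell <- grid[g, ]
    cell_file <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("cell_nb%d_len%d_J%d.csv",
                                 cell$n_b, cell$test_length, cell$J))
    }
    if (!is.null(cell_file) && file.exists(cell_file)) {
      return(readr::read_csv(cell_file, show_col_types = FALSE))
    }
    cfg <- sim_config(n_b = cell$n_b, K = cell$K, J = cell$J,
                      d = max(5, cell$n_b), trait_corr = trait_corr)
    reps <- purrr::map_dfr(seq_len(cell$replications), function(r) {
      seed_r <- cell$base_seed * 10000L + g * 100L + r
      sim <- simulate_mfc(cfg, seed = seed_r)
      fits <- tryCatch({
        lapply(stats::setNames(impls, impls), function(im) {
          fit_mfc(sim$rankings, sim$design, impl = im,
                  chains = chains, iter = iter, seed = seed_r)
        })
      }, error = function(e) e)
      if (inherits(fits, "error")) {
        return(tibble::tibble(impl_1 = NA_character_, impl_2 = NA_character_,
                              group = NA_character_, mean_abs_diff = NA_real_,
                              mean_mcse = NA_real_, n_params = NA_integer_,
                              prop_within_2mcse = NA_real_, within_mcse = NA,
                              replication = r, failure = conditionMessage(fits)))
      }
      cmp <- compare_implementations(fits, truth = sim$params)
      dplyr::mutate(cmp, replication = r, failure = NA_character_)
    })
    out <- dplyr::mutate(reps, n_b = cell$n_b, test_length = cell$test_length,
                         K = cell$K, J = cell$J, .before = 1L)
    if (!is.null(cell_file)) readr::write_csv(out, cell_file)
    out
  })
  class(res) <- c("mfc_comparison_table", class(res))
  res
}
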