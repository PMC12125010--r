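#' Read a questionnaire design file
#'
#' Design files are YAML or JSON (by extension) with keys `n_blocks`,
#' `block_length`, `traits` (per-statement trait index) and `keying`
#' (per-statement +1/-1); `n_traits` is optional.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [fc_design()].
#' @export
read_design <- function(path) {
  ext <- tolower(tools::file_ext(path))
  spec <- switch(ext,
                 yaml = ,
                 yml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 abort_mfc("design files must be YAML or JSON", "mfcirt_schema_error"))
  need <- c("n_blocks", "block_length", "traits", "keying")
  if (!all(need %in% names(spec))) {
    abort_mfc(paste("design file must provide:", paste(need, collapse = ", ")),
              "mfcirt_schema_error")
  }
  fc_design(spec$n_blocks, spec$block_length, spec$traits, spec$keying,
            n_traits = spec$n_traits %||% max(spec$traits))
}

#' Write a questionnaire design file
#'
#' @param design An [fc_design()].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  spec <- list(n_blocks = design$n_blocks,
               block_length = design$block_length,
               n_traits = design$n_traits,
               traits = design$statements$trait,
               keying = design$statements$keying)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = ,
         yml = yaml::write_yaml(spec, path),
         json = jsonlite::write_json(spec, path, auto_unbox = TRUE),
         abort_mfc("design files must be YAML or JSON", "mfcirt_schema_error"))
  invisible(path)
}

#' Read ranking responses from CSV
#'
#' Expects a header `person_id, b1_s1, ..., b<K>_s<n_b>`; each cell is the
#' within-block rank of the statement (1 = most preferred). Every block of
#' every respondent must hold a complete permutation; ties, gaps and missing
#' cells are validation errors naming the person and block.
#'
#' @param path CSV path.
#' @param design The matching [fc_design()].
#' @return An `fc_rankings` tibble.
#' @export
read_rankings <- function(path, design) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  cols <- ranking_column_names(design)
  if (!identical(setdiff(names(df), "person_id"), cols)) {
    abort_mfc(sprintf(
      "rankings header does not match the design (expected person_id plus %d rank columns)",
      length(cols)), "mfcirt_schema_error")
  }
  if (!"person_id" %in% names(df)) df$person_id <- seq_len(nrow(df))
  m <- rankings_matrix(df, design)  # validates permutations
  as_fc_rankings(m, design, person_ids = df$person_id)
}

#' Write ranking responses to CSV
#'
#' @param rankings An `fc_rankings` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rankings <- function(rankings, path) {
  readr::write_csv(rankings, path)
  invisible(path)
}

#' Write a fitted model to a directory
#'
#' Writes one draws CSV per chain (columns in the documented parameter
#' order), a posterior summary CSV, the pointwise log-likelihood matrix CSV
#' (rows = kept draws stacked by chain, columns = person-block observations),
#' a JSON echo of the sampling configuration, and `manifest.json` with MD5
#' content hashes of every artifact. A `.incomplete` marker is present while
#' writing and removed on success, so interrupted writes are detectable.
#'
#' @param fit An `mfc_fit`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a tibble (`file`, `md5`), invisibly.
#' @export
write_fit <- function(fit, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  marker <- file.path(out_dir, ".incomplete")
  file.create(marker)
  files <- character(0)
  for (ch in seq_len(dim(fit$draws)[2])) {
    f <- file.path(out_dir, sprintf("draws_chain%d.csv", ch))
    readr::write_csv(tibble::as_tibble(as.data.frame(fit$draws[, ch, ])), f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "summary.csv")
  readr::write_csv(summarize_posterior(fit), f)
  files <- c(files, f)
  f <- file.path(out_dir, "pointwise_loglik.csv")
  readr::write_csv(tibble::as_tibble(as.data.frame(pointwise_ll_matrix(fit))),
                   f)
  files <- c(files, f)
  f <- file.path(out_dir, "config.json")
  jsonlite::write_json(fit$config, f, auto_unbox = TRUE)
  files <- c(files, f)
  f <- file.path(out_dir, "design.json")
  write_design(fit$design, f)
  files <- c(files, f)
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  file.remove(marker)
  invisible(manifest)
}

#' Read a fitted model directory back
#'
#' Restores the draws array, pointwise log-likelihoods, configuration and
#' design written by [write_fit()]; summaries recomputed from the restored
#' object reproduce the stored `summary.csv`.
#'
#' @param dir Directory written by [write_fit()].
#' @return An `mfc_fit`.
#' @export
read_fit <- function(dir) {
  if (file.exists(file.path(dir, ".incomplete"))) {
    abort_mfc("fit directory is marked incomplete (interrupted write)",
              "mfcirt_io_error")
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  design <- read_design(file.path(dir, "design.json"))
  chain_files <- sort(list.files(dir, pattern = "^draws_chain\\d+\\.csv$",
                                 full.names = TRUE))
  chains <- lapply(chain_files, function(f) {
    as.matrix(readr::read_csv(f, show_col_types = FALSE))
  })
  kept <- nrow(chains[[1]])
  par_names <- colnames(chains[[1]])
  draws <- array(NA_real_, dim = c(kept, length(chains), length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]
  pw_mat <- as.matrix(readr::read_csv(file.path(dir, "pointwise_loglik.csv"),
                                      show_col_types = FALSE))
  pw <- array(pw_mat, dim = c(kept, length(chains), ncol(pw_mat)))
  structure(list(draws = draws, pointwise_loglik = pw, impl = cfg$impl,
                 config = cfg, design = design, time = NA_real_),
            class = "mfc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
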