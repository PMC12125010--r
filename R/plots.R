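#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot posterior estimates or traces of a fitted model
#'
#' @param object An `mfc_fit`.
#' @param type `"intervals"` (posterior means with 95% credible intervals) or
#'   `"trace"` (chain traces).
#' @param pars Regular expression selecting parameters; defaults to the item
#'   parameters (`mu`, `lambda`, `psi`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mfc_fit
#' @export
autoplot.mfc_fit <- function(object, type = c("intervals", "trace"),
                             pars = "^(mu|lambda|psi)\\[", ...) {
  type <- match.arg(type)
  keep <- grep(pars, dimnames(object$draws)[[3]], value = TRUE)
  if (!length(keep)) abort_mfc("no parameters match `pars`", "mfcirt_invalid_config")
  if (type == "intervals") {
    td <- dplyr::filter(tidy(object), .data$term %in% keep)
    td <- dplyr::mutate(td, group = param_group(.data$term))
    ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
      ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                            xmax = .data$conf.high),
                               linewidth = 0.3, size = 0.2) +
      ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free") +
      ggplot2::labs(x = "posterior mean (95% credible interval)", y = NULL,
                    title = sprintf("Posterior estimates (%s)", object$impl))
  } else {
    a <- object$draws[, , keep, drop = FALSE]
    df <- purrr::map_dfr(seq_along(keep), function(p) {
      purrr::map_dfr(seq_len(dim(a)[2]), function(ch) {
        tibble::tibble(term = keep[p], chain = factor(ch),
                       iteration = seq_len(dim(a)[1]),
                       value = a[, ch, p])
      })
    })
    ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$chain)) +
      ggplot2::geom_line(linewidth = 0.2) +
      ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
      ggplot2::labs(title = sprintf("Traces (%s)", object$impl))
  }
}

#' Plot an implementation comparison table
#'
#' Mirrors the standard display for implementation-agreement studies: mean
#' absolute differences between posterior means (points) against the mean
#' Monte Carlo standard errors (line ranges), per parameter group and
#' implementation pair.
#'
#' @param object Output of [compare_implementations()] or
#'   [run_simulation_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mfc_comparison
#' @export
autoplot.mfc_comparison <- function(object, ...) {
  df <- dplyr::mutate(object, pair = paste(.data$impl_1, "vs", .data$impl_2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_abs_diff,
                                     colour = .data$pair),
                        position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = 0, ymax = .data$mean_mcse,
                                         colour = .data$pair),
                            position = ggplot2::position_dodge(width = 0.5),
                            alpha = 0.4, linewidth = 2) +
    ggplot2::labs(x = "parameter group",
                  y = "mean |difference| (points) vs mean MCSE (bars)")
}

#' @method autoplot mfc_comparison_table
#' @export
autoplot.mfc_comparison_table <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$group))
  df <- dplyr::mutate(df,
                      pair = paste(.data$impl_1, "vs", .data$impl_2),
                      setting = sprintf("nb=%d L=%d J=%d", .data$n_b,
                                        .data$test_length, .data$J))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_abs_diff, colour = .data$pair),
                        position = ggplot2::position_dodge(width = 0.5), size = 0.8) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = 0, ymax = .data$mean_mcse,
                                         colour = .data$pair),
                            position = ggplot2::position_dodge(width = 0.5),
                            alpha = 0.4, linewidth = 1.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$setting)) +
    ggplot2::labs(x = "parameter group",
                  y = "mean |difference| (points) vs mean MCSE (bars)")
}

#' Plot a WAIC model comparison
#'
#' @param object Output of [compare_waic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mfc_waic_comparison
#' @export
autoplot.mfc_waic_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$elpd_waic,
                                       y = stats::reorder(.data$model,
                                                          .data$elpd_waic))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$elpd_waic - .data$se_elpd_waic,
                                          xmax = .data$elpd_waic + .data$se_elpd_waic)) +
    ggplot2::labs(x = "elpd (WAIC)", y = NULL)
}
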