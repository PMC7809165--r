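#' Plot an association scan
#'
#' Manhattan-style view of a [scan_association()] result: one point per
#' feature, \eqn{-\log_{10}} p-value on the y axis, faceted by response.
#' The Bonferroni threshold for the scanned family is drawn as a dashed
#' line.
#'
#' @param object A `medipath_scan`.
#' @param alpha Family-wise level for the threshold line (default 0.05).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot medipath_scan
#' @export
autoplot.medipath_scan <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!.data$untestable) |>
    dplyr::group_by(.data$response) |>
    dplyr::mutate(ix = dplyr::row_number(), m = dplyr::n()) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ix, y = -log10(.data$p_value))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -log10(alpha / .data$m)),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$response)) +
    ggplot2::labs(x = "feature index", y = expression(-log[10](p)),
                  title = sprintf("%s scan", unique(df$model)[1])) +
    ggplot2::theme_minimal()
}

#' Plot an empirical test
#'
#' Histogram of the per-round estimates of a [bootstrap_test()] or
#' [permutation_test()] run with `keep_rounds = TRUE`, with the interval
#' bounds and the observed point estimate marked.
#'
#' @param object A `medipath_test` carrying its rounds.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot medipath_test
#' @export
autoplot.medipath_test <- function(object, ...) {
  rounds <- attr(object, "rounds")
  if (is.null(rounds)) {
    abort("re-run the test with keep_rounds = TRUE to plot its rounds")
  }
  df <- tibble::tibble(estimate = rounds)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(object$lower, object$upper),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$estimate, colour = "firebrick") +
    ggplot2::labs(x = sprintf("%s estimate per round", object$target),
                  y = "rounds",
                  title = sprintf("%s (%d rounds)%s", object$method,
                                  object$n_rounds,
                                  if (object$significant) " *" else "")) +
    ggplot2::theme_minimal()
}

#' Plot discovery counts
#'
#' Bar chart of the per response x mediator discovery counts of a
#' [run_pipeline()] result, split by candidate vs empirically confirmed.
#'
#' @param object A `discovery_table`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot discovery_table
#' @export
autoplot.discovery_table <- function(object, ...) {
  counts <- summarize_discoveries(object) |>
    dplyr::filter(.data$kind == "mediated") |>
    tidyr::pivot_longer(c("n_candidates", "n_significant"),
                        names_to = "stage", values_to = "n") |>
    dplyr::mutate(stage = dplyr::recode(.data$stage,
                                        n_candidates = "screened",
                                        n_significant = "confirmed"))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$response, y = .data$n,
                                       fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$mediator)) +
    ggplot2::labs(x = NULL, y = "markers",
                  title = "mediated-effect discoveries") +
    ggplot2::theme_minimal()
}
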