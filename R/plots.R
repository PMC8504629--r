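# ggplot2 summaries of pipeline results.

#' Bar chart of smORF class composition
#'
#' @param result a `smorf_result` or a composition tibble from
#'   [class_composition()].
#' @return a ggplot object.
#' @export
plot_class_composition <- function(result) {
  comp <- if (inherits(result, "smorf_result")) result$composition else result
  ggplot2::ggplot(comp, ggplot2::aes(
    x = stats::reorder(.data$orf_class, -.data$count), y = .data$count)) +
    ggplot2::geom_col(fill = "#3b6ea5") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$fraction)), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "smORFs", title = "smORF class composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' P-site offset calibration summary
#'
#' Shows, per read length, the number of usable reads and the frame-0
#' fraction achieved by the chosen offset; rejected lengths are greyed out.
#'
#' @param offsets offset table from [metagene_offsets()] (or a
#'   `smorf_result`).
#' @return a ggplot object.
#' @export
plot_offsets <- function(offsets) {
  if (inherits(offsets, "smorf_result")) offsets <- offsets$offsets
  ggplot2::ggplot(offsets, ggplot2::aes(
    x = factor(.data$read_length), y = .data$frame0_frac,
    fill = .data$accepted)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(
      is.na(.data$offset), "", paste0("+", .data$offset))), vjust = -0.3, size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#3b6ea5", `FALSE` = "grey70")) +
    ggplot2::labs(x = "read length (nt)", y = "frame-0 fraction",
                  fill = "accepted",
                  title = "P-site offset calibration") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' ORFScore distribution by class
#'
#' @param result a `smorf_result`.
#' @return a ggplot object.
#' @export
plot_orf_scores <- function(result) {
  d <- tidy(result)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$orf_class, y = .data$orf_score)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, colour = "#3b6ea5") +
    ggplot2::labs(x = NULL, y = "ORFScore",
                  title = "Triplet-periodicity score by smORF class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.smorf_result <- function(object, type = c("composition", "offsets",
                                                   "scores"), ...) {
  type <- match.arg(type)
  switch(type,
         composition = plot_class_composition(object),
         offsets = plot_offsets(object),
         scores = plot_orf_scores(object))
}
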