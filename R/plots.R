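# ggplot2 renderings of the result objects.

#' Plot a logo matrix as stacked per-position nucleotide probabilities
#'
#' Letters are stacked per position with heights equal to their
#' probabilities, the standard rendering of a position probability matrix.
#' The annotated interval boundaries are drawn as dashed lines.
#'
#' @param object A [logo_matrix()] result.
#' @param refset Optional [mir_reference()]; when given, the annotated start
#'   and end of the mature are marked.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.logo_matrix <- function(object, refset = NULL, ...) {
  df <- tidy(object)
  df <- filter(df, .data$probability > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$probability, fill = .data$base,
    label = .data$base)) +
    ggplot2::geom_col(width = 0.9, colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_text(position = ggplot2::position_stack(vjust = 0.5),
                       size = 2.6) +
    ggplot2::scale_fill_manual(values = c(A = "#33a02c", C = "#1f78b4",
                                          G = "#ff7f00", U = "#e31a1c")) +
    ggplot2::labs(
      title = sprintf("%s on %s", object$mature_id, object$precursor_id),
      x = "precursor position (0-based)", y = "probability", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(refset)) {
    ann <- filter(refset$matures, .data$mature_id == object$mature_id)[1, ]
    p <- p + ggplot2::geom_vline(xintercept = c(ann$start - 0.5,
                                                ann$end - 0.5),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot the 5' and 3' offset spectrum of an isomiR profile
#'
#' @param object An [profile_reads()] result.
#' @param mature_id Optional mature to restrict to (default: all).
#' @param ... Unused.
#' @return A ggplot object with one panel per terminus.
#' @export
autoplot.isomir_profile <- function(object, mature_id = NULL, ...) {
  cls <- object$classes
  if (!is.null(mature_id)) {
    cls <- filter(cls, .data$mature_id %in% !!mature_id)
  }
  df <- bind_rows(
    cls |> group_by(offset = .data$offset5) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      mutate(terminus = "5' offset"),
    cls |> group_by(offset = .data$offset3) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      mutate(terminus = "3' offset")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset,
                                   y = .data$count / sum(cls$count))) +
    ggplot2::geom_col(fill = "#1f78b4") +
    ggplot2::facet_wrap(~terminus) +
    ggplot2::labs(x = "template offset (nt, positive = downstream)",
                  y = "fraction of reads",
                  title = object$library_id) +
    ggplot2::theme_minimal()
}
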