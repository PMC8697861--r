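#' Plot per-position substitution evidence for an amplicon
#'
#' Bar plot of the non-reference base fraction at every amplicon position,
#' with the editing window shaded and the designated target C marked --
#' window-confined C-to-T conversion shows up as a spike inside the shading.
#'
#' @param object a `substitution_table` from [quantify()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot substitution_table
#' @export
autoplot.substitution_table <- function(object, ...) {
  pos <- object$positions |>
    mutate(
      aligned = .data$A + .data$C + .data$G + .data$T + .data$N + .data$del,
      ref_count = purrr::map2_dbl(
        row_number(), .data$ref_base,
        function(i, b) if (b %in% c("A", "C", "G", "T")) object$positions[[b]][i] else 0
      ),
      nonref = if_else(.data$aligned > 0,
                       100 * (.data$aligned - .data$ref_count - .data$N) / .data$aligned,
                       0)
    )
  win <- object$reference$window_cols
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$position, y = .data$nonref)) +
    ggplot2::annotate("rect", xmin = min(win) - 0.5, xmax = max(win) + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange") +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::geom_vline(xintercept = object$reference$target_col,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "amplicon position", y = "non-reference reads (%)",
      title = sprintf("Window %s>%s substitution: %s%%",
                      object$reference$conv_from, object$reference$conv_to,
                      fmt_pct(object$window_c_to_t_percent)),
      subtitle = sprintf("%d aligned reads; editing window shaded, target C dashed",
                         object$n_reads_aligned)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a guide-by-genome presence matrix
#'
#' Tile view of the o/x presence calls, guides on the y axis, genomes on
#' the x axis; guides present in every genome are the multi-subtype
#' candidates.
#'
#' @param object a [presence_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot presence_matrix
#' @export
autoplot.presence_matrix <- function(object, ...) {
  long <- tidy(object) |>
    mutate(guide = paste0(.data$gene, ":", .data$protospacer))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genome, y = .data$guide,
                                     fill = .data$present)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$call), size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#7fc97f", `FALSE` = "#fb8072"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL, title = "Guide presence across genomes") +
    ggplot2::theme_minimal()
}
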