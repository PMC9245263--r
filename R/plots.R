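#' Plot recombination support per repeat
#'
#' Stacked percentages of reads supporting the major and the crossover
#' (alternative) conformation for each repeat.
#'
#' @param support tibble of [quantify_recombination()] rows.
#' @return a ggplot object.
#' @export
plot_recombination_support <- function(support) {
  d <- tidyr::pivot_longer(
    support[, c("repeat_id", "pct_major", "pct_alternative")],
    cols = c("pct_major", "pct_alternative"),
    names_to = "conformation", values_to = "pct")
  d$conformation <- ifelse(d$conformation == "pct_major", "major",
                           "alternative")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$repeat_id, y = .data$pct,
                                  fill = .data$conformation)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "spanning reads (%)",
                  fill = "conformation") +
    ggplot2::theme_minimal()
}

#' @method autoplot recomb_support
#' @export
autoplot.recomb_support <- function(object, ...) {
  plot_recombination_support(object)
}

#' Plot MTPT hits along the genomes
#'
#' Hit intervals on the plastid (query) axis coloured by similarity
#' class, mirroring the arc-colour convention (blue 100%, green 90-100%,
#' red 80-90%, orange <80%).
#'
#' @param hits tibble from [find_mtpts()].
#' @return a ggplot object.
#' @export
plot_mtpt_map <- function(hits) {
  pal <- c(eq100 = "#3366cc", ge90lt100 = "#2e9e4f",
           ge80lt90 = "#d43a3a", lt80 = "#e8882f")
  ggplot2::ggplot(hits,
                  ggplot2::aes(x = .data$cp_start, xend = .data$cp_end,
                               y = .data$id, yend = .data$id,
                               colour = .data$similarity_class)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::labs(x = "plastid position (bp)", y = NULL,
                  colour = "similarity") +
    ggplot2::theme_minimal()
}

#' Plot an editing summary
#'
#' Two panels worth of data are available in an `editing_summary`; this
#' plots the per-type counts or the efficiency histogram.
#'
#' @param summary an [summarize_editing()] object.
#' @param panel `"types"` or `"efficiency"`.
#' @return a ggplot object.
#' @export
plot_editing_summary <- function(summary, panel = c("types", "efficiency")) {
  panel <- match.arg(panel)
  if (panel == "types") {
    d <- summary$per_type
    d$edit_type <- factor(d$edit_type, levels = EDIT_TYPES)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$edit_type, y = .data$n)) +
      ggplot2::geom_col(fill = "#4477aa") +
      ggplot2::labs(x = NULL, y = "editing sites") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  } else {
    d <- summary$efficiency_hist
    d$bin <- factor(d$bin, levels = d$bin)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$n)) +
      ggplot2::geom_col(fill = "#66aa55") +
      ggplot2::labs(x = "editing efficiency", y = "sites") +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot editing_summary
#' @export
autoplot.editing_summary <- function(object, ...) {
  plot_editing_summary(object, ...)
}
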