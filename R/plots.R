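#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rank-transition matrix
#'
#' Heatmap of occurrence counts by (old interpreted rank, new interpreted
#' rank); cells above the diagonal are improvements.
#'
#' @param object an `impact_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.impact_report <- function(object, ...) {
  lv <- pooled_rank_levels()
  df <- object$transitions %>%
    dplyr::mutate(old_rank = factor(old_rank, lv),
                  new_rank = factor(new_rank, lv))
  ggplot2::ggplot(df, ggplot2::aes(x = new_rank, y = old_rank, fill = n)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "interpreted rank (new backbone)",
                  y = "interpreted rank (old backbone)",
                  fill = "occurrences",
                  title = "Occurrence rank transitions") +
    ggplot2::theme_minimal()
}

#' Plot name-overlap counts
#'
#' @param object an `overlap_report`.
#' @param ... unused.
#' @return a ggplot bar chart of the three overlap classes.
#' @export
autoplot.overlap_report <- function(object, ...) {
  df <- tidy(object) %>%
    dplyr::mutate(set = factor(set, c("both", "checklist_only",
                                      "backbone_only"),
                               labels = c("in both", "added from checklist",
                                          "other sources only")))
  ggplot2::ggplot(df, ggplot2::aes(x = set, y = n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "names", title = "Backbone name overlap") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-genus counts above a threshold
#'
#' Works for both the newly-added-names accounting
#' ([per_genus_new_names()]) and the improved-occurrence accounting
#' ([per_genus_improvements()]).
#'
#' @param per_genus tibble with a `genus` column and one count column.
#' @param title plot title.
#' @return a ggplot.
#' @export
plot_per_genus <- function(per_genus, title = "Per-genus counts") {
  count_col <- setdiff(names(per_genus), "genus")[1]
  df <- per_genus %>%
    dplyr::mutate(genus = factor(genus, rev(per_genus$genus)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[count_col]], y = genus)) +
    ggplot2::geom_col(fill = "darkolivegreen4") +
    ggplot2::labs(x = "count", y = NULL, title = title) +
    ggplot2::theme_minimal()
}
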