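#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy a centrality report
#'
#' @param x A `centrality_report`.
#' @param ... Unused.
#' @return A plain tibble with `gene`, `degree`, `betweenness`, `is_key`.
#' @export
tidy.centrality_report <- function(x, ...) {
  key <- select_key_nodes(x)
  out <- tibble::as_tibble(x)
  out$is_key <- out$gene %in% key$symbol
  out
}

#' One-row summary of a centrality report
#'
#' @param x A `centrality_report`.
#' @param ... Unused.
#' @return A tibble with node/edge counts, the two means, and the key-node
#'   count.
#' @export
glance.centrality_report <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x),
    n_edges = sum(x$degree) / 2,
    mean_degree = attr(x, "mean_degree"),
    mean_betweenness = attr(x, "mean_betweenness"),
    n_key = nrow(select_key_nodes(x))
  )
}

#' Tidy a funnel report
#'
#' @param x A `funnel_report`.
#' @param ... Unused.
#' @return The stage tibble (`stage`, `n`).
#' @export
tidy.funnel_report <- function(x, ...) x$stages

#' One-row summary of a funnel report
#'
#' @param x A `funnel_report`.
#' @param ... Unused.
#' @return A tibble with the matched count, final count, and number of
#'   surviving mechanism classes.
#' @export
glance.funnel_report <- function(x, ...) {
  tibble::tibble(
    n_matched = x$stages$n[x$stages$stage == "matched"],
    n_final = x$stages$n[x$stages$stage == "mechanism"],
    n_classes = nrow(x$class_tally)
  )
}

#' Plot a screening funnel
#'
#' Bar chart of survivor counts per funnel stage, in cascade order.
#'
#' @param object A `funnel_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.funnel_report <- function(object, ...) {
  df <- object$stages
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "#31688E") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3.4) +
    ggplot2::labs(
      x = NULL, y = "drugs surviving",
      title = "Drug screening funnel"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a centrality report
#'
#' Degree versus betweenness per node with the two arithmetic means as
#' dashed lines; key nodes (both values at or above their mean, i.e. the
#' upper-right quadrant) are highlighted.
#'
#' @param object A `centrality_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centrality_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$degree, y = .data$betweenness, colour = .data$is_key
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(
      xintercept = attr(object, "mean_degree"), linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = attr(object, "mean_betweenness"), linetype = "dashed"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#B40426", `FALSE` = "grey50"), name = "key node"
    ) +
    ggplot2::labs(
      x = "degree", y = "betweenness",
      title = "Key-node selection by dual mean threshold"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Horizontal bars of -log10 corrected p-value per enriched term.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::labs(title = "No enriched terms") +
      ggplot2::theme_minimal())
  }
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_corrected), y = .data$term
  )) +
    ggplot2::geom_col(fill = "#35B779") +
    ggplot2::labs(
      x = expression(-log[10] ~ "corrected p"), y = NULL,
      title = "Enriched annotation terms"
    ) +
    ggplot2::theme_minimal()
}
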