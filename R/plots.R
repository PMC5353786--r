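# ggplot2 visualisations for the main result types.

#' Plot a region class map
#'
#' Stacked bar chart of region counts per class, filled by genomic category
#' when the map has been annotated.
#'
#' @param object A `dre_classmap` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dre_classmap <- function(object, ...) {
  has_cat <- "genomic_category" %in% names(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$class)) +
    ggplot2::labs(
      x = NULL, y = "regions",
      title = "Regulatory element classes"
    ) +
    ggplot2::theme_minimal()
  if (has_cat) {
    p + ggplot2::geom_bar(ggplot2::aes(fill = .data$genomic_category))
  } else {
    p + ggplot2::geom_bar()
  }
}

#' Plot a spatial distance test
#'
#' Empirical cumulative distributions of the observed within-class distances
#' against the pooled label-shuffle background.
#'
#' @param object A `spatial_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spatial_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$distance, colour = .data$source
  )) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "nearest-neighbour distance (bp)", y = "ECDF",
      title = sprintf("Within-class distances (rank-sum p = %.2g)", object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a GWAS permutation test
#'
#' Histogram of permutation counts with the observed count marked.
#'
#' @param object A `gwas_permutation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwas_permutation <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "trait SNPs in shuffled class", y = "permutations",
      title = sprintf(
        "Permutation enrichment [%s]: p = %.3g", object$class, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot motif gain/loss statistics
#'
#' Observed changed-hit fraction per motif against its background fraction.
#'
#' @param object A `tfbs_change` tibble (with canonical `fraction` columns,
#'   i.e. produced with a `direction`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfbs_change <- function(object, ...) {
  if (!"fraction" %in% names(object)) {
    abort("plotting needs a directional tfbs_change (direction = 'lost'/'gained')")
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$enrichment, y = -log10(pmax(.data$p_value, 1e-300)),
    label = .data$motif_id
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_text(nudge_y = 0.15, size = 3) +
    ggplot2::labs(
      x = "fraction / background fraction", y = "-log10 p",
      title = "Motif change at associated substitutions"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
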