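## ggplot2 views of the result objects.

#' Volcano-style plot of a SAM differential result
#'
#' Log2 fold change against -log10 q (q-values of 0 are floored at half the
#' smallest resolvable permutation quantile so they remain plottable), with
#' the gated probes highlighted.
#'
#' @param object A `sam_de` tibble.
#' @param min_abs_fold,max_q Gates used for highlighting.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sam_de
#' @export
autoplot.sam_de <- function(object, min_abs_fold = 1.5, max_q = 0.01, ...) {
  floor_q <- 0.5 / max(attr(object, "n_assignments"), 2)
  df <- tibble::tibble(
    log2_fc = object$mean_log2_b - object$mean_log2_a,
    neg_log10_q = -log10(pmax(object$q_value, floor_q)),
    called = abs(object$fold_change) >= min_abs_fold &
      object$q_value < max_q)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, .data$neg_log10_q,
                                   colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(min_abs_fold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q",
                  colour = "passes gates",
                  title = attr(object, "comparison")) +
    ggplot2::theme_minimal()
}

#' Set-size bar chart of a dependency scheme
#'
#' @param object A `dependency_scheme` object.
#' @param final_only Show only the HI/HD/ED/DM sets (default) rather than
#'   every intermediate.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dependency_scheme
#' @export
autoplot.dependency_scheme <- function(object, final_only = TRUE, ...) {
  keep <- if (final_only) {
    intersect(c("Total", "HI", "HD", "ED", "DM"), names(object$sets))
  } else names(object$sets)
  df <- tibble::tibble(
    set = factor(keep, levels = keep),
    size = vapply(object$sets[keep], nrow, integer(1)))
  ggplot2::ggplot(df, ggplot2::aes(.data$set, .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "transcripts") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' @param object An `enrich_result` tibble.
#' @param top Number of top terms to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrich_result
#' @export
autoplot.enrich_result <- function(object, top = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$term_id <- factor(df$term_id, levels = rev(df$term_id))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p_value), .data$term_id,
                                   size = .data$hits_k)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "hits") +
    ggplot2::theme_minimal()
}

#' Tri-state concordance heat map
#'
#' Red/green/white tiles for up/down/none per probe and genotype, the
#' standard view of how a hypoxic response does or does not persist across
#' mutant backgrounds.
#'
#' @param calls Output of [concordance_calls()].
#' @param probes Optional probe subset/order (character vector).
#' @return A ggplot.
#' @export
plot_concordance <- function(calls, probes = NULL) {
  df <- calls
  if (!is.null(probes)) {
    df <- dplyr::filter(df, .data$probe_id %in% probes)
    df$probe_id <- factor(df$probe_id, levels = rev(probes))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$genotype, .data$probe_id,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(up = "firebrick",
                                          down = "darkgreen",
                                          none = "white")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Metabolite heat-map matrix
#'
#' Tiles of log2 group means relative to control normoxia, per compound and
#' genotype-by-oxygen group.
#'
#' @param rel Output of [relative_log2()].
#' @return A ggplot.
#' @export
plot_metabolite_heatmap <- function(rel) {
  df <- dplyr::mutate(rel, group = paste(.data$genotype, .data$oxygen,
                                         sep = "\n"))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$compound,
                                   fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 vs\ncontrol N") +
    ggplot2::theme_minimal()
}
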