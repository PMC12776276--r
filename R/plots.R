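#' Plot a topographic gene map
#'
#' Heatmap of the smoothed (or raw) map in score space, NT on x and DV on
#' y, matching the orientation convention of flat-mount images.
#'
#' @param object A `gene_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot gene_map
autoplot.gene_map <- function(object, ...) {
  df <- tidy(object)
  cx <- (object$x_edges[-1] + object$x_edges[-(object$G + 1)]) / 2
  cy <- (object$y_edges[-1] + object$y_edges[-(object$G + 1)]) / 2
  df$nt <- cx[df$ix]
  df$dv <- cy[df$iy]
  fill <- if (all(is.na(df$smoothed))) "value" else "smoothed"
  ggplot2::ggplot(df[df$valid | !is.na(df[[fill]]), ],
                  ggplot2::aes(x = .data$nt, y = .data$dv, fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "NT score", y = "DV score", fill = object$gene,
                  title = paste0("Topographic map: ", object$gene)) +
    ggplot2::theme_minimal()
}

#' Plot a 1D profile with its dispersion ribbon
#'
#' @param object A `profile_1d`.
#' @param ... Unused.
#' @return A ggplot object; low-confidence positions (when flagged) are
#'   drawn dashed.
#' @export
#' @method autoplot profile_1d
autoplot.profile_1d <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$spread,
                                      ymax = .data$mean + .data$spread),
                         alpha = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = "position", y = "signal") +
    ggplot2::theme_minimal()
  if ("low_confidence" %in% names(df)) {
    p + ggplot2::geom_line(ggplot2::aes(linetype = .data$low_confidence), na.rm = TRUE) +
      ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dashed"),
                                     name = "low confidence")
  } else {
    p + ggplot2::geom_line(na.rm = TRUE)
  }
}

#' Plot a FISH block map
#'
#' @param object A `block_map`.
#' @param ... Unused.
#' @return A ggplot heatmap in micrometer coordinates (origin-relative when
#'   the origin is set).
#' @export
#' @method autoplot block_map
autoplot.block_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = -.data$y_um, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma", na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "NT position (um)", y = "DV position (um)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Volcano plot of region differential expression
#'
#' @param results DE result tibble from [nb_glm_test()].
#' @param top_k,exclude_prefix Passed to [volcano_table()] for labelling.
#' @return A ggplot object with significant genes in red and the top
#'   enriched genes labelled.
#' @export
plot_volcano <- function(results, top_k = 5, exclude_prefix = "LOC") {
  hi <- suppressWarnings(volcano_table(results, top_k, exclude_prefix))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$log2_fc,
                                        y = -log10(.data$q_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::geom_text(data = hi, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "log2 fold change (in / out)", y = "-log10 q") +
    ggplot2::theme_minimal()
}

#' Scatter plot of composite axis scores
#'
#' @param object An `axis_scores` tibble.
#' @param colour Optional gene-free column to colour by (e.g. "embryo_id").
#' @param ... Unused.
#' @return A ggplot of cells in (NT.Score, DV.Score) space.
#' @export
#' @method autoplot axis_scores
autoplot.axis_scores <- function(object, colour = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$nt_score, y = .data$dv_score))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 0.3, alpha = 0.4)
  } else {
    p <- p + ggplot2::geom_point(size = 0.3, alpha = 0.3)
  }
  p + ggplot2::labs(x = "NT score", y = "DV score") + ggplot2::theme_minimal()
}
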