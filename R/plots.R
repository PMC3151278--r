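#' Coverage-probability band plot
#'
#' Plots the reference speed per interval with shaded bands at each CP
#' boundary (light to dark from the widest to the narrowest delta) and the
#' estimates overlaid, one panel style mirroring the per-level validation
#' figures. Intervals can be sorted by increasing reference speed for
#' readability.
#'
#' @param pairs A data.frame with columns `reference`, `estimate` and
#'   optionally `algorithm` (multiple estimators are drawn in different
#'   colours).
#' @param deltas CP boundaries (m/s), innermost first.
#' @param sort Sort intervals by increasing reference speed.
#' @param file Optional output path (written with [ggplot2::ggsave()];
#'   extension selects the device, e.g. `.pdf`).
#' @return The ggplot object, invisibly if `file` is given.
#' @export
plot_cp_bands <- function(pairs, deltas = c(0.1, 0.2, 0.3), sort = TRUE,
                          file = NULL) {
  if (nrow(pairs) == 0L) stop("no pairs to plot")
  if (!"algorithm" %in% names(pairs)) pairs$algorithm <- "estimate"
  ref <- pairs[!duplicated(paste(pairs$reference, pairs$cluster %||% "",
                                 pairs$label %||% "")), , drop = FALSE]
  ord <- if (sort) order(ref$reference) else seq_len(nrow(ref))
  ref <- ref[ord, , drop = FALSE]
  ref$idx <- seq_len(nrow(ref))
  key <- paste(ref$reference, ref$cluster %||% "", ref$label %||% "")
  pairs$idx <- ref$idx[match(paste(pairs$reference, pairs$cluster %||% "",
                                   pairs$label %||% ""), key)]
  bands <- do.call(rbind, lapply(seq_along(deltas), function(k) {
    data.frame(idx = ref$idx, reference = ref$reference,
               delta = deltas[k],
               ymin = pmax(0, ref$reference - deltas[k]),
               ymax = ref$reference + deltas[k])
  }))
  bands$delta <- factor(bands$delta, levels = sort(deltas, decreasing = TRUE))
  greys <- grDevices::grey.colors(length(deltas), start = 0.85, end = 0.45)
  p <- ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = bands,
      ggplot2::aes(x = .data$idx, ymin = .data$ymin, ymax = .data$ymax,
                   group = .data$delta, fill = .data$delta)) +
    ggplot2::scale_fill_manual(values = greys,
                               name = expression(delta ~ "(m/s)")) +
    ggplot2::geom_line(data = ref,
                       ggplot2::aes(x = .data$idx, y = .data$reference),
                       colour = "black", linewidth = 0.8) +
    ggplot2::geom_point(
      data = pairs,
      ggplot2::aes(x = .data$idx, y = .data$estimate,
                   colour = .data$algorithm), size = 1.2) +
    ggplot2::labs(x = "speed interval (sorted)", y = "speed (m/s)",
                  colour = "algorithm") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 5)
    return(invisible(p))
  }
  p
}
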