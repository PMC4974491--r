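#' Plot differential-expression counts over the time course
#'
#' Line plot of the number of significant probes per contrast and time
#' point (the classic DE-burst view of an interferon response).
#'
#' @param counts Tibble from [de_counts()].
#' @return A ggplot object.
#' @export
plot_de_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$timepoint, y = .data$n_de,
                                       colour = .data$contrast)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "differentially expressed probes",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Module-overlap heat map between two conditions
#'
#' Tiles colored by -log10 Fisher p with overlap counts printed, mirroring
#' the cross-condition module-correspondence view.
#'
#' @param overlap `module_overlap` tibble from [overlap_matrix()].
#' @return A ggplot object.
#' @export
plot_module_overlap <- function(overlap) {
  ggplot2::ggplot(overlap, ggplot2::aes(x = .data$module_b, y = .data$module_a,
                                        fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$overlap), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "modules (condition B)", y = "modules (condition A)",
                  fill = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Connectivity-versus-expression scatter plot
#'
#' Scaled-connectivity change against the moderated T-statistic with the
#' class thresholds drawn as dotted guides.
#'
#' @param ct Classification tibble from [classify_genes()].
#' @param k_thresh,t_thresh Guide positions (match the classification call).
#' @return A ggplot object.
#' @export
plot_connectivity <- function(ct, k_thresh = 0.285, t_thresh = 3) {
  pal <- c(expression = "blue", expression_and_connectivity = "red",
           highly_connected = "darkgreen", none = "grey70")
  ggplot2::ggplot(ct[!is.na(ct$delta_k), ],
                  ggplot2::aes(x = .data$delta_k, y = .data$t,
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-k_thresh, k_thresh), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = c(-t_thresh, t_thresh), linetype = "dotted") +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::labs(x = "change in scaled intramodular connectivity",
                  y = "moderated T-statistic", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Enrichment z-score heat map
#'
#' @param zmat `enrichment_matrix` from [enrichment_matrix()].
#' @return A ggplot object (signature x trend-list tiles on a blue-red
#'   scale, zeros white).
#' @export
plot_enrichment <- function(zmat) {
  df <- tibble::as_tibble(as.table(unclass(zmat)), .name_repair = "minimal")
  names(df) <- c("signature", "list", "z")
  df$signature <- factor(df$signature, levels = rownames(zmat))
  df$list <- factor(df$list, levels = colnames(zmat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$list, y = .data$signature,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
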