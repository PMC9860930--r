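# ggplot2 helpers for the main result types.

#' Manhattan-style plot of sweep-window statistics
#'
#' @param windows Window tibble from [sweep_scan()].
#' @param stat `"fst"` or `"pi_ratio"`.
#' @return A ggplot object; flagged top windows are highlighted.
#' @export
plot_sweep_windows <- function(windows, stat = c("fst", "pi_ratio")) {
  stat <- match.arg(stat)
  flag_col <- paste0("top_", stat)
  df <- windows[!is.na(windows[[stat]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data[[stat]],
                                   colour = .data[[flag_col]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "window midpoint (bp)",
                  y = if (stat == "fst") "weighted Fst" else
                    expression(pi ~ "ratio (reference / selected)")) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression results
#'
#' @param results Tibble from [nb_wald_test()].
#' @param lfc_threshold,fdr_threshold DEG thresholds for the guide lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, lfc_threshold = 1, fdr_threshold = 0.05) {
  df <- results[!is.na(results$q_value), ]
  df$deg <- abs(df$log2fc) > lfc_threshold & df$q_value < fdr_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$deg)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param module_trait Tibble (`module`, `trait`, `r`, `p`) from
#'   [module_trait_and_hubs()].
#' @return A ggplot object with correlation tiles annotated `r (p)`.
#' @export
plot_module_trait <- function(module_trait) {
  df <- module_trait
  df$label <- sprintf("%.2f\n(%.2g)", df$r, df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Scale-free fit across candidate soft-threshold powers
#'
#' @param fit_table Tibble from [pick_soft_threshold()].
#' @param target_r2 Horizontal guide (default 0.85).
#' @return A ggplot object.
#' @export
plot_soft_threshold <- function(fit_table, target_r2 = 0.85) {
  ggplot2::ggplot(fit_table, ggplot2::aes(x = .data$power, y = .data$r2)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_text(ggplot2::aes(label = .data$power), size = 3) +
    ggplot2::geom_hline(yintercept = target_r2, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "soft threshold power",
                  y = "signed scale-free fit R²") +
    ggplot2::theme_minimal()
}

#' Bar chart of pathway enrichment
#'
#' @param enrichment Tibble from [hypergeom_enrich()].
#' @param top Number of pathways shown (default 10).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 10) {
  df <- utils::head(enrichment, top)
  df$pathway <- factor(df$pathway, levels = rev(df$pathway))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$pathway,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "-log10 p", y = NULL) +
    ggplot2::theme_minimal()
}
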