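# ggplot2 views of the main result types. These mirror the figures a
# tissue-atlas mining analysis reports: the call heatmap, the tissue
# pyramid, the regulation volcano and the Venn region bars.

#' @exportS3Method ggplot2::autoplot
autoplot.th_calls <- function(object, ...) {
  tokens <- attr(object, "tokens") %||% th_call_tokens
  df <- as_tibble(object)
  df$tissue <- factor(df$tissue, levels = unique(df$tissue))
  df$gene <- factor(df$gene, levels = rev(unique(df$gene)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$gene,
                                   fill = .data$call)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = setNames(c("grey95", "#74add1", "#d73027"), unname(tokens)),
      drop = FALSE, name = "call"
    ) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Trichotomous expression calls") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.th_pyramid <- function(object, ...) {
  df <- as_tibble(object)
  df$tissue <- factor(df$tissue, levels = rev(df$tissue))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_subsets_high,
                                   y = .data$tissue)) +
    ggplot2::geom_col(fill = "#d73027") +
    ggplot2::geom_col(ggplot2::aes(x = .data$n_subsets_expressed),
                      alpha = 0.25, fill = "#74add1") +
    ggplot2::labs(x = "Th subsets with >=1 high (red) / expressed (blue) regulator",
                  y = NULL, title = "Tissue pyramid") +
    ggplot2::theme_minimal(base_size = 10)
}

#' @exportS3Method ggplot2::autoplot
autoplot.th_diff <- function(object, ...) {
  df <- as_tibble(object)
  if (!"p" %in% names(df)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sfc, y = .data$gene,
                                          colour = .data$call)) +
      ggplot2::geom_point(na.rm = TRUE)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sfc,
                                          y = -log10(.data$p),
                                          colour = .data$call)) +
      ggplot2::geom_point(alpha = 0.6)
  }
  p +
    ggplot2::scale_colour_manual(
      values = c(UP = "#d73027", DOWN = "#4575b4", UNCHANGED = "grey70"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "signed fold change",
                  title = "Case vs control regulation") +
    ggplot2::theme_minimal(base_size = 10)
}

#' @exportS3Method ggplot2::autoplot
autoplot.th_venn <- function(object, ...) {
  df <- as_tibble(object)
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n,
                                   fill = factor(.data$degree))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "degree") +
    ggplot2::labs(x = NULL, y = "items exclusive to region",
                  title = "Exact Venn regions") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
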