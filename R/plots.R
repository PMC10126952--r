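#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

apobec_palette <- function(sig, apobec) {
  ifelse(sig %in% apobec, "APOBEC", "other")
}

#' Plot per-tumor signature weights
#'
#' Box plot of normalized signature weights across tumors, one box per
#' signature, sorted by descending mean weight; APOBEC-tagged signatures
#' are highlighted in red.
#'
#' @param object A `signature_fit`.
#' @param apobec Character vector of signature names to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_fit
#' @export
autoplot.signature_fit <- function(object,
                                   apobec = grep("APOBEC",
                                                 object$catalog$names,
                                                 value = TRUE),
                                   ...) {
  long <- tidy(object)
  ord <- mean_signature_weights(object)$signature
  long$signature <- factor(long$signature, levels = ord)
  long$group <- apobec_palette(as.character(long$signature), apobec)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$signature, y = .data$weight,
                                     colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.35, size = 0.8) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA) +
    ggplot2::scale_colour_manual(values = c(APOBEC = "red", other = "black"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "signature weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot effect-size estimates
#'
#' Point plot of estimated cancer effect sizes (log scale) for each
#' recurrent variant, labelled by gene, unbounded estimates marked.
#'
#' @param object An `effect_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot effect_fit
#' @export
autoplot.effect_fit <- function(object, ...) {
  est <- tidy(object)
  est$label <- paste0(est$gene, " ", est$variant_key)
  est$label <- factor(est$label, levels = rev(est$label))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$gamma_hat, y = .data$label,
                                    shape = .data$unbounded)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "cancer effect size (gamma)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mean relative attributable effect per signature
#'
#' Bar plot of the mean share of per-tumor total attributed effect carried
#' by each signature, in descending order; APOBEC-tagged signatures in
#' red.
#'
#' @param records Attribution tibble from [attribute_effects()].
#' @param apobec Signature names to highlight.
#' @return A ggplot object.
#' @export
plot_attributable_effects <- function(records,
                                      apobec = grep("APOBEC",
                                                    unique(records$signature),
                                                    value = TRUE)) {
  means <- mean_relative_attributable_effect(records)
  means$signature <- factor(means$signature, levels = means$signature)
  means$group <- apobec_palette(as.character(means$signature), apobec)
  ggplot2::ggplot(means, ggplot2::aes(x = .data$signature,
                                      y = .data$mean_relative_effect,
                                      fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(APOBEC = "red", other = "grey30"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "mean relative attributable effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-variant proportionate effects by signature
#'
#' One point per carrier tumor, per (variant, signature) pair, showing the
#' proportionate attributable effect; variants ordered by descending median.
#'
#' @param records Attribution tibble from [attribute_effects()].
#' @param apobec Signature names to highlight.
#' @param top_n Show only the top variants by median (default 20).
#' @return A ggplot object.
#' @export
plot_variant_effects <- function(records,
                                 apobec = grep("APOBEC",
                                               unique(records$signature),
                                               value = TRUE),
                                 top_n = 20L) {
  tab <- variant_signature_table(records)
  keep <- utils::head(unique(tab$variant_key), top_n)
  pts <- records[records$variant_key %in% keep, , drop = FALSE]
  pts$label <- paste0(pts$gene, " ", pts$variant_key)
  ord <- unique(paste0(tab$gene, " ", tab$variant_key))
  pts$label <- factor(pts$label, levels = rev(intersect(ord, pts$label)))
  pts$group <- apobec_palette(pts$signature, apobec)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$proportionate_effect,
                                    y = .data$label, colour = .data$group)) +
    ggplot2::geom_jitter(height = 0.15, alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(APOBEC = "red", other = "black")) +
    ggplot2::labs(x = "proportionate attributable effect", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
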