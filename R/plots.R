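#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style plot of a sex-bias classification
#'
#' @param object A [classify_sex_bias()] table.
#' @param ... Unused.
#' @return A ggplot: log2 fold change (male-positive) against -log10 adjusted
#'   p, coloured by category, faceted by chromosome class.
#' @export
autoplot.sex_bias_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$adj_pvalue, 1e-300)),
                                   colour = .data$category)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom_class), scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(male = "#2166ac",
                                            female = "#b2182b",
                                            unbiased = "grey60")) +
    ggplot2::labs(x = "log2 fold change (male / female)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Morph expression profiles for sex-biased gene sets
#'
#' Distribution of per-gene mean log2 expression for each morph, split by
#' bias category (and bias quartile when available) — the standard view of
#' demasculinization and feminization of the intermediate morph.
#'
#' @param ms A [morph_means()] summary.
#' @param sbt A [classify_sex_bias()] table (quartile column used if filled).
#' @param chrom_class Chromosome class to show (default `"autosome"`).
#' @return A ggplot of boxplots per morph, faceted by category/quartile.
#' @export
plot_morph_expression <- function(ms, sbt, chrom_class = "autosome") {
  use_quart <- !all(is.na(sbt$quartile))
  sets <- list()
  for (cat in c("male", "female")) {
    if (use_quart) {
      for (q in 1:4) {
        ids <- sbt_gene_set(sbt, cat, q, chrom_class)
        if (length(ids)) sets[[paste0(cat, " Q", q)]] <- ids
      }
    } else {
      ids <- sbt_gene_set(sbt, cat, NULL, chrom_class)
      if (length(ids)) sets[[paste0(cat, "-biased")]] <- ids
    }
  }
  df <- purrr::imap(sets, function(ids, nm) {
    ms[ms$gene_id %in% ids, ] |>
      tidyr::pivot_longer(dplyr::all_of(.MORPHS), names_to = "morph",
                          values_to = "log2_expr") |>
      mutate(set = nm)
  }) |> bind_rows() |>
    mutate(morph = factor(.data$morph, levels = .MORPHS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$morph, y = .data$log2_expr,
                                   fill = .data$morph)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$set), nrow = 2) +
    ggplot2::scale_fill_manual(values = c(female = "#b2182b",
                                          subordinate = "#92c5de",
                                          dominant = "#2166ac")) +
    ggplot2::labs(x = NULL, y = "average log2 expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bar plot of a three-morph Venn partition
#'
#' @param object A [presence_venn()] result.
#' @param ... Unused.
#' @return A ggplot of region counts.
#' @export
autoplot.venn_partition <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(region = factor(.data$region, levels = rev(.VENN_REGIONS)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$region)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.1, size = 3) +
    ggplot2::labs(x = "genes", y = NULL,
                  title = sprintf("%.1f%% expressed in all three morphs",
                                  attr(object, "pct_all_three"))) +
    ggplot2::theme_minimal()
}

#' Point-range plot of category-level dN, dS and dN/dS
#'
#' @param object An [aggregate_dnds()] / [bootstrap_dnds_ci()] table.
#' @param ... Unused.
#' @return A ggplot with one panel per statistic (intervals shown when
#'   bootstrap columns are present).
#' @export
autoplot.category_dnds <- function(object, ...) {
  df <- as_tibble(object)
  long <- tibble(
    category = rep(df$category, 3),
    stat = rep(c("dN", "dS", "dN/dS"), each = nrow(df)),
    value = c(df$dn, df$ds, df$dnds),
    lo = if ("dn_lo" %in% names(df)) c(df$dn_lo, df$ds_lo, df$dnds_lo) else NA,
    hi = if ("dn_hi" %in% names(df)) c(df$dn_hi, df$ds_hi, df$dnds_hi) else NA)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stat), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!all(is.na(long$lo))) {
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo,
                                                 ymax = .data$hi), width = 0.2)
  }
  p
}

#' Sample positions in factor space
#'
#' @param object A [factor_analysis()] result.
#' @param ... Unused.
#' @return A ggplot of the first two factor loadings per sample, coloured by
#'   morph.
#' @export
autoplot.factor_result <- function(object, ...) {
  load <- object$loadings
  df <- tibble(sample_id = rownames(load),
               f1 = load[, 1],
               f2 = if (ncol(load) > 1) load[, 2] else 0) |>
    left_join(object$samples, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f1, y = .data$f2,
                                   colour = .data$morph)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(female = "#b2182b",
                                            subordinate = "#92c5de",
                                            dominant = "#2166ac")) +
    ggplot2::labs(
      x = sprintf("factor 1 (%.1f%%)", 100 * object$var_explained[1]),
      y = if (ncol(load) > 1)
        sprintf("factor 2 (%.1f%%)", 100 * object$var_explained[2]) else "",
      colour = NULL) +
    ggplot2::theme_minimal()
}
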