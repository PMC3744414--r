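#' Remove non- and lowly-expressed genes
#'
#' A gene is retained when, in at least one morph group (within each tissue),
#' at least `min_group_fraction` of that group's samples express it at or above
#' `threshold_per_million` reads per million mappable reads. This keeps genes
#' expressed in only one morph, which the presence analysis requires, while
#' dropping genes whose counts are dominated by sampling noise.
#'
#' @param cm A [count_matrix()].
#' @param threshold_per_million Minimum expression in reads per million
#'   mappable reads (default 4).
#' @param min_group_fraction Fraction of a morph's samples that must reach the
#'   threshold (default 0.5).
#' @return A filtered [count_matrix()]. Warns (does not error) if nothing
#'   survives.
#' @export
filter_expressed <- function(cm, threshold_per_million = 4,
                             min_group_fraction = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  libs <- library_sizes(cm)
  if (any(libs <= 0)) abort("library sizes must be positive")
  cpm <- sweep(cm$counts, 2, libs / 1e6, "/")
  ok <- cpm >= threshold_per_million

  groups <- interaction(cm$samples$morph, cm$samples$tissue, drop = TRUE)
  keep <- rep(FALSE, nrow(cm$counts))
  for (g in levels(groups)) {
    cols <- which(groups == g)
    keep <- keep | rowMeans(ok[, cols, drop = FALSE]) >= min_group_fraction
  }
  if (!any(keep)) warn("no genes pass the expression filter")
  subset_genes(cm, which(keep))
}

#' FPKM and log2 expression from raw counts
#'
#' FPKM corrects for gene length and sequencing depth:
#' `fpkm[g, s] = count[g, s] * 1e9 / (library_size[s] * exonic_length[g])`.
#' Log2 expression is `log2(fpkm + pseudocount)`; with the default pseudocount
#' of 1 FPKM, a zero count maps to log2 expression 0.
#'
#' @param cm A [count_matrix()].
#' @param pseudocount Added to FPKM before taking log2 (default 1).
#' @return An object of class `expression_matrix`: list with `fpkm` and
#'   `log2_expr` matrices, `library_sizes`, and the `samples`/`genes` tibbles.
#' @export
compute_fpkm <- function(cm, pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  libs <- library_sizes(cm)
  if (any(libs <= 0)) abort("library sizes must be positive")
  len <- cm$genes$exonic_length
  fpkm <- cm$counts * 1e9 / outer(len, libs)
  structure(list(
    fpkm = fpkm,
    log2_expr = log2(fpkm + pseudocount),
    library_sizes = libs,
    samples = cm$samples,
    genes = cm$genes,
    pseudocount = pseudocount
  ), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (pseudocount %g)\n",
              nrow(x$fpkm), ncol(x$fpkm), x$pseudocount))
  invisible(x)
}

#' Per-gene average log2 expression for each morph
#'
#' Arithmetic mean of log2 expression over exactly the samples of each morph
#' (within one tissue).
#'
#' @param em An [compute_fpkm()] result.
#' @param tissue Tissue to summarise; may be omitted when only one is present.
#' @return A `morph_summary` tibble with columns `gene_id`, `chrom_class`,
#'   `female`, `subordinate`, `dominant`; group sizes are kept in the
#'   `n_samples` attribute.
#' @export
morph_means <- function(em, tissue = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  samples <- em$samples
  tissues <- unique(samples$tissue)
  if (is.null(tissue)) {
    if (length(tissues) > 1) abort("multiple tissues present; pass `tissue`")
    tissue <- tissues
  }
  sel <- samples$tissue == tissue
  samples <- samples[sel, ]
  expr <- em$log2_expr[, sel, drop = FALSE]

  missing <- setdiff(.MORPHS, unique(samples$morph))
  if (length(missing)) {
    abort(paste0("morph absent from tissue ", tissue, ": ", toString(missing)))
  }
  means <- vapply(.MORPHS, function(m) {
    unname(rowMeans(expr[, samples$morph == m, drop = FALSE]))
  }, numeric(nrow(expr)))

  out <- tibble(gene_id = em$genes$gene_id,
                chrom_class = em$genes$chrom_class,
                female = means[, "female"],
                subordinate = means[, "subordinate"],
                dominant = means[, "dominant"])
  attr(out, "n_samples") <- table(samples$morph)[.MORPHS]
  attr(out, "tissue") <- tissue
  class(out) <- c("morph_summary", class(out))
  out
}
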