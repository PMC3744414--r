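sbt_gene_set <- function(sbt, category, quartile = NULL,
                         chrom_class = NULL) {
  stopifnot(inherits(sbt, "sex_bias_table"))
  if (!is.null(chrom_class)) sbt <- sbt[sbt$chrom_class %in% chrom_class, ]
  if (is.null(quartile)) {
    sbt$gene_id[sbt$category == category]
  } else {
    # quartile sets drop the fold-change criterion: membership is by direction
    dir <- if (category == "male") 1 else -1
    sbt$gene_id[!is.na(sbt$quartile) & sbt$quartile == quartile &
                  sign(sbt$log2fc) == dir]
  }
}

#' Paired rank test for demasculinization / feminization
#'
#' Compares subordinate-male against dominant-male per-gene mean log2
#' expression across a gene set (a bias category, or one bias-magnitude
#' quartile) with a two-sided Wilcoxon test. The gene sets are identical in
#' both morphs, so the signed-rank (paired) form is the default; an unpaired
#' rank-sum variant is available. A male-biased set expressed lower in
#' subordinates is reported as demasculinized; a female-biased set expressed
#' higher as feminized.
#'
#' @param ms A [morph_means()] summary.
#' @param sbt A [classify_sex_bias()] table (after [quartile_bins()] when
#'   `quartile` is used).
#' @param category `"male"` or `"female"`.
#' @param quartile Optional quartile number (1-4); when given, membership uses
#'   the quartile binning (significance only, no fold threshold).
#' @param chrom_class Chromosome class(es) to include (default `"autosome"`).
#' @param method `"signed_rank"` (paired, default) or `"rank_sum"`.
#' @return One-row tibble: gene-set size, per-morph means, mean
#'   subordinate-minus-dominant shift, test statistic, p-value, and direction
#'   (`"demasculinized"`, `"feminized"`, or `"none"`).
#' @export
demasc_fem_test <- function(ms, sbt, category = c("male", "female"),
                            quartile = NULL, chrom_class = "autosome",
                            method = c("signed_rank", "rank_sum")) {
  category <- match.arg(category)
  method <- match.arg(method)
  ids <- sbt_gene_set(sbt, category, quartile, chrom_class)
  rows <- ms[ms$gene_id %in% ids, ]
  if (nrow(rows) == 0) abort("empty gene set")
  if (nrow(rows) < 5) warn("fewer than 5 genes in set; test is unreliable")

  d <- rows$subordinate - rows$dominant
  if (all(d == 0)) {
    stat <- 0; p <- 1
  } else if (method == "signed_rank") {
    wt <- suppressWarnings(wilcox.test(rows$subordinate, rows$dominant,
                                       paired = TRUE))
    stat <- unname(wt$statistic); p <- wt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(rows$subordinate, rows$dominant))
    stat <- unname(wt$statistic); p <- wt$p.value
  }

  shift <- mean(d)
  direction <- "none"
  if (p < 0.05) {
    if (category == "male" && shift < 0) direction <- "demasculinized"
    if (category == "female" && shift > 0) direction <- "feminized"
  }
  tibble(category = category,
         quartile = if (is.null(quartile)) NA_integer_ else as.integer(quartile),
         n_genes = nrow(rows),
         mean_female = mean(rows$female),
         mean_subordinate = mean(rows$subordinate),
         mean_dominant = mean(rows$dominant),
         shift_sub_vs_dom = shift,
         statistic = stat,
         p_value = p,
         direction = direction)
}

#' Regression of male-morph expression divergence on bias degree
#'
#' Ordinary least squares of the per-gene difference between dominant and
#' subordinate male mean log2 expression on the signed degree of female bias
#' (log2 fold change oriented female-positive), over all sex-biased genes.
#' A non-zero slope indicates that dominant and subordinate transcription
#' decouple as sex bias grows.
#'
#' @param ms A [morph_means()] summary.
#' @param sbt A [classify_sex_bias()] table.
#' @param chrom_class Chromosome class(es) to include (default all).
#' @return A `decoupling_fit` object; see [tidy.decoupling_fit()] and
#'   [glance.decoupling_fit()].
#' @export
decoupling_regression <- function(ms, sbt, chrom_class = NULL) {
  if (!is.null(chrom_class)) sbt <- sbt[sbt$chrom_class %in% chrom_class, ]
  sel <- sbt[sbt$category %in% c("male", "female") & is.finite(sbt$log2fc), ]
  if (nrow(sel) < 10) abort("need at least 10 sex-biased genes")
  rows <- ms[match(sel$gene_id, ms$gene_id), ]
  y <- rows$dominant - rows$subordinate
  x <- -sel$log2fc  # female-positive orientation
  if (var(x) == 0) abort("zero variance in bias degree")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  degenerate <- var(y) == 0  # subordinate identical to dominant
  structure(list(
    model = fit,
    n = length(y),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (degenerate) 0 else sm$r.squared,
    p_value = if (degenerate) 1 else sm$coefficients[2, 4]
  ), class = "decoupling_fit")
}

#' @export
print.decoupling_fit <- function(x, ...) {
  cat(sprintf("<decoupling_fit> n = %d, slope = %.4f, r2 = %.4f, p = %.3g\n",
              x$n, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Compare decoupling slopes between chromosome classes
#'
#' Among male-biased genes, regresses the dominant-minus-subordinate
#' expression difference on the degree of male bias separately for each
#' chromosome class, with 95% t-intervals on the slopes and a flag for
#' whether the intervals overlap.
#'
#' @param ms A [morph_means()] summary.
#' @param sbt A [classify_sex_bias()] table.
#' @param min_genes Classes with fewer male-biased genes are skipped with a
#'   warning (default 10).
#' @return Tibble with one row per class: `chrom_class`, `n`, `slope`,
#'   `ci_lo`, `ci_hi`; attribute `overlap` is `TRUE` when all pairwise
#'   intervals intersect.
#' @export
slope_compare <- function(ms, sbt, min_genes = 10) {
  res <- list()
  for (cls in unique(sbt$chrom_class)) {
    sel <- sbt[sbt$chrom_class == cls & sbt$category == "male" &
                 is.finite(sbt$log2fc), ]
    if (nrow(sel) < min_genes) {
      warn(paste0("skipping class with too few male-biased genes: ", cls))
      next
    }
    rows <- ms[match(sel$gene_id, ms$gene_id), ]
    fit <- lm(I(rows$dominant - rows$subordinate) ~ sel$log2fc)
    ci <- confint(fit)[2, ]
    res[[cls]] <- tibble(chrom_class = cls, n = nrow(sel),
                         slope = unname(coef(fit)[2]),
                         ci_lo = ci[1], ci_hi = ci[2])
  }
  if (!length(res)) abort("no chromosome class had enough male-biased genes")
  out <- bind_rows(res)
  overlap <- TRUE
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
      overlap <- overlap &&
        out$ci_lo[i] <= out$ci_hi[j] && out$ci_lo[j] <= out$ci_hi[i]
    }
  }
  attr(out, "overlap") <- overlap
  out
}

#' Spearman correlation matrix across the three morphs
#'
#' Rank correlation of per-gene mean expression between every pair of morphs,
#' over the genes of one bias category (or a caller-supplied gene set).
#'
#' @param ms A [morph_means()] summary.
#' @param sbt A [classify_sex_bias()] table; ignored when `genes` is given.
#' @param category `"male"`, `"female"`, `"unbiased"`, or `"all"`.
#' @param chrom_class Chromosome class(es) to include (default `"autosome"`).
#' @param genes Optional explicit gene ids.
#' @return A `morph_cor` object: the 3x3 rho matrix plus the gene count `n`.
#' @export
spearman_morph_matrix <- function(ms, sbt = NULL, category = "all",
                                  chrom_class = "autosome", genes = NULL) {
  if (is.null(genes)) {
    rows <- ms
    if (!is.null(chrom_class)) rows <- rows[rows$chrom_class %in% chrom_class, ]
    if (category != "all") {
      if (is.null(sbt)) abort("pass `sbt` when selecting by category")
      ids <- sbt$gene_id[sbt$category == category]
      rows <- rows[rows$gene_id %in% ids, ]
    }
  } else {
    rows <- ms[ms$gene_id %in% genes, ]
  }
  if (nrow(rows) < 10) abort("need at least 10 genes")
  m <- as.matrix(rows[, .MORPHS])
  if (any(apply(m, 2, var) == 0)) abort("constant expression vector")
  rho <- cor(m, method = "spearman")
  structure(list(rho = rho, n = nrow(rows), category = category),
            class = "morph_cor")
}

#' @export
print.morph_cor <- function(x, ...) {
  cat(sprintf("<morph_cor> category = %s, n = %d genes\n", x$category, x$n))
  print(round(x$rho, 3))
  invisible(x)
}

#' Fisher r-to-z comparison of two correlations
#'
#' Tests equality of two independent correlation coefficients via
#' `z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param rho1,rho2 Correlation coefficients.
#' @param n1,n2 Numbers of observations behind each coefficient.
#' @return Tibble with `z` and the two-sided `p_value`.
#' @export
fisher_rz <- function(rho1, n1, rho2, n2) {
  stopifnot(n1 > 3, n2 > 3, abs(rho1) < 1, abs(rho2) < 1)
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

.VENN_REGIONS <- c("female_only", "subordinate_only", "dominant_only",
                   "female_subordinate", "female_dominant",
                   "subordinate_dominant", "all_three")

#' Build a three-morph Venn partition from region counts
#'
#' @param counts Named numeric vector or list with entries `female_only`,
#'   `subordinate_only`, `dominant_only`, `female_subordinate`,
#'   `female_dominant`, `subordinate_dominant`, `all_three` (exclusive region
#'   counts).
#' @return A `venn_partition` tibble (one row per region, membership flags and
#'   `n`), with attributes `total` and `pct_all_three` (percentage of genes
#'   present in all three morphs, one decimal).
#' @export
venn_partition <- function(counts) {
  counts <- unlist(counts)
  miss <- setdiff(.VENN_REGIONS, names(counts))
  if (length(miss)) abort(paste0("missing region count(s): ", toString(miss)))
  counts <- counts[.VENN_REGIONS]
  member <- matrix(c(
    1, 0, 0,
    0, 1, 0,
    0, 0, 1,
    1, 1, 0,
    1, 0, 1,
    0, 1, 1,
    1, 1, 1), ncol = 3, byrow = TRUE)
  out <- tibble(region = .VENN_REGIONS,
                female = member[, 1] == 1,
                subordinate = member[, 2] == 1,
                dominant = member[, 3] == 1,
                n = as.numeric(counts))
  total <- sum(out$n)
  attr(out, "total") <- total
  attr(out, "pct_all_three") <- round(100 * counts[["all_three"]] / total, 1)
  class(out) <- c("venn_partition", class(out))
  out
}

#' Partition expressed genes by presence across the three morphs
#'
#' A gene is "present" in a morph when at least `min_fraction` of that morph's
#' samples show at least `min_count` reads (expressed to some degree). Every
#' expressed gene then falls in exactly one of the 7 regions of the three-set
#' Venn diagram.
#'
#' @param cm A filtered [count_matrix()].
#' @param tissue Tissue to partition; may be omitted when only one is present.
#' @param chrom_class Optional restriction (e.g. `"autosome"`).
#' @param min_count,min_fraction Presence rule (defaults 1 read, half the
#'   samples).
#' @return A [venn_partition()] with an extra `genes` attribute: per-region
#'   gene-id lists (morph-limited lists included).
#' @export
presence_venn <- function(cm, tissue = NULL, chrom_class = NULL,
                          min_count = 1, min_fraction = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  cm <- select_tissue(cm, tissue)
  if (!is.null(chrom_class)) {
    cm <- subset_genes(cm, which(cm$genes$chrom_class %in% chrom_class))
  }
  present <- vapply(.MORPHS, function(m) {
    cols <- cm$samples$morph == m
    rowMeans(cm$counts[, cols, drop = FALSE] >= min_count) >= min_fraction
  }, logical(nrow(cm$counts)))

  key <- paste0(present[, "female"] + 0, present[, "subordinate"] + 0,
                present[, "dominant"] + 0)
  region_key <- c(female_only = "100", subordinate_only = "010",
                  dominant_only = "001", female_subordinate = "110",
                  female_dominant = "101", subordinate_dominant = "011",
                  all_three = "111")
  counts <- vapply(region_key, function(k) sum(key == k), numeric(1))
  names(counts) <- names(region_key)
  out <- venn_partition(counts)
  attr(out, "genes") <- lapply(region_key, function(k) {
    rownames(cm$counts)[key == k]
  })
  attr(out, "n_absent") <- sum(key == "000")
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> %d genes, %.1f%% present in all three morphs\n",
              attr(x, "total"), attr(x, "pct_all_three")))
  NextMethod()
}

#' Two-proportion z-test for shared-gene counts
#'
#' Compares two counts of shared genes as proportions of their candidate
#' pools, using the pooled-variance two-proportion z statistic, and reports
#' the count ratio.
#'
#' @param count1,count2 Shared-gene counts.
#' @param pool1,pool2 Sizes of the gene pools each count was drawn from.
#' @return Tibble: `ratio` (`count1/count2`), `prop1`, `prop2`, `z`,
#'   `p_value` (two-sided).
#' @export
shared_gene_ztest <- function(count1, count2, pool1, pool2) {
  if (pool1 <= 0 || pool2 <= 0) abort("pools must be positive")
  if (count1 > pool1 || count2 > pool2) abort("counts cannot exceed pools")
  p1 <- count1 / pool1; p2 <- count2 / pool2
  pp <- (count1 + count2) / (pool1 + pool2)
  se <- sqrt(pp * (1 - pp) * (1 / pool1 + 1 / pool2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble(ratio = count1 / count2, prop1 = p1, prop2 = p2,
         z = z, p_value = min(1, 2 * pnorm(-abs(z))))
}
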