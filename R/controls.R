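#' Recompute relative expression after removing male-biased reads
#'
#' RNA-seq measures relative, not absolute, expression: a genuine drop in
#' male-biased transcription in one morph inflates the apparent expression of
#' every other gene in that morph. This control removes all reads mapping to
#' male-biased genes in every sample, recomputes per-sample library sizes as
#' the remaining totals, and re-derives FPKM, so that feminization tests on
#' female-biased and unbiased genes can be re-run free of that compositional
#' artifact. (Reads are removed at the gene level; multimapping-driven
#' redistribution of reads is assumed negligible.)
#'
#' @param cm The [count_matrix()] the bias table was derived from.
#' @param sbt A [classify_sex_bias()] table on the same gene universe.
#' @param pseudocount Passed to [compute_fpkm()].
#' @return An `expression_matrix` over the non-male-biased genes, with the
#'   removed gene ids in attribute `removed_genes`.
#' @export
renormalize_without_malebiased <- function(cm, sbt, pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  male_ids <- sbt$gene_id[sbt$category == "male"]
  is_male <- cm$genes$gene_id %in% male_ids
  if (all(is_male)) abort("all genes are male-biased; nothing left to renormalize")

  removed <- colSums(cm$counts[is_male, , drop = FALSE])
  out <- subset_genes(cm, which(!is_male))
  libs <- library_sizes(cm) - removed
  out$samples$library_size <- unname(libs)
  em <- compute_fpkm(out, pseudocount = pseudocount)
  attr(em, "removed_genes") <- cm$genes$gene_id[is_male]
  em
}

#' Resampling control against regression toward the mean
#'
#' Genes selected as sex-biased because of sampling noise in the defining
#' samples will look less extreme in held-out samples ("regression toward the
#' mean"), which could mimic an intermediate subordinate transcriptome. This
#' control repeatedly (1) picks `n_define` dominant-male and `n_define` female
#' samples at random and defines sex-bias on them alone (fold threshold +
#' adjusted p), then (2) compares, across each newly defined gene set, the
#' defining samples against the held-out samples of the same morph (a pure
#' regression-toward-the-mean read-out) and the subordinate males against the
#' held-out dominants (the biological contrast), by paired Wilcoxon tests on
#' per-gene mean log2 expression. Within each iteration p-values are
#' Bonferroni-adjusted across all tests performed.
#'
#' @param cm A filtered [count_matrix()] (one tissue).
#' @param n_iter Number of random sample combinations (default 100).
#' @param n_define Defining samples per morph (default 3).
#' @param fc_threshold,alpha Bias definition applied within each iteration.
#' @param tissue Tissue; may be omitted when only one is present.
#' @param seed Optional integer; makes the iteration record reproducible.
#' @param pseudocount Passed to [compute_fpkm()].
#' @param ... Passed to [nb_test()] via [classify_sex_bias()].
#' @return An `rtm_result` list: `iterations` (one row per iteration, gene-set
#'   and contrast, with raw and Bonferroni-adjusted p) and `summary` (per
#'   contrast and gene set, counts of raw- and Bonferroni-significant
#'   outcomes at `alpha`).
#' @export
rtm_randomization <- function(cm, n_iter = 100, n_define = 3,
                              fc_threshold = 2, alpha = 0.05,
                              tissue = NULL, seed = NULL,
                              pseudocount = 1, ...) {
  stopifnot(inherits(cm, "count_matrix"))
  cm <- select_tissue(cm, tissue)
  if (!is.null(seed)) set.seed(seed)

  dom_ids <- cm$samples$sample_id[cm$samples$morph == "dominant"]
  fem_ids <- cm$samples$sample_id[cm$samples$morph == "female"]
  sub_ids <- cm$samples$sample_id[cm$samples$morph == "subordinate"]
  if (length(dom_ids) < n_define + 2 || length(fem_ids) < n_define + 2) {
    abort(sprintf("need at least %d dominant and %d female samples",
                  n_define + 2, n_define + 2))
  }

  em <- compute_fpkm(cm, pseudocount = pseudocount)
  expr <- em$log2_expr

  one_iter <- function(it) {
    def_dom <- sort(sample(dom_ids, n_define))
    def_fem <- sort(sample(fem_ids, n_define))
    held_dom <- setdiff(dom_ids, def_dom)
    held_fem <- setdiff(fem_ids, def_fem)

    cm_def <- subset_samples(cm, c(def_fem, def_dom))
    sbt <- classify_sex_bias(cm_def, fc_threshold = fc_threshold,
                             alpha = alpha, ...)
    gene_means <- function(ids) rowMeans(expr[, ids, drop = FALSE])
    mean_def_dom <- gene_means(def_dom); mean_held_dom <- gene_means(held_dom)
    mean_def_fem <- gene_means(def_fem); mean_held_fem <- gene_means(held_fem)
    mean_sub <- gene_means(sub_ids)

    rows <- list()
    for (set in c("male", "female")) {
      idx <- which(cm$genes$gene_id %in% sbt$gene_id[sbt$category == set])
      contrasts <- list(
        dominant_vs_dominant = c("mean_def_dom", "mean_held_dom"),
        female_vs_female = c("mean_def_fem", "mean_held_fem"),
        subordinate_vs_dominant = c("mean_sub", "mean_held_dom"))
      for (cn in names(contrasts)) {
        a <- get(contrasts[[cn]][1])[idx]
        b <- get(contrasts[[cn]][2])[idx]
        p <- if (length(idx) < 5 || all(a == b)) 1 else
          suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
        rows[[length(rows) + 1]] <- tibble(
          iteration = it, gene_set = set, contrast = cn,
          n_genes = length(idx), p_raw = p,
          defining_dominant = paste(def_dom, collapse = ","),
          defining_female = paste(def_fem, collapse = ","))
      }
    }
    out <- bind_rows(rows)
    out$p_bonf <- pmin(1, out$p_raw * nrow(out))
    out
  }

  iterations <- purrr::map(seq_len(n_iter), one_iter) |> bind_rows()
  summary <- iterations |>
    group_by(.data$gene_set, .data$contrast) |>
    summarise(n_iter = n(),
              n_sig_raw = sum(.data$p_raw < alpha),
              n_sig_bonf = sum(.data$p_bonf < alpha),
              .groups = "drop")
  structure(list(iterations = iterations, summary = summary,
                 n_iter = n_iter, n_define = n_define, alpha = alpha),
            class = "rtm_result")
}

#' @export
print.rtm_result <- function(x, ...) {
  cat(sprintf("<rtm_result> %d iterations, %d defining samples per morph\n",
              x$n_iter, x$n_define))
  print(x$summary)
  invisible(x)
}

#' Annotate genes with upstream androgen binding-site proximity
#'
#' For each gene, finds the nearest predicted androgen transcription-factor
#' binding site strictly upstream of the transcription start (5' of the TSS on
#' the gene's strand, midpoint rule) and flags membership in 2 kb, 5 kb and
#' 10 kb upstream windows.
#'
#' @param genes Gene sheet tibble with `gene_id`, `tss_coordinate` (1-based),
#'   `strand` (`+`/`-`) and a `chrom` column (falls back to `chrom_class`).
#' @param tfbs Either a path to a BED file (0-based half-open; read with
#'   `rtracklayer`) or a tibble with `chrom`, `start`, `end` in BED
#'   convention.
#' @param windows Upstream window widths in bp.
#' @return A `motif_annotation` tibble: `gene_id`, `distance_upstream` (bp to
#'   nearest upstream site midpoint, `NA` when none) and one logical
#'   `within_<w>` column per window. Flags are monotone in window size.
#' @export
annotate_motifs <- function(genes, tfbs, windows = c(2000, 5000, 10000)) {
  genes <- as_tibble(genes)
  need <- setdiff(c("gene_id", "tss_coordinate", "strand"), names(genes))
  if (length(need)) abort(paste0("gene sheet missing: ", toString(need)))
  chrom_col <- if ("chrom" %in% names(genes)) "chrom" else "chrom_class"

  if (is.character(tfbs) && length(tfbs) == 1) {
    gr <- rtracklayer::import(tfbs)
    sites <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                    mid = (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
  } else {
    tfbs <- as_tibble(tfbs)
    # BED: 0-based half-open; midpoint in 1-based coordinates
    sites <- tibble(chrom = tfbs$chrom, mid = (tfbs$start + tfbs$end + 1) / 2)
  }
  if (any(sites$mid < 0)) {
    warn("binding-site interval before chromosome start; clipping")
    sites$mid <- pmax(sites$mid, 0)
  }

  dist <- rep(NA_real_, nrow(genes))
  by_chrom <- split(sites$mid, sites$chrom)
  for (ch in names(by_chrom)) {
    mids <- sort(by_chrom[[ch]])
    gi <- which(genes[[chrom_col]] == ch)
    if (!length(gi)) next
    tss <- genes$tss_coordinate[gi]
    plus <- genes$strand[gi] == "+"
    # "+" strand: nearest midpoint below TSS; "-" strand: nearest above
    idx_below <- findInterval(tss - 1e-9, mids)
    d_plus <- ifelse(idx_below >= 1, tss - mids[pmax(idx_below, 1)], NA_real_)
    idx_above <- findInterval(tss + 1e-9, mids) + 1
    d_minus <- ifelse(idx_above <= length(mids),
                      mids[pmin(idx_above, length(mids))] - tss, NA_real_)
    dist[gi] <- ifelse(plus, d_plus, d_minus)
  }
  dist[!is.na(dist) & dist <= 0] <- NA_real_  # strictly upstream only

  out <- tibble(gene_id = genes$gene_id, distance_upstream = dist)
  for (w in sort(windows)) {
    out[[paste0("within_", w)]] <- !is.na(dist) & dist < w
  }
  class(out) <- c("motif_annotation", class(out))
  out
}

#' Bias enrichment and expression-shift tests for motif-proximal genes
#'
#' For each upstream window: (1) a one-sample two-sided z-test of the
#' proportion of male-biased genes among motif-proximal genes against the
#' genome-wide male-biased proportion; (2) a permutation test of the mean
#' log2 fold change between subordinate and dominant males in the proximal
#' set, against `n_perm` random gene sets of the same size (two-sided around
#' the overall mean, with add-one correction).
#'
#' @param ma An [annotate_motifs()] table.
#' @param sbt A [classify_sex_bias()] table.
#' @param ms A [morph_means()] summary (source of per-gene subordinate minus
#'   dominant log2 expression).
#' @param n_perm Number of permutation replicates (default 1000).
#' @param seed Optional integer seed for the permutations.
#' @return Tibble with one row per window: set size, male-biased proportion in
#'   the set and genome-wide, `z` and `p_z`, mean subordinate-vs-dominant
#'   log2 fold change in the set and overall, and the permutation `p_perm`.
#' @export
motif_bias_tests <- function(ma, sbt, ms, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wcols <- grep("^within_", names(ma), value = TRUE)
  merged <- ma |>
    inner_join(sbt[, c("gene_id", "category")], by = "gene_id") |>
    inner_join(tibble(gene_id = ms$gene_id,
                      fc_sub_dom = ms$subordinate - ms$dominant),
               by = "gene_id")
  p0 <- mean(merged$category == "male")
  overall_fc <- mean(merged$fc_sub_dom)
  n_univ <- nrow(merged)

  rows <- list()
  for (wc in wcols) {
    flagged <- merged[[wc]]
    m <- sum(flagged)
    if (m == 0) {
      warn(paste0("no genes flagged in window ", wc, "; skipped"))
      next
    }
    prop <- mean(merged$category[flagged] == "male")
    se <- sqrt(p0 * (1 - p0) / m)
    z <- if (se == 0) 0 else (prop - p0) / se
    obs <- mean(merged$fc_sub_dom[flagged])
    perm <- vapply(seq_len(n_perm), function(i) {
      mean(merged$fc_sub_dom[sample.int(n_univ, m)])
    }, numeric(1))
    p_perm <- (1 + sum(abs(perm - overall_fc) >= abs(obs - overall_fc))) /
      (n_perm + 1)
    rows[[wc]] <- tibble(
      window = as.numeric(sub("^within_", "", wc)),
      n_flagged = m,
      prop_male_biased = prop,
      genome_prop_male_biased = p0,
      z = z,
      p_z = min(1, 2 * pnorm(-abs(z))),
      mean_log2fc_sub_dom = obs,
      overall_log2fc_sub_dom = overall_fc,
      p_perm = p_perm)
  }
  bind_rows(rows)
}
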