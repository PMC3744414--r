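# fixture builders and independent brute-force oracles shared across tests

make_cm <- function(counts, morphs = NULL, tissue = "gonad",
                    chrom_class = "autosome", exonic_length = 1000L,
                    library_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  if (is.null(morphs)) {
    morphs <- rep(c("female", "subordinate", "dominant"),
                  length.out = ncol(counts))
  }
  samples <- data.frame(sample_id = colnames(counts), morph = morphs,
                        tissue = tissue)
  if (!is.null(library_size)) samples$library_size <- library_size
  genes <- data.frame(gene_id = rownames(counts),
                      chrom_class = rep(chrom_class, length.out = nrow(counts)),
                      exonic_length = rep(exonic_length, length.out = nrow(counts)))
  count_matrix(counts, samples, genes)
}

random_cm <- function(n_genes, n_per_morph = 3, mu = 50, size = 5,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_s <- 3 * n_per_morph
  counts <- matrix(rnbinom(n_genes * n_s, mu = mu, size = size),
                   nrow = n_genes)
  make_cm(counts, morphs = rep(c("female", "subordinate", "dominant"),
                               each = n_per_morph))
}

make_ms <- function(female, subordinate, dominant,
                    chrom_class = "autosome") {
  n <- length(female)
  out <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)),
                        chrom_class = rep(chrom_class, length.out = n),
                        female = female, subordinate = subordinate,
                        dominant = dominant)
  class(out) <- c("morph_summary", class(out))
  out
}

make_sbt <- function(category, log2fc, chrom_class = "autosome",
                     adj_pvalue = NULL, gene_id = NULL) {
  n <- length(category)
  out <- tibble::tibble(
    gene_id = if (is.null(gene_id)) sprintf("g%03d", seq_len(n)) else gene_id,
    chrom_class = rep(chrom_class, length.out = n),
    category = category,
    log2fc = log2fc,
    pvalue = if (is.null(adj_pvalue)) rep(0.001, n) else adj_pvalue,
    adj_pvalue = if (is.null(adj_pvalue)) rep(0.001, n) else adj_pvalue,
    quartile = NA_integer_)
  attr(out, "alpha") <- 0.05
  class(out) <- c("sex_bias_table", class(out))
  out
}

# --- brute-force oracles -----------------------------------------------------

bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# exact two-sided signed-rank p by enumerating all sign assignments
signed_rank_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

spearman_brute <- function(x, y) cor(rank(x), rank(y))

# complete-linkage agglomeration by direct set scanning
complete_linkage_brute <- function(mat) {
  n <- nrow(mat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  d <- as.matrix(dist(mat))
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    merges[[length(merges) + 1]] <-
      sort(rownames(mat)[c(clusters[[best[1]]], clusters[[best[2]]])])
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, clades = merges)
}

# expression filter re-evaluated gene by gene
filter_brute <- function(counts, morphs, libs, threshold = 4, frac = 0.5) {
  keep <- logical(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    per_million <- counts[g, ] / libs * 1e6
    for (m in unique(morphs)) {
      idx <- morphs == m
      if (mean(per_million[idx] >= threshold) >= frac) keep[g] <- TRUE
    }
  }
  keep
}

size_factors_brute <- function(counts) {
  geo <- exp(rowMeans(log(counts)))
  ok <- is.finite(geo) & geo > 0
  apply(counts, 2, function(x) median((x / geo)[ok & x > 0]))
}
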