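#' Hierarchical clustering of morph (or sample) expression profiles
#'
#' Complete-linkage clustering on Euclidean distances between mean-expression
#' vectors. Given a [morph_means()] summary the three morphs are clustered on
#' their per-gene average log2 expression; given an `expression_matrix`,
#' individual samples are clustered instead.
#'
#' @param x A `morph_summary` or `expression_matrix`.
#' @param genes Optional gene ids to restrict to (e.g. one bias category).
#' @return A `cluster_tree`: list with the `hclust` object, leaf `labels`, and
#'   `support` (`NULL` until [bootstrap_support()]).
#' @export
hcluster <- function(x, genes = NULL) {
  mat <- cluster_input(x, genes)
  if (nrow(mat) < 2) abort("need at least 2 units to cluster")
  if (ncol(mat) < 2) abort("need at least 2 genes to cluster")
  hc <- hclust(dist(mat), method = "complete")
  structure(list(hclust = hc, labels = rownames(mat), support = NULL,
                 n_genes = ncol(mat)),
            class = "cluster_tree")
}

# units x genes matrix for clustering
cluster_input <- function(x, genes = NULL) {
  if (inherits(x, "morph_summary")) {
    rows <- if (is.null(genes)) x else x[x$gene_id %in% genes, ]
    mat <- t(as.matrix(rows[, .MORPHS]))
    colnames(mat) <- rows$gene_id
  } else if (inherits(x, "expression_matrix")) {
    idx <- if (is.null(genes)) seq_len(nrow(x$log2_expr)) else
      which(x$genes$gene_id %in% genes)
    mat <- t(x$log2_expr[idx, , drop = FALSE])
  } else {
    abort("x must be a morph_summary or expression_matrix")
  }
  mat
}

# leaf-label sets under each internal node, in merge order
tree_clades <- function(hc) {
  n <- length(hc$labels)
  clades <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leaves <- unlist(lapply(kids, function(k) {
      if (k < 0) hc$labels[-k] else clades[[k]]
    }))
    clades[[i]] <- sort(leaves)
  }
  clades
}

#' Bootstrap support for dendrogram nodes
#'
#' Genes are resampled with replacement `n_boot` times, the tree is rebuilt
#' for each replicate, and each original internal node receives the
#' percentage of replicates containing the same leaf set as a clade (plain
#' bipartition frequency).
#'
#' @inheritParams hcluster
#' @param n_boot Number of replicates (default 1000).
#' @param seed Optional integer seed.
#' @return A `cluster_tree` whose `support` is a numeric vector in `[0, 100]`,
#'   one value per internal node in merge order.
#' @export
bootstrap_support <- function(x, genes = NULL, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- cluster_input(x, genes)
  if (ncol(mat) < 10) abort("need at least 10 genes for bootstrap support")
  ct <- hcluster(x, genes)
  orig <- tree_clades(ct$hclust)
  hits <- numeric(length(orig))
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    hb <- hclust(dist(mat[, cols, drop = FALSE]), method = "complete")
    boot_clades <- tree_clades(hb)
    keys <- vapply(boot_clades, paste, "", collapse = "\r")
    hits <- hits + (vapply(orig, paste, "", collapse = "\r") %in% keys)
  }
  ct$support <- 100 * hits / n_boot
  ct$n_boot <- n_boot
  ct
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves on %d genes\n",
              length(x$labels), x$n_genes))
  if (!is.null(x$support)) {
    cat("bootstrap support (merge order): ",
        paste(round(x$support, 1), collapse = ", "), "\n")
  }
  cat(write_newick(x), "\n")
  invisible(x)
}

#' Export a cluster tree as Newick
#'
#' Internal node labels carry the bootstrap support percentages when present.
#'
#' @param ct A [hcluster()] / [bootstrap_support()] result.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(ct, path = NULL) {
  stopifnot(inherits(ct, "cluster_tree"))
  phy <- ape::as.phylo(ct$hclust)
  if (!is.null(ct$support)) {
    # ape internal node order: root is node n+1; hclust merge order maps to
    # ape nodes via match on clade membership
    clades <- tree_clades(ct$hclust)
    labs <- character(phy$Nnode)
    for (i in seq_along(clades)) {
      node <- ape::getMRCA(phy, clades[[i]])
      labs[node - length(phy$tip.label)] <- as.character(round(ct$support[i], 1))
    }
    phy$node.label <- labs
  }
  if (is.null(path)) ape::write.tree(phy)
  else invisible(ape::write.tree(phy, file = path))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(a^2))` over off-diagonal entries, where
#' `r` are the correlations and `a` the anti-image partial correlations
#' obtained from the inverse correlation matrix (pseudo-inverse with a flag
#' when the matrix is singular).
#'
#' @param R A correlation matrix.
#' @return List with `kmo` and `pseudo_inverse` (logical).
#' @export
kmo_statistic <- function(R) {
  inv <- tryCatch(solve(R), error = function(e) NULL)
  pseudo <- is.null(inv)
  if (pseudo) inv <- MASS_ginv(R)
  d <- sqrt(diag(inv))
  partial <- -inv / outer(d, d)
  off <- upper.tri(R)
  list(kmo = sum(R[off]^2) / (sum(R[off]^2) + sum(partial[off]^2)),
       pseudo_inverse = pseudo)
}

# Moore-Penrose inverse via SVD (keeps MASS out of Imports)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' `chi2 = -((n - 1) - (2p + 5) / 6) * log(det(R))` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param R Correlation matrix.
#' @param n Number of observations behind `R`.
#' @return Tibble with `chisq`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  p <- ncol(R)
  detR <- det(R)
  chisq <- -((n - 1) - (2 * p + 5) / 6) * log(max(detR, .Machine$double.xmin))
  df <- p * (p - 1) / 2
  tibble(chisq = chisq, df = df, p_value = pchisq(chisq, df, lower.tail = FALSE))
}

#' Factor analysis of expression profiles with adequacy diagnostics
#'
#' Maximum-likelihood factor analysis treating samples as the variables and
#' genes as the observations (so the factor loadings place each sample, and
#' morphs can be compared in factor space). The number of factors defaults to
#' the smallest count whose cumulative eigenvalue share of the sample
#' correlation matrix reaches `cum_var_cutoff`, capped by the
#' degrees-of-freedom limit. KMO sampling adequacy and Bartlett's sphericity
#' test are computed from the same correlation matrix.
#'
#' @param em An `expression_matrix` (uses `log2_expr`).
#' @param n_factors Fixed number of factors; default chooses by cumulative
#'   variance.
#' @param cum_var_cutoff Eigenvalue cumulative-variance cutoff (default 0.95).
#' @param rotation Passed to [stats::factanal()] (default `"none"`;
#'   `"varimax"` available).
#' @return A `factor_result`: loadings, per-gene scores, `var_explained`
#'   (SS-loadings proportions, non-increasing), eigenvalue shares, `n_factors`,
#'   `kmo`, `bartlett`.
#' @export
factor_analysis <- function(em, n_factors = NULL, cum_var_cutoff = 0.95,
                            rotation = "none") {
  stopifnot(inherits(em, "expression_matrix"))
  X <- em$log2_expr
  if (any(!is.finite(X))) abort("non-finite expression values")
  p <- ncol(X)
  R <- cor(X)
  eig <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  eig_share <- pmax(eig, 0) / sum(pmax(eig, 0))
  k_dof <- max(1, floor((2 * p + 1 - sqrt(8 * p + 1)) / 2))
  if (is.null(n_factors)) {
    n_factors <- which(cumsum(eig_share) >= cum_var_cutoff)[1]
    n_factors <- min(max(n_factors, 1), k_dof)
  }
  if (nrow(X) <= n_factors) abort("need more observations than factors")

  fa <- factanal(x = X, factors = n_factors, rotation = rotation,
                 scores = "regression")
  load <- unclass(fa$loadings)
  ss <- colSums(load^2)
  ord <- order(ss, decreasing = TRUE)
  structure(list(
    loadings = load[, ord, drop = FALSE],
    scores = fa$scores[, ord, drop = FALSE],
    var_explained = ss[ord] / p,
    eigen_share = eig_share,
    n_factors = n_factors,
    kmo = kmo_statistic(R),
    bartlett = bartlett_sphericity(R, n = nrow(X)),
    samples = em$samples
  ), class = "factor_result")
}

#' @export
print.factor_result <- function(x, ...) {
  cat(sprintf("<factor_result> %d factors; variance explained: %s\n",
              x$n_factors,
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", ")))
  cat(sprintf("KMO = %.3f%s; Bartlett chi2 = %.1f (df %d, p = %.3g)\n",
              x$kmo$kmo, if (x$kmo$pseudo_inverse) " (pseudo-inverse)" else "",
              x$bartlett$chisq, x$bartlett$df, x$bartlett$p_value))
  invisible(x)
}

#' Export a clustered expression matrix for heat-map rendering
#'
#' Writes (or returns) the morph-mean matrix with rows ordered by a gene-wise
#' complete-linkage clustering, the standard input for external heat-map
#' tools.
#'
#' @param ms A [morph_means()] summary.
#' @param genes Optional gene ids to restrict to.
#' @param path Optional TSV output path.
#' @return The reordered tibble (invisibly when written).
#' @export
heatmap_matrix <- function(ms, genes = NULL, path = NULL) {
  rows <- if (is.null(genes)) ms else ms[ms$gene_id %in% genes, ]
  m <- as.matrix(rows[, .MORPHS])
  ord <- if (nrow(m) > 2) hclust(dist(m), method = "complete")$order
         else seq_len(nrow(m))
  out <- as_tibble(rows[ord, ])
  if (is.null(path)) out else {
    readr::write_tsv(out, path)
    invisible(out)
  }
}
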