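#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes (restricted to genes
#' with positive counts in every sample) of the ratio between that sample's
#' count and the gene's geometric mean across samples. When no gene is positive
#' in all samples, falls back to upper-quartile ratios with a warning.
#'
#' @param cm A [count_matrix()] (or a plain counts matrix).
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    warn("no gene has positive counts in every sample; using upper-quartile factors")
    uq <- apply(counts, 2, function(x) quantile(x[x > 0], 0.75, names = FALSE))
    sf <- uq / exp(mean(log(uq)))
    return(setNames(sf, colnames(counts)))
  }
  geo <- exp(log_geo)
  sf <- apply(counts, 2, function(x) {
    median((x / geo)[usable & x > 0])
  })
  setNames(sf, colnames(counts))
}

# dispersion estimation: per-gene method of moments on pooled within-group
# variance of size-factor-normalized counts, with a fitted a0 + a1/mu trend.
# method: "max" takes the larger of gene-wise and trend (conservative),
# "trend" uses the fitted trend only, "gene" uses raw gene-wise estimates.
estimate_dispersions <- function(q, sf, group, method = c("trend", "max", "gene")) {
  method <- match.arg(method)
  groups <- split(seq_along(group), group)
  n_rep <- vapply(groups, length, 1L)
  base_mean <- rowMeans(q)
  xi <- mean(1 / sf)

  if (all(n_rep < 2)) {
    # no replicates anywhere: pool all samples ("blind")
    v <- apply(q, 1, var)
  } else {
    use <- groups[n_rep >= 2]
    wss_parts <- vapply(use, function(cols) {
      m <- q[, cols, drop = FALSE]
      rowSums((m - rowMeans(m))^2)
    }, numeric(nrow(q)))
    wss <- rowSums(matrix(wss_parts, nrow = nrow(q)))
    v <- wss / sum(vapply(use, length, 1L) - 1L)
  }
  disp_gene <- pmax((v - xi * base_mean) / base_mean^2, 1e-8)

  pos <- base_mean > 0 & is.finite(disp_gene)
  trend <- fit_dispersion_trend(base_mean[pos], disp_gene[pos])
  disp_trend <- pmax(trend$a0 + trend$a1 / base_mean, 1e-8)
  disp <- switch(method,
                 gene = disp_gene,
                 trend = disp_trend,
                 max = pmax(disp_gene, disp_trend))
  disp[!is.finite(disp)] <- 1e-8
  list(dispersion = disp, gene_wise = disp_gene, trend = trend)
}

fit_dispersion_trend <- function(mu, disp) {
  # the a1/mu term is only identifiable when means span a real range;
  # otherwise use a winsorized location so isolated high-dispersion genes
  # (true DE, outliers) cannot drag the trend
  narrow <- length(mu) < 10 || var(1 / mu) == 0 ||
    max(mu) / max(min(mu), 1e-8) < 10
  if (narrow) {
    cap <- quantile(disp, 0.95, names = FALSE)
    return(list(a0 = mean(pmin(disp, cap)), a1 = 0))
  }
  fit1 <- fit_gamma_trend(mu, disp)
  fitted <- fit1$a0 + fit1$a1 / mu
  keep <- disp < 10 * fitted & disp > fitted / 10
  if (sum(keep) >= 10 && any(!keep)) fit_gamma_trend(mu[keep], disp[keep])
  else fit1
}

fit_gamma_trend <- function(mu, disp) {
  fit <- tryCatch(
    stats::glm(disp ~ I(1 / mu), family = stats::Gamma(link = "identity"),
               start = c(mean(disp), 1)),
    error = function(e) NULL, warning = function(w) NULL)
  co <- if (!is.null(fit)) coef(fit) else coef(lm(disp ~ I(1 / mu)))
  list(a0 = unname(max(co[1], 1e-8)), a1 = unname(max(co[2], 0)))
}

# two-sided p for one gene from the conditioned NB test: given the total count
# kS = kA + kB, sum the probabilities of all splits no more likely than the
# observed one. For totals above `exact_total_limit` a Gaussian conditioning
# approximation on kA | kS is used instead (documented tolerance ~1% on p).
nb_exact_p <- function(ka, ks, mu_a, mu_b, var_a, var_b, exact_total_limit) {
  if (ks == 0) return(1)
  if (ks <= exact_total_limit) {
    size_a <- if (var_a > mu_a) mu_a^2 / (var_a - mu_a) else 1e8
    size_b <- if (var_b > mu_b) mu_b^2 / (var_b - mu_b) else 1e8
    k <- 0:ks
    pk <- dnbinom(k, mu = mu_a, size = size_a) *
      dnbinom(ks - k, mu = mu_b, size = size_b)
    tot <- sum(pk)
    if (tot == 0) return(1)
    min(1, sum(pk[pk <= pk[ka + 1] * (1 + 1e-7)]) / tot)
  } else {
    m <- mu_a + var_a / (var_a + var_b) * (ks - mu_a - mu_b)
    v <- var_a * var_b / (var_a + var_b)
    z <- (abs(ka - m) - 0.5) / sqrt(v)
    min(1, 2 * pnorm(-max(z, 0)))
  }
}

#' Pairwise negative-binomial test of equal expression between morph groups
#'
#' Size-factor-normalized counts are compared between two groups of samples
#' with a conditioned negative-binomial exact test: per gene, the two group
#' sums are modelled as negative binomial with a common mean (the pooled
#' normalized mean scaled by each group's size-factor total) and a dispersion
#' estimated by method of moments on pooled within-group variance, stabilized
#' by a fitted mean-dispersion trend. Two-sided p-values sum the probabilities
#' of all outcomes no more likely than the observed split of the total count;
#' totals above `exact_total_limit` use a Gaussian conditioning approximation.
#'
#' @param cm A [count_matrix()].
#' @param group_a,group_b Morph name(s) defining the two groups (e.g.
#'   `"female"` vs `"dominant"`, or `c("dominant", "subordinate")`).
#' @param tissue Tissue to test; may be omitted when only one is present.
#' @param dispersion_method `"trend"` (fitted mean-dispersion trend, default;
#'   near-nominal type-I control in replicated designs), `"max"` (larger of
#'   gene-wise and trend, conservative) or `"gene"` (raw gene-wise).
#' @param exact_total_limit Largest total count for which the exact sum is
#'   evaluated (default 1e4).
#' @param fc_pseudocount Pseudocount (normalized-count scale) used only for the
#'   reported log2 fold change.
#' @param sf Optional pre-computed size factors for the selected samples.
#' @return A `de_test` tibble: `gene_id`, `base_mean`, `mean_a`, `mean_b`,
#'   `log2fc` (log2 of b over a), `dispersion`, `pvalue`.
#' @export
nb_test <- function(cm, group_a, group_b, tissue = NULL,
                    dispersion_method = c("trend", "max", "gene"),
                    exact_total_limit = 1e4, fc_pseudocount = 0.5,
                    sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  dispersion_method <- match.arg(dispersion_method)
  cm <- select_tissue(cm, tissue)
  in_a <- cm$samples$morph %in% group_a
  in_b <- cm$samples$morph %in% group_b
  if (!any(in_a)) abort(paste0("no samples for group: ", toString(group_a)))
  if (!any(in_b)) abort(paste0("no samples for group: ", toString(group_b)))
  cm <- subset_samples(cm, which(in_a | in_b))
  grp <- ifelse(cm$samples$morph %in% group_a, "A", "B")

  counts <- cm$counts
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")

  disp <- estimate_dispersions(q, sf, grp, method = dispersion_method)
  alpha <- disp$dispersion

  a_cols <- grp == "A"
  mean_a <- rowMeans(q[, a_cols, drop = FALSE])
  mean_b <- rowMeans(q[, !a_cols, drop = FALSE])
  q0 <- rowMeans(q)

  s_a <- sum(sf[a_cols]);  s2_a <- sum(sf[a_cols]^2)
  s_b <- sum(sf[!a_cols]); s2_b <- sum(sf[!a_cols]^2)
  ka <- rowSums(counts[, a_cols, drop = FALSE])
  ks <- ka + rowSums(counts[, !a_cols, drop = FALSE])

  mu_a <- q0 * s_a; mu_b <- q0 * s_b
  var_a <- q0 * s_a + alpha * q0^2 * s2_a
  var_b <- q0 * s_b + alpha * q0^2 * s2_b

  pval <- vapply(seq_along(ks), function(i) {
    nb_exact_p(ka[i], ks[i], mu_a[i], mu_b[i], var_a[i], var_b[i],
               exact_total_limit)
  }, numeric(1))

  out <- tibble(
    gene_id = rownames(counts),
    base_mean = q0,
    mean_a = mean_a,
    mean_b = mean_b,
    log2fc = log2((mean_b + fc_pseudocount) / (mean_a + fc_pseudocount)),
    dispersion = alpha,
    pvalue = pval
  )
  attr(out, "groups") <- list(a = group_a, b = group_b)
  attr(out, "size_factors") <- sf
  class(out) <- c("de_test", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with input validation.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues)) abort("p-values must not contain NA/NaN")
  if (any(pvalues < 0 | pvalues > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Classify genes as male-biased, female-biased or unbiased
#'
#' Runs the pairwise negative-binomial test between females and a configurable
#' male reference, adjusts p-values by Benjamini-Hochberg separately for
#' autosomal and Z-linked genes (the incompletely dose-compensated Z cannot be
#' pooled with autosomes), and labels genes male-biased when expressed at least
#' `fc_threshold`-fold higher in the male reference with adjusted p below
#' `alpha` (female-biased symmetrically). With `mode = "p_only"` the
#' fold-change criterion is dropped and direction follows the sign of the fold
#' change, as used for weakly dimorphic somatic tissue.
#'
#' @param cm A (filtered) [count_matrix()].
#' @param tissue Tissue to classify; may be omitted when only one is present.
#' @param male_reference `"dominant"` (default), `"subordinate"`, or
#'   `"all_males"` (both male morphs pooled).
#' @param fc_threshold Fold-change threshold, >= 1 (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param mode `"fc_and_p"` (default) or `"p_only"`.
#' @param ... Passed to [nb_test()].
#' @return A `sex_bias_table` tibble: `gene_id`, `chrom_class`, `category`,
#'   `log2fc` (male-positive), `pvalue`, `adj_pvalue`, `quartile` (`NA` until
#'   [quartile_bins()] is applied).
#' @export
classify_sex_bias <- function(cm, tissue = NULL,
                              male_reference = c("dominant", "subordinate", "all_males"),
                              fc_threshold = 2, alpha = 0.05,
                              mode = c("fc_and_p", "p_only"), ...) {
  male_reference <- match.arg(male_reference)
  mode <- match.arg(mode)
  if (fc_threshold < 1) abort("fc_threshold must be >= 1")
  male_grp <- if (male_reference == "all_males") c("dominant", "subordinate")
              else male_reference

  de <- nb_test(cm, group_a = "female", group_b = male_grp, tissue = tissue, ...)
  cmx <- select_tissue(cm, tissue)
  out <- de |>
    mutate(chrom_class = cmx$genes$chrom_class[match(.data$gene_id,
                                                     cmx$genes$gene_id)]) |>
    group_by(.data$chrom_class) |>
    mutate(adj_pvalue = bh_adjust(.data$pvalue)) |>
    ungroup()

  lfc_min <- log2(fc_threshold)
  sig <- out$adj_pvalue < alpha
  category <- rep("unbiased", nrow(out))
  if (mode == "fc_and_p") {
    category[sig & out$log2fc >= lfc_min] <- "male"
    category[sig & out$log2fc <= -lfc_min] <- "female"
  } else {
    category[sig & out$log2fc > 0] <- "male"
    category[sig & out$log2fc < 0] <- "female"
  }

  out <- out |>
    mutate(category = category, quartile = NA_integer_) |>
    select("gene_id", "chrom_class", "category", "log2fc",
           "pvalue", "adj_pvalue", "quartile")
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "male_reference") <- male_reference
  attr(out, "mode") <- mode
  class(out) <- c("sex_bias_table", class(out))
  out
}

#' Bin significant genes into bias-magnitude quartiles
#'
#' Among genes with adjusted p below alpha — the fold-change criterion is
#' dropped here, so genes differentially expressed between the sexes but below
#' the fold threshold are included — genes are ranked by absolute log2 fold
#' change within each direction (male-positive vs female-positive) and within
#' each chromosome class. Quartile 4 holds the most biased genes; ties are
#' broken by gene id for determinism.
#'
#' @param sbt A [classify_sex_bias()] result.
#' @param alpha Significance threshold; defaults to the one used for
#'   classification.
#' @return The table with the `quartile` column filled (`NA` for genes not in
#'   any quartile). With fewer than 4 significant genes in a direction, all of
#'   them are assigned quartile 1 with a warning.
#' @export
quartile_bins <- function(sbt, alpha = attr(sbt, "alpha") %||% 0.05) {
  stopifnot(inherits(sbt, "sex_bias_table"))
  quart <- rep(NA_integer_, nrow(sbt))
  for (cls in unique(sbt$chrom_class)) {
    for (dir in c(1, -1)) {
      idx <- which(sbt$chrom_class == cls & sbt$adj_pvalue < alpha &
                     sign(sbt$log2fc) == dir & sbt$log2fc != 0)
      if (!length(idx)) next
      ord <- idx[order(abs(sbt$log2fc[idx]), sbt$gene_id[idx])]
      n <- length(ord)
      if (n < 4) {
        warn(sprintf("fewer than 4 significant %s-biased genes on %s; all in quartile 1",
                     if (dir == 1) "male" else "female", cls))
        quart[ord] <- 1L
      } else {
        quart[ord] <- as.integer(ceiling(4 * seq_len(n) / n))
      }
    }
  }
  sbt$quartile <- quart
  sbt
}
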