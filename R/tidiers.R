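#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a decoupling regression
#'
#' @param x A [decoupling_regression()] fit.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error, statistic
#'   and p-value.
#' @export
tidy.decoupling_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$model))$coefficients
  tibble(term = c("intercept", "bias_degree"),
         estimate = co[, 1], std_error = co[, 2],
         statistic = co[, 3], p_value = co[, 4])
}

#' @rdname tidy.decoupling_fit
#' @return For `glance`: one row with `r_squared`, `slope`, `p_value`, `n`.
#' @export
glance.decoupling_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope,
         intercept = x$intercept, p_value = x$p_value, n = x$n)
}

#' Tidy the morph correlation matrix
#'
#' @param x A [spearman_morph_matrix()] result.
#' @param ... Unused.
#' @return One row per morph pair with the Spearman rho.
#' @export
tidy.morph_cor <- function(x, ...) {
  pairs <- utils::combn(rownames(x$rho), 2)
  tibble(morph_1 = pairs[1, ], morph_2 = pairs[2, ],
         rho = x$rho[t(pairs)], n = x$n, category = x$category)
}

#' Tidy a bootstrapped cluster tree
#'
#' @param x A [bootstrap_support()] result.
#' @param ... Unused.
#' @return One row per internal node: member leaves and support percentage.
#' @export
tidy.cluster_tree <- function(x, ...) {
  clades <- tree_clades(x$hclust)
  tibble(node = seq_along(clades),
         members = vapply(clades, paste, "", collapse = ","),
         height = x$hclust$height,
         support = if (is.null(x$support)) NA_real_ else x$support)
}

#' Tidy / summarise a factor analysis
#'
#' @param x A [factor_analysis()] result.
#' @param ... Unused.
#' @return `tidy`: one row per variable (sample) and factor with the loading.
#'   `glance`: factor count, variance explained, KMO and Bartlett p.
#' @export
tidy.factor_result <- function(x, ...) {
  load <- x$loadings
  tibble(sample_id = rep(rownames(load), ncol(load)),
         factor = rep(paste0("factor", seq_len(ncol(load))),
                      each = nrow(load)),
         loading = as.vector(load))
}

#' @rdname tidy.factor_result
#' @export
glance.factor_result <- function(x, ...) {
  tibble(n_factors = x$n_factors,
         var_explained_total = sum(x$var_explained),
         kmo = x$kmo$kmo,
         bartlett_chisq = x$bartlett$chisq,
         bartlett_p = x$bartlett$p_value)
}

#' Summarise a resampling-control run
#'
#' @param x An [rtm_randomization()] result.
#' @param ... Unused.
#' @return `tidy`: the per-iteration record. `glance`: one row per contrast
#'   and gene set with significant-iteration counts.
#' @export
tidy.rtm_result <- function(x, ...) x$iterations

#' @rdname tidy.rtm_result
#' @export
glance.rtm_result <- function(x, ...) x$summary

#' Summarise a Venn partition
#'
#' @param x A [presence_venn()] / [venn_partition()] result.
#' @param ... Unused.
#' @return One row: total genes, count and percentage present in all three
#'   morphs, and the morph-limited counts.
#' @export
glance.venn_partition <- function(x, ...) {
  n <- setNames(x$n, x$region)
  tibble(total = attr(x, "total"),
         all_three = n[["all_three"]],
         pct_all_three = attr(x, "pct_all_three"),
         female_limited = n[["female_only"]],
         male_limited = n[["subordinate_only"]] + n[["dominant_only"]] +
           n[["subordinate_dominant"]])
}
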