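#' Read a per-gene branch divergence table
#'
#' The canonical input is a TSV with one row per gene and columns `gene_id`,
#' `nonsyn_sites` (N, potential nonsynonymous sites), `dn` (branch-specific
#' nonsynonymous rate), `syn_sites` (S), `ds`, `gapless_len` (aligned gapless
#' length in bp), `has_inframe_stop`, `is_retrotransposon` (logical flags;
#' the flags default to `FALSE` when absent).
#'
#' @param path Path to the TSV.
#' @return A validated `divergence_records` tibble.
#' @export
read_divergence <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  as_divergence_records(tab)
}

#' @rdname read_divergence
#' @param records A data frame in the schema above.
#' @export
as_divergence_records <- function(records) {
  records <- as_tibble(records)
  need <- setdiff(c("gene_id", "nonsyn_sites", "dn", "syn_sites", "ds",
                    "gapless_len"), names(records))
  if (length(need)) {
    abort(paste0("divergence table missing column(s): ", toString(need)),
          class = "dimorphix_schema_error")
  }
  if (!"has_inframe_stop" %in% names(records)) records$has_inframe_stop <- FALSE
  if (!"is_retrotransposon" %in% names(records)) records$is_retrotransposon <- FALSE
  num <- c("nonsyn_sites", "dn", "syn_sites", "ds", "gapless_len")
  bad <- vapply(records[num], function(x) any(!is.finite(x) | x < 0), TRUE)
  if (any(bad)) {
    abort(paste0("negative or non-finite values in: ",
                 toString(num[bad])), class = "dimorphix_validation_error")
  }
  class(records) <- c("divergence_records", class(records))
  records
}

#' Extract branch estimates from codeml main output
#'
#' Minimal parser for the per-branch `dN & dS for each branch` block of a
#' codeml (branch model) main-output file: pulls `N`, `S`, `dN` and `dS` for
#' one named branch per gene block. Gene blocks are recognized by lines
#' starting with `Data set` or by a supplied separator pattern; the canonical
#' input for this package remains the TSV read by [read_divergence()].
#'
#' @param path Path to a codeml main-output file.
#' @param branch Branch label to extract (e.g. `"7..1"`); default takes the
#'   first branch row of each block.
#' @return A `divergence_records` tibble (gapless length is not present in
#'   this layout and is set to `NA`; filter on it upstream if needed).
#' @export
parse_codeml <- function(path, branch = NULL) {
  lines <- readr::read_lines(path)
  block_starts <- grep("^Data set", lines)
  if (!length(block_starts)) block_starts <- 1L
  block_ends <- c(block_starts[-1] - 1L, length(lines))
  rows <- purrr::map2(block_starts, block_ends, function(b0, b1) {
    chunk <- lines[b0:b1]
    hdr <- grep("^\\s*branch\\s+t\\s+N\\s+S", chunk)
    if (!length(hdr)) return(NULL)
    body <- chunk[(hdr[1] + 1):length(chunk)]
    body <- body[grepl("^\\s*\\S+\\.\\.\\S+", body)]
    if (!is.null(branch)) body <- body[startsWith(trimws(body), branch)]
    if (!length(body)) return(NULL)
    f <- strsplit(trimws(body[1]), "\\s+")[[1]]
    # columns: branch t N S dN/dS dN dS N*dN S*dS
    tibble(gene_id = sub("^Data set\\s+", "", chunk[1]),
           nonsyn_sites = as.numeric(f[3]), dn = as.numeric(f[6]),
           syn_sites = as.numeric(f[4]), ds = as.numeric(f[7]),
           gapless_len = NA_real_)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) abort("no branch blocks found in codeml output")
  out$has_inframe_stop <- FALSE
  out$is_retrotransposon <- FALSE
  class(out) <- c("divergence_records", class(out))
  out
}

#' Filter divergence records before aggregation
#'
#' Drops alignments past mutational saturation (`ds > ds_max`), short
#' alignments (`gapless_len < min_gapless`, boundary inclusive: exactly
#' `min_gapless` is retained), genes with in-frame stop codons, and
#' retrotransposons.
#'
#' @param records A `divergence_records` tibble.
#' @param ds_max Synonymous-rate saturation threshold (default 2).
#' @param min_gapless Minimum aligned gapless length in bp (default 100).
#' @return The surviving records; errors if nothing survives.
#' @export
filter_divergence <- function(records, ds_max = 2, min_gapless = 100) {
  stopifnot(inherits(records, "divergence_records"))
  keep <- records$ds <= ds_max &
    (is.na(records$gapless_len) | records$gapless_len >= min_gapless) &
    !records$has_inframe_stop & !records$is_retrotransposon
  if (!any(keep)) abort("all divergence records removed by filtering")
  records[keep, ]
}

#' Category-level dN, dS and dN/dS by site-weighted sums
#'
#' Per expression category, substitutions and sites are summed across genes
#' before dividing: `dN = sum(N_g * dn_g) / sum(N_g)` and likewise for dS, and
#' the category ratio is `dN / dS` of those sums. Summing first weights each
#' gene by its alignment length and avoids the infinite per-gene ratios of
#' genes without synonymous substitutions.
#'
#' @param records A `divergence_records` tibble (normally pre-filtered with
#'   [filter_divergence()]).
#' @param categories Either a [classify_sex_bias()] table or any data frame
#'   with `gene_id` and `category`; genes absent from it are dropped.
#' @return A `category_dnds` tibble: `category`, `n_genes`, `dn`, `ds`,
#'   `dnds` (`NA` with a warning when a category has no synonymous mass).
#' @export
aggregate_dnds <- function(records, categories) {
  stopifnot(inherits(records, "divergence_records"))
  categories <- as_tibble(categories)[, c("gene_id", "category")]
  merged <- inner_join(records, categories, by = "gene_id")
  if (!nrow(merged)) abort("no divergence records match the category table")
  out <- merged |>
    group_by(.data$category) |>
    summarise(n_genes = n(),
              dn = sum(.data$nonsyn_sites * .data$dn) / sum(.data$nonsyn_sites),
              ds = sum(.data$syn_sites * .data$ds) / sum(.data$syn_sites),
              .groups = "drop") |>
    mutate(dnds = ifelse(.data$ds > 0, .data$dn / .data$ds, NA_real_))
  if (anyNA(out$dnds)) {
    warn("category with zero synonymous mass; dN/dS undefined there")
  }
  class(out) <- c("category_dnds", class(out))
  out
}

#' Bootstrap confidence intervals for category-level dN, dS and dN/dS
#'
#' Nonparametric gene-level bootstrap: genes are resampled with replacement
#' within each category, the site-weighted aggregate is recomputed for each
#' replicate, and 95% percentile intervals are taken. Replicates with zero
#' synonymous mass are skipped and counted.
#'
#' @param records A `divergence_records` tibble.
#' @param categories As in [aggregate_dnds()].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param level Interval coverage (default 0.95).
#' @return The [aggregate_dnds()] tibble with `*_lo` / `*_hi` columns for
#'   `dn`, `ds` and `dnds`, plus `n_degenerate` skipped replicates.
#' @export
bootstrap_dnds_ci <- function(records, categories, n_boot = 1000,
                              seed = NULL, level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  point <- aggregate_dnds(records, categories)
  categories <- as_tibble(categories)[, c("gene_id", "category")]
  merged <- inner_join(records, categories, by = "gene_id")
  lo_q <- (1 - level) / 2; hi_q <- 1 - lo_q

  ci <- purrr::map(point$category, function(cat) {
    rows <- merged[merged$category == cat, ]
    if (nrow(rows) < 5) warn(paste0("fewer than 5 records in category ", cat))
    reps <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      r <- rows[sample.int(nrow(rows), replace = TRUE), ]
      s_mass <- sum(r$syn_sites * r$ds)
      if (s_mass == 0 || sum(r$syn_sites) == 0 || sum(r$nonsyn_sites) == 0) next
      dn <- sum(r$nonsyn_sites * r$dn) / sum(r$nonsyn_sites)
      ds <- sum(r$syn_sites * r$ds) / sum(r$syn_sites)
      reps[b, ] <- c(dn, ds, dn / ds)
    }
    ok <- complete.cases(reps)
    qs <- apply(reps[ok, , drop = FALSE], 2, quantile,
                probs = c(lo_q, hi_q), names = FALSE)
    tibble(dn_lo = qs[1, 1], dn_hi = qs[2, 1],
           ds_lo = qs[1, 2], ds_hi = qs[2, 2],
           dnds_lo = qs[1, 3], dnds_hi = qs[2, 3],
           n_degenerate = sum(!ok))
  })
  out <- dplyr::bind_cols(point, bind_rows(ci))
  class(out) <- c("category_dnds", class(out))
  out
}
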