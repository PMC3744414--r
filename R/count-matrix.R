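#' Assemble a validated count matrix with sample and gene annotations
#'
#' The central container every pipeline stage reads: a genes x samples matrix
#' of non-negative integer read counts, a sample sheet giving the morph
#' (`female`, `subordinate`, `dominant`) and tissue of each library, and a gene
#' sheet giving chromosome class (`autosome`, `Z`), exonic length, transcription
#' start coordinate and strand.
#'
#' @param counts Integer matrix, genes in rows, samples in columns. Dimnames
#'   must match the `gene_id` / `sample_id` columns of the sheets.
#' @param samples Data frame with columns `sample_id`, `morph`, `tissue` and
#'   optionally `library_size` (total mappable reads; when absent, column sums
#'   are used wherever a library size is needed).
#' @param genes Data frame with columns `gene_id`, `chrom_class`,
#'   `exonic_length`, and optionally `tss_coordinate`, `strand`, `chrom`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `samples` (tibble) and `genes` (tibble).
#' @export
#' @examples
#' cm <- count_matrix(
#'   matrix(0:5, nrow = 2, dimnames = list(c("g1", "g2"), paste0("s", 1:3))),
#'   samples = data.frame(sample_id = paste0("s", 1:3),
#'                        morph = c("female", "subordinate", "dominant"),
#'                        tissue = "gonad"),
#'   genes = data.frame(gene_id = c("g1", "g2"), chrom_class = "autosome",
#'                      exonic_length = c(1000L, 2000L))
#' )
#' cm
count_matrix <- function(counts, samples, genes) {
  counts <- as.matrix(counts)
  samples <- as_tibble(samples)
  genes <- as_tibble(genes)

  need_s <- setdiff(c("sample_id", "morph", "tissue"), names(samples))
  if (length(need_s)) {
    abort(paste0("sample sheet is missing column(s): ", toString(need_s)),
          class = "dimorphix_schema_error")
  }
  need_g <- setdiff(c("gene_id", "chrom_class", "exonic_length"), names(genes))
  if (length(need_g)) {
    abort(paste0("gene sheet is missing column(s): ", toString(need_g)),
          class = "dimorphix_schema_error")
  }

  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample ids in sample sheet", class = "dimorphix_schema_error")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicate gene ids in gene sheet", class = "dimorphix_schema_error")
  }
  bad_morph <- setdiff(unique(samples$morph), .MORPHS)
  if (length(bad_morph)) {
    abort(paste0("unknown morph label(s): ", toString(bad_morph)),
          class = "dimorphix_schema_error")
  }
  bad_class <- setdiff(unique(genes$chrom_class), c("autosome", "Z"))
  if (length(bad_class)) {
    abort(paste0("unknown chrom_class label(s): ", toString(bad_class)),
          class = "dimorphix_schema_error")
  }

  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must carry gene ids as rownames and sample ids as colnames",
          class = "dimorphix_schema_error")
  }
  miss_g <- setdiff(rownames(counts), genes$gene_id)
  if (length(miss_g)) {
    abort(paste0("gene id in counts absent from gene sheet: ", miss_g[1]),
          class = "dimorphix_schema_error")
  }
  miss_s <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss_s)) {
    abort(paste0("sample id in counts absent from sample sheet: ", miss_s[1]),
          class = "dimorphix_schema_error")
  }
  # align sheets to matrix order
  genes <- genes[match(rownames(counts), genes$gene_id), ]
  samples <- samples[match(colnames(counts), samples$sample_id), ]

  if (anyNA(counts) || any(counts < 0)) {
    abort("counts must be non-negative and non-missing",
          class = "dimorphix_validation_error")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort("counts must be integers", class = "dimorphix_validation_error")
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)

  if (any(!is.finite(genes$exonic_length)) || any(genes$exonic_length < 1)) {
    abort("exonic_length must be >= 1 for every gene",
          class = "dimorphix_validation_error")
  }
  if ("library_size" %in% names(samples) &&
      any(!is.finite(samples$library_size) | samples$library_size <= 0)) {
    abort("library_size must be positive where supplied",
          class = "dimorphix_validation_error")
  }

  structure(list(counts = counts, samples = samples, genes = genes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$morph, x$samples$tissue)
  print(tab)
  cat(sprintf("chrom_class: %s\n",
              paste(sprintf("%s=%d", names(table(x$genes$chrom_class)),
                            table(x$genes$chrom_class)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Total mappable reads per sample
#'
#' Uses the `library_size` column of the sample sheet when present (mappable
#' reads can exceed the column sum once genes have been filtered), otherwise
#' falls back to column sums of the count matrix.
#'
#' @param cm A [count_matrix()].
#' @return Named numeric vector, one entry per sample.
#' @export
library_sizes <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if ("library_size" %in% names(cm$samples)) {
    setNames(as.numeric(cm$samples$library_size), cm$samples$sample_id)
  } else {
    colSums(cm$counts)
  }
}

#' Read counts and annotation sheets from disk
#'
#' Counts are accepted either as TSV (a `gene_id` column followed by one column
#' per sample) or as MatrixMarket (`.mtx`) with `<stem>.genes.txt` and
#' `<stem>.samples.txt` sidecar id lists. Sheets are TSV with the headers
#' documented in [count_matrix()].
#'
#' @param counts_path Path to the counts TSV or `.mtx` file.
#' @param sample_sheet_path,gene_sheet_path Paths to the annotation TSVs.
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(counts_path, sample_sheet_path, gene_sheet_path) {
  for (p in c(counts_path, sample_sheet_path, gene_sheet_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  if (grepl("\\.mtx$", counts_path)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    stem <- sub("\\.mtx$", "", counts_path)
    rownames(m) <- readr::read_lines(paste0(stem, ".genes.txt"))
    colnames(m) <- readr::read_lines(paste0(stem, ".samples.txt"))
  } else {
    tab <- readr::read_tsv(counts_path, show_col_types = FALSE)
    if (names(tab)[1] != "gene_id") {
      abort("counts TSV must start with a 'gene_id' column",
            class = "dimorphix_schema_error")
    }
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$gene_id
  }
  samples <- readr::read_tsv(sample_sheet_path, show_col_types = FALSE)
  genes <- readr::read_tsv(gene_sheet_path, show_col_types = FALSE)
  count_matrix(m, samples, genes)
}

#' Write a count matrix and its sheets as canonical TSV
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @param stem File stem; writes `<stem>_counts.tsv`, `<stem>_samples.tsv`,
#'   `<stem>_genes.tsv`.
#' @return Invisibly, the three paths written.
#' @export
write_counts <- function(cm, dir, stem = "dataset") {
  stopifnot(inherits(cm, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(stem, c("_counts.tsv", "_samples.tsv", "_genes.tsv")))
  counts_tab <- bind_cols_counts(cm)
  readr::write_tsv(counts_tab, paths[1])
  readr::write_tsv(cm$samples, paths[2])
  readr::write_tsv(cm$genes, paths[3])
  invisible(paths)
}

bind_cols_counts <- function(cm) {
  tab <- as_tibble(cm$counts)
  tibble(gene_id = rownames(cm$counts)) |> dplyr::bind_cols(tab)
}

# restrict a count_matrix to a sample subset (character ids or logical/integer)
subset_samples <- function(cm, idx) {
  if (is.character(idx)) idx <- match(idx, cm$samples$sample_id)
  out <- cm
  out$counts <- cm$counts[, idx, drop = FALSE]
  out$samples <- cm$samples[idx, ]
  out
}

subset_genes <- function(cm, idx) {
  if (is.character(idx)) idx <- match(idx, cm$genes$gene_id)
  out <- cm
  out$counts <- cm$counts[idx, , drop = FALSE]
  out$genes <- cm$genes[idx, ]
  out
}

# pick one tissue; error when ambiguous
select_tissue <- function(cm, tissue = NULL) {
  tissues <- unique(cm$samples$tissue)
  if (is.null(tissue)) {
    if (length(tissues) > 1) {
      abort(paste0("multiple tissues present (", toString(tissues),
                   "); pass `tissue`"))
    }
    return(cm)
  }
  if (!tissue %in% tissues) abort(paste0("tissue not present: ", tissue))
  subset_samples(cm, cm$samples$tissue == tissue)
}
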