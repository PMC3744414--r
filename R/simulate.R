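#' Configuration for the morph-continuum count simulator
#'
#' Defaults emulate the statistical structure of a strongly dimorphic gonad
#' transcriptome: ~10,000 autosomal and ~360 Z-linked genes, 22% male-biased
#' and 29% female-biased, sex-bias effects of at least two-fold with an
#' exponential tail, subordinate-male means displaced from dominant-male
#' means toward female means by a fraction `demasc_d` (male-biased genes) or
#' `fem_f` (female-biased genes) on the log2 scale, average male-bias of
#' Z-linked expression from incomplete dosage compensation, negative-binomial
#' sampling noise, and log-normal library sizes around 26 million mappable
#' reads. Sex-bias is created by *reducing* expression in the opposite sex
#' relative to a shared baseline, and expected counts are compositional
#' (each sample's expected counts are its library size times relative
#' transcript shares), so relative-measurement artifacts behave as they do in
#' real RNA-seq.
#'
#' @param n_genes_autosome,n_genes_z Gene counts per chromosome class.
#' @param frac_male_biased,frac_female_biased Planted bias fractions (applied
#'   within each chromosome class); must sum to at most 1.
#' @param effect_min_log2,effect_scale_log2 Bias effect sizes are
#'   `effect_min_log2 + Exp(mean = effect_scale_log2)` in log2 units.
#' @param demasc_d,fem_f Subordinate displacement along the dominant-female
#'   continuum for male- and female-biased genes, in `[0, 1]`
#'   (0 = identical to dominant, 1 = identical to female).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param depth Mean library size (mappable reads per sample).
#' @param depth_cv Coefficient of variation of log-normal library sizes.
#' @param n_per_morph Samples per morph per tissue.
#' @param z_dosage_offset_log2 Added to male (dominant and subordinate) log2
#'   means for Z-linked genes.
#' @param tissues Tissues to emit (`"gonad"`, optionally `"spleen"`).
#' @param tissue_bias_scale Multiplier on bias effects in the spleen.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 expression is
#'   normal with these parameters (a heavy right tail on the natural scale).
#' @param quartile_coupling When `TRUE`, displacement scales with the gene's
#'   effect rank so demasculinization grows across bias quartiles.
#' @param motif_frac_male,motif_frac_background Fractions of male-biased /
#'   other genes given an upstream androgen binding site.
#' @param dnds_means Per-category list of `c(dn=, ds=)` means for the
#'   divergence generator.
#' @param seed Default seed used by [simulate_dataset()].
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes_autosome = 10000,
                              n_genes_z = 360,
                              frac_male_biased = 0.22,
                              frac_female_biased = 0.29,
                              effect_min_log2 = 1.2,
                              effect_scale_log2 = 0.8,
                              demasc_d = 0.4,
                              fem_f = 0.4,
                              dispersion = 0.1,
                              depth = 26e6,
                              depth_cv = 0.2,
                              n_per_morph = 6,
                              z_dosage_offset_log2 = 0.5,
                              tissues = "gonad",
                              tissue_bias_scale = 0.3,
                              baseline_log2_mean = 4,
                              baseline_log2_sd = 2,
                              quartile_coupling = FALSE,
                              motif_frac_male = 0.35,
                              motif_frac_background = 0.10,
                              dnds_means = list(
                                male = c(dn = 0.0069, ds = 0.051),
                                female = c(dn = 0.0051, ds = 0.054),
                                unbiased = c(dn = 0.0050, ds = 0.051)),
                              seed = 1L) {
  cfg <- as.list(environment())
  if (frac_male_biased + frac_female_biased > 1) {
    abort("bias fractions must sum to at most 1")
  }
  stopifnot(demasc_d >= 0, demasc_d <= 1, fem_f >= 0, fem_f <= 1,
            dispersion > 0, depth > 0, n_per_morph >= 1,
            effect_min_log2 >= 0, effect_scale_log2 > 0,
            tissue_bias_scale >= 0, tissue_bias_scale <= 1)
  stopifnot(all(tissues %in% c("gonad", "spleen")))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a morph-continuum dataset with ground truth
#'
#' Generates a [count_matrix()] (with gene and sample sheets), a per-gene
#' truth table, androgen binding-site intervals in BED convention, and
#' per-gene divergence records, all from one [simulation_config()]. Same seed
#' and config give bit-identical output.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A `morph_simulation` list: `counts` (count_matrix), `truth`
#'   (tibble: gene, class, true category, signed true effect, displacement),
#'   `tfbs` (BED tibble: chrom, start, end, name), `divergence`
#'   (`divergence_records`).
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)

  n_g <- cfg$n_genes_autosome + cfg$n_genes_z
  gene_id <- sprintf("g%05d", seq_len(n_g))
  chrom_class <- rep(c("autosome", "Z"),
                     c(cfg$n_genes_autosome, cfg$n_genes_z))
  chrom <- ifelse(chrom_class == "Z", "chrZ", "chrA")
  exonic_length <- pmax(200, round(rlnorm(n_g, log(1500), 0.6)))
  strand <- sample(c("+", "-"), n_g, replace = TRUE)
  # genes spaced 50 kb apart so upstream windows never reach a neighbour
  pos_in_class <- stats::ave(seq_len(n_g), chrom, FUN = seq_along)
  tss_coordinate <- 20000 + (pos_in_class - 1) * 50000

  category <- unname(unlist(
    lapply(split(seq_len(n_g), chrom_class), function(idx) {
      n <- length(idx)
      n_m <- round(cfg$frac_male_biased * n)
      n_f <- round(cfg$frac_female_biased * n)
      sample(rep(c("male", "female", "unbiased"), c(n_m, n_f, n - n_m - n_f)))
    })[c("autosome", "Z")]))

  effect <- ifelse(category == "unbiased", 0,
                   cfg$effect_min_log2 + rexp(n_g, 1 / cfg$effect_scale_log2))
  disp_frac <- ifelse(category == "male", cfg$demasc_d,
                      ifelse(category == "female", cfg$fem_f, 0))
  if (cfg$quartile_coupling) {
    # stronger displacement for more biased genes (scaled by effect rank)
    rk <- stats::ave(effect, category, FUN = function(x) rank(x) / length(x))
    disp_frac <- disp_frac * 2 * rk * (category != "unbiased")
  }

  base <- rnorm(n_g, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  genes <- tibble(gene_id, chrom_class, chrom, exonic_length,
                  tss_coordinate, strand)
  truth <- tibble(gene_id, chrom_class, category,
                  effect_log2 = effect * ifelse(category == "female", -1, 1),
                  displacement = disp_frac)
  attr(truth, "demasc_d") <- cfg$demasc_d
  attr(truth, "fem_f") <- cfg$fem_f
  attr(truth, "seed") <- seed

  all_counts <- list(); all_samples <- list()
  for (tis in cfg$tissues) {
    scale <- if (tis == "gonad") 1 else cfg$tissue_bias_scale
    e <- effect * scale
    # bias by reduction in the opposite sex relative to the shared baseline
    mu_dom <- base - ifelse(category == "female", e, 0)
    mu_fem <- base - ifelse(category == "male", e, 0)
    mu_sub <- mu_dom - disp_frac * (mu_dom - mu_fem)
    zm <- (chrom_class == "Z") * cfg$z_dosage_offset_log2
    mu <- cbind(female = mu_fem, subordinate = mu_sub + zm,
                dominant = mu_dom + zm)

    # compositional expected counts: library size times relative share,
    # with read yield proportional to transcript abundance times length
    weight <- 2^mu * (exonic_length / 1000)
    share <- sweep(weight, 2, colSums(weight), "/")

    for (m in .MORPHS) {
      for (r in seq_len(cfg$n_per_morph)) {
        lib <- rlnorm(1, log(cfg$depth) - log(1 + cfg$depth_cv^2) / 2,
                      sqrt(log(1 + cfg$depth_cv^2)))
        k <- rnbinom(n_g, mu = share[, m] * lib, size = 1 / cfg$dispersion)
        sid <- sprintf("%s_%s_%02d", substr(tis, 1, 3), m, r)
        all_counts[[sid]] <- k
        # library_size is the sample's total mappable reads (the drawn depth),
        # of which the realized per-gene counts are one draw; normalizing by
        # it rather than the column sum matches real data, where totals are
        # spread over far more genes than any desk-scale simulation carries
        all_samples[[sid]] <- tibble(sample_id = sid, morph = m, tissue = tis,
                                     library_size = round(lib))
      }
    }
  }
  counts <- do.call(cbind, all_counts)
  rownames(counts) <- gene_id
  samples <- bind_rows(all_samples)
  cm <- count_matrix(counts, samples, genes)

  # androgen binding sites upstream of a fraction of genes
  p_motif <- ifelse(category == "male", cfg$motif_frac_male,
                    cfg$motif_frac_background)
  has_motif <- runif(n_g) < p_motif
  up <- round(runif(sum(has_motif), 100, 9500))
  mid <- ifelse(strand[has_motif] == "+",
                tss_coordinate[has_motif] - up,
                tss_coordinate[has_motif] + up)
  tfbs <- tibble(chrom = chrom[has_motif],
                 start = pmax(0, round(mid - 8)),   # 0-based half-open, 15 bp
                 end = pmax(0, round(mid - 8)) + 15,
                 name = paste0("ar_", gene_id[has_motif]))

  # divergence records with category-specific rate means
  dn_mean <- vapply(category, function(cc) cfg$dnds_means[[cc]]["dn"], 1)
  ds_mean <- vapply(category, function(cc) cfg$dnds_means[[cc]]["ds"], 1)
  aln_len <- round(exonic_length * runif(n_g, 0.7, 0.95))
  divergence <- tibble(
    gene_id,
    nonsyn_sites = round(0.75 * aln_len),
    dn = rgamma(n_g, shape = 0.8, scale = dn_mean / 0.8),
    syn_sites = aln_len - round(0.75 * aln_len),
    ds = rgamma(n_g, shape = 2, scale = ds_mean / 2),
    gapless_len = aln_len,
    has_inframe_stop = runif(n_g) < 0.003,
    is_retrotransposon = runif(n_g) < 0.002)
  sat <- runif(n_g) < 0.015  # saturated alignments past the dS cutoff
  divergence$ds[sat] <- runif(sum(sat), 2.05, 5)
  divergence <- as_divergence_records(divergence)

  structure(list(counts = cm, truth = truth, tfbs = tfbs,
                 divergence = divergence, config = cfg, seed = seed),
            class = "morph_simulation")
}

#' @export
print.morph_simulation <- function(x, ...) {
  cat(sprintf("<morph_simulation> seed %d\n", x$seed))
  print(x$counts)
  invisible(x)
}

#' Estimate the continuum displacement of subordinate males
#'
#' For each sex-biased gene the subordinate position along the
#' dominant-to-female axis is `(dominant - subordinate) / (dominant - female)`
#' on per-gene mean log2 expression; the estimator returns the median over
#' male-biased genes (`d_hat`) and over female-biased genes (`f_hat`),
#' restricted to genes whose dominant-female gap exceeds `min_gap` log2 units
#' (ratios on small gaps are unstable). Per-gene ratios are clipped to
#' `[-0.5, 1.5]` and the clipped fraction reported.
#'
#' @param ms A [morph_means()] summary.
#' @param sbt A [classify_sex_bias()] table.
#' @param min_gap Minimum |dominant - female| gap in log2 units (default 0.5).
#' @return One-row tibble: `d_hat`, `f_hat`, genes used per direction, and the
#'   clipped fraction.
#' @export
recover_continuum <- function(ms, sbt, min_gap = 0.5) {
  ratios <- function(ids) {
    rows <- ms[ms$gene_id %in% ids, ]
    gap <- rows$dominant - rows$female
    rows <- rows[abs(gap) > min_gap, ]
    if (!nrow(rows)) return(NULL)
    (rows$dominant - rows$subordinate) / (rows$dominant - rows$female)
  }
  r_m <- ratios(sbt$gene_id[sbt$category == "male"])
  r_f <- ratios(sbt$gene_id[sbt$category == "female"])
  n_used <- length(r_m) + length(r_f)
  if (n_used < 20) abort("fewer than 20 biased genes with a usable gap")
  clip <- function(x) pmin(pmax(x, -0.5), 1.5)
  n_clip <- sum(abs(c(r_m, r_f)) > 1.5 | c(r_m, r_f) < -0.5)
  tibble(d_hat = if (length(r_m)) median(clip(r_m)) else NA_real_,
         f_hat = if (length(r_f)) median(clip(r_f)) else NA_real_,
         n_male = length(r_m), n_female = length(r_f),
         clip_fraction = n_clip / n_used)
}
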