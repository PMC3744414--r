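test_that("renormalization conserves non-male-biased counts and library math", {
  cfg <- simulation_config(n_genes_autosome = 200, n_genes_z = 20,
                           depth = 5e5, seed = 131)
  cm <- filter_expressed(simulate_dataset(cfg)$counts)
  sbt <- classify_sex_bias(cm)
  em <- renormalize_without_malebiased(cm, sbt)

  male_ids <- sbt$gene_id[sbt$category == "male"]
  keep <- !cm$genes$gene_id %in% male_ids
  # remaining library sizes = original minus male-biased column sums
  expect_equal(unname(em$library_sizes),
               unname(library_sizes(cm) -
                        colSums(cm$counts[!keep, , drop = FALSE])))
  # counts of surviving genes untouched: fpkm recomputable from them
  expect_equal(em$fpkm * outer(em$genes$exonic_length, em$library_sizes) / 1e9,
               cm$counts[keep, , drop = FALSE], tolerance = 1e-12)

  # with no male-biased genes the result is plain compute_fpkm
  sbt0 <- sbt; sbt0$category[sbt0$category == "male"] <- "unbiased"
  em0 <- renormalize_without_malebiased(cm, sbt0)
  expect_equal(em0$fpkm, compute_fpkm(cm)$fpkm)

  sbt_all <- sbt; sbt_all$category <- "male"
  expect_error(renormalize_without_malebiased(cm, sbt_all), "all genes")
})

test_that("rtm randomization is reproducible and validates sample counts", {
  cfg <- simulation_config(n_genes_autosome = 120, n_genes_z = 20,
                           depth = 5e5, n_per_morph = 6, seed = 141)
  cm <- filter_expressed(simulate_dataset(cfg)$counts)
  r1 <- rtm_randomization(cm, n_iter = 4, n_define = 3, seed = 99)
  r2 <- rtm_randomization(cm, n_iter = 4, n_define = 3, seed = 99)
  expect_identical(r1$iterations, r2$iterations)
  expect_true(all(r1$iterations$p_bonf >= r1$iterations$p_raw))
  # defining and held-out samples are disjoint by construction: defining ids
  # recorded per iteration never exhaust a morph
  expect_true(all(nchar(r1$iterations$defining_dominant) > 0))

  fem_ids <- cm$samples$sample_id[cm$samples$morph == "female"]
  cm4 <- dimorphix:::subset_samples(
    cm, cm$samples$morph != "female" |
      cm$samples$sample_id %in% fem_ids[1:4])
  expect_error(rtm_randomization(cm4, n_iter = 2, n_define = 3), "at least")
})

test_that("motif annotation flags nested upstream windows correctly", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    chrom = "chr1",
    tss_coordinate = c(50000, 100000, 150000, 200000),
    strand = c("+", "+", "-", "+"))
  # BED (0-based half-open): midpoints 1 bp, 3000 bp upstream, 3000 bp
  # upstream of a minus-strand gene, and 1 bp DOWNstream (must not count)
  tfbs <- tibble::tibble(
    chrom = "chr1",
    start = c(49998, 96999, 152999, 200000),
    end = c(49999, 97000, 153000, 200001))
  ma <- annotate_motifs(genes, tfbs)
  expect_equal(ma$within_2000, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ma$within_5000, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(ma$within_10000, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(ma$distance_upstream[1:3], c(1, 3000, 3000))
  # g4's downstream site never counts; its nearest upstream site is g3's
  expect_equal(ma$distance_upstream[4], 47000)
  # monotone windows
  expect_true(all(!ma$within_2000 | ma$within_5000))
  expect_true(all(!ma$within_5000 | ma$within_10000))
})

test_that("motif annotation matches a brute-force scan on random intervals", {
  set.seed(151)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:80),
    chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
    tss_coordinate = sample(20000:500000, 80),
    strand = sample(c("+", "-"), 80, replace = TRUE))
  tfbs <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
    start = sample(1:500000, 300))
  tfbs$end <- tfbs$start + 15
  ma <- annotate_motifs(genes, tfbs)
  mid <- (tfbs$start + tfbs$end + 1) / 2
  for (i in seq_len(nrow(genes))) {
    same <- tfbs$chrom == genes$chrom[i]
    d <- if (genes$strand[i] == "+") genes$tss_coordinate[i] - mid[same]
         else mid[same] - genes$tss_coordinate[i]
    d <- d[d > 0]
    expected <- if (length(d)) min(d) else NA_real_
    expect_equal(ma$distance_upstream[i], expected)
    expect_equal(ma$within_5000[i], !is.na(expected) && expected < 5000)
  }
})

test_that("motif annotation reads BED files through rtracklayer", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "sites.bed")
  writeLines(c("chr1\t49998\t49999\tsite1\t0\t+"), bed)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          tss_coordinate = 50000, strand = "+")
  ma <- annotate_motifs(genes, bed)
  expect_true(ma$within_2000)
})

test_that("motif bias tests: degenerate set, printed baseline, exhaustive permutation", {
  # flagged set = all genes: proportion equals genome-wide, z = 0
  n <- 40
  ma <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                       distance_upstream = 1000,
                       within_2000 = TRUE)
  class(ma) <- c("motif_annotation", class(ma))
  sbt <- make_sbt(category = rep(c("male", "unbiased"), n / 2),
                  log2fc = rep(c(2, 0), n / 2))
  ms <- make_ms(female = rnorm(n), subordinate = rnorm(n), dominant = rnorm(n))
  res <- motif_bias_tests(ma, sbt, ms, n_perm = 50, seed = 1)
  expect_equal(res$z, 0)
  expect_equal(res$prop_male_biased, res$genome_prop_male_biased)

  # genome-wide male-biased proportion from the printed study counts
  n2 <- 9872
  sbt2 <- make_sbt(category = rep(c("male", "unbiased"), c(2217, 9872 - 2217)),
                   log2fc = rep(c(2, 0), c(2217, 9872 - 2217)),
                   gene_id = sprintf("G%05d", 1:n2))
  ma2 <- tibble::tibble(gene_id = sprintf("G%05d", 1:n2),
                        distance_upstream = 1000, within_2000 = c(TRUE, rep(FALSE, n2 - 1)))
  class(ma2) <- c("motif_annotation", class(ma2))
  ms2 <- make_ms(female = rnorm(n2), subordinate = rnorm(n2),
                 dominant = rnorm(n2))
  ms2$gene_id <- sprintf("G%05d", 1:n2)
  res2 <- motif_bias_tests(ma2, sbt2, ms2, n_perm = 10, seed = 1)
  expect_equal(round(100 * res2$genome_prop_male_biased, 2), 22.46)

  # permutation p approximates exhaustive enumeration over all 120 subsets
  set.seed(161)
  fc <- rnorm(10)
  ms3 <- make_ms(female = rnorm(10), subordinate = fc, dominant = rep(0, 10))
  sbt3 <- make_sbt(category = rep("unbiased", 10), log2fc = rnorm(10))
  ma3 <- tibble::tibble(gene_id = sprintf("g%03d", 1:10),
                        distance_upstream = 500,
                        within_2000 = c(TRUE, TRUE, TRUE, rep(FALSE, 7)))
  class(ma3) <- c("motif_annotation", class(ma3))
  res3 <- motif_bias_tests(ma3, sbt3, ms3, n_perm = 4000, seed = 2)
  sets <- utils::combn(10, 3)
  centre <- mean(fc)
  obs <- mean(fc[1:3])
  exact <- mean(apply(sets, 2, function(s) {
    abs(mean(fc[s]) - centre) >= abs(obs - centre) - 1e-12
  }))
  expect_equal(res3$p_perm, exact, tolerance = 0.05)
  expect_gte(res3$p_perm, 1 / 4001)
  expect_lte(res3$p_perm, 1)
})
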