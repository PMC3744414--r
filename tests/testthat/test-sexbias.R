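test_that("size factors follow the median-of-ratios definition", {
  counts <- matrix(rep(c(10, 20, 30, 40), 3), nrow = 4)
  cm <- make_cm(counts)
  expect_equal(unname(size_factors(cm)), rep(1, 3))

  cm2 <- make_cm(cbind(counts, counts[, 1] * 2))
  sf <- unname(size_factors(cm2))
  expect_equal(sf[4] / sf[1], 2)

  set.seed(5)
  rcm <- random_cm(100, n_per_morph = 2, mu = 60)
  expect_equal(unname(size_factors(rcm)),
               unname(size_factors_brute(rcm$counts)))
})

test_that("size factors fall back to upper quartiles with a warning", {
  counts <- rbind(c(10, 0, 5), c(0, 8, 4), c(3, 6, 0), c(50, 40, 60))
  counts[4, 1] <- 0  # no gene positive everywhere
  cm <- make_cm(counts)
  expect_warning(sf <- size_factors(cm), "upper-quartile")
  expect_true(all(sf > 0))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(8)
  for (rep in 1:5) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(adj >= p))
  }
})

test_that("nb_test handles degenerate genes and label swaps", {
  set.seed(21)
  cm <- random_cm(60, n_per_morph = 3, mu = 40)
  cm$counts[1, ] <- 0
  de <- nb_test(cm, "female", "dominant")
  expect_equal(de$pvalue[1], 1)
  expect_true(all(de$pvalue >= 0 & de$pvalue <= 1))
  expect_true(all(is.finite(de$dispersion)))

  swapped <- nb_test(cm, "dominant", "female")
  expect_equal(swapped$log2fc, -de$log2fc)
  expect_equal(swapped$pvalue, de$pvalue)
})

test_that("nb_test is approximately alpha-calibrated under the null", {
  set.seed(31)
  counts <- matrix(rnbinom(2000 * 8, mu = 100, size = 5), nrow = 2000)
  cm <- make_cm(counts, morphs = rep(c("female", "dominant"), each = 4))
  de <- nb_test(cm, "female", "dominant")
  expect_gt(mean(de$pvalue < 0.05), 0.025)
  expect_lt(mean(de$pvalue < 0.05), 0.075)
})

test_that("nb_test agrees with an exhaustive permutation test on a printed fixture", {
  counts <- matrix(c(12, 10, 8, 19, 15, 22), nrow = 1,
                   dimnames = list("g1", paste0("s", 1:6)))
  cm <- make_cm(counts, morphs = rep(c("female", "dominant"), each = 3))
  de <- nb_test(cm, "female", "dominant")

  sf <- size_factors(cm$counts)
  q <- as.numeric(counts) / sf
  splits <- utils::combn(6, 3)
  obs <- abs(mean(q[1:3]) - mean(q[4:6]))
  stats <- apply(splits, 2, function(a) abs(mean(q[a]) - mean(q[-a])))
  p_perm <- mean(stats >= obs - 1e-12)
  expect_gt(de$pvalue, p_perm / 2)
  expect_lt(de$pvalue, p_perm * 2)
})

test_that("classification applies fold-change and significance rules", {
  # 16 context genes stabilise size factors; focal genes planted on top
  set.seed(41)
  base <- matrix(rnbinom(16 * 6, mu = 200, size = 50), nrow = 16)
  focal_strong <- c(50, 55, 60, 240, 230, 250)   # ~4x, tight
  focal_noisy <- c(5, 300, 40, 120, 400, 30)     # ~4x on average, wild
  counts <- rbind(base, focal_strong, focal_noisy)
  rownames(counts) <- NULL
  cm <- make_cm(counts, morphs = rep(c("female", "dominant"), each = 3))
  sbt <- classify_sex_bias(cm)
  expect_s3_class(sbt, "sex_bias_table")
  strong <- sbt[sbt$gene_id == "g017", ]
  expect_identical(strong$category, "male")
  expect_lt(strong$adj_pvalue, 0.05)
  noisy <- sbt[sbt$gene_id == "g018", ]
  expect_identical(noisy$category, "unbiased")
  expect_gt(noisy$adj_pvalue, 0.05)

  expect_error(classify_sex_bias(cm, fc_threshold = 0.5), "fc_threshold")
})

test_that("p-only classification is a superset of fold-change classification", {
  cfg <- simulation_config(n_genes_autosome = 400, n_genes_z = 40,
                           depth = 1e6, seed = 51)
  cm <- filter_expressed(simulate_dataset(cfg)$counts)
  strict <- classify_sex_bias(cm, mode = "fc_and_p")
  loose <- classify_sex_bias(cm, mode = "p_only")
  biased_strict <- strict$gene_id[strict$category != "unbiased"]
  biased_loose <- loose$gene_id[loose$category != "unbiased"]
  expect_true(all(biased_strict %in% biased_loose))
})

test_that("planted bias fractions are recovered within 3 points", {
  hits <- sapply(1:3, function(seed) {
    cfg <- simulation_config(n_genes_autosome = 800, n_genes_z = 60,
                             frac_male_biased = 0.20, frac_female_biased = 0.25,
                             effect_min_log2 = 3, effect_scale_log2 = 0.01,
                             depth = 1e6, seed = seed)
    cm <- filter_expressed(simulate_dataset(cfg)$counts)
    sbt <- classify_sex_bias(cm)
    auto <- sbt[sbt$chrom_class == "autosome", ]
    c(male = mean(auto$category == "male"),
      female = mean(auto$category == "female"))
  })
  expect_true(all(abs(hits["male", ] - 0.20) <= 0.03))
  expect_true(all(abs(hits["female", ] - 0.25) <= 0.03))
})

test_that("quartile bins drop the fold criterion and split evenly", {
  lfc <- c(seq(0.5, 4, length.out = 8), -seq(0.6, 3, length.out = 8))
  sbt <- make_sbt(category = ifelse(lfc >= 1, "male",
                                    ifelse(lfc <= -1, "female", "unbiased")),
                  log2fc = lfc, adj_pvalue = rep(0.01, 16))
  out <- quartile_bins(sbt)
  male_side <- out[out$log2fc > 0, ]
  expect_equal(as.integer(table(male_side$quartile)), rep(2L, 4))
  # a significant sub-threshold gene (1.7-fold, log2fc 0.77) is binned
  weak <- out[out$log2fc > 0 & out$log2fc < 1, ]
  expect_true(all(!is.na(weak$quartile)))
  expect_true(all(weak$category == "unbiased"))
  # quartile 4 holds the largest |log2fc|
  expect_equal(male_side$quartile[which.max(male_side$log2fc)], 4L)

  # boundaries equal brute-force rank binning
  set.seed(61)
  lfc2 <- rnorm(37, 0, 2)
  sbt2 <- make_sbt(category = rep("unbiased", 37), log2fc = lfc2,
                   adj_pvalue = rep(0.01, 37))
  out2 <- quartile_bins(sbt2)
  pos <- which(lfc2 > 0)
  ord <- pos[order(abs(lfc2[pos]))]
  expect_equal(out2$quartile[ord],
               as.integer(ceiling(4 * seq_along(ord) / length(ord))))
})

test_that("non-significant genes never receive a quartile", {
  sbt <- make_sbt(category = rep("unbiased", 10),
                  log2fc = rnorm(10),
                  adj_pvalue = rep(0.5, 10))
  out <- quartile_bins(sbt)
  expect_true(all(is.na(out$quartile)))
})
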