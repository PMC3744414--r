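test_that("demasc_fem_test returns null results on identical morphs", {
  ms <- make_ms(female = rnorm(20), subordinate = 1:20 / 10,
                dominant = 1:20 / 10)
  sbt <- make_sbt(category = rep("male", 20), log2fc = rep(2, 20))
  res <- demasc_fem_test(ms, sbt, "male")
  expect_equal(res$p_value, 1)
  expect_equal(res$shift_sub_vs_dom, 0)
  expect_identical(res$direction, "none")
  no_female <- make_sbt(category = rep("male", 20), log2fc = rep(2, 20))
  expect_error(demasc_fem_test(ms, no_female, "female"), "empty")
})

test_that("signed-rank p matches exhaustive enumeration on a 10-gene set", {
  set.seed(71)
  for (rep in 1:4) {
    sub <- rnorm(10); dom <- rnorm(10, mean = 0.3)
    ms <- make_ms(female = rnorm(10), subordinate = sub, dominant = dom)
    sbt <- make_sbt(category = rep("male", 10), log2fc = rep(2, 10))
    res <- demasc_fem_test(ms, sbt, "male")
    expect_equal(res$p_value, signed_rank_exact(sub, dom), tolerance = 1e-10)
  }
})

test_that("demasculinization is detected on the simulated continuum", {
  hits <- sapply(1:3, function(seed) {
    cfg <- simulation_config(n_genes_autosome = 600, n_genes_z = 40,
                             demasc_d = 0.4, fem_f = 0.4, depth = 1e6,
                             seed = seed)
    sim <- simulate_dataset(cfg)
    cm <- filter_expressed(sim$counts)
    ms <- morph_means(compute_fpkm(cm))
    sbt <- classify_sex_bias(cm)
    m <- demasc_fem_test(ms, sbt, "male")
    f <- demasc_fem_test(ms, sbt, "female")
    m$direction == "demasculinized" && f$direction == "feminized"
  })
  expect_true(all(hits))
})

test_that("decoupling regression recovers exact linear constructions", {
  set.seed(81)
  bias <- c(runif(15, 1, 4), -runif(15, 1, 4))  # male-positive log2fc
  dom <- rnorm(30, 5)
  # subordinate displaced by exactly 0.3 x female-bias degree
  sub <- dom - 0.3 * (-bias)
  ms <- make_ms(female = rnorm(30, 5), subordinate = sub, dominant = dom)
  sbt <- make_sbt(category = ifelse(bias > 0, "male", "female"),
                  log2fc = bias)
  fit <- decoupling_regression(ms, sbt)
  expect_equal(fit$slope, 0.3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # subordinate identical to dominant: no decoupling
  ms0 <- make_ms(female = rnorm(30, 5), subordinate = dom, dominant = dom)
  fit0 <- decoupling_regression(ms0, sbt)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)

  td <- tidy(fit); gl <- glance(fit)
  expect_identical(td$term, c("intercept", "bias_degree"))
  expect_equal(gl$slope, fit$slope)
})

test_that("slope comparison flags separated and overlapping classes", {
  set.seed(91)
  n <- 200
  bias <- runif(2 * n, 1, 4)
  cls <- rep(c("autosome", "Z"), each = n)
  slope_true <- ifelse(cls == "autosome", 0.1, 0.9)
  dom <- rnorm(2 * n, 6)
  sub <- dom - slope_true * bias + rnorm(2 * n, 0, 0.05)
  ms <- make_ms(female = rnorm(2 * n), subordinate = sub, dominant = dom,
                chrom_class = cls)
  sbt <- make_sbt(category = rep("male", 2 * n), log2fc = bias,
                  chrom_class = cls)
  out <- slope_compare(ms, sbt)
  expect_false(attr(out, "overlap"))
  expect_lt(abs(out$slope[out$chrom_class == "autosome"] - 0.1), 0.02)
  expect_lt(abs(out$slope[out$chrom_class == "Z"] - 0.9), 0.02)

  # identical gene sets duplicated into both classes: identical slopes
  ms2 <- make_ms(female = ms$female[1:(2*n)],
                 subordinate = rep(sub[1:n], 2),
                 dominant = rep(dom[1:n], 2), chrom_class = cls)
  sbt2 <- make_sbt(category = rep("male", 2 * n),
                   log2fc = rep(bias[1:n], 2), chrom_class = cls)
  out2 <- slope_compare(ms2, sbt2)
  expect_equal(out2$slope[1], out2$slope[2])
  expect_true(attr(out2, "overlap"))
})

test_that("slope CI width shrinks like one over root n", {
  set.seed(101)
  widths <- sapply(c(50, 200, 800), function(n) {
    bias <- runif(n, 1, 4)
    dom <- rnorm(n, 6)
    sub <- dom - 0.3 * bias + rnorm(n, 0, 0.5)
    ms <- make_ms(female = rnorm(n), subordinate = sub, dominant = dom)
    sbt <- make_sbt(category = rep("male", n), log2fc = bias)
    out <- slope_compare(ms, sbt)
    out$ci_hi - out$ci_lo
  })
  ratio <- unname(widths[1:2] / widths[2:3])
  expect_equal(ratio, rep(2, 2), tolerance = 0.35)
})

test_that("Spearman matrix matches rank-then-Pearson and permutes consistently", {
  set.seed(111)
  f <- rnorm(60); s <- f + rnorm(60, 0, 0.5); d <- s + rnorm(60, 0, 0.5)
  ms <- make_ms(female = f, subordinate = s, dominant = d)
  mc <- spearman_morph_matrix(ms, category = "all")
  expect_equal(diag(mc$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(mc$rho["female", "dominant"], spearman_brute(f, d))
  expect_equal(mc$rho["subordinate", "dominant"], spearman_brute(s, d))

  # relabeling morphs permutes the matrix consistently
  ms2 <- make_ms(female = d, subordinate = s, dominant = f)
  mc2 <- spearman_morph_matrix(ms2, category = "all")
  expect_equal(mc2$rho["female", "subordinate"],
               mc$rho["dominant", "subordinate"])

  expect_error(spearman_morph_matrix(
    make_ms(rep(1, 12), rnorm(12), rnorm(12)), category = "all"),
    "constant")
})

test_that("Fisher r-to-z reproduces the printed correlation contrast", {
  res <- fisher_rz(0.881, 2217, 0.970, 2908)
  expect_lt(res$p_value, 1e-4)
  expect_lt(res$z, 0)
  expect_equal(fisher_rz(0.5, 100, 0.5, 100)$z, 0)
})

test_that("presence Venn partitions match brute-force set algebra", {
  set.seed(121)
  counts <- matrix(rbinom(50 * 9, 1, 0.6) * rpois(50 * 9, 5), nrow = 50)
  cm <- make_cm(counts, morphs = rep(c("female", "subordinate", "dominant"),
                                     each = 3))
  vp <- presence_venn(cm)
  present <- sapply(c("female", "subordinate", "dominant"), function(m) {
    rowMeans(counts[, cm$samples$morph == m] >= 1) >= 0.5
  })
  brute <- c(
    female_only = sum(present[, 1] & !present[, 2] & !present[, 3]),
    subordinate_only = sum(!present[, 1] & present[, 2] & !present[, 3]),
    dominant_only = sum(!present[, 1] & !present[, 2] & present[, 3]),
    female_subordinate = sum(present[, 1] & present[, 2] & !present[, 3]),
    female_dominant = sum(present[, 1] & !present[, 2] & present[, 3]),
    subordinate_dominant = sum(!present[, 1] & present[, 2] & present[, 3]),
    all_three = sum(present[, 1] & present[, 2] & present[, 3]))
  expect_equal(setNames(vp$n, vp$region), brute[vp$region])
  expect_equal(attr(vp, "total") + attr(vp, "n_absent"), 50)

  # gene order invariance
  cm_shuf <- dimorphix:::subset_genes(cm, sample(nrow(counts)))
  vp2 <- presence_venn(cm_shuf)
  expect_equal(vp2$n, vp$n)
})

test_that("shared-gene z-test reports ratios and calibrated p-values", {
  null <- shared_gene_ztest(30, 30, 500, 500)
  expect_equal(null$z, 0)
  expect_equal(null$p_value, 1)

  res <- shared_gene_ztest(188, 41, 9872, 9872)
  expect_gt(res$ratio, 4)
  expect_lt(res$p_value, 1e-5)

  # matches the pooled-variance two-proportion chi-square without correction
  for (case in list(c(8, 3, 40, 50), c(12, 20, 80, 90))) {
    mine <- shared_gene_ztest(case[1], case[2], case[3], case[4])
    ref <- suppressWarnings(
      prop.test(case[1:2], case[3:4], correct = FALSE))$p.value
    expect_equal(mine$p_value, ref, tolerance = 1e-12)
  }
  expect_error(shared_gene_ztest(5, 5, 0, 10), "positive")
  expect_error(shared_gene_ztest(15, 5, 10, 10), "exceed")
})
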