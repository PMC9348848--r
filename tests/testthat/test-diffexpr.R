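test_that("QC flags collapsed libraries and only those", {
  set.seed(1)
  counts <- matrix(rnbinom(200 * 12, mu = 50, size = 5), 200, 12,
                   dimnames = list(NULL, paste0("s", 1:12)))
  qc0 <- qc_filter(counts)
  expect_false(any(qc0$outlier))

  counts[, 3] <- rbinom(200, counts[, 3], 0.01)  # ~100x lower library
  qc1 <- qc_filter(counts)
  expect_identical(attr(qc1, "excluded"), "s3")

  identical_cols <- matrix(5L, 10, 6, dimnames = list(NULL, paste0("s", 1:6)))
  expect_false(any(qc_filter(identical_cols)$outlier))

  expect_error(qc_filter(counts[, 1:3]), ">= 4 samples")
})

test_that("QC recovers the generator's failed replicates", {
  hits <- 0
  for (s in 1:20) {
    sim <- gen_counts(sim_config(seed = s, chrom_proportions = c(I = 800, X = 800),
                                 n_samples_per_group = 10,
                                 failed_replicate_rate = 0.15))
    qc <- qc_filter(sim$counts)
    hits <- hits + identical(sort(attr(qc, "excluded")),
                             sort(attr(sim$truth, "failed_samples")))
  }
  expect_gte(hits, 19)
})

test_that("size factors are exact on scaled columns and recover truth", {
  base <- matrix(rep(c(10L, 20L, 40L, 100L), 25), 100, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  for (m in c("median_ratio", "deconvolution")) {
    expect_equal(unname(size_factors(base, m)), rep(1, 4), tolerance = 1e-6)
  }
  doubled <- base
  doubled[, 2] <- base[, 2] * 2L
  for (m in c("median_ratio", "deconvolution")) {
    sf <- size_factors(doubled, m)
    expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-6)
  }

  # parameter recovery from generated data with known library scalings
  lf <- 2^seq(-1, 1, length.out = 24)
  sim <- gen_counts(sim_config(seed = 3, chrom_proportions = c(I = 2000, X = 2000),
                               de_fraction = 0, dropout_rate = 0.25,
                               library_factors = lf))
  sf <- size_factors(sim$counts, "deconvolution")
  truth <- lf / exp(mean(log(lf)))
  expect_gte(cor(sf, truth), 0.95)
  expect_lt(max(abs(sf / truth - 1)), 0.10)

  allzero_somewhere <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                              dimnames = list(NULL, c("a", "b")))
  expect_error(size_factors(allzero_somewhere, "median_ratio"),
               "deconvolution")
})

test_that("scaling one sample scales its factor and leaves p-values fixed", {
  sim <- gen_counts(sim_config(seed = 6, chrom_proportions = c(I = 400, X = 400),
                               n_samples_per_group = 6, de_fraction = 0.1,
                               dropout_rate = 0, base_mean_log_mu = log(200),
                               base_mean_log_sd = 0.5))
  counts <- sim$counts
  groups <- factor(sim$sample_meta$genotype, levels = c("wt", "mutant"))
  scaled <- counts
  scaled[, 4] <- counts[, 4] * 3L
  # exact for the closed-form estimator; statistical for the pooled one
  for (m in c("median_ratio", "deconvolution")) {
    sf0 <- size_factors(counts, m)
    sf1 <- size_factors(scaled, m)
    tol <- if (m == "median_ratio") 1e-6 else 0.08
    expect_equal(unname(sf1[4] / sf0[4]) / unname(sf1[1] / sf0[1]), 3,
                 tolerance = tol)
  }
  de0 <- fit_de(counts, size_factors(counts, "median_ratio"), groups)
  de1 <- fit_de(scaled, size_factors(scaled, "median_ratio"), groups)
  ok <- !is.na(de0$p)
  expect_equal(de1$p[ok], de0$p[ok], tolerance = 0.05)
  expect_gt(cor(de1$lfc_raw[ok], de0$lfc_raw[ok]), 0.999)
})

test_that("Wald test is calibrated under the null and powered for planted LFCs", {
  # null: no planted signal, 12 vs 12
  null_sim <- gen_counts(sim_config(seed = 11, chrom_proportions = c(I = 2500, X = 2500),
                                    de_fraction = 0))
  g <- factor(null_sim$sample_meta$genotype, levels = c("wt", "mutant"))
  de <- fit_de(null_sim$counts, size_factors(null_sim$counts), g)
  ok <- !is.na(de$p)
  expect_gte(sum(ok), 4000)
  frac <- mean(de$p[ok] < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)

  # power: planted |log2 fc| = 2 at moderate expression
  alt <- gen_counts(sim_config(seed = 5))
  g2 <- factor(alt$sample_meta$genotype, levels = c("wt", "mutant"))
  de2 <- fit_de(alt$counts, size_factors(alt$counts), g2)
  plant <- alt$truth$is_de & alt$truth$base_mean >= 20
  expect_gte(mean(de2$q[plant] < 0.05, na.rm = TRUE), 0.8)
  # planted LFC recovered with small bias at decent expression
  expect_lt(abs(mean(de2$lfc_raw[plant], na.rm = TRUE) - 2), 0.25)
  # direction: planted genes called UP, not DOWN
  expect_equal(sum(de2$call[plant] == "DOWN"), 0)
})

test_that("degenerate genes are handled explicitly", {
  counts <- rbind(gene_a = rep(10L, 8), gene_zero = rep(0L, 8))
  colnames(counts) <- paste0("s", 1:8)
  g <- factor(rep(c("wt", "mutant"), each = 4), levels = c("wt", "mutant"))
  de <- fit_de(counts, rep(1, 8), g)
  expect_equal(de$lfc_raw[1], 0, tolerance = 1e-8)
  expect_gte(de$p[1], 0.999)
  expect_true(is.na(de$p[2]))
  expect_equal(de$call[2], "NS")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (m in c(5, 100, 1000)) {
    p <- runif(m)^2
    p[sample(m, m %/% 10)] <- NA
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("LFC shrinkage pulls toward zero and respects limits", {
  set.seed(3)
  de <- data.frame(lfc_raw = rnorm(500, 0, 1.5),
                   se = runif(500, 0.05, 2))
  sh <- shrink_lfc(de)
  expect_true(all(abs(sh) <= abs(de$lfc_raw) + 1e-12))
  expect_equal(sh[de$lfc_raw == 0], numeric(0))  # none exactly zero by chance
  de0 <- data.frame(lfc_raw = c(0, 2), se = c(0.5, 1e-8))
  sh0 <- shrink_lfc(rbind(de, de0))
  expect_equal(sh0[501], 0)
  expect_equal(sh0[502], 2, tolerance = 1e-4)  # se -> 0 keeps the raw LFC
})

test_that("calls obey the strict q threshold and LFC sign", {
  de <- data.frame(q = c(0.049, 0.05, 0.01, NA),
                   lfc_raw = c(1, 1, -0.3, 2))
  expect_equal(classify(de), c("UP", "NS", "DOWN", "NS"))
})

test_that("expressed background uses an inclusive mean threshold", {
  counts <- rbind(boundary = c(0L, 0L, 3L), zero = c(0L, 0L, 0L),
                  high = c(9L, 9L, 9L))
  colnames(counts) <- paste0("s", 1:3)
  bg <- expressed_background(counts, rep("wt", 3), "wt")
  expect_identical(bg, c("boundary", "high"))

  sim <- gen_counts(sim_config(seed = 2, chrom_proportions = c(I = 1500, X = 1500),
                               de_fraction = 0, dropout_rate = 0,
                               library_factors = rep(1, 24)))
  bg2 <- expressed_background(sim$counts, sim$sample_meta$genotype, "wt")
  truth_bg <- sim$truth$gene_id[sim$truth$mean_wt >= 1]
  agree <- length(intersect(bg2, truth_bg)) / length(union(bg2, truth_bg))
  expect_gte(agree, 0.95)
})

test_that("variance-stabilized PCA separates groups and orders components", {
  sim <- gen_counts(sim_config(seed = 13, chrom_proportions = c(I = 500, X = 500),
                               n_samples_per_group = 6, de_fraction = 0.3,
                               de_log2fc = 3, dropout_rate = 0))
  pca <- vst_pca(sim$counts, size_factors(sim$counts))
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  expect_lte(sum(pca$variance_explained), 1 + 1e-8)
  grp <- sim$sample_meta$genotype
  pc1 <- pca$coordinates[, 1]
  gap <- abs(mean(pc1[grp == "wt"]) - mean(pc1[grp == "mutant"]))
  spread <- max(sd(pc1[grp == "wt"]), sd(pc1[grp == "mutant"]))
  expect_gt(gap, 2 * spread)  # clear separation on PC1

  dup <- cbind(sim$counts, dup1 = sim$counts[, 1])
  sf <- size_factors(sim$counts)
  pca2 <- vst_pca(dup, c(sf, sf[1]))
  expect_equal(unname(pca2$coordinates[1, ]), unname(pca2$coordinates[13, ]),
               tolerance = 1e-8)
})

test_that("Spearman concordance reproduces hand-computed values", {
  mk <- function(l) data.frame(gene_id = letters[seq_along(l)], lfc_raw = l)
  expect_equal(spearman_lfc(mk(1:5), mk(1:5), letters[1:5])$rho, 1)
  expect_equal(spearman_lfc(mk(1:5), mk(5:1), letters[1:5])$rho, -1)
  # d^2 = (1,1,1,1): rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_lfc(mk(c(1, 2, 3, 4)), mk(c(2, 1, 4, 3)),
                            letters[1:4])$rho, 0.6)
  expect_error(spearman_lfc(mk(1:2), mk(1:2), letters[1:2]), ">= 3")
})

test_that("NB Wald fits agree with an established DE implementation", {
  skip_if_not_installed("DESeq2")
  sim <- gen_counts(sim_config(seed = 17, chrom_proportions = c(I = 300, X = 300),
                               n_samples_per_group = 8, de_fraction = 0.2,
                               dropout_rate = 0))
  groups <- factor(sim$sample_meta$genotype, levels = c("wt", "mutant"))
  sf <- size_factors(sim$counts, "median_ratio")
  mine <- fit_de(sim$counts, sf, groups)

  dds <- DESeq2::DESeqDataSetFromMatrix(
    sim$counts, S4Vectors::DataFrame(genotype = groups), ~genotype)
  DESeq2::sizeFactors(dds) <- sf
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  ref <- DESeq2::results(dds, contrast = c("genotype", "mutant", "wt"))

  ok <- !is.na(mine$p) & !is.na(ref$pvalue) & mine$base_mean > 5
  expect_gt(cor(mine$lfc_raw[ok], ref$log2FoldChange[ok]), 0.98)
  expect_gt(cor(-log10(mine$p[ok] + 1e-300), -log10(ref$pvalue[ok] + 1e-300)),
            0.95)
  # significant calls largely coincide
  both <- table(mine = mine$q[ok] < 0.05, ref = ref$padj[ok] < 0.05)
  agree <- sum(diag(both)) / sum(both)
  expect_gt(agree, 0.9)
})
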