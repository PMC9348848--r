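test_that("promoter windows are strand-resolved, half-open, and clipped", {
  anno <- data.frame(gene_id = c("p", "m", "edge"),
                     chrom = "X", strand = c("+", "-", "+"),
                     start = c(1000L, 1000L, 200L),
                     end = c(2000L, 2000L, 900L))
  pr <- build_promoters(anno)
  expect_equal(pr$start, c(500L, 2000L, 0L))
  expect_equal(pr$end, c(1000L, 2500L, 200L))

  bad <- anno
  bad$strand[1] <- "."
  expect_error(build_promoters(bad), "strand")

  clipped <- build_promoters(anno, chrom_lengths = c(X = 2100L))
  expect_equal(clipped$end[2], 2100L)
})

test_that("peak assignment uses >= 1 bp overlap and merges experiments", {
  promoters <- data.frame(gene_id = "g1", chrom = "X",
                          start = 500L, end = 1000L, strand = "+")
  over <- data.frame(chrom = "X", start = 400L, end = 600L, tf_name = "tf")
  expect_equal(assign_peaks(over, promoters)$tf, "g1")
  abut <- data.frame(chrom = "X", start = 1000L, end = 1100L, tf_name = "tf")
  expect_length(assign_peaks(abut, promoters)$tf, 0)

  two_exp <- data.frame(chrom = "X", start = c(400L, 700L),
                        end = c(600L, 800L), tf_name = "tf",
                        experiment_id = c("e1", "e2"))
  expect_equal(assign_peaks(two_exp, promoters)$tf, "g1")

  off_chrom <- data.frame(chrom = c("X", "weird"), start = c(400L, 1L),
                          end = c(600L, 100L), tf_name = "tf")
  expect_warning(res <- assign_peaks(off_chrom, promoters), "skipped")
  expect_equal(res$tf, "g1")
})

test_that("peak assignment equals truth and the brute-force scan", {
  reg <- gen_regulome(regulome_sim_config(seed = 2))
  got <- assign_peaks(reg$peaks, reg$promoters)
  for (nm in names(reg$truth$targets)) {
    expect_identical(got[[nm]] %||% character(0), reg$truth$targets[[nm]],
                     info = nm)
  }

  set.seed(14)
  promoters <- data.frame(gene_id = paste0("g", 1:60),
                          chrom = sample(c("I", "X"), 60, TRUE),
                          start = sample(0:5000, 60), strand = "+")
  promoters$end <- promoters$start + 500L
  peaks <- data.frame(chrom = sample(c("I", "X"), 300, TRUE),
                      start = sample(0:5400, 300),
                      tf_name = sample(c("a", "b", "c"), 300, TRUE))
  peaks$end <- peaks$start + sample(50:400, 300, TRUE)
  got2 <- assign_peaks(peaks, promoters)
  exp2 <- oracle_assign(peaks, promoters)
  for (nm in names(exp2)) expect_identical(got2[[nm]], exp2[[nm]], info = nm)
})

test_that("binds_fraction computes the X UP coverage", {
  xup <- paste0("g", 1:100)
  expect_equal(binds_fraction(c(xup, "other"), xup), 1)
  expect_equal(binds_fraction(c("a", "b"), xup), 0)
  expect_equal(binds_fraction(xup[1:30], xup), 0.30)
  expect_gte(binds_fraction(xup[1:30], xup), 0.25)
  expect_error(binds_fraction("a", character(0)), "non-empty")
})

test_that("PWM scanning finds planted consensus sites and nothing under a flat motif", {
  reg <- gen_regulome(regulome_sim_config(seed = 2))
  hits <- scan_pwm(reg$promoter_seqs, reg$pwms$tf_multi, 1e-4)
  off <- reg$truth$motif_offsets
  expect_true(all(off$gene_id %in% hits))
  hd <- attr(hits, "hits")
  for (i in seq_len(nrow(off))) {
    rows <- hd[hd$gene_id == off$gene_id[i], ]
    expect_true(off$offset[i] %in% rows$offset, label = off$gene_id[i])
  }

  # a motif identical to the background scores 0 everywhere: no hits at
  # any threshold below 1
  flat <- pwm(matrix(0.25, 8, 4), name = "flat")
  none <- scan_pwm(reg$promoter_seqs[1:20], flat, p_threshold = 0.5,
                   background = rep(0.25, 4))
  expect_length(none, 0)
})

test_that("scan p-values are calibrated against the exact null tail", {
  set.seed(6)
  m <- matrix(stats::rgamma(40, 1), 10, 4)
  m <- m / rowSums(m)
  motif <- pwm(m, name = "rand")
  seqs <- setNames(vapply(1:60, function(i) {
    paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  }, character(1)), paste0("s", 1:60))
  hits <- scan_pwm(seqs, motif, p_threshold = 1e-3,
                   background = rep(0.25, 4))
  realized <- attr(hits, "realized_tail")
  expect_lte(realized, 1e-3)
  n_windows <- 2 * 60 * (600 - 10 + 1)
  n_hits <- nrow(attr(hits, "hits"))
  se <- sqrt(realized * (1 - realized) / n_windows)
  expect_lt(abs(n_hits / n_windows - realized), 4 * se + 1e-5)
})

test_that("reverse-complementing sequences and motif leaves hits unchanged", {
  set.seed(3)
  m <- matrix(stats::rgamma(32, 1), 8, 4)
  m <- m / rowSums(m)
  motif <- pwm(m, name = "fwd")
  seqs <- setNames(vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  }, character(1)), paste0("s", 1:30))
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  h1 <- scan_pwm(seqs, motif, 1e-3, background = rep(0.25, 4))
  h2 <- scan_pwm(vapply(seqs, rc, character(1)), pwm_revcomp(motif), 1e-3,
                 background = rep(0.25, 4))
  expect_identical(sort(unclass(h1)), sort(unclass(h2)))
})

test_that("motif scanning skips impossible or ambiguous windows", {
  motif <- pwm(matrix(0.25, 8, 4))
  expect_warning(res <- scan_pwm(c(short = "ACGT"), motif, 0.5),
                 "wider than sequence")
  expect_length(res, 0)
  withN <- c(a = paste0(strrep("N", 50)))
  expect_length(scan_pwm(withN, motif, 0.99), 0)
})

test_that("motif enrichment among X UP genes behaves at the extremes", {
  all_x <- paste0("x", 1:500)
  x_up <- all_x[1:50]
  everywhere <- motif_enrichment(all_x, x_up, all_x)
  expect_equal(everywhere$p, 1)
  only_up <- motif_enrichment(x_up, x_up, all_x)
  expect_lt(only_up$p, 1e-10)
  none <- motif_enrichment(character(0), x_up, all_x)
  expect_equal(none$observed, 0)
  expect_equal(none$p, 1)
})

test_that("the three-criterion filter ranks the constructed multi-hit TF first", {
  reg <- gen_regulome(regulome_sim_config(seed = 2))
  targets <- assign_peaks(reg$peaks, reg$promoters)
  hits <- scan_pwm(reg$promoter_seqs, reg$pwms$tf_multi, 1e-4)
  mp <- motif_enrichment(hits, reg$truth$x_up, reg$annotation$gene_id)
  tft <- data.frame(
    tf_name = c("tf_multi", "tf_peaks", "tf_null"),
    tf_gene_id = c(reg$truth$x_up[1], "not_a_gene", "not_a_gene"),
    motif_p = c(mp$p, NA, NA), stringsAsFactors = FALSE)
  pr <- prioritize(tft, targets, x_up_pgc = reg$truth$x_up)
  expect_equal(pr$tf_name[1], "tf_multi")
  expect_equal(pr$n_criteria[1], 3)
  expect_true(pr$prioritized[1])
  expect_false(pr$prioritized[pr$tf_name == "tf_null"])
  expect_false("tf_null" %in% pr$tf_name[pr$prioritized])
})

test_that("equal criteria counts break ties by binds fraction", {
  xup <- paste0("g", 1:100)
  targets <- list(lo = xup[1:30], hi = xup[1:60])
  tft <- data.frame(tf_name = c("lo", "hi"), tf_gene_id = NA_character_)
  pr <- prioritize(tft, targets, xup)
  expect_equal(pr$tf_name, c("hi", "lo"))
  expect_equal(pr$n_criteria, c(1L, 1L))
})
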