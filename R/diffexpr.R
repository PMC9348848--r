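#' Flag low-quality samples by library size and genes detected
#'
#' Lower-tail outlier detection in the style used for low-input capture
#' failures: a sample is flagged when its log10 library size or log10
#' number of detected genes falls below `median - n_mads * MAD` across
#' samples.
#'
#' @param counts Gene x sample integer matrix.
#' @param n_mads MAD multiplier (default 3).
#' @return An object of class `qc_report`: data.frame per sample with
#'   `sample`, `library_size`, `genes_detected`, `outlier`; attribute
#'   `excluded` holds the flagged sample IDs.
#' @export
qc_filter <- function(counts, n_mads = 3) {
  .check(is.matrix(counts) && ncol(counts) >= 4,
         "need >= 4 samples for MAD-based QC")
  .check(all(counts >= 0), "counts must be non-negative")
  lib <- colSums(counts)
  det <- colSums(counts > 0)
  .check(all(lib > 0), "sample with all-zero counts")
  flag_low <- function(v) {
    lv <- log10(v)
    # MAD floored at 0.01 log10 units so near-constant metrics (e.g.
    # saturated genes-detected) cannot flag trivial fluctuations
    lv < median(lv) - n_mads * max(mad(lv), 0.01)
  }
  outlier <- flag_low(lib) | flag_low(det)
  rep <- data.frame(sample = colnames(counts), library_size = lib,
                    genes_detected = det, outlier = outlier,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(rep, "excluded") <- colnames(counts)[outlier]
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Per-sample size factors for count normalization
#'
#' `median_ratio`: the classic median-of-ratios estimator - for each
#' sample, the median over genes of count / geometric row mean, using
#' only genes nonzero in every sample. `deconvolution`: a pooled
#' deconvolution estimator for zero-inflated low-input data - summed
#' pseudo-samples over sliding pools of samples are normalized against an
#' average reference by median ratio, and the per-sample factors are
#' recovered from the pool equations by least squares. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Gene x sample matrix.
#' @param method `"median_ratio"` or `"deconvolution"`.
#' @param pool_sizes Pool sizes for the deconvolution method; default
#'   `seq(5, min(15, n_samples))`, truncated to the sample count.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts,
                         method = c("deconvolution", "median_ratio"),
                         pool_sizes = NULL) {
  method <- match.arg(method)
  .check(is.matrix(counts) && all(counts >= 0), "counts must be non-negative")
  .check(all(colSums(counts) > 0), "every sample needs >= 1 nonzero count")
  n <- ncol(counts)
  sf <- if (method == "median_ratio") {
    nz <- rowSums(counts == 0) == 0
    if (!any(nz)) {
      stop("no gene is nonzero in all samples; use method = 'deconvolution'",
           call. = FALSE)
    }
    sub <- counts[nz, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    apply(sub, 2, function(col) median(col / geo))
  } else {
    .deconv_factors(counts, pool_sizes)
  }
  .check(all(sf > 0), "non-positive size factor estimated")
  sf <- sf / .geomean(sf)
  names(sf) <- colnames(counts)
  sf
}

# pooled deconvolution: ring-ordered sliding pools; pool median-ratio factors
# define linear equations sum_{j in pool} s_j = theta_pool, solved by
# weighted least squares with a light library-size ridge for identifiability
.deconv_factors <- function(counts, pool_sizes = NULL) {
  n <- ncol(counts)
  if (is.null(pool_sizes)) pool_sizes <- seq(min(5L, n), min(15L, n))
  pool_sizes <- unique(pmin(pool_sizes, n))
  lib <- colSums(counts)
  ref <- rowMeans(sweep(counts, 2, lib / mean(lib), `/`))
  use <- ref > 0
  ord <- order(lib %% (max(lib) / pi))  # quasi-random ring ordering
  ring <- c(ord, ord)
  rows <- list(); rhs <- numeric(0)
  for (ps in pool_sizes) {
    for (start in seq_len(n)) {
      members <- ring[start:(start + ps - 1L)]
      pooled <- rowSums(counts[, members, drop = FALSE])
      ratio <- pooled[use] / ref[use]
      theta <- median(ratio[is.finite(ratio)])
      row <- numeric(n); row[members] <- 1
      rows[[length(rows) + 1L]] <- row
      rhs <- c(rhs, theta)
    }
  }
  A <- do.call(rbind, rows)
  # ridge rows tying each factor weakly to its library-size factor
  lam <- sqrt(0.1)
  A <- rbind(A, diag(lam, n))
  rhs <- c(rhs, lam * lib / mean(lib))
  fit <- stats::lsfit(A, rhs, intercept = FALSE)
  pmax(fit$coefficients, 1e-8)
}

#' Negative-binomial Wald differential expression
#'
#' Per-gene two-group NB model with `log(size factor)` offsets. Gene-wise
#' dispersions are estimated by method of moments, shrunk toward a robust
#' log-linear mean-dispersion trend, and held fixed while group means are
#' fit by Newton iterations (the exact NB GLM MLE for a two-group
#' design). The Wald statistic `lfc_raw / se` is referred to the standard
#' normal; q-values are Benjamini-Hochberg; calls use [classify()].
#'
#' @param counts Gene x sample integer matrix (post-QC).
#' @param factors Size factors from [size_factors()] (or all 1).
#' @param groups Two-level factor/character vector over samples; the
#'   second level is the numerator of the fold change (use levels
#'   `c("wt", "mutant")` for mutant-over-wild-type).
#' @param alpha Significance threshold for calls (default 0.05).
#' @param prior_df Strength of dispersion shrinkage toward the trend, in
#'   pseudo-degrees-of-freedom (default 10).
#' @param shrink Also compute normal-prior shrunken LFCs via
#'   [shrink_lfc()] (default TRUE).
#' @return An object of class `de_result`: data.frame with `gene_id`,
#'   `base_mean`, `lfc_raw`, `lfc_shrunk`, `se`, `p`, `q`, `call`,
#'   `dispersion`. Genes with all-zero counts get `NA` statistics and an
#'   `NS` call.
#' @export
fit_de <- function(counts, factors = NULL, groups, alpha = 0.05,
                   prior_df = 10, shrink = TRUE) {
  .check(is.matrix(counts) && all(counts >= 0), "counts must be non-negative")
  groups <- as.factor(groups)
  .check(nlevels(groups) == 2, "groups must have exactly two levels")
  .check(all(table(groups) >= 2), "both groups need >= 2 samples")
  .check(length(groups) == ncol(counts), "groups must match samples")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  .check(all(factors > 0) && length(factors) == ncol(counts),
         "factors must be positive, one per sample")

  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  norm <- sweep(counts, 2, factors, `/`)
  base_mean <- rowMeans(norm)
  testable <- rowSums(counts) > 0

  disp <- .estimate_dispersion(norm, g1, g2, base_mean, prior_df)

  fit1 <- .nb_group_fit(counts[, g1, drop = FALSE], factors[g1], disp)
  fit2 <- .nb_group_fit(counts[, g2, drop = FALSE], factors[g2], disp)

  lfc <- (log(fit2$q) - log(fit1$q)) / log(2)
  se <- sqrt(fit1$var_log + fit2$var_log) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!testable] <- NA_real_
  lfc[!testable] <- NA_real_
  se[!testable] <- NA_real_
  q <- bh_adjust(p)

  res <- data.frame(
    gene_id = if (is.null(rownames(counts))) sprintf("gene_%05d", seq_len(nrow(counts)))
              else rownames(counts),
    base_mean = base_mean,
    lfc_raw = lfc,
    lfc_shrunk = NA_real_,
    se = se,
    p = p,
    q = q,
    call = "NS",
    dispersion = disp,
    row.names = NULL, stringsAsFactors = FALSE)
  if (shrink) res$lfc_shrunk <- shrink_lfc(res)
  res$call <- classify(res, alpha)
  class(res) <- c("de_result", "data.frame")
  res
}

# method-of-moments gene dispersions shrunk toward a robust trend
.estimate_dispersion <- function(norm, g1, g2, base_mean, prior_df) {
  pooled_var <- function(idx) {
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, var)
    list(m = m, v = v, df = sum(idx) - 1)
  }
  a <- pooled_var(g1); b <- pooled_var(g2)
  v <- (a$v * a$df + b$v * b$df) / (a$df + b$df)
  m <- (a$m * sum(g1) + b$m * sum(g2)) / length(g1)
  raw <- (v - m) / m^2
  raw[!is.finite(raw)] <- NA
  floor_a <- 1e-8
  ok <- !is.na(raw) & raw > 0 & m > 1
  alpha_trend <- if (sum(ok) >= 20) {
    fit <- MASS::rlm(log(raw[ok]) ~ log(m[ok]), maxit = 50)
    co <- stats::coef(fit)
    exp(co[1] + co[2] * log(pmax(m, 1e-3)))
  } else {
    rep(stats::median(raw[ok], na.rm = TRUE) %||% 0.1, length(m))
  }
  alpha_trend[!is.finite(alpha_trend)] <- 0.1
  df_gene <- a$df + b$df
  w <- df_gene / (df_gene + prior_df)
  gene_part <- ifelse(is.na(raw) | raw <= 0, floor_a, raw)
  disp <- exp(w * log(gene_part) + (1 - w) * log(pmax(alpha_trend, floor_a)))
  pmax(disp, floor_a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorised Newton for per-gene NB group mean q with offsets sf and fixed
# dispersion: score(log q) = sum_j (k_j - mu_j) / (1 + alpha * mu_j),
# info(log q) = sum_j mu_j / (1 + alpha * mu_j), mu_j = sf_j * q
.nb_group_fit <- function(k, sf, disp) {
  n_genes <- nrow(k)
  tot_sf <- sum(sf)
  q <- pmax(rowSums(k) / tot_sf, 0.5 / tot_sf)  # floored init = Poisson MLE
  all_zero <- rowSums(k) == 0
  for (iter in 1:25) {
    mu <- q %o% sf
    denom <- 1 + disp * mu
    score <- rowSums((k - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmax(pmin(step, 3), -3)
    q <- q * exp(step)
    q <- pmax(q, 0.5 / tot_sf)
    if (max(abs(step)) < 1e-10) break
  }
  mu <- q %o% sf
  info <- rowSums(mu / (1 + disp * mu))
  list(q = q, var_log = 1 / pmax(info, 1e-12), all_zero = all_zero)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' `NA` p-values are passed through. Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  .check(is.numeric(pvals), "pvals must be numeric")
  ok <- !is.na(pvals)
  .check(all(pvals[ok] >= 0 & pvals[ok] <= 1), "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Normal-prior shrinkage of log2 fold changes
#'
#' Empirical-Bayes posterior mean under a zero-centred normal prior:
#' `lfc_shrunk = lfc_raw * tau2 / (tau2 + se^2)`, with the prior variance
#' `tau2` estimated by method of moments from the raw LFCs and their
#' standard errors across genes (`tau2 = max(0, var(lfc) - mean(se^2))`).
#'
#' @param de A [fit_de()] result (or data.frame with `lfc_raw`, `se`).
#' @return Numeric vector of shrunken LFCs (NA where the input is NA).
#' @export
shrink_lfc <- function(de) {
  .check(all(c("lfc_raw", "se") %in% names(de)),
         "de must have lfc_raw and se columns")
  ok <- is.finite(de$lfc_raw) & is.finite(de$se)
  tau2 <- max(0, var(de$lfc_raw[ok]) - mean(de$se[ok]^2))
  out <- rep(NA_real_, nrow(de))
  out[ok] <- de$lfc_raw[ok] * tau2 / (tau2 + de$se[ok]^2)
  out
}

#' Classify genes as UP, DOWN or NS
#'
#' `UP` when `q < alpha` and the raw LFC is positive, `DOWN` when
#' `q < alpha` and it is negative, `NS` otherwise (strict inequality; a
#' gene at exactly `q == alpha` is NS).
#'
#' @param de A [fit_de()] result (columns `q`, `lfc_raw`).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of calls.
#' @export
classify <- function(de, alpha = 0.05) {
  .check(all(c("q", "lfc_raw") %in% names(de)), "de must have q and lfc_raw")
  call <- rep("NS", nrow(de))
  sig <- !is.na(de$q) & de$q < alpha
  call[sig & de$lfc_raw > 0] <- "UP"
  call[sig & de$lfc_raw < 0] <- "DOWN"
  call
}

#' Expressed-gene background for enrichment tests
#'
#' Genes whose mean raw count across the named group's samples is at
#' least `min_mean` (inclusive; default 1, the "minimum average read
#' count of 1" definition of expressed).
#'
#' @param counts Gene x sample matrix.
#' @param groups Group labels over samples.
#' @param group Which group defines the background (e.g., `"wt"`).
#' @param min_mean Inclusive mean-count threshold (default 1).
#' @return Character vector of gene IDs.
#' @export
expressed_background <- function(counts, groups, group, min_mean = 1) {
  .check(group %in% groups, "group '%s' not present", group)
  sub <- counts[, groups == group, drop = FALSE]
  ids <- rownames(counts) %||% sprintf("gene_%05d", seq_len(nrow(counts)))
  ids[rowMeans(sub) >= min_mean]
}

#' PCA on variance-stabilized counts
#'
#' Transforms counts to `log2(count / size_factor + 1)`, centres genes,
#' and decomposes by SVD. Optionally restricts to the `ntop` most
#' variable genes, the convention for sample-level PCA displays.
#'
#' @param counts Gene x sample matrix.
#' @param factors Size factors (default all 1).
#' @param ntop Number of top-variance genes to use (default 500; `Inf`
#'   for all).
#' @return list with `coordinates` (samples x PCs) and
#'   `variance_explained` (fractions, non-increasing, summing to <= 1).
#' @export
vst_pca <- function(counts, factors = NULL, ntop = 500) {
  .check(is.matrix(counts) && ncol(counts) >= 3, "need >= 3 samples")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  vst <- log2(sweep(counts, 2, factors, `/`) + 1)
  rv <- apply(vst, 1, var)
  use <- head(order(rv, decreasing = TRUE), min(ntop, nrow(vst)))
  x <- t(vst[use, , drop = FALSE])
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(apply(scale(x, scale = FALSE), 2, var))
  list(coordinates = pc$x, variance_explained = ve[seq_len(ncol(pc$x))])
}

#' Spearman concordance of log2 fold changes between two analyses
#'
#' Rank correlation of raw LFCs over a shared gene list; exact p by
#' permutation distribution for n <= 9 (no ties), t-approximation
#' otherwise.
#'
#' @param de_a,de_b [fit_de()] results (columns `gene_id`, `lfc_raw`).
#' @param genes Character vector of gene IDs to correlate (>= 3 shared).
#' @return list with `rho` and `p`.
#' @export
spearman_lfc <- function(de_a, de_b, genes) {
  a <- de_a$lfc_raw[match(genes, de_a$gene_id)]
  b <- de_b$lfc_raw[match(genes, de_b$gene_id)]
  ok <- is.finite(a) & is.finite(b)
  .check(sum(ok) >= 3, "need >= 3 shared genes with finite LFCs")
  a <- a[ok]; b <- b[ok]
  exact <- length(a) <= 9 && !anyDuplicated(a) && !anyDuplicated(b)
  ht <- suppressWarnings(
    cor.test(a, b, method = "spearman", exact = exact))
  list(rho = unname(ht$estimate), p = ht$p.value)
}
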