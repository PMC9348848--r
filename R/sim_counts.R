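#' Simulation configuration for low-input RNA-seq counts
#'
#' Describes a two-group (wild type vs mutant) negative-binomial count
#' simulation whose structure mirrors ultra-low-input germ-cell profiling:
#' a fixed protein-coding gene universe distributed over the six
#' C. elegans chromosomes, a planted set of differentially expressed genes
#' concentrated on the X, per-entry dropout, and occasional failed
#' replicates whose library collapses.
#'
#' @param seed Integer seed; the generator is a pure function of the config.
#' @param n_genes Number of genes. Must equal `sum(chrom_proportions)`.
#' @param chrom_proportions Named integer vector, genes per chromosome.
#'   Default is the C. elegans protein-coding distribution:
#'   I 2888, II 3508, III 2670, IV 3300, V 5084, X 2808 (20258 total).
#' @param n_samples_per_group Biological replicates per group (default 12).
#' @param nb_dispersion NB dispersion alpha in `var = mu + alpha * mu^2`
#'   (default 0.2, typical of low-input replicates).
#' @param de_fraction Fraction of genes carrying a planted fold change.
#' @param de_log2fc Planted log2 fold change (mutant over wild type).
#' @param x_bias Fraction of planted DE genes placed on chromosome X.
#' @param dropout_rate Independent Bernoulli zeroing probability applied
#'   after count sampling (low-input mRNA capture failure).
#' @param failed_replicate_rate Probability a mutant-or-wt replicate is a
#'   failed capture; failed libraries are scaled down 20-fold.
#' @param library_factors Optional numeric vector (length `2 *
#'   n_samples_per_group`) of true library scalings; default drawn
#'   log-uniformly from \[0.5, 2\].
#' @param base_mean_log_mu,base_mean_log_sd Log-normal parameters of the
#'   per-gene baseline mean.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_proportions = c(I = 2888L, II = 3508L,
                                             III = 2670L, IV = 3300L,
                                             V = 5084L, X = 2808L),
                       n_genes = sum(chrom_proportions),
                       n_samples_per_group = 12L,
                       nb_dispersion = 0.2,
                       de_fraction = 0.03,
                       de_log2fc = 2,
                       x_bias = 0.7,
                       dropout_rate = 0.1,
                       failed_replicate_rate = 0,
                       library_factors = NULL,
                       base_mean_log_mu = log(20),
                       base_mean_log_sd = 1.5) {
  .check(.is_count(seed), "seed must be a single integer")
  .check(is.numeric(chrom_proportions) && length(chrom_proportions) >= 1 &&
           !is.null(names(chrom_proportions)),
         "chrom_proportions must be a named integer vector")
  .check(all(chrom_proportions >= 0), "chromosome gene counts must be >= 0")
  .check(.is_count(n_genes) && n_genes == sum(chrom_proportions),
         "chromosome gene counts must sum to n_genes")
  .check(.is_count(n_samples_per_group) && n_samples_per_group >= 1,
         "n_samples_per_group must be a positive integer")
  .check(is.numeric(nb_dispersion) && nb_dispersion >= 0,
         "nb_dispersion must be non-negative")
  for (f in c("de_fraction", "x_bias", "dropout_rate",
              "failed_replicate_rate")) {
    .check(.is_fraction(get(f)), "%s must be a fraction in [0, 1]", f)
  }
  n_samples <- 2L * as.integer(n_samples_per_group)
  if (!is.null(library_factors)) {
    .check(is.numeric(library_factors) && length(library_factors) == n_samples
           && all(library_factors > 0),
           "library_factors must be %d positive values", n_samples)
  }
  n_de <- round(de_fraction * n_genes)
  n_de_x <- round(x_bias * n_de)
  n_x <- if ("X" %in% names(chrom_proportions)) chrom_proportions[["X"]] else 0L
  .check(n_de_x <= n_x,
         "impossible config: %d DE genes requested on X but only %d X genes exist",
         n_de_x, n_x)
  structure(list(seed = as.integer(seed),
                 chrom_proportions = chrom_proportions,
                 n_genes = as.integer(n_genes),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 nb_dispersion = nb_dispersion,
                 de_fraction = de_fraction,
                 de_log2fc = de_log2fc,
                 x_bias = x_bias,
                 dropout_rate = dropout_rate,
                 failed_replicate_rate = failed_replicate_rate,
                 library_factors = library_factors,
                 base_mean_log_mu = base_mean_log_mu,
                 base_mean_log_sd = base_mean_log_sd),
            class = "sim_config")
}

#' Generate a synthetic two-group count matrix with ground truth
#'
#' Draws gene-by-sample negative-binomial counts around per-group means,
#' plants `de_fraction` of genes with a `de_log2fc` fold change (an
#' `x_bias` share of them on chromosome X), scales failed replicates down
#' 20-fold, and applies independent dropout. Identical configs (including
#' seed) give identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples; column names are
#'       sample IDs.}
#'     \item{sample_meta}{data.frame with `sample`, `genotype`
#'       (`wt`/`mutant`), `replicate`.}
#'     \item{annotation}{data.frame `gene_id`, `chrom`, `strand`, `start`,
#'       `end` (0-based half-open).}
#'     \item{truth}{data.frame per gene: `gene_id`, `base_mean`,
#'       `mean_wt`, `mean_mutant`, `log2fc`, `is_de`; plus attributes
#'       `library_factors` and `failed_samples`.}
#'   }
#' @export
gen_counts <- function(config) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  cfg <- config
  n_samples <- 2L * cfg$n_samples_per_group
  .with_seed(cfg$seed, {
    anno <- .gen_annotation(cfg$chrom_proportions)
    n <- cfg$n_genes
    base_mean <- exp(rnorm(n, cfg$base_mean_log_mu, cfg$base_mean_log_sd))

    # plant DE genes, x_bias of them on X
    n_de <- round(cfg$de_fraction * n)
    n_de_x <- round(cfg$x_bias * n_de)
    x_idx <- which(anno$chrom == "X")
    aut_idx <- setdiff(seq_len(n), x_idx)
    de_idx <- integer(0)
    if (n_de > 0) {
      de_idx <- c(sample(x_idx, n_de_x),
                  sample(aut_idx, n_de - n_de_x))
    }
    log2fc <- numeric(n)
    log2fc[de_idx] <- cfg$de_log2fc

    mean_wt <- base_mean
    mean_mut <- base_mean * 2^log2fc

    lib <- cfg$library_factors
    if (is.null(lib)) lib <- 2^runif(n_samples, -1, 1)
    failed <- runif(n_samples) < cfg$failed_replicate_rate
    lib_eff <- lib * ifelse(failed, 1 / 20, 1)

    groups <- rep(c("wt", "mutant"), each = cfg$n_samples_per_group)
    sample_ids <- paste0(groups, "_", sequence(rep(cfg$n_samples_per_group, 2)))

    mu <- cbind(matrix(mean_wt, n, cfg$n_samples_per_group),
                matrix(mean_mut, n, cfg$n_samples_per_group))
    mu <- sweep(mu, 2, lib_eff, `*`)
    counts <- if (cfg$nb_dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
             n, n_samples)
    } else {
      matrix(stats::rpois(length(mu), lambda = mu), n, n_samples)
    }
    if (cfg$dropout_rate > 0) {
      drop <- matrix(runif(length(counts)) < cfg$dropout_rate, n, n_samples)
      counts[drop] <- 0L
    }
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(anno$gene_id, sample_ids)

    truth <- data.frame(gene_id = anno$gene_id,
                        base_mean = base_mean,
                        mean_wt = mean_wt,
                        mean_mutant = mean_mut,
                        log2fc = log2fc,
                        is_de = seq_len(n) %in% de_idx,
                        stringsAsFactors = FALSE)
    attr(truth, "library_factors") <- setNames(lib, sample_ids)
    attr(truth, "failed_samples") <- sample_ids[failed]

    list(counts = counts,
         sample_meta = data.frame(sample = sample_ids,
                                  genotype = groups,
                                  replicate = sequence(rep(cfg$n_samples_per_group, 2)),
                                  stringsAsFactors = FALSE),
         annotation = anno,
         truth = truth)
  })
}

# genes tiled along each chromosome with random lengths and gaps
.gen_annotation <- function(chrom_proportions) {
  chroms <- rep(names(chrom_proportions), chrom_proportions)
  n <- length(chroms)
  len <- sample(500:3000, n, replace = TRUE)
  gap <- sample(200:2000, n, replace = TRUE)
  start <- integer(n)
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    start[i] <- cumsum(c(1000L, (len + gap)[i[-length(i)]]))
  }
  data.frame(gene_id = sprintf("gene_%05d", seq_len(n)),
             chrom = chroms,
             strand = sample(c("+", "-"), n, replace = TRUE),
             start = start,
             end = start + len,
             stringsAsFactors = FALSE)
}
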