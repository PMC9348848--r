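#' Simulation configuration for a synthetic regulome
#'
#' Describes promoters, ChIP peaks and motifs with planted ground truth:
#' each TF has a designated target gene set; peaks are placed over target
#' promoters; motif-driven TFs have their exact consensus inserted at
#' recorded offsets in target promoters.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (all placed on chromosome X).
#' @param n_x_up Number of genes designated as X UP (the first
#'   `n_x_up` genes).
#' @param promoter_len Promoter length in bp (default 500).
#' @param motif_width Consensus width in bp (default 8); must not exceed
#'   `promoter_len`.
#' @param tf_specs data.frame with one row per TF: `tf_name`,
#'   `x_up_frac` (fraction of the X UP set targeted), `n_other` (extra
#'   non-UP targets), `plant_motif` (logical: insert consensus in target
#'   promoters), `is_x_up_gene` (logical: the TF's own gene is in the X
#'   UP set).
#' @param base_freqs 0-order background base frequencies (A, C, G, T;
#'   default uniform).
#' @param peak_width Peak width in bp (default 200).
#' @return An object of class `regulome_sim_config`.
#' @export
regulome_sim_config <- function(seed = 1L,
                                n_genes = 200L,
                                n_x_up = 50L,
                                promoter_len = 500L,
                                motif_width = 8L,
                                tf_specs = data.frame(
                                  tf_name = c("tf_multi", "tf_peaks", "tf_null"),
                                  x_up_frac = c(0.30, 0.30, 0),
                                  n_other = c(10L, 10L, 0L),
                                  plant_motif = c(TRUE, FALSE, FALSE),
                                  is_x_up_gene = c(TRUE, FALSE, FALSE),
                                  stringsAsFactors = FALSE),
                                base_freqs = rep(0.25, 4),
                                peak_width = 200L) {
  .check(.is_count(seed), "seed must be a single integer")
  .check(.is_count(n_genes) && n_genes >= 2, "n_genes must be >= 2")
  .check(.is_count(n_x_up) && n_x_up >= 1 && n_x_up <= n_genes,
         "n_x_up must be between 1 and n_genes")
  .check(motif_width <= promoter_len,
         "motif (%d bp) wider than promoter (%d bp)", motif_width,
         promoter_len)
  .check(length(base_freqs) == 4 && abs(sum(base_freqs) - 1) < 1e-6,
         "base_freqs must be 4 probabilities summing to 1")
  .check(is.data.frame(tf_specs) &&
           all(c("tf_name", "x_up_frac", "n_other", "plant_motif",
                 "is_x_up_gene") %in% names(tf_specs)),
         "tf_specs missing required columns")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_x_up = as.integer(n_x_up),
                 promoter_len = as.integer(promoter_len),
                 motif_width = as.integer(motif_width),
                 tf_specs = tf_specs, base_freqs = base_freqs,
                 peak_width = as.integer(peak_width)),
            class = "regulome_sim_config")
}

#' Generate a synthetic regulome with known ground truth
#'
#' Builds an X-chromosome gene annotation, promoter sequences from a
#' 0-order background, per-TF ChIP peaks overlapping target promoters,
#' and PWMs whose exact consensus is inserted at recorded offsets in the
#' promoters of motif-driven TF targets. Deterministic in the seed.
#'
#' @param config A [regulome_sim_config()].
#' @return list with
#'   \describe{
#'     \item{annotation}{gene annotation data.frame (0-based half-open).}
#'     \item{promoters}{[build_promoters()] intervals.}
#'     \item{promoter_seqs}{named character vector of promoter sequences.}
#'     \item{peaks}{data.frame `chrom`, `start`, `end`, `tf_name`,
#'       `experiment_id`, `score`, `strand` (BED-style, 0-based
#'       half-open).}
#'     \item{pwms}{named list of [pwm()] objects (motif-driven TFs).}
#'     \item{truth}{list: `x_up` gene IDs, per-TF `targets`, per-TF
#'       `consensus`, and `motif_offsets` (data.frame `tf_name`,
#'       `gene_id`, `offset` 0-based within the promoter).}
#'   }
#' @export
gen_regulome <- function(config = regulome_sim_config()) {
  .check(inherits(config, "regulome_sim_config"),
         "config must be a regulome_sim_config")
  cfg <- config
  bases <- c("A", "C", "G", "T")
  .with_seed(cfg$seed, {
    n <- cfg$n_genes
    # genes tiled on X, all '+' strand, bodies well inside the chromosome
    gene_len <- 1000L
    pitch <- gene_len + cfg$promoter_len + 500L
    start <- cfg$promoter_len + 100L + pitch * (seq_len(n) - 1L)
    anno <- data.frame(gene_id = sprintf("xgene_%04d", seq_len(n)),
                       chrom = "X", strand = "+",
                       start = start, end = start + gene_len,
                       stringsAsFactors = FALSE)
    promoters <- build_promoters(anno, upstream = cfg$promoter_len)
    x_up <- anno$gene_id[seq_len(cfg$n_x_up)]

    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(bases, cfg$promoter_len, replace = TRUE,
                   prob = cfg$base_freqs), collapse = "")
    }, character(1))
    names(seqs) <- anno$gene_id

    specs <- cfg$tf_specs
    targets <- list(); pwms <- list(); consensus <- list()
    offsets <- list()
    peaks <- list()
    for (i in seq_len(nrow(specs))) {
      nm <- specs$tf_name[i]
      n_up <- round(specs$x_up_frac[i] * cfg$n_x_up)
      tgt <- character(0)
      if (n_up > 0) tgt <- x_up[seq_len(n_up)]  # deterministic coverage
      pool <- setdiff(anno$gene_id, x_up)
      if (specs$n_other[i] > 0) {
        tgt <- c(tgt, sample(pool, min(specs$n_other[i], length(pool))))
      }
      targets[[nm]] <- sort(tgt)

      # peaks overlapping each target promoter (two experiments merged)
      if (length(tgt) > 0) {
        pr <- promoters[match(tgt, promoters$gene_id), ]
        half <- split(seq_len(nrow(pr)),
                      rep(1:2, length.out = nrow(pr)))
        for (e in 1:2) {
          idx <- half[[e]]
          if (length(idx) == 0) next
          off <- sample(0:(cfg$promoter_len - 50L), length(idx),
                        replace = TRUE)
          peaks[[length(peaks) + 1]] <- data.frame(
            chrom = "X",
            start = pmax(0L, pr$start[idx] + off - cfg$peak_width %/% 2L),
            end = pr$start[idx] + off + cfg$peak_width %/% 2L,
            tf_name = nm,
            experiment_id = paste0(nm, "_exp", e),
            score = 100L, strand = ".",
            stringsAsFactors = FALSE)
        }
      }

      if (isTRUE(specs$plant_motif[i])) {
        cons <- paste(sample(bases, cfg$motif_width, replace = TRUE),
                      collapse = "")
        consensus[[nm]] <- cons
        pm <- matrix(0.02, cfg$motif_width, 4,
                     dimnames = list(NULL, bases))
        for (j in seq_len(cfg$motif_width)) {
          pm[j, substr(cons, j, j)] <- 0.94
        }
        pwms[[nm]] <- pwm(pm, background = cfg$base_freqs, name = nm)
        if (length(tgt) > 0) {
          off <- sample(0:(cfg$promoter_len - cfg$motif_width), length(tgt),
                        replace = TRUE)
          for (k in seq_along(tgt)) {
            substr(seqs[[tgt[k]]], off[k] + 1L,
                   off[k] + cfg$motif_width) <- cons
          }
          offsets[[nm]] <- data.frame(tf_name = nm, gene_id = tgt,
                                      offset = off,
                                      stringsAsFactors = FALSE)
        }
      }
    }
    peaks <- if (length(peaks) > 0) do.call(rbind, peaks) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 tf_name = character(0), experiment_id = character(0),
                 score = integer(0), strand = character(0))
    motif_offsets <- if (length(offsets) > 0) do.call(rbind, offsets) else
      data.frame(tf_name = character(0), gene_id = character(0),
                 offset = integer(0))
    rownames(peaks) <- rownames(motif_offsets) <- NULL
    list(annotation = anno,
         promoters = promoters,
         promoter_seqs = seqs,
         peaks = peaks,
         pwms = pwms,
         truth = list(x_up = x_up, targets = targets,
                      consensus = consensus,
                      motif_offsets = motif_offsets))
  })
}
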