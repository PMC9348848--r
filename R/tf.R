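#' Strand-resolved promoter windows upstream of TSSs
#'
#' The promoter of a gene is the 500 bp window strictly upstream of its
#' transcription start site: for a `+` gene with start t, `[t-500, t)`;
#' for a `-` gene with end e, `[e, e+500)`. Intervals are 0-based
#' half-open and clipped at chromosome bounds.
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open gene bodies).
#' @param upstream Window width in bp (default 500).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   right-side clipping of `-` promoters.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open promoter intervals).
#' @export
build_promoters <- function(annotation, upstream = 500L,
                            chrom_lengths = NULL) {
  .check(all(c("gene_id", "chrom", "strand", "start", "end") %in%
               names(annotation)), "annotation missing required columns")
  .check(all(annotation$strand %in% c("+", "-")),
         "missing or invalid strand (must be + or -)")
  plus <- annotation$strand == "+"
  start <- ifelse(plus, pmax(0L, annotation$start - upstream),
                  annotation$end)
  end <- ifelse(plus, annotation$start, annotation$end + upstream)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[.norm_chrom(annotation$chrom)]
    end <- pmin(end, ifelse(is.na(lim), end, lim))
  }
  data.frame(gene_id = annotation$gene_id,
             chrom = .norm_chrom(annotation$chrom),
             start = start, end = end,
             strand = annotation$strand,
             stringsAsFactors = FALSE)
}

#' Assign ChIP peaks to gene promoters
#'
#' A gene is a TF target iff any peak interval overlaps its promoter by
#' at least 1 bp (half-open intervals; abutting intervals do not
#' overlap). Multiple experiments for one TF are unioned. Peaks on
#' chromosomes absent from the promoter index are skipped with a
#' warning.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `tf_name` (and
#'   optionally `experiment_id`), 0-based half-open.
#' @param promoters A [build_promoters()] result.
#' @return Named list mapping TF name to a character vector of target
#'   gene IDs.
#' @export
assign_peaks <- function(peaks, promoters) {
  .check(all(c("chrom", "start", "end") %in% names(peaks)),
         "peaks missing chrom/start/end")
  tf <- if ("tf_name" %in% names(peaks)) peaks$tf_name else "TF"
  pk_chrom <- .norm_chrom(peaks$chrom)
  known <- pk_chrom %in% unique(promoters$chrom)
  if (!all(known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from the ",
            "annotation were skipped", call. = FALSE)
  }
  prom_gr <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(promoters$start + 1L, promoters$end))  # 1-based closed
  out <- list()
  for (name in unique(tf)) {
    sel <- known & tf == name
    if (!any(sel)) { out[[name]] <- character(0); next }
    pk_gr <- GenomicRanges::GRanges(
      pk_chrom[sel],
      IRanges::IRanges(peaks$start[sel] + 1L, peaks$end[sel]))
    hits <- GenomicRanges::findOverlaps(pk_gr, prom_gr, minoverlap = 1L)
    out[[name]] <- sort(unique(promoters$gene_id[S4Vectors::subjectHits(hits)]))
  }
  out
}

#' Fraction of X UP genes bound by a TF
#'
#' `|targets intersect x_up| / |x_up|`; the "binds the promoter of at
#' least 25 percent of X UP genes" criterion compares this fraction to a
#' threshold.
#'
#' @param tf_targets Character vector of genes a TF is assigned to.
#' @param x_up_genes Non-empty character vector of X-linked UP genes.
#' @return Fraction in \[0, 1\].
#' @export
binds_fraction <- function(tf_targets, x_up_genes) {
  x_up_genes <- unique(x_up_genes)
  .check(length(x_up_genes) > 0, "x_up_genes must be non-empty")
  length(intersect(unique(tf_targets), x_up_genes)) / length(x_up_genes)
}

#' Construct a position-weight matrix
#'
#' @param mat Width x 4 probability matrix, columns named A, C, G, T;
#'   each row sums to 1.
#' @param background Length-4 background probabilities (default uniform).
#' @param name Motif name.
#' @param pseudocount Added to probabilities before log-odds scoring
#'   (default 1e-3).
#' @return An object of class `pwm`.
#' @export
pwm <- function(mat, background = rep(0.25, 4), name = "motif",
                pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  .check(ncol(mat) == 4, "PWM must have 4 columns (A, C, G, T)")
  if (is.null(colnames(mat))) colnames(mat) <- c("A", "C", "G", "T")
  .check(all(abs(rowSums(mat) - 1) < 1e-6), "each PWM position must sum to 1")
  .check(length(background) == 4 && abs(sum(background) - 1) < 1e-6,
         "background must be 4 probabilities summing to 1")
  structure(list(mat = mat, background = as.numeric(background),
                 name = name, pseudocount = pseudocount),
            class = "pwm")
}

# log2 odds score matrix (width x 4), with pseudocounts
.pwm_scores <- function(p) {
  pc <- p$pseudocount
  m <- (p$mat + pc) / (1 + 4 * pc)
  bg <- (p$background + pc) / (1 + 4 * pc)
  log2(sweep(m, 2, bg, `/`))
}

# exact null distribution of the window score under the 0-order background,
# by dynamic programming over discretized per-column score distributions;
# window scoring uses the same discretized matrix so p-values are exact
.pwm_score_tail <- function(score_mat, background, gran = 0.01) {
  si <- round(score_mat / gran)
  offset <- -apply(si, 1, min)
  width <- nrow(si)
  pmf <- 1
  for (i in seq_len(width)) {
    vals <- si[i, ] + offset[i]  # non-negative integers
    col_pmf <- numeric(max(vals) + 1)
    for (b in 1:4) col_pmf[vals[b] + 1] <- col_pmf[vals[b] + 1] + background[b]
    pmf <- .convolve_pmf(pmf, col_pmf)
  }
  total_offset <- sum(offset)
  tail_from <- rev(cumsum(rev(pmf)))
  tail <- function(score) {
    k <- as.integer(round(score / gran)) + total_offset + 1L
    k <- max(1L, k)
    if (k > length(tail_from)) 0 else tail_from[k]
  }
  list(tail = tail, smat_d = si * gran, gran = gran,
       min_score = (0 - total_offset) * gran,
       max_score = (length(tail_from) - 1 - total_offset) * gran)
}

.convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(b)) {
    if (b[i] > 0) {
      idx <- i:(i + length(a) - 1)
      out[idx] <- out[idx] + a * b[i]
    }
  }
  out
}

.revcomp_chars <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Scan promoter sequences for PWM hits
#'
#' FIMO-style scan: every window on both strands is scored as the sum of
#' `log2(p_motif / p_background)`; a window is a hit when the p-value of
#' its score under the 0-order background (computed by exact dynamic
#' programming over discretized column score distributions) is at most
#' `p_threshold`. Windows containing N are skipped. By default the
#' background is estimated from the scanned sequences.
#'
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`)
#'   of promoter sequences keyed by gene ID.
#' @param motif A [pwm()].
#' @param p_threshold Per-window score p-value threshold (default 1e-4).
#' @param background `"sequences"` (0-order frequencies estimated from
#'   the input, the default) or a length-4 probability vector.
#' @return Character vector of gene IDs with >= 1 hit, with attribute
#'   `hits`: data.frame `gene_id`, `offset` (0-based), `strand`, `score`,
#'   `p`; and attribute `realized_tail`, the exact tail probability at
#'   the score cutoff actually applied.
#' @export
scan_pwm <- function(sequences, motif, p_threshold = 1e-4,
                     background = "sequences") {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  .check(is.character(sequences) && !is.null(names(sequences)),
         "sequences must be a named character vector")
  .check(inherits(motif, "pwm"), "motif must be a pwm object")
  seqs <- toupper(sequences)
  .check(all(grepl("^[ACGTN]*$", seqs)), "sequence alphabet must be A/C/G/T/N")

  if (identical(background, "sequences")) {
    tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")),
                        levels = c("A", "C", "G", "T")))
    bg <- as.numeric(tab) / sum(tab)
    if (any(bg == 0) || sum(tab) == 0) bg <- rep(0.25, 4)
  } else {
    .check(length(background) == 4, "background must be 4 probabilities")
    bg <- background / sum(background)
  }
  m <- motif
  m$background <- bg
  smat <- .pwm_scores(m)
  width <- nrow(smat)
  dp <- .pwm_score_tail(smat, bg)
  tail_fun <- dp$tail
  gran <- dp$gran

  # score cutoff: smallest grid score with tail <= p_threshold
  all_scores <- seq(dp$min_score, dp$max_score, by = gran)
  tails <- vapply(all_scores, tail_fun, numeric(1))
  ok <- which(tails <= p_threshold)
  if (length(ok) == 0) {
    cutoff <- Inf; realized <- 0
  } else {
    cutoff <- all_scores[ok[1]] - gran / 4  # grid tolerance
    realized <- tails[ok[1]]
  }

  # windows are scored with the discretized matrix so sums lie on the grid
  lut <- matrix(NA_real_, 5, width,
                dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  lut[1:4, ] <- t(dp$smat_d)

  hits <- list()
  genes <- character(0)
  for (g in names(seqs)) {
    s <- seqs[[g]]
    n <- nchar(s)
    if (n < width) {
      warning("motif wider than sequence for gene ", g, "; skipped",
              call. = FALSE)
      next
    }
    chars <- strsplit(s, "")[[1]]
    for (strand in c("+", "-")) {
      cs <- if (strand == "+") chars else rev(unname(.revcomp_chars[chars]))
      code <- match(cs, c("A", "C", "G", "T", "N"))
      n_win <- n - width + 1
      # sliding window score; windows containing N skipped
      sc <- numeric(n_win)
      valid <- rep(TRUE, n_win)
      for (j in seq_len(width)) {
        cj <- code[j:(j + n_win - 1)]
        valid <- valid & cj < 5
        v <- lut[cbind(cj, j)]
        v[cj == 5] <- 0
        sc <- sc + v
      }
      hit_at <- which(valid & sc >= cutoff)
      for (h in hit_at) {
        off0 <- if (strand == "+") h - 1L else n - width - (h - 1L)
        hits[[length(hits) + 1]] <-
          data.frame(gene_id = g, offset = off0, strand = strand,
                     score = sc[h], p = tail_fun(sc[h]),
                     stringsAsFactors = FALSE)
      }
      if (length(hit_at) > 0) genes <- union(genes, g)
    }
  }
  hit_df <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(gene_id = character(0), offset = integer(0),
               strand = character(0), score = numeric(0), p = numeric(0))
  structure(sort(genes), hits = hit_df, realized_tail = realized,
            cutoff = cutoff)
}

#' Motif enrichment among X-linked UP genes
#'
#' Upper-tail hypergeometric test of whether genes carrying a motif in
#' their promoter are over-represented among X UP genes relative to all
#' X-linked genes.
#'
#' @param motif_genes Genes with >= 1 motif hit ([scan_pwm()] output).
#' @param x_up X-linked UP genes (subset of `all_x`).
#' @param all_x All X-linked genes (the background).
#' @return An `enrichment_result` (see [hypergeom_enrich()]).
#' @export
motif_enrichment <- function(motif_genes, x_up, all_x) {
  .check(all(x_up %in% all_x), "x_up must be a subset of all_x")
  hypergeom_enrich(hits = x_up, target_set = motif_genes, background = all_x)
}

#' Three-criterion transcription-factor candidate filter
#'
#' Flags each TF on the three candidate criteria: (1) the TF gene itself
#' is an X UP gene in PGCs and/or EGCs; (2) the TF binds the promoter of
#' at least `binds_threshold` of X UP genes; (3) the TF's DNA motif is
#' enriched in promoters of X UP genes (hypergeometric p below
#' `enrich_alpha`). A TF is prioritized when any criterion holds; output
#' is sorted by number of criteria met, then binds fraction, descending.
#'
#' @param tf_table data.frame with `tf_name`, `tf_gene_id` (ID of the
#'   gene encoding the TF; NA if unknown), and optionally `motif_p`
#'   (from [motif_enrichment()]).
#' @param tf_targets Named list of target gene sets ([assign_peaks()]).
#' @param x_up_pgc,x_up_egc Character vectors of X UP genes in PGCs /
#'   EGCs; their union is the X UP reference set.
#' @param binds_threshold Criterion-2 fraction (default 0.25).
#' @param enrich_alpha Criterion-3 significance level (default 0.05).
#' @return data.frame of class `candidate_tf`: `tf_name`, `is_x_up`,
#'   `binds_fraction`, `motif_enrichment_p`, `n_criteria`, `prioritized`,
#'   sorted as described.
#' @export
prioritize <- function(tf_table, tf_targets, x_up_pgc, x_up_egc = character(0),
                       binds_threshold = 0.25, enrich_alpha = 0.05) {
  .check(all(c("tf_name", "tf_gene_id") %in% names(tf_table)),
         "tf_table needs tf_name and tf_gene_id")
  x_up <- union(x_up_pgc, x_up_egc)
  .check(length(x_up) > 0, "X UP set is empty")
  n <- nrow(tf_table)
  is_x_up <- !is.na(tf_table$tf_gene_id) & tf_table$tf_gene_id %in% x_up
  bf <- vapply(tf_table$tf_name, function(nm) {
    binds_fraction(tf_targets[[nm]] %||% character(0), x_up)
  }, numeric(1))
  mp <- if ("motif_p" %in% names(tf_table)) tf_table$motif_p else
    rep(NA_real_, n)
  crit <- cbind(c1 = is_x_up,
                c2 = bf >= binds_threshold,
                c3 = !is.na(mp) & mp < enrich_alpha)
  n_crit <- rowSums(crit)
  out <- data.frame(tf_name = tf_table$tf_name,
                    is_x_up = is_x_up,
                    binds_fraction = bf,
                    motif_enrichment_p = mp,
                    n_criteria = n_crit,
                    prioritized = n_crit >= 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$n_criteria, -out$binds_fraction), ]
  rownames(out) <- NULL
  class(out) <- c("candidate_tf", "data.frame")
  out
}

#' Reverse complement of a PWM
#'
#' Reverses the position order and swaps complementary base columns; the
#' background is complement-swapped likewise.
#'
#' @param motif A [pwm()].
#' @return A [pwm()] for the reverse-complement motif.
#' @export
pwm_revcomp <- function(motif) {
  .check(inherits(motif, "pwm"), "motif must be a pwm object")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- motif$mat[rev(seq_len(nrow(motif$mat))), comp[colnames(motif$mat)],
                 drop = FALSE]
  colnames(m) <- names(comp)
  bgn <- motif$background
  names(bgn) <- c("A", "C", "G", "T")
  pwm(m, background = unname(bgn[comp[c("A", "C", "G", "T")]]),
      name = paste0(motif$name, "_rc"), pseudocount = motif$pseudocount)
}
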