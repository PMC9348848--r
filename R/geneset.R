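#' Tally UP/DOWN calls per chromosome
#'
#' Partitions called genes exactly over chromosomes; totals across
#' chromosomes equal the total number of calls of each class.
#'
#' @param de A [fit_de()] result (or data.frame with `gene_id`, `call`).
#' @param annotation data.frame with `gene_id` and `chrom`.
#' @return data.frame with one row per chromosome and columns `chrom`,
#'   `UP`, `DOWN`.
#' @export
tally_by_chromosome <- function(de, annotation) {
  idx <- match(de$gene_id, annotation$gene_id)
  if (anyNA(idx)) {
    stop("unannotated gene(s): ",
         paste(head(de$gene_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  chrom <- .norm_chrom(annotation$chrom[idx])
  chroms <- unique(.norm_chrom(annotation$chrom))
  up <- table(factor(chrom[de$call == "UP"], levels = chroms))
  down <- table(factor(chrom[de$call == "DOWN"], levels = chroms))
  data.frame(chrom = chroms, UP = as.integer(up), DOWN = as.integer(down),
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests whether a hit list overlaps a target set more (default) or less
#' than expected by chance within a background universe. The target is
#' intersected with the background before testing; hits must already lie
#' inside the background. Reports the observed overlap alongside the
#' chance expectation `n_hits * |target| / |background|` (the
#' observed-vs-expected bars of enrichment figures).
#'
#' @param hits Character vector of hit gene IDs (subset of background).
#' @param target_set Character vector, the gene set being tested.
#' @param background Character vector, the gene universe.
#' @param alternative `"greater"` (upper-tail enrichment, default) or
#'   `"less"` (depletion).
#' @return An object of class `enrichment_result`: list with `observed`,
#'   `expected`, `p`, `background_size`, `set_size_in_background`,
#'   `n_hits`.
#' @export
hypergeom_enrich <- function(hits, target_set, background,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  .check(length(background) > 0, "empty background")
  hits <- unique(hits)
  .check(all(hits %in% background), "hits must be a subset of the background")
  target <- unique(intersect(target_set, background))
  observed <- length(intersect(hits, target))
  N <- length(background); K <- length(target); n <- length(hits)
  p <- if (alternative == "greater") {
    phyper(observed - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(observed, K, N - K, n, lower.tail = TRUE)
  }
  structure(list(observed = observed,
                 expected = n * K / N,
                 p = p,
                 background_size = N,
                 set_size_in_background = K,
                 n_hits = n),
            class = "enrichment_result")
}

#' Venn region counts for two or three gene sets
#'
#' Exact inclusion-exclusion region counts; the disjoint regions sum to
#' the size of the union.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector of disjoint region counts; names are
#'   `&`-joined set names (e.g., `"A"`, `"A&B"`).
#' @export
venn <- function(sets) {
  .check(is.list(sets) && length(sets) %in% 2:3 && !is.null(names(sets)),
         "sets must be a named list of 2 or 3 gene sets")
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 0) {
    member <- matrix(logical(0), 0, length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  n <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  out <- integer(nrow(combos))
  nm <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pattern <- unlist(combos[i, ])
    inside <- rep(TRUE, length(univ))
    for (j in seq_len(n)) {
      inside <- inside & (member[, j] == pattern[j])
    }
    out[i] <- sum(inside)
    nm[i] <- paste(names(sets)[pattern], collapse = "&")
  }
  setNames(out, nm)
}

#' Rounded integer percentage
#'
#' `round(100 * k / n)` with halves rounded away from zero, the
#' convention for percentages quoted from count pairs (e.g., 350 of 584
#' is 60 percent).
#'
#' @param k Numerator count (0 <= k <= n).
#' @param n Denominator count (> 0).
#' @return Integer percent.
#' @export
percent <- function(k, n) {
  .check(.is_count(n) && n > 0, "n must be a positive integer")
  .check(.is_count(k) && k >= 0 && k <= n, "k must satisfy 0 <= k <= n")
  as.integer(.round_half_away(100 * k / n))
}

#' Two-tailed Fisher's exact test on full-germline proportions
#'
#' Collapses germline-health scores to full vs not-full and tests whether
#' the proportion of worms with a full germline differs between two
#' genotypes. The two-sided p-value sums the probabilities of all tables
#' with the observed margins whose point probability does not exceed that
#' of the observed table. The sample (unconditional) odds ratio is
#' reported, with a 0.5 continuity correction when any cell is zero.
#'
#' @param full_a,notfull_a Counts for genotype A.
#' @param full_b,notfull_b Counts for genotype B.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_full <- function(full_a, notfull_a, full_b, notfull_b) {
  tab <- matrix(c(full_a, notfull_a, full_b, notfull_b), 2, 2, byrow = TRUE)
  .check(all(tab >= 0) && all(tab == round(tab)), "counts must be non-negative integers")
  .check(all(rowSums(tab) > 0) && all(colSums(tab) > 0), "empty margin")
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  cc <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + cc) * (tab[2, 2] + cc)) /
    ((tab[1, 2] + cc) * (tab[2, 1] + cc))
  list(odds_ratio = or, p = p)
}

#' Collapse a germline score table and test two genotypes
#'
#' Convenience wrapper around [fisher_full()] for a score table with
#' columns `genotype`, `absent_tiny`, `partial`, `full`.
#'
#' @param scores data.frame score table.
#' @param genotype_a,genotype_b Row names (genotypes) to compare.
#' @return As [fisher_full()].
#' @export
fisher_germline <- function(scores, genotype_a, genotype_b) {
  .check(all(c("genotype", "absent_tiny", "partial", "full") %in% names(scores)),
         "scores needs genotype, absent_tiny, partial, full columns")
  row_of <- function(g) {
    i <- match(g, scores$genotype)
    .check(!is.na(i), "genotype '%s' not in table", g)
    c(full = scores$full[i],
      notfull = scores$absent_tiny[i] + scores$partial[i])
  }
  a <- row_of(genotype_a); b <- row_of(genotype_b)
  fisher_full(a["full"], a["notfull"], b["full"], b["notfull"])
}
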