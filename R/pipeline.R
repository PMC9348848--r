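#' Validate a pipeline configuration
#'
#' A pipeline config is a named list with input paths and stage
#' parameter blocks:
#' \describe{
#'   \item{counts, sample_sheet, annotation}{paths (counts TSV, sample
#'     TSV, tsv0 annotation TSV); required for the `de` stages.}
#'   \item{gene_sets}{optional path to a set_name/gene_id TSV.}
#'   \item{peaks, promoters_fasta, pwms}{optional paths (BED, FASTA,
#'     MEME) enabling the TF stage.}
#'   \item{de, enrich, tf}{optional parameter blocks: `de$alpha`,
#'     `de$min_mean`, `de$norm`, `tf$upstream`, `tf$binds_threshold`,
#'     `tf$motif_p`, `tf$enrich_alpha`.}
#'   \item{seed}{global seed recorded in the report.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config Named list.
#' @return The config, with defaults filled in; errors before any stage
#'   runs if a referenced path does not exist.
#' @export
validate_config <- function(config) {
  .check(is.list(config), "config must be a list")
  for (key in c("counts", "sample_sheet", "annotation")) {
    .check(!is.null(config[[key]]), "config missing required path '%s'", key)
  }
  paths <- c("counts", "sample_sheet", "annotation", "gene_sets",
             "peaks", "promoters_fasta", "pwms")
  for (key in paths) {
    p <- config[[key]]
    if (!is.null(p)) .check(file.exists(p), "input path does not exist: %s", p)
  }
  de <- config$de %||% list()
  config$de <- list(alpha = de$alpha %||% 0.05,
                    min_mean = de$min_mean %||% 1,
                    norm = de$norm %||% "deconvolution",
                    n_mads = de$n_mads %||% 3,
                    shrink = de$shrink %||% TRUE)
  tf <- config$tf %||% list()
  config$tf <- list(upstream = tf$upstream %||% 500L,
                    binds_threshold = tf$binds_threshold %||% 0.25,
                    motif_p = tf$motif_p %||% 1e-4,
                    enrich_alpha = tf$enrich_alpha %||% 0.05)
  config$seed <- config$seed %||% 1L
  config$out_dir <- config$out_dir %||% "."
  config
}

#' Run the end-to-end expression/enrichment/TF pipeline
#'
#' Executes QC -> size factors -> NB Wald differential expression ->
#' UP/DOWN classification -> per-chromosome tallies and gene-set
#' enrichment -> (optionally) TF candidate prioritization, and writes a
#' machine-readable JSON report plus a DE result TSV into
#' `config$out_dir`. Stage failures halt with the failing stage named;
#' outputs written before the failure are preserved. Rerunning with the
#' same config and inputs gives a byte-identical report.
#'
#' @param config A config list; see [validate_config()].
#' @return The report, invisibly (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema_version = "1.0", seed = config$seed,
                 parameters = config[c("de", "tf")])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  dat <- stage("load", {
    cm <- read_counts(config$counts, config$sample_sheet)
    anno <- read_annotation(config$annotation, "tsv0")
    .check(!is.null(cm$sample_meta) && "genotype" %in% names(cm$sample_meta),
           "sample sheet needs a genotype column")
    cm$annotation <- anno
    cm
  })

  de_out <- stage("de", {
    qc <- qc_filter(dat$counts, config$de$n_mads)
    keep <- !qc$outlier
    counts <- dat$counts[, keep, drop = FALSE]
    groups <- factor(dat$sample_meta$genotype[keep],
                     levels = unique(dat$sample_meta$genotype))
    sf <- size_factors(counts, config$de$norm)
    de <- fit_de(counts, sf, groups, alpha = config$de$alpha,
                 shrink = config$de$shrink)
    list(qc = qc, de = de, counts = counts, groups = groups, sf = sf)
  })
  write_de(de_out$de, file.path(config$out_dir, "de_results.tsv"))
  report$qc <- list(excluded = as.list(attr(de_out$qc, "excluded")))

  enrich_out <- stage("enrich", {
    de <- de_out$de
    anno <- dat$annotation
    tal <- tally_by_chromosome(de, anno)
    up <- de$gene_id[de$call == "UP"]
    down <- de$gene_id[de$call == "DOWN"]
    all_genes <- anno$gene_id
    expressed <- expressed_background(de_out$counts, de_out$groups,
                                      levels(de_out$groups)[1],
                                      config$de$min_mean)
    x_genes <- anno$gene_id[anno$chrom == "X"]
    res <- list(
      tally = tal,
      x_up = hypergeom_enrich(up, x_genes, all_genes),
      percent_up_on_x = if (length(up) > 0)
        percent(length(intersect(up, x_genes)), length(up)) else NA)
    if (!is.null(config$gene_sets)) {
      sets <- read_gene_sets(config$gene_sets)
      res$sets <- lapply(sets, function(s) list(
        up = hypergeom_enrich(up, s, all_genes),
        down = hypergeom_enrich(intersect(down, expressed), s, expressed)))
    }
    res$expressed_n <- length(expressed)
    res
  })
  report$tally <- enrich_out$tally
  report$x_up_enrichment <- unclass(enrich_out$x_up)
  report$percent_up_on_x <- enrich_out$percent_up_on_x
  report$expressed_background_size <- enrich_out$expressed_n
  if (!is.null(enrich_out$sets)) {
    report$gene_set_enrichment <- lapply(enrich_out$sets, function(e) {
      list(up = unclass(e$up), down = unclass(e$down))
    })
  }

  if (!is.null(config$peaks) && !is.null(config$promoters_fasta)) {
    tf_out <- stage("tf", {
      anno <- dat$annotation
      de <- de_out$de
      x_genes <- anno$gene_id[anno$chrom == "X"]
      x_up <- intersect(de$gene_id[de$call == "UP"], x_genes)
      promoters <- build_promoters(anno, config$tf$upstream)
      peaks <- read_bed(config$peaks)
      targets <- assign_peaks(peaks, promoters)
      seqs <- read_promoters_fasta(config$promoters_fasta)
      tf_names <- names(targets)
      motif_p <- rep(NA_real_, length(tf_names))
      if (!is.null(config$pwms) && length(x_up) > 0) {
        pwms <- read_meme(config$pwms)
        for (i in seq_along(tf_names)) {
          pm <- pwms[[tf_names[i]]]
          if (is.null(pm)) next
          hits <- scan_pwm(seqs[intersect(names(seqs), x_genes)], pm,
                           config$tf$motif_p)
          motif_p[i] <- motif_enrichment(hits, x_up, x_genes)$p
        }
      }
      tf_table <- data.frame(tf_name = tf_names,
                             tf_gene_id = tf_names,
                             motif_p = motif_p,
                             stringsAsFactors = FALSE)
      if (length(x_up) == 0) NULL else
        prioritize(tf_table, targets, x_up,
                   binds_threshold = config$tf$binds_threshold,
                   enrich_alpha = config$tf$enrich_alpha)
    })
    if (!is.null(tf_out)) report$candidates <- tf_out
  }

  json <- jsonlite::toJSON(report, dataframe = "rows", digits = I(6),
                           auto_unbox = TRUE, pretty = TRUE, na = "null")
  writeLines(json, file.path(config$out_dir, "report.json"))
  invisible(report)
}
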