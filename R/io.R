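#' Read a gene x sample count matrix from TSV
#'
#' Expects a `gene_id` column plus one integer column per sample. A
#' sibling sample sheet (TSV with `sample`, `genotype`, ...) may be
#' joined on.
#'
#' @param path Counts TSV path.
#' @param sample_sheet Optional sample-metadata TSV path.
#' @return list with `counts` (integer matrix) and `sample_meta`
#'   (data.frame or NULL).
#' @export
read_counts <- function(path, sample_sheet = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .check("gene_id" %in% names(df), "counts file needs a gene_id column")
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    stop("duplicated gene_id at row(s) ",
         paste(head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  for (j in seq_len(ncol(m))) {
    bad <- which(!is.finite(m[, j]) | m[, j] < 0 | m[, j] != round(m[, j]))
    if (length(bad) > 0) {
      stop(sprintf("invalid count at row %d, sample '%s'",
                   bad[1], colnames(m)[j]), call. = FALSE)
    }
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  meta <- NULL
  if (!is.null(sample_sheet)) {
    meta <- read.delim(sample_sheet, stringsAsFactors = FALSE)
    .check("sample" %in% names(meta), "sample sheet needs a sample column")
    meta <- meta[match(colnames(m), meta$sample), , drop = FALSE]
  }
  list(counts = m, sample_meta = meta)
}

#' Write a count matrix as TSV (gene_id + one column per sample)
#' @param counts Integer matrix with rownames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of ChIP peaks
#'
#' Accepts >= 3 tab-separated columns; `track`/`browser` lines are
#' skipped. Intervals are 0-based half-open and preserved verbatim.
#'
#' @param path BED path.
#' @param tf_name TF name to attach (default: the `name` column if
#'   present, else the file base name).
#' @return data.frame `chrom`, `start`, `end`, and when present `name`,
#'   `score`, `strand`, plus `tf_name`.
#' @export
read_bed <- function(path, tf_name = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  ln <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), tf_name = character(0)))
  }
  ncols <- lengths(fields)
  bad <- which(ncols < 3)
  if (length(bad) > 0) {
    stop("malformed BED line ", ln[bad[1]], ": fewer than 3 columns",
         call. = FALSE)
  }
  nc <- min(ncols)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  out <- data.frame(chrom = get(1),
                    start = suppressWarnings(as.integer(get(2))),
                    end = suppressWarnings(as.integer(get(3))),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end) | out$start >= out$end)
  if (length(bad) > 0) {
    stop("malformed BED line ", ln[bad[1]],
         ": start must be a number < end", call. = FALSE)
  }
  if (nc >= 4) out$name <- get(4)
  if (nc >= 5) out$score <- suppressWarnings(as.numeric(get(5)))
  if (nc >= 6) out$strand <- get(6)
  out$tf_name <- if (!is.null(tf_name)) tf_name
    else if (nc >= 4) out$name
    else sub("\\.bed$", "", basename(path))
  out
}

#' Write peaks as 6-column BED
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `tf_name`/`name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(peaks, path) {
  nm <- peaks$name %||% peaks$tf_name %||% "."
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, nm,
                   peaks$score %||% 0, peaks$strand %||% ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation
#'
#' `tsv0`: columns `gene_id`, `chrom`, `strand`, `start`, `end`, already
#' 0-based half-open. `gff3`: gene features with 1-based closed
#' coordinates, converted internally to 0-based half-open; the gene ID
#' comes from the `ID=` attribute. Strand is required, and chromosome
#' naming must be consistent (one of bare `I..X` or `chr`-prefixed, not
#' mixed).
#'
#' @param path Annotation path.
#' @param dialect `"tsv0"` or `"gff3"`.
#' @return data.frame `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
read_annotation <- function(path, dialect = c("tsv0", "gff3")) {
  dialect <- match.arg(dialect)
  anno <- if (dialect == "tsv0") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    .check(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                 names(df)), "tsv0 annotation missing required columns")
    df[, c("gene_id", "chrom", "strand", "start", "end")]
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    .check(all(lengths(fields) == 9), "gff3 lines must have 9 columns")
    type <- vapply(fields, `[[`, character(1), 3)
    fields <- fields[type == "gene"]
    ids <- vapply(fields, function(f) {
      m <- regmatches(f[9], regexpr("ID=[^;]+", f[9]))
      if (length(m) == 0) NA_character_ else sub("^ID=(gene:)?", "", m)
    }, character(1))
    data.frame(gene_id = ids,
               chrom = vapply(fields, `[[`, character(1), 1),
               strand = vapply(fields, `[[`, character(1), 7),
               start = as.integer(vapply(fields, `[[`, character(1), 4)) - 1L,
               end = as.integer(vapply(fields, `[[`, character(1), 5)),
               stringsAsFactors = FALSE)
  }
  .check(all(anno$strand %in% c("+", "-")), "missing strand in annotation")
  pref <- grepl("^chr", anno$chrom)
  if (any(pref) && !all(pref)) {
    stop("mixed chromosome naming styles: ",
         paste(head(unique(anno$chrom[pref]), 3), collapse = ", "),
         " vs ", paste(head(unique(anno$chrom[!pref]), 3), collapse = ", "),
         call. = FALSE)
  }
  anno$chrom <- .norm_chrom(anno$chrom)
  anno
}

#' Write a tsv0 annotation
#' @param annotation data.frame `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation[, c("gene_id", "chrom", "strand", "start", "end")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read promoter sequences from FASTA (record ID = gene_id)
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write promoter sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_promoters_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read PWMs from minimal MEME text
#'
#' Parses the minimal MEME motif format: a `MEME version` header,
#' optional `Background letter frequencies` line, and per motif a
#' `MOTIF <name>` line followed by a `letter-probability matrix` block.
#'
#' @param path MEME text path.
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  .check(any(grepl("^MEME version", lines)), "not a MEME file (no version line)")
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- unname(vals[c("A", "C", "G", "T")])
  }
  out <- list()
  motif_i <- grep("^MOTIF", lines)
  for (mi in motif_i) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > mi][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    colnames(m) <- c("A", "C", "G", "T")
    out[[name]] <- pwm(m / rowSums(m), background = bg, name = name)
  }
  out
}

#' Write PWMs as minimal MEME text
#' @param pwms Named list of [pwm()] objects.
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  bg <- pwms[[1]]$background
  writeLines(c("Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(p$mat)), con)
    for (i in seq_len(nrow(p$mat))) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", p$mat[i, 1], p$mat[i, 2],
                         p$mat[i, 3], p$mat[i, 4]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write a multi-channel 3D stack as multi-page TIFF
#'
#' Pages are ordered channel-major within Z (for each Z slice, one page
#' per channel in the given order), 16-bit unsigned.
#'
#' @param channels Named list of 3D arrays (z, y, x), values in
#'   \[0, 65535\]. Channels are written in the canonical order
#'   `spot`, `gfp`, `dapi` (those present), any others after.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(channels, path) {
  .check(is.list(channels) && length(channels) >= 1 &&
           !is.null(names(channels)), "channels must be a named list")
  canon <- c(intersect(c("spot", "gfp", "dapi"), names(channels)),
             setdiff(names(channels), c("spot", "gfp", "dapi")))
  channels <- channels[canon]
  d <- dim(channels[[1]])
  pages <- list()
  for (z in seq_len(d[1])) {
    for (ch in names(channels)) {
      pages[[length(pages) + 1]] <- channels[[ch]][z, , ] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-channel 3D stack written by [write_stack()]
#'
#' Pages are channel-major within Z; the channel order is a convention,
#' not stored in the file, and defaults to `spot`, `gfp` (pass
#' `c("spot", "gfp", "dapi")` for three-channel stacks).
#'
#' @param path TIFF path.
#' @param channels Channel names in page order.
#' @return Named list of 3D integer-valued arrays (z, y, x).
#' @export
read_stack <- function(path, channels = c("spot", "gfp")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(channels)
  .check(length(pages) %% nch == 0, "page count not a multiple of channels")
  nz <- length(pages) %/% nch
  d2 <- dim(pages[[1]])
  out <- lapply(channels, function(ch) array(0, c(nz, d2[1], d2[2])))
  names(out) <- channels
  for (z in seq_len(nz)) {
    for (c_i in seq_len(nch)) {
      out[[c_i]][z, , ] <- round(pages[[(z - 1) * nch + c_i]] * 65535)
    }
  }
  out
}

#' Read gene-set membership lists from TSV (set_name, gene_id)
#' @param path TSV path with columns `set_name`, `gene_id`.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("set_name", "gene_id") %in% names(df)),
         "gene-set file needs set_name and gene_id columns")
  split(df$gene_id, df$set_name)
}

#' Write a differential-expression result table as TSV
#' @param de A [fit_de()] result.
#' @param path Output path.
#' @export
write_de <- function(de, path) {
  write.table(de[, c("gene_id", "base_mean", "lfc_raw", "lfc_shrunk",
                     "se", "p", "q", "call")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
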