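# Data model and readers/writers.
#
# Conventions: every coordinate inside the package is 0-based half-open
# [start, end). BED files already use this convention; GTF (1-based,
# closed) is converted on read. TSV site reports are written 1-based and
# say so in their header.

# ---- TranscriptModel ------------------------------------------------------

#' Construct a transcript model
#'
#' Describes one transcript: its exon structure on the genome, optional CDS
#' bounds, and the derived 5'UTR/CDS/3'UTR segments in spliced transcript
#' coordinates (transcript orientation, 0-based half-open).
#'
#' @param transcript_id,gene_id identifiers
#' @param chrom chromosome name
#' @param strand "+" or "-"
#' @param exons two-column matrix (start, end) of genomic exon intervals,
#'   0-based half-open; need not be sorted
#' @param cds_start,cds_end genomic CDS bounds (0-based half-open), or `NA`
#'   for a non-coding transcript
#' @return an object of class `transcript_model` with fields
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` (sorted by
#'   genomic start), `cds_start`, `cds_end`, `transcript_length`, and
#'   `segments`: for coding transcripts a list of `utr5`, `cds`, `utr3`
#'   transcript-coordinate intervals `c(start, end)` that partition
#'   `[0, transcript_length)`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start = NA, cds_end = NA) {
  exons <- matrix(as.integer(as.matrix(exons)), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stopf("transcript %s: exon with end <= start", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stopf("transcript %s: overlapping exons", transcript_id)
  if (!strand %in% c("+", "-"))
    stopf("transcript %s: strand must be '+' or '-'", transcript_id)
  len <- sum(exons[, 2] - exons[, 1])
  m <- structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         transcript_length = as.integer(len), segments = NULL),
    class = "transcript_model")
  if (!is.na(cds_start) && !is.na(cds_end)) {
    if (cds_end - cds_start < 3)
      stopf("transcript %s: CDS shorter than 3 nt", transcript_id)
    # CDS must lie within the exon union
    covered <- sum(pmax(0L, pmin(exons[, 2], as.integer(cds_end)) -
                          pmax(exons[, 1], as.integer(cds_start))))
    in_exon <- !is.na(genomic_to_transcript(m, c(cds_start, cds_end - 1L)))
    if (!all(in_exon))
      stopf("transcript %s: CDS bounds outside exon union", transcript_id)
    tp <- genomic_to_transcript(m, c(cds_start, cds_end - 1L))
    cds_t <- sort(tp)            # on '-' the genomic start maps to the 3' end
    cds_t <- c(cds_t[1], cds_t[2] + 1L)
    if (cds_t[2] - cds_t[1] != covered)
      stopf("transcript %s: CDS bounds outside exon union", transcript_id)
    m$segments <- list(utr5 = c(0L, cds_t[1]),
                       cds  = cds_t,
                       utr3 = c(cds_t[2], len))
  }
  m
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s %d exon(s), %d nt%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$transcript_length,
              if (is.null(x$segments)) ", non-coding" else ", coding"))
  invisible(x)
}

#' Bundle transcript models into a database
#'
#' @param models list of `transcript_model`
#' @return object of class `transcript_db`: a named list of models indexed
#'   by transcript_id
#' @export
transcript_db <- function(models) {
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  structure(models, class = "transcript_db")
}

#' @export
print.transcript_db <- function(x, ...) {
  cat(sprintf("<transcript_db of %d transcripts (%d coding)>\n", length(x),
              sum(!vapply(x, function(m) is.null(m$segments), TRUE))))
  invisible(x)
}

#' @export
`[.transcript_db` <- function(x, i) {
  transcript_db(unclass(x)[i])
}

# ---- Coordinate mapping ---------------------------------------------------

#' Map genomic positions into spliced transcript coordinates
#'
#' @param model a `transcript_model`
#' @param pos integer vector of genomic positions (0-based)
#' @return integer vector of 0-based transcript positions in transcript
#'   orientation; `NA` where the position is not exonic
#' @export
genomic_to_transcript <- function(model, pos) {
  ex <- model$exons
  w <- ex[, 2] - ex[, 1]
  before <- c(0L, cumsum(w))[-(nrow(ex) + 1L)]
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(ex))) {
    hit <- pos >= ex[i, 1] & pos < ex[i, 2]
    out[hit] <- before[i] + (pos[hit] - ex[i, 1])
  }
  if (model$strand == "-") out <- model$transcript_length - 1L - out
  as.integer(out)
}

#' Map spliced transcript coordinates back to the genome
#'
#' Inverse of [genomic_to_transcript()].
#'
#' @param model a `transcript_model`
#' @param tpos integer vector of 0-based transcript positions
#' @return integer vector of genomic positions; `NA` where `tpos` is out of
#'   range
#' @export
transcript_to_genomic <- function(model, tpos) {
  len <- model$transcript_length
  off <- as.integer(tpos)
  off[off < 0L | off >= len] <- NA_integer_
  if (model$strand == "-") off <- len - 1L - off
  ex <- model$exons
  w <- ex[, 2] - ex[, 1]
  before <- c(0L, cumsum(w))
  out <- rep(NA_integer_, length(off))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(off) & off >= before[i] & off < before[i + 1L]
    out[hit] <- ex[i, 1] + (off[hit] - before[i])
  }
  out
}

# ---- Annotation readers ---------------------------------------------------

#' Read a transcript annotation (GTF or BED12)
#'
#' GTF rows of type `exon` define exon structure and rows of type `CDS`
#' define coding bounds; BED12 blocks define exons and the thick interval
#' the CDS. Transcripts whose thick interval is empty (thickStart ==
#' thickEnd) are non-coding.
#'
#' @param path file path; format detected from the extension unless given
#' @param format "auto", "gtf" or "bed12"
#' @return a [transcript_db()]
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed12"
  }
  if (format == "gtf") read_annotation_gtf(path) else read_annotation_bed12(path)
}

read_annotation_gtf <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    bad <- which(body)[which(nf < 9)[1]]
    stopf("malformed GTF record at line %d of %s", bad, path)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  if (is.null(md$transcript_id) || anyNA(md$transcript_id[md$type == "exon"]))
    stopf("GTF %s: exon records lack transcript_id", path)
  ids <- unique(md$transcript_id)
  models <- lapply(ids, function(id) {
    sel <- md$transcript_id == id
    sub <- gr[sel]; ty <- md$type[sel]
    exons <- sub[ty == "exon"]
    if (length(exons) == 0)
      stopf("GTF %s: transcript %s has no exon records", path, id)
    cds <- sub[ty == "CDS"]
    gene <- md$gene_id[sel][1]
    transcript_model(
      transcript_id = id, gene_id = gene,
      chrom = as.character(GenomicRanges::seqnames(exons))[1],
      strand = as.character(GenomicRanges::strand(exons))[1],
      exons = cbind(GenomicRanges::start(exons) - 1L,
                    GenomicRanges::end(exons)),
      cds_start = if (length(cds)) min(GenomicRanges::start(cds)) - 1L else NA,
      cds_end = if (length(cds)) max(GenomicRanges::end(cds)) else NA)
  })
  transcript_db(models)
}

read_annotation_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$blocks))
    stopf("BED %s has no block (BED12) columns", path)
  models <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    chrom_start <- GenomicRanges::start(gr[i]) - 1L   # back to 0-based
    blocks <- md$blocks[[i]]                          # 1-based, relative
    exons <- cbind(chrom_start + IRanges::start(blocks) - 1L,
                   chrom_start + IRanges::end(blocks))
    thick <- md$thick[i]
    ts <- IRanges::start(thick) - 1L
    te <- IRanges::end(thick)
    coding <- te > ts
    models[[i]] <- transcript_model(
      transcript_id = md$name[i], gene_id = md$name[i],
      chrom = as.character(GenomicRanges::seqnames(gr[i])),
      strand = as.character(GenomicRanges::strand(gr[i])),
      exons = exons,
      cds_start = if (coding) ts else NA,
      cds_end = if (coding) te else NA)
  }
  transcript_db(models)
}

# ---- Feature tracks -------------------------------------------------------

#' Construct a feature track
#'
#' A named set of genomic intervals (miRNA target sites, RBP binding sites,
#' m6A peaks, ...) with optional per-interval metadata such as mirSVR
#' scores.
#'
#' @param name track name
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `name`, `score`, `strand`
#' @param metadata optional data.frame of extra per-interval columns
#' @return object of class `feature_track`
#' @export
feature_track <- function(name, intervals, metadata = NULL) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(intervals)))
    stopf("track %s: intervals need columns chrom, start, end", name)
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stopf("track %s: interval with start >= end", name)
  if (is.null(intervals$name))
    intervals$name <- if (nrow(intervals))
      paste0(name, "_", seq_len(nrow(intervals))) else character(0)
  if (is.null(intervals$score)) intervals$score <- rep(0, nrow(intervals))
  if (is.null(intervals$strand)) intervals$strand <- rep("*", nrow(intervals))
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(name = name, intervals = intervals, metadata = metadata),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track '%s': %d interval(s)>\n", x$name,
              nrow(x$intervals)))
  invisible(x)
}

#' Read a BED file into a feature track
#'
#' Accepts BED3/6/12 dialects; BED12 records are used as plain intervals
#' (blocks are ignored for track purposes).
#'
#' @param path BED file
#' @param name track name; default the file base name
#' @return a [feature_track()]
#' @export
read_track <- function(path, name = NULL) {
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(path))
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e)
                   stopf("BED %s failed validation: %s", path,
                         conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  iv <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(md$name)) md$name else paste0(name, "_", seq_along(gr)),
    score = if (!is.null(md$score) && !all(is.na(md$score)))
      as.numeric(md$score) else rep(0, length(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (nrow(iv) && any(iv$end <= iv$start))
    stopf("BED %s: interval with end <= start", path)
  feature_track(name, iv)
}

#' Write a feature track as BED6
#'
#' @param track a [feature_track()]
#' @param path output path
#' @export
write_track <- function(track, path) {
  iv <- track$intervals
  gr <- GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    strand = ifelse(iv$strand %in% c("+", "-"), iv$strand, "*"))
  S4Vectors::mcols(gr)$name <- iv$name
  S4Vectors::mcols(gr)$score <- iv$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# ---- Site tables ----------------------------------------------------------

#' Write site reports
#'
#' Writes a BED6 file (0-based half-open, one 1-nt interval per site) and a
#' TSV report whose positions are 1-based; the TSV header comment states the
#' convention.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `strand`
#'   plus any extra columns, all carried into the TSV
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip)
#' @export
write_sites <- function(sites, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    tr <- feature_track("sites", data.frame(
      chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L,
      name = site_key(sites$chrom, sites$pos, sites$strand),
      score = rep(0, nrow(sites)), strand = sites$strand,
      stringsAsFactors = FALSE))
    write_track(tr, bed_path)
  }
  if (!is.null(tsv_path)) {
    out <- sites
    out$pos <- out$pos + 1L
    con <- file(tsv_path, "w")
    writeLines("# bsm5c site report; positions are 1-based", con)
    write.table(format(out, trim = TRUE, digits = 10), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(sites)
}

#' Read a TSV site report written by [write_sites()]
#'
#' @param path TSV path
#' @return data.frame with 0-based `pos`
#' @export
read_sites <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  x$pos <- as.integer(x$pos) - 1L
  x
}
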