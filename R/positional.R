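# Positional analysis: assignment of sites to transcript features,
# meta-gene profiles over length-normalized transcripts, random-C controls,
# and Fisher exact segment/start-codon enrichment against the cytosine
# background of m5C-bearing transcripts.

#' Assign sites to transcript features
#'
#' Each site receives exactly one feature among `utr5`, `cds`, `utr3`,
#' `intron`, `non_annotated`. When several transcripts overlap a site, the
#' precedence is: exonic mRNA feature (in the transcript with the longest
#' CDS, ties broken by transcript_id) over intron over non-annotated.
#' Sites exonic only in non-coding transcripts fall through to `intron`
#' (if intronic elsewhere) or `non_annotated`.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`
#' @param models a [transcript_db()]
#' @return `sites` with columns `feature`, `transcript_id` (chosen
#'   transcript or `NA`), `tpos` (transcript coordinate or `NA`)
#' @export
assign_segment <- function(sites, models) {
  meta <- data.frame(
    tid = names(models),
    cds_len = vapply(models, function(m)
      if (is.null(m$segments)) 0L else
        as.integer(m$segments$cds[2] - m$segments$cds[1]), 0L),
    stringsAsFactors = FALSE)
  meta <- meta[order(-meta$cds_len, meta$tid), , drop = FALSE]

  n <- nrow(sites)
  feature <- rep("non_annotated", n)
  tid_out <- rep(NA_character_, n)
  tpos_out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    intron_tid <- NA_character_
    for (tid in meta$tid) {
      m <- models[[tid]]
      if (m$chrom != sites$chrom[i] || m$strand != sites$strand[i]) next
      span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
      if (sites$pos[i] < span[1] || sites$pos[i] >= span[2]) next
      tp <- genomic_to_transcript(m, sites$pos[i])
      if (is.na(tp)) {
        if (is.na(intron_tid)) intron_tid <- tid
        next
      }
      if (is.null(m$segments)) next          # exonic but non-coding
      feature[i] <- segment_of_tpos(m, tp)
      tid_out[i] <- tid
      tpos_out[i] <- tp
      break
    }
    if (feature[i] == "non_annotated" && !is.na(intron_tid)) {
      feature[i] <- "intron"
      tid_out[i] <- intron_tid
    }
  }
  out <- sites
  out$feature <- feature
  out$transcript_id <- tid_out
  out$tpos <- tpos_out
  out
}

# Average 5'UTR/CDS/3'UTR lengths over the coding transcripts of a db.
average_segment_lengths <- function(models) {
  coding <- Filter(function(m) !is.null(m$segments), models)
  if (!length(coding)) stopf("no coding transcripts in the annotation")
  lens <- sapply(coding, function(m)
    c(utr5 = m$segments$utr5[2] - m$segments$utr5[1],
      cds = m$segments$cds[2] - m$segments$cds[1],
      utr3 = m$segments$utr3[2] - m$segments$utr3[1]))
  rowMeans(lens)
}

#' Meta-gene profile over a length-normalized transcript
#'
#' Each segment (5'UTR, CDS, 3'UTR) is rescaled to its average length over
#' the coding transcripts; a site's meta-coordinate is the cumulative
#' average-length offset of its segment plus its relative position within
#' its own segment times the segment's average length. The normalized
#' transcript is binned into 100 bins of 1% and the percentage of sites
#' per bin reported.
#'
#' @param sites data.frame from [assign_segment()] restricted to
#'   `utr5`/`cds`/`utr3` features (`transcript_id`, `tpos`, `feature`)
#' @param models a [transcript_db()]
#' @return object of class `metagene_profile`: list with `bins`
#'   (data.frame `bin`, `percent`), `boundaries` (bin index of the
#'   5'UTR/CDS and CDS/3'UTR borders), `avg_lengths`, `n_sites`
#' @export
metagene_profile <- function(sites, models) {
  avg <- average_segment_lengths(models)
  total <- sum(avg)
  offs <- c(utr5 = 0, cds = avg[["utr5"]],
            utr3 = avg[["utr5"]] + avg[["cds"]])
  coord <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    m <- models[[sites$transcript_id[i]]]
    seg <- sites$feature[i]
    if (!seg %in% c("utr5", "cds", "utr3"))
      stopf("site %d has feature '%s'; metagene needs utr5/cds/utr3",
            i, seg)
    if (is.null(m$segments))
      stopf("site %d: transcript %s lacks segment annotation", i,
            m$transcript_id)
    s <- m$segments[[seg]]
    if (s[2] - s[1] == 0)
      stopf("site %d: transcript %s has an empty %s segment", i,
            m$transcript_id, seg)
    rel <- (sites$tpos[i] - s[1]) / (s[2] - s[1])
    coord[i] <- offs[[seg]] + rel * avg[[seg]]
  }
  bin <- pmin(floor(100 * coord / total), 99)
  counts <- tabulate(bin + 1L, nbins = 100L)
  pct <- if (nrow(sites)) 100 * counts / nrow(sites) else counts
  structure(list(
    bins = data.frame(bin = 0:99, percent = pct),
    boundaries = c(utr5_cds = floor(100 * avg[["utr5"]] / total),
                   cds_utr3 = floor(100 * (avg[["utr5"]] + avg[["cds"]]) /
                                      total)),
    avg_lengths = avg, n_sites = nrow(sites)),
    class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(paste0("<metagene_profile: %d sites; segment borders at bins",
                     " %d and %d>\n"),
              x$n_sites, x$boundaries[1], x$boundaries[2]))
  invisible(x)
}

# Enumerate cytosine transcript positions of a set of coding transcripts.
transcript_cytosines <- function(models, genome, transcripts) {
  out <- list()
  for (tid in transcripts) {
    m <- models[[tid]]
    chars <- strsplit(spliced_sequence(m, genome), "")[[1]]
    tpos <- which(chars == "C") - 1L
    if (length(tpos))
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tid, tpos = tpos,
        feature = segment_of_tpos(m, tpos), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0), tpos = integer(0),
                      feature = character(0)))
  do.call(rbind, out)
}

#' Sample random cytosines from a transcript set
#'
#' Uniform sample without replacement from all cytosine positions of the
#' given transcripts; the control set for meta-gene and enrichment
#' analyses.
#'
#' @param models a [transcript_db()]
#' @param genome named character vector of sequences
#' @param n number of cytosines to draw
#' @param seed RNG seed
#' @param transcripts transcript ids to draw from (default: all)
#' @return data.frame `transcript_id`, `tpos`, `feature`, plus genomic
#'   `chrom`, `pos`, `strand`
#' @export
sample_random_cs <- function(models, genome, n, seed,
                             transcripts = names(models)) {
  cs <- transcript_cytosines(models, genome, transcripts)
  if (nrow(cs) < n)
    stopf("requested %d random Cs but transcripts contain only %d", n,
          nrow(cs))
  idx <- with_seed(seed, sample.int(nrow(cs), n))
  out <- cs[idx, , drop = FALSE]
  out$chrom <- vapply(out$transcript_id, function(t) models[[t]]$chrom, "")
  out$strand <- vapply(out$transcript_id, function(t) models[[t]]$strand,
                       "")
  out$pos <- NA_integer_
  for (tid in unique(out$transcript_id)) {
    sel <- out$transcript_id == tid
    out$pos[sel] <- transcript_to_genomic(models[[tid]], out$tpos[sel])
  }
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' p is the sum of hypergeometric probabilities of all tables with the
#' observed margins whose probability does not exceed the observed table's
#' (within a relative tolerance of 1e-7). The odds ratio is the sample
#' odds ratio (a d)/(b c), with the Haldane 0.5 correction applied to all
#' cells iff any cell is 0; the 95% CI uses the Woolf log-OR standard
#' error on the corrected cells.
#'
#' @param a,b,c_,d_ cell counts: rows = in/out of region, columns =
#'   m5C / other C
#' @return list with `p_value`, `odds_ratio`, `ci95` (length 2), `table`
#' @export
fisher_exact_2x2 <- function(a, b, c_, d_) {
  m <- a + b; nn <- c_ + d_; k <- a + c_
  lo <- max(0L, k - nn); hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, nn, k)
  obs <- dhyper(a, m, nn, k)
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  corr <- if (any(c(a, b, c_, d_) == 0)) 0.5 else 0
  aa <- a + corr; bb <- b + corr; cc <- c_ + corr; dd <- d_ + corr
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  list(p_value = p, odds_ratio = or,
       ci95 = exp(log(or) + c(-1.96, 1.96) * se),
       table = matrix(c(a, b, c_, d_), 2, byrow = TRUE,
                      dimnames = list(c("in_region", "elsewhere"),
                                      c("m5C", "other_C"))))
}

#' Segment / start-codon enrichment of m5C sites
#'
#' Tests whether m5C sites concentrate in a region of the mRNA relative to
#' the cytosine background of the transcripts that carry at least one m5C.
#' The 2x2 table crosses (m5C vs other C) with (in region vs elsewhere in
#' those transcripts); regions are the three segments and the +/-25 nt
#' window around the AUG (51 transcript positions including the A of the
#' start codon).
#'
#' @param m5c_sites data.frame from [assign_segment()] with
#'   `transcript_id` and `tpos` (exonic mRNA sites only)
#' @param models a [transcript_db()]
#' @param genome named character vector of sequences
#' @param region one of "utr5", "cds", "utr3", "aug25"
#' @return object of class `enrichment_result`: list with `region`,
#'   `table`, `odds_ratio`, `ci95`, `p_value`, `n_m5C` (m5Cs in the
#'   region)
#' @export
segment_enrichment <- function(m5c_sites, models, genome,
                               region = c("utr5", "cds", "utr3", "aug25")) {
  region <- match.arg(region)
  m5c_sites <- m5c_sites[!is.na(m5c_sites$tpos) &
                           m5c_sites$feature %in% c("utr5", "cds", "utr3"),
                         , drop = FALSE]
  tids <- unique(m5c_sites$transcript_id)
  if (!length(tids)) stopf("no mRNA m5C sites; empty background")
  bg <- transcript_cytosines(models, genome, tids)
  if (!nrow(bg)) stopf("empty cytosine background")
  bg <- bg[bg$feature %in% c("utr5", "cds", "utr3"), , drop = FALSE]
  bkey <- paste(bg$transcript_id, bg$tpos)
  mkey <- paste(m5c_sites$transcript_id, m5c_sites$tpos)
  is_m5c <- bkey %in% mkey

  in_region <- if (region == "aug25") {
    aug <- vapply(tids, function(t) models[[t]]$segments$cds[1], 0L)
    names(aug) <- tids
    abs(bg$tpos - aug[bg$transcript_id]) <= 25L
  } else {
    bg$feature == region
  }
  a <- sum(is_m5c & in_region); b <- sum(is_m5c & !in_region)
  cc <- sum(!is_m5c & in_region); dd <- sum(!is_m5c & !in_region)
  ft <- fisher_exact_2x2(a, b, cc, dd)
  structure(list(region = region, table = ft$table,
                 odds_ratio = ft$odds_ratio, ci95 = ft$ci95,
                 p_value = ft$p_value, n_m5C = a),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment %s: OR %.3f [%.3f-%.3f], p %.3g, n_m5C %d>\n",
    x$region, x$odds_ratio, x$ci95[1], x$ci95[2], x$p_value, x$n_m5C))
  invisible(x)
}
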