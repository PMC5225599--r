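# Overlap analyses: RBP track preparation, permutation tests of m5C
# overlap with feature tracks, m6A consensus-motif scanning, and the
# codon-proximal distribution of modification sites.

track_granges <- function(track) {
  iv <- track$intervals
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    strand = ifelse(iv$strand %in% c("+", "-"), iv$strand, "*"))
}

sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand = ifelse(sites$strand %in% c("+", "-"), sites$strand, "*"))
}

# logical: is each site inside >= 1 interval of the track (strand-aware;
# '*' intervals match either strand)
sites_in_track <- function(sites, track) {
  if (!nrow(sites)) return(logical(0))
  if (!nrow(track$intervals)) return(rep(FALSE, nrow(sites)))
  hits <- GenomicRanges::findOverlaps(sites_granges(sites),
                                      track_granges(track))
  out <- rep(FALSE, nrow(sites))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Filter a miRNA target track by mirSVR score
#'
#' Keeps intervals whose score (mirSVR efficacy score; more negative =
#' stronger predicted repression) is below the threshold.
#'
#' @param track a [feature_track()] with mirSVR scores in `score`
#' @param max_score keep intervals with score strictly below this
#'   (default -0.1)
#' @return filtered [feature_track()]
#' @export
prepare_mirna_track <- function(track, max_score = -0.1) {
  iv <- track$intervals[track$intervals$score < max_score, , drop = FALSE]
  rownames(iv) <- NULL
  feature_track(track$name, iv)
}

#' Prepare RBP binding-site tracks
#'
#' Within each factor, intervals closer than `merge_gap` nt (on the same
#' chromosome and strand) are merged; merged intervals of length
#' `max_len` nt or more are dropped; finally, intervals overlapping an
#' interval of any other factor are dropped so every retained site is
#' unique to one RBP.
#'
#' @param tracks named list of [feature_track()], one per factor
#' @param merge_gap merge intervals with gap < this many nt (default 15)
#' @param max_len drop merged intervals with length >= this (default 200)
#' @return named list of filtered [feature_track()]s
#' @export
prepare_rbp_sites <- function(tracks, merge_gap = 15L, max_len = 200L) {
  merged <- lapply(tracks, function(tr) {
    iv <- tr$intervals
    if (!nrow(iv)) return(tr)
    out <- list()
    for (grp in split(iv, paste(iv$chrom, iv$strand))) {
      grp <- grp[order(grp$start), , drop = FALSE]
      cur <- grp[1, , drop = FALSE]
      for (i in seq_len(nrow(grp))[-1]) {
        if (grp$start[i] - cur$end < merge_gap) {
          cur$end <- max(cur$end, grp$end[i])
        } else {
          out[[length(out) + 1L]] <- cur
          cur <- grp[i, , drop = FALSE]
        }
      }
      out[[length(out) + 1L]] <- cur
    }
    iv <- do.call(rbind, out)
    iv <- iv[iv$end - iv$start < max_len, , drop = FALSE]
    rownames(iv) <- NULL
    feature_track(tr$name, iv)
  })
  # drop intervals claimed by more than one factor
  grl <- lapply(merged, track_granges)
  keep <- lapply(seq_along(merged), function(i) {
    if (length(grl[[i]]) == 0) return(logical(0))
    claimed <- rep(FALSE, length(grl[[i]]))
    for (j in seq_along(merged)[-i]) {
      if (length(grl[[j]]) == 0) next
      h <- GenomicRanges::findOverlaps(grl[[i]], grl[[j]])
      claimed[unique(S4Vectors::queryHits(h))] <- TRUE
    }
    !claimed
  })
  out <- lapply(seq_along(merged), function(i)
    feature_track(merged[[i]]$name,
                  merged[[i]]$intervals[keep[[i]], , drop = FALSE]))
  names(out) <- names(tracks)
  out
}

#' Permutation test of site-track overlap
#'
#' Counts how many of the given m5C sites fall inside the track, then
#' repeatedly samples the same number of cytosines from the background
#' universe (without replacement) and counts overlaps to build the null.
#' Empirical p-values use the add-one correction
#' p = (#\{null >= obs\} + 1)/(N + 1) (and symmetrically for the low tail),
#' so p is never 0 at finite iterations; Z = (obs - mean)/sd is `NA` when
#' the null is degenerate (sd = 0).
#'
#' @param sites data.frame of m5C sites (`chrom`, `pos`, `strand`)
#' @param track a [feature_track()]
#' @param background data.frame of all eligible cytosines (`chrom`, `pos`,
#'   `strand`); for miRNA targets the Cs of 3'UTRs carrying an m5C, for
#'   RBP sites the Cs of expressed transcripts
#' @param iterations number of permutations (default 10000)
#' @param seed RNG seed
#' @return object of class `permutation_result`
#' @export
overlap_permutation_test <- function(sites, track, background,
                                     iterations = 10000L, seed = 1L) {
  iterations <- as.integer(iterations)
  n_sample <- nrow(sites)
  if (nrow(background) < n_sample)
    stopf("background (%d Cs) smaller than sample size (%d)",
          nrow(background), n_sample)
  member <- sites_in_track(background, track)
  observed <- sum(sites_in_track(sites, track))
  null <- with_seed(seed, vapply(seq_len(iterations), function(it)
    sum(member[sample.int(length(member), n_sample)]), 0L))
  mu <- mean(null); sdev <- sd(null)
  structure(list(
    observed = observed, null_mean = mu, null_sd = sdev,
    z_score = if (isTRUE(sdev > 0)) (observed - mu) / sdev else NA_real_,
    p_high = (sum(null >= observed) + 1) / (iterations + 1),
    p_low = (sum(null <= observed) + 1) / (iterations + 1),
    iterations = iterations, seed = seed, n_sites = n_sample,
    track = track$name),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation '%s': obs %d, null %.2f +/- %.2f, ",
                     "Z %.3f, p_high %.3g, p_low %.3g (%d iter)>\n"),
              x$track, x$observed, x$null_mean, x$null_sd, x$z_score,
              x$p_high, x$p_low, x$iterations))
  invisible(x)
}

#' Scan sequences for the m6A consensus motif HGGACNN
#'
#' Exact IUPAC matching (H = A/C/U, N = any); every matching 7-mer window
#' is reported, including overlapping ones. The reported position is the
#' methylatable A (window offset + 3, 0-based).
#'
#' @param sequences named character vector (DNA or RNA alphabet)
#' @return data.frame `transcript_id`, `pos` (0-based position of the A),
#'   `match` (the 7-mer, in the input alphabet)
#' @export
scan_m6a_motif <- function(sequences) {
  dna <- Biostrings::DNAStringSet(chartr("Uu", "Tt", sequences))
  hits <- Biostrings::vmatchPattern("HGGACNN", dna, fixed = FALSE)
  out <- list()
  for (i in seq_along(hits)) {
    st <- IRanges::start(hits[[i]])
    if (!length(st)) next
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = names(sequences)[i],
      pos = st - 1L + 3L,
      match = substring(sequences[[i]], st, st + 6L),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0), pos = integer(0),
                      match = character(0)))
  do.call(rbind, out)
}

#' Codon-proximal distribution of modification sites
#'
#' Bins site positions within +/-500 nt of the AUG or STOP codon (anchor =
#' first base of the codon) into 40 bins of 25 nt and reports each bin as
#' a percentage of all sites of the mark; sites outside the window count
#' in the denominator only. Sites on transcripts lacking the anchor
#' (non-coding) are skipped and counted in `n_skipped`.
#'
#' @param sites data.frame with `transcript_id` and `tpos`
#' @param models a [transcript_db()]
#' @param anchor "AUG" or "STOP"
#' @return data.frame `bin_start` (offset of the bin's left edge from the
#'   anchor: -500, -475, ..., 475), `count`, `percent`; attributes
#'   `n_sites` (denominator) and `n_skipped`
#' @export
codon_proximal_distribution <- function(sites, models,
                                        anchor = c("AUG", "STOP")) {
  anchor <- match.arg(anchor)
  counts <- integer(40)
  n_used <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    m <- models[[sites$transcript_id[i]]]
    if (is.null(m) || is.null(m$segments)) { n_skipped <- n_skipped + 1L
      next }
    a <- if (anchor == "AUG") m$segments$cds[1] else m$segments$cds[2] - 3L
    rel <- sites$tpos[i] - a
    n_used <- n_used + 1L
    if (rel >= -500 && rel < 500) {
      bin <- floor(rel / 25) + 20L
      counts[bin + 1L] <- counts[bin + 1L] + 1L
    }
  }
  out <- data.frame(bin_start = seq(-500L, 475L, by = 25L),
                    count = counts,
                    percent = if (n_used) 100 * counts / n_used else counts)
  attr(out, "n_sites") <- n_used
  attr(out, "n_skipped") <- n_skipped
  out
}
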