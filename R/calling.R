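# m5C candidate calling: conversion-error estimation from spike-ins, exact
# one-sided binomial test per cytosine, Benjamini-Hochberg FDR, threshold
# flags, and three-replicate consensus.

#' Aggregate positioned reads into a per-cytosine pileup
#'
#' Applies the m-bias trimming and base-quality filtering used before
#' methylation calling: the first `trim_fwd` bases at the 5' end of forward
#' reads and the first `trim_rev` bases at the 5' end of reverse reads are
#' ignored, as is every base with phred quality below `q_min`. Remaining
#' C/T evidence at reference cytosines is counted per position.
#'
#' @param reads data.frame with columns `target`, `start` (0-based leftmost
#'   position on the reference), `orientation` ("fwd"/"rev"), `seq`, `qual`
#'   (phred+33 string), e.g. from [simulate_reads()]
#' @param reference named character vector of reference sequences
#' @param trim_fwd,trim_rev 5'-end bases to discard on forward/reverse
#'   reads (defaults 10 and 7)
#' @param q_min minimum phred base quality (default 35, the single-end
#'   setting; use 30 for paired-end data)
#' @return pileup data.frame: `chrom` (the target), `pos` (0-based),
#'   `strand` ("+" in reference orientation), `n` (C+T evidence), `k`
#'   (C evidence)
#' @export
pileup_from_reads <- function(reads, reference, trim_fwd = 10L,
                              trim_rev = 7L, q_min = 35L) {
  stopifnot(all(c("target", "start", "orientation", "seq", "qual") %in%
                  names(reads)))
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reads))) {
    ref <- reference[[reads$target[i]]]
    if (is.null(ref)) stopf("read %d: unknown target '%s'", i,
                            reads$target[i])
    bases <- strsplit(reads$seq[i], "")[[1]]
    L <- length(bases)
    if (reads$start[i] < 0 || reads$start[i] + L > nchar(ref))
      stopf("read %d extends beyond target '%s'", i, reads$target[i])
    pos <- reads$start[i] + seq_len(L) - 1L
    qual <- utf8ToInt(reads$qual[i]) - 33L
    off5 <- if (reads$orientation[i] == "fwd") seq_len(L) - 1L else
      rev(seq_len(L) - 1L)
    trim <- if (reads$orientation[i] == "fwd") trim_fwd else trim_rev
    refbase <- strsplit(substr(ref, reads$start[i] + 1L,
                               reads$start[i] + L), "")[[1]]
    use <- off5 >= trim & qual >= q_min & refbase == "C" &
      bases %in% c("C", "T")
    for (j in which(use)) {
      key <- paste0(reads$target[i], ":", pos[j])
      cur <- if (is.null(acc[[key]])) c(0L, 0L) else acc[[key]]
      acc[[key]] <- cur + c(1L, as.integer(bases[j] == "C"))
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), n = integer(0),
                      k = integer(0)))
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    strand = "+",
    n = vapply(keys, function(k) acc[[k]][1], 0L),
    k = vapply(keys, function(k) acc[[k]][2], 0L),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the bisulfite conversion error from spike-in pileups
#'
#' Spike-in transcripts are unmethylated by construction, so their pooled
#' non-conversion rate estimates the conversion error
#' epsilon = sum(k) / sum(n). The estimate is floored at `eps_min` so a
#' perfectly converted spike-in cannot produce p = 0 degeneracies in the
#' binomial test.
#'
#' @param spike_pileups pileup data.frame with columns `n`, `k`
#' @param eps_min numeric floor for epsilon (default 1e-4)
#' @return object of class `spikein_estimate`: list with `epsilon`,
#'   `conversion_rate`, `n_positions`, `total_evidence`, `total_unconverted`
#' @export
estimate_conversion_error <- function(spike_pileups, eps_min = 1e-4) {
  N <- sum(spike_pileups$n)
  if (N == 0) stopf("no spike-in evidence (total coverage is 0)")
  K <- sum(spike_pileups$k)
  eps <- max(K / N, eps_min)
  structure(list(epsilon = eps, conversion_rate = 1 - K / N,
                 n_positions = nrow(spike_pileups),
                 total_evidence = N, total_unconverted = K),
            class = "spikein_estimate")
}

#' @export
print.spikein_estimate <- function(x, ...) {
  cat(sprintf(paste0("<spikein_estimate: conversion %.4f%%, epsilon %.3g ",
                     "(%d positions, %d reads)>\n"),
              100 * x$conversion_rate, x$epsilon, x$n_positions,
              x$total_evidence))
  invisible(x)
}

#' Exact upper-tail binomial p-value
#'
#' p = P(X >= k) for X ~ Binomial(n, epsilon): the probability of seeing at
#' least the observed non-converted count if the position were unmethylated
#' and only conversion error operated. One-sided because methylation can
#' only inflate non-conversion.
#'
#' @param n,k coverage and non-converted count (vectorized)
#' @param epsilon conversion error in (0, 1)
#' @return p-values in (0, 1]
#' @export
binomial_pvalue <- function(n, k, epsilon) {
  stopifnot(epsilon > 0, epsilon < 1, all(k >= 0), all(k <= n))
  pbinom(k - 1, n, epsilon, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: q_(i) = min_{j >= i} m p_(j) / j, capped at 1,
#' returned in the input order.
#'
#' @param p numeric p-values in \[0, 1\]
#' @return q-values, same length and order as `p`
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Call m5C candidates from a pileup
#'
#' Tests every pileup position with [binomial_pvalue()] against the
#' spike-in conversion error, applies BH FDR over all tested positions,
#' and flags each position on three criteria: coverage `n >= min_cov`,
#' non-conversion rate `k/n > min_rate` (equivalently a conversion rate
#' below `1 - min_rate`), and `q < max_fdr`. A candidate passes all three.
#'
#' @param pileups pileup data.frame (`chrom`, `pos`, `strand`, `n`, `k`)
#' @param epsilon conversion error (scalar, or a `spikein_estimate`)
#' @param min_cov minimum coverage (default 10, "at least 10 reads")
#' @param min_rate non-conversion rate threshold (default 0.2, strictly
#'   exceeded)
#' @param max_fdr FDR threshold (default 0.01, strict)
#' @return data.frame of class `methylation_calls`: input columns plus
#'   `rate`, `p_value`, `q_value`, `pass_coverage`, `pass_rate`,
#'   `pass_fdr`, `pass`
#' @export
call_candidates <- function(pileups, epsilon, min_cov = 10L,
                            min_rate = 0.2, max_fdr = 0.01) {
  if (inherits(epsilon, "spikein_estimate")) epsilon <- epsilon$epsilon
  out <- pileups
  out$rate <- ifelse(out$n > 0, out$k / out$n, NA_real_)
  out$p_value <- ifelse(out$n > 0,
                        binomial_pvalue(out$n, out$k, epsilon), NA_real_)
  tested <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[tested] <- bh_adjust(out$p_value[tested])
  out$pass_coverage <- !is.na(out$n) & out$n >= min_cov
  out$pass_rate <- !is.na(out$rate) & out$rate > min_rate
  out$pass_fdr <- !is.na(out$q_value) & out$q_value < max_fdr
  out$pass <- out$pass_coverage & out$pass_rate & out$pass_fdr
  attr(out, "epsilon") <- epsilon
  attr(out, "thresholds") <- list(min_cov = min_cov, min_rate = min_rate,
                                  max_fdr = max_fdr)
  class(out) <- c("methylation_calls", class(out))
  out
}

#' Three-replicate consensus of candidate calls
#'
#' A site is a consensus candidate only when it is present and passing in
#' every replicate; a site untested in any replicate is dropped.
#'
#' @param calls_list list of [call_candidates()] outputs, one per replicate
#' @param n_reps required replicate count (default 3)
#' @return data.frame of consensus sites: `chrom`, `pos`, `strand`,
#'   `consensus` (always TRUE), `mean_coverage`, `mean_rate`, and
#'   per-replicate `n`, `k`, `rate` columns
#' @export
replicate_consensus <- function(calls_list, n_reps = 3L) {
  if (length(calls_list) != n_reps)
    stopf("expected %d replicates, got %d", n_reps, length(calls_list))
  keys <- lapply(calls_list, function(x)
    site_key(x$chrom, x$pos, x$strand)[x$pass])
  common <- Reduce(intersect, keys)
  first <- calls_list[[1]]
  fk <- site_key(first$chrom, first$pos, first$strand)
  idx <- match(common, fk)
  out <- data.frame(chrom = first$chrom[idx], pos = first$pos[idx],
                    strand = first$strand[idx],
                    consensus = rep(TRUE, length(idx)),
                    stringsAsFactors = FALSE)
  nmat <- kmat <- rmat <- matrix(NA_real_, nrow = length(common),
                                 ncol = n_reps)
  for (r in seq_len(n_reps)) {
    x <- calls_list[[r]]
    m <- match(common, site_key(x$chrom, x$pos, x$strand))
    nmat[, r] <- x$n[m]; kmat[, r] <- x$k[m]; rmat[, r] <- x$rate[m]
    out[[paste0("n_rep", r)]] <- x$n[m]
    out[[paste0("k_rep", r)]] <- x$k[m]
    out[[paste0("rate_rep", r)]] <- x$rate[m]
  }
  out$mean_coverage <- rowMeans(nmat)
  out$mean_rate <- rowMeans(rmat)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
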