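# Between-sample-type comparison: expression estimation (median-of-ratios
# normalization of exon counts), unique/common classification of consensus
# sites, and the four-way decomposition of uniquely methylated sites.

#' Estimate gene expression with median-of-ratios normalization
#'
#' Size factor per replicate = median over genes of count / geometric-mean
#' pseudo-reference; genes with a zero count in any replicate are excluded
#' from the median. A gene is called expressed in a sample type when its
#' mean normalized count strictly exceeds `expressed_min`.
#'
#' @param counts integer matrix genes x replicates (rownames = gene ids)
#' @param groups character vector assigning each column to a sample type;
#'   default: all columns one group named "all"
#' @param expressed_min expression threshold on the mean normalized count
#'   (default 10, strictly exceeded)
#' @return object of class `expression_table`: list with `size_factors`,
#'   `normalized` (matrix), `mean_normalized` (genes x sample types),
#'   `expressed` (logical matrix, same shape)
#' @export
estimate_expression <- function(counts, groups = NULL, expressed_min = 10) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stopf("need >= 2 replicates")
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  stopifnot(length(groups) == ncol(counts))
  if (any(colSums(counts) == 0)) stopf("a replicate has all-zero counts")
  log_geo <- rowMeans(log(counts))             # -Inf for genes with a zero
  usable <- is.finite(log_geo)
  if (!any(usable))
    stopf("no gene has nonzero counts in every replicate")
  sf <- apply(counts, 2, function(col)
    exp(median(log(col[usable]) - log_geo[usable])))
  normalized <- sweep(counts, 2, sf, "/")
  types <- unique(groups)
  mean_norm <- sapply(types, function(ty)
    rowMeans(normalized[, groups == ty, drop = FALSE]))
  mean_norm <- matrix(mean_norm, nrow = nrow(counts),
                      dimnames = list(rownames(counts), types))
  structure(list(size_factors = sf, normalized = normalized,
                 mean_normalized = mean_norm,
                 expressed = mean_norm > expressed_min,
                 expressed_min = expressed_min),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table: %d genes, %d replicates, %d group(s)>\n",
              nrow(x$normalized), ncol(x$normalized),
              ncol(x$mean_normalized)))
  invisible(x)
}

#' Classify consensus sites as unique or common between sample types
#'
#' A consensus site of sample type A is `unique_A` when it passes in none
#' of B's replicates and `common` when it passes in at least one.
#'
#' @param consensus_a consensus sites of sample type A
#'   ([replicate_consensus()] output)
#' @param calls_b list of per-replicate [call_candidates()] outputs of
#'   sample type B
#' @param label_a,label_b sample type names used in the status labels
#' @return data.frame: `chrom`, `pos`, `strand`, `n_pass_other` (0..3),
#'   `status` ("unique_<label_a>" or "common")
#' @export
classify_unique_common <- function(consensus_a, calls_b,
                                   label_a = "A", label_b = "B") {
  keys_b <- lapply(calls_b, function(x)
    site_key(x$chrom, x$pos, x$strand)[x$pass])
  ka <- site_key(consensus_a$chrom, consensus_a$pos, consensus_a$strand)
  npass <- Reduce(`+`, lapply(keys_b, function(kb)
    as.integer(ka %in% kb)), accumulate = FALSE)
  if (length(ka) == 0) npass <- integer(0)
  data.frame(chrom = consensus_a$chrom, pos = consensus_a$pos,
             strand = consensus_a$strand,
             n_pass_other = as.integer(npass),
             status = ifelse(npass == 0, paste0("unique_", label_a),
                             "common"),
             stringsAsFactors = FALSE)
}

#' Decompose uniquely methylated sites
#'
#' Explains why a site unique to sample type A is absent from B, with one
#' exclusive label per site, in precedence order:
#' \describe{
#'   \item{not_expressed}{the gene's mean normalized count in B is at or
#'     below the expression threshold;}
#'   \item{low_position_coverage}{the site's mean coverage across B's
#'     replicates is below `min_cov`;}
#'   \item{biased_mean}{mean non-conversion rate across B's replicates is
#'     at or above `min_rate` but the median replicate rate is below it:
#'     the mean is skewed towards methylation by an individual replicate;}
#'   \item{low_methylation_rate}{every remaining site (typically mean rate
#'     below `min_rate` at sufficient coverage).}
#' }
#' A site entirely absent from B's pileups is treated as coverage 0.
#'
#' @param unique_sites data.frame of sites unique to A (`chrom`, `pos`,
#'   `strand`, plus a `gene_id` column or see `gene_of`)
#' @param pileups_b list of per-replicate pileup data.frames of B
#' @param expression_b an `expression_table` for B (or `NULL` to skip the
#'   expression tier)
#' @param gene_of optional named vector mapping site keys to gene ids; if
#'   `NULL`, `unique_sites$gene_id` is used
#' @param min_cov coverage threshold (default 10)
#' @param min_rate rate threshold (default 0.2)
#' @param type_b column of `expression_b$mean_normalized` to use
#' @return `unique_sites` with columns `mean_coverage_other`,
#'   `mean_rate_other`, `median_rate_other`, `label`
#' @export
decompose_unique_sites <- function(unique_sites, pileups_b,
                                   expression_b = NULL, gene_of = NULL,
                                   min_cov = 10, min_rate = 0.2,
                                   type_b = 1L) {
  keys <- site_key(unique_sites$chrom, unique_sites$pos,
                   unique_sites$strand)
  nmat <- sapply(pileups_b, function(p) {
    m <- match(keys, site_key(p$chrom, p$pos, p$strand))
    out <- p$n[m]; out[is.na(out)] <- 0L; out
  })
  kmat <- sapply(pileups_b, function(p) {
    m <- match(keys, site_key(p$chrom, p$pos, p$strand))
    out <- p$k[m]; out[is.na(out)] <- 0L; out
  })
  nmat <- matrix(nmat, nrow = length(keys))
  kmat <- matrix(kmat, nrow = length(keys))
  rates <- ifelse(nmat > 0, kmat / nmat, 0)
  mean_cov <- rowMeans(nmat)
  mean_rate <- rowMeans(rates)
  med_rate <- apply(rates, 1, median)

  genes <- if (!is.null(gene_of)) unname(gene_of[keys]) else
    unique_sites$gene_id
  expressed <- rep(TRUE, length(keys))
  if (!is.null(expression_b)) {
    mn <- expression_b$mean_normalized[, type_b]
    expressed <- !is.na(genes) & genes %in% names(mn) &
      mn[genes] > expression_b$expressed_min
  }
  label <- ifelse(!expressed, "not_expressed",
           ifelse(mean_cov < min_cov, "low_position_coverage",
           ifelse(mean_rate >= min_rate & med_rate < min_rate,
                  "biased_mean", "low_methylation_rate")))
  out <- unique_sites
  out$mean_coverage_other <- mean_cov
  out$mean_rate_other <- mean_rate
  out$median_rate_other <- med_rate
  out$label <- label
  out
}
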