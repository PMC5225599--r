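# Small fixture builders shared across test files.

# One-exon coding transcript on '+': exon [0,300), CDS [50,200).
simple_model <- function(strand = "+", cds = c(50L, 200L)) {
  transcript_model("t1", "g1", "chr1", strand,
                   exons = cbind(0L, 300L),
                   cds_start = cds[1], cds_end = cds[2])
}

# Two-exon transcript [0,100) + [200,300).
two_exon_model <- function(strand = "+", tid = "t2", ...) {
  transcript_model(tid, "g2", "chr1", strand,
                   exons = rbind(c(0L, 100L), c(200L, 300L)), ...)
}

# A random multi-exon model for property tests.
random_model <- function(seed, tid = sprintf("rt%d", seed)) {
  set.seed(seed)
  n_ex <- sample(1:4, 1)
  starts <- cumsum(sample(50:200, n_ex * 2))
  exons <- cbind(starts[seq(1, 2 * n_ex, 2)], starts[seq(2, 2 * n_ex, 2)])
  transcript_model(tid, paste0("g", tid), "chrR",
                   sample(c("+", "-"), 1), exons)
}

# Tiny pileup data.frame.
mk_pileup <- function(n, k, chrom = "c", strand = "+") {
  data.frame(chrom = chrom, pos = seq_along(n) - 1L, strand = strand,
             n = as.integer(n), k = as.integer(k),
             stringsAsFactors = FALSE)
}

# Small simulation shared by several files (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_transcriptome(sim_config(seed = 11, n_genes = 8))
    cache
  }
})
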