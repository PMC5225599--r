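test_that("the generator is fully deterministic under its seed", {
  a <- generate_transcriptome(sim_config(seed = 5, n_genes = 5))
  b <- generate_transcriptome(sim_config(seed = 5, n_genes = 5))
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expression, b$expression)
  c <- generate_transcriptome(sim_config(seed = 6, n_genes = 5))
  expect_false(identical(a$genome, c$genome))
})

test_that("hairpin fraction 1 plants the C:G stem / UUCG loop everywhere", {
  sim <- generate_transcriptome(sim_config(seed = 2, n_genes = 5,
                                           hairpin_fraction = 1))
  for (s in sim$transcript_seqs)
    expect_match(s, "CCCCCCTTCGGGGGGG")
  expect_equal(nrow(sim$hairpins), 5L)
  # stem arms are reverse-complementary by construction
  hp <- sim$hairpins[1, ]
  seq <- sim$transcript_seqs[[hp$transcript_id]]
  stem5 <- substr(seq, hp$stem5_start + 1L, hp$stem5_end)
  stem3 <- substr(seq, hp$stem3_start + 1L, hp$stem3_end)
  expect_equal(stem3,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(stem5))))
})

test_that("generated annotation round-trips through core_io", {
  sim <- generate_transcriptome(sim_config(seed = 3, n_genes = 50))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  db <- read_annotation(file.path(dir, "annotation.gtf"))
  genes <- unique(vapply(db, `[[`, "", "gene_id"))
  expect_length(genes, 50L)
  # exon structure and segments survive the round trip
  for (tid in names(sim$models)[1:5]) {
    expect_equal(db[[tid]]$exons, sim$models[[tid]]$exons)
    expect_equal(db[[tid]]$segments, sim$models[[tid]]$segments)
  }
  # genome FASTA reads back identical
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(g[["chrT"]], sim$genome[["chrT"]])
})

test_that("planted truth sites are cytosines on the transcript strand", {
  sim <- small_sim()
  tr <- sim$truth[!is.na(sim$truth$tpos), ]
  for (i in seq_len(min(nrow(tr), 50))) {
    seq <- sim$transcript_seqs[[tr$transcript_id[i]]]
    expect_equal(substr(seq, tr$tpos[i] + 1L, tr$tpos[i] + 1L), "C")
  }
})

test_that("pileup counts follow the stated binomial model", {
  # degenerate: eps = 0, delta = 0, level = 1 -> k == n at planted sites
  cfg <- sim_config(seed = 4, n_genes = 4, conversion_error = 0,
                    meth_level_range = c(1, 1),
                    meth_fraction = c(utr5 = 0.2, cds = 0.2, utr3 = 0.2,
                                      intron = 0.2))
  sim <- generate_transcriptome(cfg)
  pu <- simulate_pileups(sim, "ESC", 1)
  key <- site_key(pu$main$chrom, pu$main$pos, pu$main$strand)
  tr <- sim$truth[sim$truth$in_ESC, ]
  idx <- match(site_key(tr$chrom, tr$pos, tr$strand), key)
  expect_false(anyNA(idx))
  expect_equal(pu$main$k[idx], pu$main$n[idx])

  # unmethylated positions: pooled non-conversion within 3 binomial SDs
  cfg0 <- sim_config(seed = 5, n_genes = 10,
                     meth_fraction = c(utr5 = 0, cds = 0, utr3 = 0,
                                       intron = 0),
                     hairpin_fraction = 0)
  sim0 <- generate_transcriptome(cfg0)
  pu0 <- simulate_pileups(sim0, "ESC", 1)
  N <- sum(pu0$main$n); K <- sum(pu0$main$k)
  eps <- cfg0$conversion_error
  expect_lt(abs(K / N - eps), 3 * sqrt(eps * (1 - eps) / N))

  # intermediate level: mean observed rate near 0.5
  cfg5 <- sim_config(seed = 6, n_genes = 10, coverage_mean = 200,
                     meth_level_range = c(0.5, 0.5),
                     meth_fraction = c(utr5 = 0.2, cds = 0.2, utr3 = 0.2,
                                       intron = 0),
                     hairpin_fraction = 0, silence_prob = 0)
  sim5 <- generate_transcriptome(cfg5)
  pu5 <- simulate_pileups(sim5, "ESC", 1)
  key5 <- site_key(pu5$main$chrom, pu5$main$pos, pu5$main$strand)
  tr5 <- sim5$truth[sim5$truth$in_ESC & sim5$truth$element == "none", ]
  idx5 <- match(site_key(tr5$chrom, tr5$pos, tr5$strand), key5)
  ok <- !is.na(idx5) & pu5$main$n[idx5] > 0
  rates <- pu5$main$k[idx5][ok] / pu5$main$n[idx5][ok]
  ntot <- sum(pu5$main$n[idx5][ok])
  expect_lt(abs(mean(rates) - 0.5), 3 * sqrt(0.25 / ntot) * 3)
})

test_that("spike-in cytosines are never methylated", {
  sim <- small_sim()
  for (r in 1:3) {
    pu <- simulate_pileups(sim, "ESC", r)
    expect_true(all(startsWith(pu$spike$chrom, "spike")))
    # pooled spike rate consistent with epsilon, far below min_rate
    expect_lt(sum(pu$spike$k) / sum(pu$spike$n), 0.05)
  }
})

test_that("replicates share truth but differ in sampling", {
  sim <- small_sim()
  p1 <- simulate_pileups(sim, "ESC", 1)
  p2 <- simulate_pileups(sim, "ESC", 2)
  expect_identical(p1$main[, c("chrom", "pos", "strand")],
                   p2$main[, c("chrom", "pos", "strand")])
  expect_false(identical(p1$main$n, p2$main$n))
  expect_identical(simulate_pileups(sim, "ESC", 1)$main, p1$main)
})

test_that("feature track modes give known overlap direction", {
  sim <- generate_transcriptome(sim_config(seed = 9, n_genes = 12,
                                           meth_fraction = c(
                                             utr5 = 0.02, cds = 0.01,
                                             utr3 = 0.05, intron = 0.005)))
  truth <- sim$truth[sim$truth$in_ESC & sim$truth$element == "none" &
                       sim$truth$segment == "utr3", ]

  excl <- generate_feature_tracks(sim, "exclude")$mirna_targets
  expect_equal(sum(bsm5c:::sites_in_track(truth, excl)), 0L)

  incl <- generate_feature_tracks(sim, "include")$mirna_targets
  expect_gt(sum(bsm5c:::sites_in_track(truth, incl)), 0L)

  # null mode: planted-site overlap frequency matches the track's
  # C-coverage fraction within sampling error
  null <- generate_feature_tracks(sim, "null")$mirna_targets
  bg <- bsm5c:::transcript_cytosines(sim$models, sim$genome,
                                     unique(truth$transcript_id))
  bg <- bg[bg$feature == "utr3", ]
  bg <- bsm5c:::add_genomic_coords(bg, sim$models)
  p_track <- mean(bsm5c:::sites_in_track(bg, null))
  x <- mean(bsm5c:::sites_in_track(truth, null))
  expect_lt(abs(x - p_track),
            4 * sqrt(p_track * (1 - p_track) / nrow(truth)) + 0.02)
})

test_that("every planted m6A motif is found by the scanner", {
  sim <- generate_transcriptome(sim_config(seed = 10, n_genes = 15,
                                           m6a_per_transcript = 2))
  expect_gt(nrow(sim$m6a_sites), 0L)
  hits <- scan_m6a_motif(sim$transcript_seqs)
  hk <- paste(hits$transcript_id, hits$pos)
  expect_true(all(paste(sim$m6a_sites$transcript_id,
                        sim$m6a_sites$tpos) %in% hk))
})

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(utr5_mean = 5), ">= 10")
  expect_error(sim_config(conversion_error = 1.5))
  expect_error(simulate_pileups(small_sim(), "yeast", 1), "unknown sample")
})
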