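test_that("segment assignment follows the precedence rules", {
  # transcript X: exon [0,300) coding; transcript Y: exons [0,100)+[200,300)
  x <- transcript_model("tX", "gX", "chr1", "+", cbind(0L, 300L),
                        cds_start = 50L, cds_end = 200L)
  y <- two_exon_model("+", tid = "tY", cds_start = 0L, cds_end = 250L)
  db <- transcript_db(list(x, y))

  sites <- data.frame(chrom = "chr1",
                      pos = c(100L, 150L, 5000L, 10L, 250L),
                      strand = "+", stringsAsFactors = FALSE)
  asn <- assign_segment(sites, db)
  # pos 100: CDS of X (exonic in X, exonic in Y too; X has longer CDS? X
  # CDS 150 nt, Y CDS spans blocks -> 150 nt; tie broken by id: tX first)
  expect_equal(asn$feature[1], "cds")
  expect_equal(asn$transcript_id[1], "tX")
  # pos 150: exonic in X, intronic in Y -> exonic wins
  expect_equal(asn$feature[2], "cds")
  expect_equal(asn$transcript_id[2], "tX")
  # pos 5000: outside everything
  expect_equal(asn$feature[3], "non_annotated")
  # pos 10: 5'UTR of X
  expect_equal(asn$feature[4], "utr5")
  # pos 250: 3'UTR of X
  expect_equal(asn$feature[5], "utr3")

  # intron only: a site exonic in no transcript but inside a gene span
  only_y <- transcript_db(list(y))
  asn <- assign_segment(data.frame(chrom = "chr1", pos = 150L,
                                   strand = "+"), only_y)
  expect_equal(asn$feature, "intron")
  # strand mismatch means no assignment
  asn <- assign_segment(data.frame(chrom = "chr1", pos = 100L,
                                   strand = "-"), db)
  expect_equal(asn$feature, "non_annotated")
})

test_that("metagene coordinates rescale segments by their average length", {
  # single transcript with segment lengths exactly (200, 1000, 800)
  m <- transcript_model("t", "g", "c", "+", cbind(0L, 2000L),
                        cds_start = 200L, cds_end = 1200L)
  db <- transcript_db(list(m))
  mk <- function(tpos, feature)
    data.frame(transcript_id = "t", tpos = tpos, feature = feature,
               stringsAsFactors = FALSE)
  # site at the CDS start: cumulative offset 200 of 2000 -> bin 10
  p <- metagene_profile(mk(200L, "cds"), db)
  expect_equal(p$bins$percent[p$bins$bin == 10], 100)
  # transcript start -> bin 0
  p <- metagene_profile(mk(0L, "utr5"), db)
  expect_equal(p$bins$percent[p$bins$bin == 0], 100)
  # last base of the 3'UTR -> clamped into bin 99
  p <- metagene_profile(mk(1999L, "utr3"), db)
  expect_equal(p$bins$percent[p$bins$bin == 99], 100)
  expect_equal(p$boundaries, c(utr5_cds = 10, cds_utr3 = 60))
  expect_error(metagene_profile(mk(10L, "intron"), db), "utr5/cds/utr3")
})

test_that("metagene percentages always sum to 100", {
  sim <- small_sim()
  tr <- sim$truth[!is.na(sim$truth$tpos) &
                    sim$truth$segment %in% c("utr5", "cds", "utr3"), ]
  tr$feature <- tr$segment
  p <- metagene_profile(tr, sim$models)
  expect_equal(sum(p$bins$percent), 100)
  expect_equal(p$n_sites, nrow(tr))
})

test_that("random-C sampling is seeded, uniform and exhaustive", {
  sim <- small_sim()
  tids <- names(sim$models)[1:2]
  cs <- bsm5c:::transcript_cytosines(sim$models, sim$genome, tids)
  all_c <- sample_random_cs(sim$models, sim$genome, nrow(cs), seed = 1,
                            transcripts = tids)
  expect_setequal(paste(all_c$transcript_id, all_c$tpos),
                  paste(cs$transcript_id, cs$tpos))
  expect_identical(
    sample_random_cs(sim$models, sim$genome, 10, seed = 9,
                     transcripts = tids),
    sample_random_cs(sim$models, sim$genome, 10, seed = 9,
                     transcripts = tids))
  expect_error(sample_random_cs(sim$models, sim$genome, nrow(cs) + 1,
                                seed = 1, transcripts = tids), "only")
  # genomic coordinates map back to the sampled transcript positions
  one <- sample_random_cs(sim$models, sim$genome, 25, seed = 2,
                          transcripts = tids)
  for (i in 1:nrow(one)) {
    m <- sim$models[[one$transcript_id[i]]]
    expect_equal(genomic_to_transcript(m, one$pos[i]), one$tpos[i])
  }
  # uniformity: each C of a small pool drawn with equal frequency
  pool <- bsm5c:::transcript_cytosines(sim$models, sim$genome, tids[1])
  n_pool <- nrow(pool)
  draws <- table(unlist(lapply(1:2000, function(s)
    sample_random_cs(sim$models, sim$genome, 1, seed = 10000 + s,
                     transcripts = tids[1])$tpos)))
  expected <- 2000 / n_pool
  sdev <- sqrt(2000 * (1 / n_pool) * (1 - 1 / n_pool))
  expect_true(all(abs(draws - expected) < 4 * sdev + 1))
})

test_that("the Fisher test matches the enumeration oracle", {
  r <- fisher_exact_2x2(5, 95, 5, 95)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  r <- fisher_exact_2x2(3, 1, 1, 3)
  expect_equal(r$p_value, fisher_enum_oracle(3, 1, 1, 3),
               tolerance = 1e-12)
  expect_equal(r$odds_ratio, 9)
  # random tables against both the enumeration oracle and fisher.test
  set.seed(5)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, sample(8:60, 1), rep(0.25, 4)))
    p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    expect_equal(p, fisher_enum_oracle(cells[1], cells[2], cells[3],
                                       cells[4]),
                 tolerance = 1e-9)
    expect_equal(p, fisher.test(matrix(cells, 2))$p.value,
                 tolerance = 1e-7)
  }
  # Haldane correction engages only for zero cells
  r0 <- fisher_exact_2x2(0, 10, 10, 10)
  expect_equal(r0$odds_ratio, (0.5 * 10.5) / (10.5 * 10.5))
  expect_true(all(is.finite(r0$ci95)))
})

test_that("planted start-codon bias is detected by segment enrichment", {
  # all m5Cs within 25 nt of the AUG: strong AUG enrichment, CDS depletion
  m <- transcript_model("t", "g", "c", "+", cbind(0L, 2000L),
                        cds_start = 200L, cds_end = 1200L)
  db <- transcript_db(list(m))
  genome <- list(c = rand_dna(2000, seed = 8))
  chars <- strsplit(genome$c, "")[[1]]
  cpos <- which(chars == "C") - 1L
  aug_cs <- cpos[abs(cpos - 200L) <= 25L]
  sites <- data.frame(chrom = "c", pos = aug_cs, strand = "+",
                      transcript_id = "t", tpos = aug_cs,
                      feature = ifelse(aug_cs < 200L, "utr5", "cds"),
                      stringsAsFactors = FALSE)
  enr <- segment_enrichment(sites, db, genome, "aug25")
  expect_gt(enr$odds_ratio, 1)
  expect_lt(enr$p_value, 1e-6)
  expect_equal(enr$n_m5C, length(aug_cs))
  cds <- segment_enrichment(sites, db, genome, "cds")
  expect_lt(cds$odds_ratio, 1)
  # contingency table margins add up to the full C background
  expect_equal(sum(enr$table), length(cpos))
})
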