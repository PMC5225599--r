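test_that("median-of-ratios normalization recovers depth differences", {
  # replicate 2 sequenced exactly twice as deep: size factors 1:2 up to a
  # common scale, normalized counts identical
  c1 <- c(g1 = 100L, g2 = 40L, g3 = 250L, g4 = 7L, g5 = 1000L)
  counts <- cbind(rep1 = c1, rep2 = 2L * c1)
  et <- estimate_expression(counts)
  expect_equal(et$size_factors[["rep2"]] / et$size_factors[["rep1"]], 2)
  expect_equal(et$normalized[, 1], et$normalized[, 2])
  # hand-computed: sf1 = 1/sqrt(2), so normalized g1 = 100*sqrt(2)
  expect_equal(unname(et$normalized["g1", 1]), 100 * sqrt(2))

  # expressed means strictly greater than the threshold
  cc <- cbind(a = c(gA = 10L, gB = 1000L), b = c(gA = 10L, gB = 1000L))
  et <- estimate_expression(cc)
  expect_false(et$expressed["gA", 1])
  expect_true(et$expressed["gB", 1])

  # single-gene table: forced by the formula
  one <- cbind(r1 = c(gX = 50L), r2 = c(gX = 200L))
  et <- estimate_expression(one)
  expect_equal(unname(et$size_factors), c(50, 200) / 100)
  expect_equal(unname(et$normalized[1, ]), c(100, 100))

  # genes with zeros are excluded from the median but still normalized
  cz <- cbind(r1 = c(g1 = 100L, g2 = 0L, g3 = 400L),
              r2 = c(g1 = 100L, g2 = 90L, g3 = 400L))
  et <- estimate_expression(cz)
  expect_equal(unname(et$size_factors), c(1, 1))
  expect_error(estimate_expression(cbind(a = c(0L, 0L), b = c(1L, 2L))),
               "all-zero")
})

test_that("normalization matches the reference estimator", {
  set.seed(7)
  counts <- matrix(rnbinom(300, mu = 200, size = 5), ncol = 3,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   c("a", "b", "c")))
  counts[, 2] <- rnbinom(100, mu = 600, size = 5)
  sf <- estimate_expression(counts)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("unique/common classification covers every replicate pattern", {
  # consensus site of A at pos 0; build B call sets over all 3^3 patterns
  # of {absent, present-failing, present-passing} per replicate
  cons <- data.frame(chrom = "c", pos = 0L, strand = "+",
                     stringsAsFactors = FALSE)
  states <- expand.grid(r1 = 0:2, r2 = 0:2, r3 = 0:2)
  mk_rep <- function(state) {
    if (state == 0)           # absent: some other site only
      return(call_candidates(mk_pileup(50L, 40L, chrom = "other"), 0.005))
    k <- if (state == 2) 40L else 1L
    call_candidates(mk_pileup(50L, k), 0.005)
  }
  for (i in seq_len(nrow(states))) {
    st <- unlist(states[i, ])
    cls <- classify_unique_common(cons, lapply(st, mk_rep), "A", "B")
    expect_equal(nrow(cls), 1L)
    expected <- if (any(st == 2)) "common" else "unique_A"
    expect_equal(cls$status, expected,
                 info = paste(st, collapse = ","))
    expect_equal(cls$n_pass_other, sum(st == 2))
  }
})

test_that("classification partitions the consensus set", {
  sim <- small_sim()
  calls <- lapply(c("ESC", "brain"), function(ty)
    lapply(1:3, function(r) {
      pu <- simulate_pileups(sim, ty, r)
      call_candidates(pu$main, estimate_conversion_error(pu$spike))
    }))
  cons_a <- replicate_consensus(calls[[1]])
  cls <- classify_unique_common(cons_a, calls[[2]], "ESC", "brain")
  expect_equal(nrow(cls), nrow(cons_a))
  expect_true(all(cls$status %in% c("unique_ESC", "common")))
  expect_equal(sum(cls$status == "unique_ESC") +
                 sum(cls$status == "common"), nrow(cons_a))
})

test_that("unique-site decomposition follows the precedence ladder", {
  mk_b <- function(ns, ks) lapply(1:3, function(r)
    mk_pileup(ns[r], ks[r]))
  site <- data.frame(chrom = "c", pos = 0L, strand = "+",
                     gene_id = "g1", stringsAsFactors = FALSE)
  expr <- structure(list(
    mean_normalized = matrix(c(4, 500), 2,
                             dimnames = list(c("g1", "g2"), "B")),
    expressed_min = 10), class = "expression_table")

  # gene below the expression threshold wins over everything
  d <- decompose_unique_sites(site, mk_b(c(50, 50, 50), c(0, 0, 0)), expr)
  expect_equal(d$label, "not_expressed")

  site$gene_id <- "g2"
  # mean coverage (3+5+4)/3 < 10
  d <- decompose_unique_sites(site, mk_b(c(3, 5, 4), c(0, 0, 0)), expr)
  expect_equal(d$label, "low_position_coverage")

  # rates (0.05, 0.05, 0.8): mean 0.3 >= 0.2 but median 0.05 < 0.2
  d <- decompose_unique_sites(site, mk_b(c(20, 20, 20), c(1, 1, 16)), expr)
  expect_equal(d$label, "biased_mean")
  expect_equal(d$mean_rate_other, 0.3)
  expect_equal(d$median_rate_other, 0.05)

  # well-covered, uniformly low rate
  d <- decompose_unique_sites(site, mk_b(c(20, 20, 20), c(1, 2, 1)), expr)
  expect_equal(d$label, "low_methylation_rate")

  # absent from B's pileups entirely: treated as zero coverage
  far <- data.frame(chrom = "c", pos = 99L, strand = "+", gene_id = "g2",
                    stringsAsFactors = FALSE)
  d <- decompose_unique_sites(far, mk_b(c(20, 20, 20), c(0, 0, 0)), expr)
  expect_equal(d$label, "low_position_coverage")
})

test_that("decomposition is exhaustive and exclusive", {
  labels <- c("not_expressed", "low_position_coverage", "biased_mean",
              "low_methylation_rate")
  set.seed(3)
  for (i in 1:200) {
    ns <- sample(0:40, 3, replace = TRUE)
    ks <- vapply(ns, function(n) sample(0:n, 1), 0L)
    gene <- sample(c("g1", "g2"), 1)
    site <- data.frame(chrom = "c", pos = 0L, strand = "+",
                       gene_id = gene, stringsAsFactors = FALSE)
    expr <- structure(list(
      mean_normalized = matrix(c(4, 500), 2,
                               dimnames = list(c("g1", "g2"), "B")),
      expressed_min = 10), class = "expression_table")
    d <- decompose_unique_sites(site,
                                lapply(1:3, function(r)
                                  mk_pileup(ns[r], ks[r])), expr)
    expect_true(d$label %in% labels)
    expect_length(d$label, 1L)
  }
})
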