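test_that("pileup_from_reads applies 5' trimming and quality cutoffs", {
  ref <- c(tx = paste0(strrep("A", 5), "C", strrep("A", 24)))  # C at pos 5

  # single forward read covering the C at read-offset 5 with trim_fwd=10:
  # the base is inside the trimmed window, so the site gets no coverage
  reads <- data.frame(target = "tx", start = 0L, orientation = "fwd",
                      seq = paste0(strrep("A", 5), "C", strrep("A", 24)),
                      qual = strrep("I", 30), stringsAsFactors = FALSE)
  pu <- pileup_from_reads(reads, ref, trim_fwd = 10L)
  expect_equal(nrow(pu), 0L)
  # a reverse read of the same span has the C at 5'-offset 24 >= trim_rev
  reads$orientation <- "rev"
  pu <- pileup_from_reads(reads, ref, trim_rev = 7L)
  expect_equal(pu$n, 1L)

  # base quality 34 is excluded at q_min = 35 ('C' = phred 34, 'D' = 35)
  reads <- data.frame(target = "tx", start = 0L, orientation = "fwd",
                      seq = strrep("C", 30),
                      qual = paste0(strrep("I", 5), "C", strrep("I", 24)),
                      stringsAsFactors = FALSE)
  ref2 <- c(tx = strrep("C", 30))
  pu <- pileup_from_reads(reads, ref2, trim_fwd = 0L, q_min = 35L)
  expect_false(5L %in% pu$pos)
  expect_true(6L %in% pu$pos)

  # 20 clean all-C reads -> n = k = 20 at every untrimmed C
  reads20 <- data.frame(target = "tx", start = 0L, orientation = "fwd",
                        seq = strrep("C", 30), qual = strrep("I", 30),
                        stringsAsFactors = FALSE)[rep(1, 20), ]
  pu <- pileup_from_reads(reads20, ref2, trim_fwd = 10L)
  expect_true(all(pu$n == 20L & pu$k == 20L))
  expect_equal(pu$pos, 10:29)

  expect_error(pileup_from_reads(
    data.frame(target = "tx", start = 25L, orientation = "fwd",
               seq = strrep("C", 30), qual = strrep("I", 30)),
    ref2), "beyond")
})

test_that("trimming removes simulated m-bias", {
  seq <- rand_dna(300, seed = 1)
  rates <- numeric(300)
  reads <- simulate_reads(seq, rates, n_reads = 3000L, read_length = 60L,
                          conversion_error = 0.005, mbias_len = 10L,
                          mbias_rate = 0.4, seed = 2)
  ref <- c(tx = seq)
  raw <- pileup_from_reads(reads, ref, trim_fwd = 0L, trim_rev = 0L,
                           q_min = 0L)
  trimmed <- pileup_from_reads(reads, ref, trim_fwd = 10L, trim_rev = 7L,
                               q_min = 30L)
  rate_raw <- sum(raw$k) / sum(raw$n)
  rate_trim <- sum(trimmed$k) / sum(trimmed$n)
  expect_gt(rate_raw, rate_trim)     # m-bias inflates the untrimmed rate
  expect_lt(rate_trim, 0.02)
})

test_that("conversion error is pooled over spike-in positions and floored", {
  expect_equal(estimate_conversion_error(mk_pileup(1000L, 10L))$epsilon,
               0.01)
  expect_equal(estimate_conversion_error(
    mk_pileup(1000L, 10L))$conversion_rate, 0.99)
  # floor at eps_min when spike-ins convert perfectly
  est <- estimate_conversion_error(mk_pileup(c(500L, 500L), c(0L, 0L)))
  expect_equal(est$epsilon, 1e-4)
  expect_equal(est$conversion_rate, 1)
  # pooling: (3 + 2) / (600 + 400)
  est <- estimate_conversion_error(mk_pileup(c(600L, 400L), c(3L, 2L)))
  expect_equal(est$epsilon, 5 / 1000)
  expect_error(estimate_conversion_error(mk_pileup(0L, 0L)), "spike-in")
})

test_that("binomial_pvalue is the exact upper tail", {
  expect_equal(binomial_pvalue(10, 10, 0.5), 0.5^10)
  expect_equal(binomial_pvalue(7, 0, 0.3), 1)
  # independent term-wise summation oracle
  expect_equal(binomial_pvalue(50, 20, 0.01),
               binom_tail_oracle(50, 20, 0.01), tolerance = 1e-12)
  for (n in c(10, 100, 500)) {
    for (k in unique(pmin(n, c(1, 3, n %/% 10, n %/% 2)))) {
      for (eps in c(0.005, 0.1, 0.5)) {
        o <- binom_tail_oracle(n, k, eps)
        if (o < 1e-280) next
        expect_equal(binomial_pvalue(n, k, eps), o, tolerance = 1e-10)
      }
    }
  }
})

test_that("p(k) decreases in k and passing is stable as n grows", {
  p <- binomial_pvalue(rep(50, 51), 0:50, 0.01)
  expect_true(all(diff(p) < 0))
  # with k/n fixed at 0.3, the tail p only shrinks as n grows
  ns <- seq(10, 500, by = 10)
  p <- binomial_pvalue(ns, ceiling(0.3 * ns), 0.005)
  expect_true(all(diff(p) < 1e-12))
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.5)),
               c(0.004, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  # agrees with the reference implementation on random input, in any order
  set.seed(1)
  for (i in 1:5) {
    p <- runif(200)^3
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
})

test_that("call_candidates applies the three thresholds", {
  pu <- mk_pileup(n = c(9L, 100L, 100L, 50L),
                  k = c(9L, 15L, 40L, 0L))
  calls <- call_candidates(pu, epsilon = 0.005)
  expect_false(calls$pass[1])            # n = 9 < 10: coverage
  expect_true(calls$pass_rate[1])
  expect_false(calls$pass[2])            # rate 0.15 <= 0.2
  expect_true(calls$pass_coverage[2])
  expect_true(calls$pass[3])             # n=100, k=40: q far below 0.01
  expect_lt(calls$q_value[3], 0.01)
  expect_false(calls$pass[4])            # k = 0
  expect_equal(calls$p_value[4], 1)
  # boundary: rate must strictly exceed min_rate
  b <- call_candidates(mk_pileup(100L, 20L), epsilon = 0.005)
  expect_false(b$pass_rate)
})

test_that("replicate consensus requires presence and passing everywhere", {
  base <- mk_pileup(n = c(50L, 50L, 50L), k = c(40L, 40L, 40L))
  r1 <- call_candidates(base, 0.005)
  r2 <- call_candidates(base, 0.005)
  # replicate 3 fails the rate at site 2 and lacks site 3 entirely
  r3 <- call_candidates(mk_pileup(n = c(50L, 50L), k = c(40L, 5L)), 0.005)
  cons <- replicate_consensus(list(r1, r2, r3))
  expect_equal(cons$pos, 0L)             # only site 1 in all three
  expect_equal(cons$mean_rate, 0.8)
  expect_equal(cons$mean_coverage, 50)
  expect_error(replicate_consensus(list(r1, r2)), "expected 3")
})
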