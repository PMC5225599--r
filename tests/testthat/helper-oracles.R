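# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Upper-tail binomial P(X >= k) by term-wise summation in log space.
binom_tail_oracle <- function(n, k, eps) {
  if (k <= 0) return(1)
  lt <- dbinom(k:n, n, eps, log = TRUE)
  m <- max(lt)
  exp(m + log(sum(exp(lt - m))))
}

# Two-sided Fisher p for table (a b / c d) by exhaustive enumeration of all
# tables with the observed margins, probabilities from binomial
# coefficients (not dhyper).
fisher_enum_oracle <- function(a, b, c_, d_) {
  m <- a + b; n <- c_ + d_; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  lp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  probs <- exp(lp)
  obs <- probs[match(a, xs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Maximum base-pair count under the fallback folding rules (canonical +
# wobble, min hairpin loop, max pair span) by plain O(n^3) recursion with
# memoisation. For short sequences only.
nussinov_count_oracle <- function(seq, max_dist = 150L, min_loop = 3L) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(s)
  ok <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    if (ok(s[i], s[j]) && j - i <= max_dist)
      best <- max(best, rec(i + 1L, j - 1L) + 1L)
    for (k in seq(i + 1L, j - 1L))
      best <- max(best, rec(i, k) + rec(k + 1L, j))
    memo[[key]] <- best
    best
  }
  if (n < 2) return(0L)
  rec(1L, n)
}

# Parse a dot-bracket string into a pair matrix; errors on imbalance.
pairs_from_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket")
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket")
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

# TRUE when no two pairs cross (nested structure).
noncrossing <- function(pairs) {
  if (nrow(pairs) < 2) return(TRUE)
  for (i in seq_len(nrow(pairs) - 1)) {
    for (j in (i + 1):nrow(pairs)) {
      a <- pairs[i, ]; b <- pairs[j, ]
      inside <- (b[1] > a[1] & b[2] < a[2]) | (a[1] > b[1] & a[2] < b[2])
      disjoint <- b[1] > a[2] | a[1] > b[2]
      if (!inside && !disjoint) return(FALSE)
    }
  }
  TRUE
}

# Brute-force IUPAC HGGACNN scan over every window.
m6a_scan_oracle <- function(seq) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  hits <- integer(0)
  if (length(s) >= 7) {
    for (i in seq_len(length(s) - 6)) {
      w <- s[i:(i + 6)]
      if (w[1] %in% c("A", "C", "T") && w[2] == "G" && w[3] == "G" &&
          w[4] == "A" && w[5] == "C")
        hits <- c(hits, i - 1L + 3L)    # 0-based position of the A
    }
  }
  hits
}

# Random sequence as a plain string.
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
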