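---
title: "Methods: m5C calling from RNA bisulfite sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m5C calling from RNA bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsm5c)
```

# The model

RNA bisulfite sequencing converts unmethylated cytosine to uracil;
5-methylcytosine resists. At a cytosine covered by $n$ informative reads
of which $k$ retain C, the non-conversion rate $\hat r = k/n$ estimates
the methylation level. Two error processes contaminate $\hat r$:

* **conversion error** $\varepsilon$ — an unmethylated C read as C
  (incomplete deamination, sequencing error);
* **structure protection** — base-paired cytosines resist deamination
  chemically, mimicking methylation.

The caller addresses the first statistically and the second by an explicit
filter.

## Conversion error from spike-ins

Unmethylated in-vitro transcripts added before treatment estimate
$\varepsilon = \sum k / \sum n$ pooled over all their cytosines
(`estimate_conversion_error()`). The estimate is floored at
$\varepsilon_{\min} = 10^{-4}$: a finite spike-in can show zero
non-conversion, and $\varepsilon = 0$ would make every $k > 0$ position
infinitely significant. The floor is configurable; at typical spike-in
evidence (tens of thousands of reads) it never binds.

## The per-position test

Under the null (no methylation), $k \sim \mathrm{Binomial}(n,
\varepsilon)$. The test is the exact upper tail $p = P(X \ge k)$
(`binomial_pvalue()`), one-sided because methylation can only inflate
non-conversion. Benjamini–Hochberg q-values (`bh_adjust()`) are computed
per replicate over all tested positions of that replicate — the original
analysis ran per-sample calling before consensus and did not state the
FDR pool, so the per-replicate pool is the faithful minimal reading. A
candidate passes when $n \ge 10$, $\hat r > 0.2$ and $q < 0.01$, and
must pass in all three replicates (`replicate_consensus()`). The
coverage boundary follows the operational "at least 10 reads" statement;
the narrative ">10 reads" phrasing would shift only the single case
$n = 10$ and is available via `min_cov`.

Read-level evidence is prepared by `pileup_from_reads()`: the first 10
bases at the 5′ end of forward reads and 7 of reverse reads are excluded
(the m-bias artifact), as are bases below Q35 (single-end; 30 for
paired-end data).

## The structure filter

Exonic candidates are folded in their full spliced transcript;
intronic/non-annotated candidates in a 300-nt window centred on the site;
pair spans are capped at 150 nt. A candidate whose base is non-`.` in the
dot-bracket structure is discarded — pairing with any partner counts, not
only C:G, since protection is a property of being double-stranded.

The folding engine is pluggable. The thermodynamic target is the
maximum-expected-accuracy structure at 70 °C with $\gamma = 0.1$
(`engine = "mea"`, requiring ViennaRNA's `RNAfold` on the PATH). This
environment pins no ViennaRNA, so the always-available default is a
Nussinov-style **maximum base-pairing** engine (`engine = "maxpair"`,
Rcpp): canonical plus wobble pairs, minimum hairpin loop 3 nt, same
150-nt span cap; it ignores temperature and $\gamma$, which have no
meaning without an energy model. Every result records its engine.

Two numerical choices matter in the fallback engine:

* **Lexicographic scoring.** Maximum-base-pairing structures are heavily
  degenerate. The DP maximizes pair count first and, among count-optimal
  structures, the number of G:C pairs. The returned pair count therefore
  always equals the plain Nussinov maximum (the oracle contract), but
  ties resolve toward C:G stems instead of arbitrary wobble
  rearrangements. Traceback prefers closing the outermost pair, keeping
  stems intact.
* **Banded DP.** Because no pair may span more than 150 nt, the interval
  DP is banded ($O(n\,W^2)$, $W = 150$) and a linear chain DP composes
  intervals across the full transcript, so folding a 5-kb transcript is
  immediate.

Under maximum base-pairing most cytosines of a random-sequence transcript
are paired, so the filter is far more aggressive than thermodynamic MEA
at $\gamma = 0.1$ would be: on simulated data it typically discards
~2/3 of consensus candidates. A green structure-filter test therefore
establishes the planted guarantees (stems discarded, isolated cytosines
retained), not that the fallback reproduces MEA attrition rates.

## Comparison between sample types

Expression is estimated from exon read counts by median-of-ratios
normalization (`estimate_expression()`): size factor = median over genes
of count / geometric-mean reference, genes with any zero excluded from
the median; expressed ⇔ mean normalized count > 10. This is the standard
definition of the estimator the original tooling delegates to; the
package implements it directly and tests it against the reference
implementation.

A consensus site of sample type A is **unique** when it passes in none of
B's replicates and **common** when it passes in at least one
(`classify_unique_common()`). Unique sites are explained by one of four
exclusive labels (`decompose_unique_sites()`), in precedence order:

1. `not_expressed` — gene mean normalized count ≤ 10 in B;
2. `low_position_coverage` — mean site coverage in B < 10 (a site absent
   from B's pileups counts as coverage 0);
3. `biased_mean` — mean rate ≥ 0.2 but median replicate rate < 0.2;
4. `low_methylation_rate` — everything else.

"Biased mean" has no published formula; the phrase "skewed towards
methylation by an individual replicate" is operationalized as
mean-passing but median-failing, the simplest reading that detects a
single outlier replicate. The fourth label is a catch-all: the literal
reading (mean rate < 0.2) leaves a rare configuration unlabeled (mean and
median ≥ 0.2 with the site failing in B only through FDR or per-replicate
patterns), and the decomposition is required to be exhaustive; such sites
are still "not methylated above threshold in B" in every replicate-robust
sense.

## Positional analysis

`assign_segment()` gives each site exactly one feature with precedence
exonic mRNA segment > intron > non-annotated; among several exonic
transcripts the one with the longest CDS wins, ties broken by id — one
deterministic choice point shared by all downstream consumers.

The meta-gene (`metagene_profile()`) rescales each segment to its average
length over coding transcripts; a site's coordinate is its segment's
cumulative average offset plus its within-segment relative position times
the segment's average length, binned into 100 bins of 1% (bin 100 clamps
to 99). Random-C controls (`sample_random_cs()`) draw uniformly without
replacement from the cytosines of the same transcripts.

Enrichment (`segment_enrichment()`) crosses (m5C vs other C) with (in
region vs elsewhere) over the cytosines of transcripts carrying ≥ 1 m5C.
The two-sided Fisher p sums hypergeometric probabilities ≤ the observed
table's (relative tolerance 1e-7, matching the reference test). The odds
ratio is the sample OR $(ad)/(bc)$ with Haldane 0.5 correction iff any
cell is zero, CI from the Woolf log-OR standard error — the conditional
MLE that `fisher.test()` reports differs slightly by construction. The
AUG window is the ±25 nt around the first base of the start codon (51
positions), tested within the same mRNA cytosine background.

## Overlap analyses

RBP tracks are prepared per factor by merging intervals closer than 15 nt,
dropping merged intervals ≥ 200 nt, then dropping intervals claimed by
more than one factor (`prepare_rbp_sites()`). miRNA target tracks are
filtered to mirSVR score < −0.1 at load (`prepare_mirna_track()`).

`overlap_permutation_test()` samples |m5C| cytosines without replacement
from the stated background (3′UTR Cs of m5C-bearing UTRs for miRNA
targets; Cs of expressed transcripts for RBPs) for 10,000 iterations,
reporting observed count, null mean/sd, $Z$, and both empirical tails
with the add-one correction $p = (\#\{null \ge obs\} + 1)/(N+1)$ — the
floor $\approx 10^{-4}$ at 10,000 iterations matches how such p-values
are conventionally reported, and both tails are given because printed
one-sided p-values accompany signed Z-scores.

The m6A consensus HGGACNN is matched exactly as IUPAC (H = A/C/U, N =
any), all overlapping windows reported, hit position = the methylatable A
(`scan_m6a_motif()`); a PWM adds nothing for a consensus-degenerate
motif with no published score threshold. `codon_proximal_distribution()`
bins sites within ±500 nt of the AUG or STOP (anchor = first codon base)
into 40 × 25-nt bins as percentages of **all** sites of the mark —
out-of-window sites stay in the denominator.

# The simulator: what it emulates and what it does not

`generate_transcriptome()` builds ~30 genes (one transcript each) with
5′UTR/CDS/3′UTR of mean 200/1000/800 nt, ~1.5 introns of mean 300 nt per
gene, on one chromosome with intergenic spacers; two unmethylated
spike-in transcripts (552 nt 16S-like, 2000 nt vector-like); planted
HGGACNN motifs; and per-sample-type truth sets sharing a configurable
fraction of sites (default 0.3). Pileups are simulated directly:
$k \sim \mathrm{Binomial}(n,\; r(1-\delta) + (1-r)\varepsilon)$ with
negative-binomial coverage (mean 50 on exons, 20% of that on introns,
dispersion 8) scaled by per-gene lognormal expression; 10% of genes are
near-silent per sample type, which exercises the `not_expressed` and
`low_position_coverage` branches. Defaults state the regime the pipeline
targets: $\varepsilon = 0.005$ (conversion > 99%), $\delta = 0$,
methylation levels uniform on [0.2, 1], three replicates. A read-level
layer (`simulate_reads()`) adds per-base qualities and a 5′ m-bias
artifact for testing `pileup_from_reads()`; the statistics operate on
pileups, so read-level is not the primary path. The spike-in mass ratio
(1:20,000) is not emulated — only pooled conversion evidence matters —
and there is no PCR/adapter model, no splice variation, no SNPs.

Structure controls are planted in half-visible form: a 6-bp C:G stem with
UUCG tetraloop, and a lone "spacer" cytosine inside a 301-nt G-free
stretch. Both sit inside A-only buffers spanning the 150-nt pair cap.
This is deliberate: a hairpin dropped into random 50% GC sequence is not
a clean planted structure — its stem guanines get claimed by neighbouring
cytosines in count-equal or count-better pairings, and the "planted
hairpin" label would be false. Isolated, the stem is the unique
count-and-GC-optimal pairing and the spacer C provably cannot pair, so
the filter guarantees (100% stem discard, 0% spacer loss) are properties
of the method, not luck. The synthetic sequence consequently does not
emulate the pairing density of real transcriptomes — a caveat a green
test inherits.

Ground truth records every planted site's genomic position, level,
segment and element flag, enabling recovery scoring: at the defaults,
planted sites with $r \ge 0.5$ and $n \ge 50$ are recovered at ≥ 99%,
with $\hat r$ within 3 binomial SDs of truth.

# Determinism

Every stochastic entry point takes a seed; internal streams derive child
seeds (kept below $2^{31}$) per sample type, replicate and analysis so
that adding a step never perturbs another's stream, and seeded sections
restore the caller's RNG state. Two pipeline runs with the same seed are
byte-identical, which the acceptance suite checks by hashing every output
file.

# Known limitations

* The fallback folding engine maximizes pairing; thermodynamic MEA at
  $\gamma = 0.1$ pairs far fewer bases. Absolute attrition of the
  structure filter is engine-dependent; only the planted-control
  guarantees are engine-independent.
* BH is applied per replicate; a pooled-across-replicates FDR would be
  slightly more conservative at consensus level.
* Multi-mapping sites contribute to downstream backgrounds through a
  single chosen transcript; transcript-level multiplicity is not modeled.
* The simulator plants sites independently; clustering of methylation
  along transcripts (sites/gene structure in real data) is not emulated.
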