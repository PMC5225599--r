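# Seeded generator of a small annotated transcriptome with known m5C ground
# truth: the stand-in for a real bisulfite-sequencing experiment.
#
# The stated world: ~30 genes with 5'UTR/CDS/3'UTR and introns on one
# chromosome, three biological replicates for each of two sample types,
# bisulfite non-conversion error around 0.5% (conversion >99%), coverage
# ~50x on exons, wholly unmethylated spike-in transcripts, planted
# C:G-stem/UUCG-loop hairpins and G-free "spacer" contexts for the
# structure filter, and planted miRNA/RBP/m6A feature tracks.

#' Simulation configuration
#'
#' Defaults describe the regime the pipeline is designed for: conversion
#' error `conversion_error = 0.005` (conversion rate >99%), mean exon
#' coverage 50, three replicates, methylation levels drawn uniformly from
#' \[0.2, 1\], and two sample types whose planted truth sets share
#' `truth_overlap` of their sites.
#'
#' @param seed integer; fully determines all generator output
#' @param n_genes number of genes (one transcript per gene)
#' @param utr5_mean,cds_mean,utr3_mean mean segment lengths (nt)
#' @param intron_mean mean intron length (nt)
#' @param introns_per_gene Poisson mean of introns per gene
#' @param coverage_mean mean exonic read depth per position
#' @param coverage_dispersion negative-binomial size parameter of depth
#' @param intron_coverage_frac intronic depth as a fraction of exonic depth
#' @param conversion_error probability an unmethylated C reads as C
#' @param inappropriate_conversion probability a methylated C reads as T
#' @param meth_fraction named fractions of cytosines planted methylated per
#'   segment (`utr5`, `cds`, `utr3`, `intron`)
#' @param meth_fraction_aug additional fraction of cytosines within +/-25
#'   nt of the AUG planted methylated (0 = no start-codon bias)
#' @param meth_level_range range of planted methylation levels r
#' @param n_replicates biological replicates per sample type
#' @param read_length read length (nt), used for read-level simulation and
#'   expression count scaling
#' @param base_quality_mean mean phred base quality
#' @param hairpin_fraction fraction of genes carrying a planted hairpin
#'   (6-bp C:G stem, UUCG tetraloop) plus a G-free spacer context
#' @param m6a_per_transcript Poisson mean of planted HGGACNN motifs per
#'   transcript
#' @param spike_lengths lengths of the unmethylated spike-in transcripts
#' @param spike_coverage mean depth on spike-in positions
#' @param sample_types names of the two sample types
#' @param truth_overlap fraction of sample-type A truth sites shared by B
#' @param silence_prob probability a gene is (nearly) silent in a given
#'   sample type
#' @param gc_content GC content of random sequence
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 30L,
                       utr5_mean = 200, cds_mean = 1000, utr3_mean = 800,
                       intron_mean = 300, introns_per_gene = 1.5,
                       coverage_mean = 50, coverage_dispersion = 8,
                       intron_coverage_frac = 0.2,
                       conversion_error = 0.005,
                       inappropriate_conversion = 0,
                       meth_fraction = c(utr5 = 0.03, cds = 0.01,
                                         utr3 = 0.015, intron = 0.005),
                       meth_fraction_aug = 0,
                       meth_level_range = c(0.2, 1.0),
                       n_replicates = 3L,
                       read_length = 100L,
                       base_quality_mean = 38,
                       hairpin_fraction = 0.2,
                       m6a_per_transcript = 1.0,
                       spike_lengths = c(552L, 2000L),
                       spike_coverage = 50,
                       sample_types = c("ESC", "brain"),
                       truth_overlap = 0.3,
                       silence_prob = 0.1,
                       gc_content = 0.5) {
  if (min(utr5_mean, cds_mean, utr3_mean) < 10)
    stopf("segment mean lengths must be >= 10 nt")
  stopifnot(conversion_error >= 0, conversion_error <= 1,
            inappropriate_conversion >= 0, inappropriate_conversion <= 1,
            truth_overlap >= 0, truth_overlap <= 1,
            length(sample_types) == 2)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

HAIRPIN_SEQ <- c(strsplit("CCCCCCTTCGGGGGGG", "")[[1]])[1:16] # 6 C, UUCG, 6 G
HAIRPIN_FLANK <- 150L  # A-only buffer so the stem is the only partner set
SPACER_LEN <- 301L   # G-free on both sides of the central C within 150 nt

#' Generate a synthetic transcriptome with planted ground truth
#'
#' Builds gene loci (with introns) along one chromosome, plants HGGACNN
#' m6A motifs in coding sequence, hairpin + spacer structure controls in a
#' fraction of 3'UTRs, unmethylated spike-in transcripts, per-sample-type
#' gene expression factors, and per-sample-type methylation truth sets:
#' all hairpin-stem and spacer Cs at level 1, plus segment-stratified
#' random Cs at levels drawn from `meth_level_range`.
#'
#' @param config a [sim_config()]
#' @return object of class `bs_simulation`: list with `genome`
#'   (named character vector of chromosome/spike sequences), `models`
#'   (a [transcript_db()]), `truth` (data.frame of planted sites with
#'   genomic coordinates, segment, level, element flag, and one logical
#'   `in_<type>` column per sample type), `hairpins`, `spacers`,
#'   `m6a_sites` (transcript-coordinate tables), `expression`
#'   (gene x sample-type relative expression), `intron_ranges`, `config`
#' @export
generate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_transcriptome_impl(config))
}

generate_transcriptome_impl <- function(config) {
  n <- config$n_genes
  gap <- 300L
  chrom <- "chrT"
  cursor <- gap
  genome_parts <- list(rand_seq(gap, config$gc_content))
  models <- vector("list", n)
  tx_seqs <- character(n)
  hairpins <- list(); spacers <- list(); m6a <- list()
  intron_ranges <- list()
  has_hairpin <- runif(n) < config$hairpin_fraction

  for (i in seq_len(n)) {
    gid <- sprintf("gene%03d", i)
    tid <- sprintf("tx%03d", i)
    strand <- sample(c("+", "-"), 1)
    u5 <- max(20L, rpois(1, config$utr5_mean))
    cds <- 3L * max(40L, round(rpois(1, config$cds_mean) / 3))
    u3 <- max(40L, rpois(1, config$utr3_mean))
    if (has_hairpin[i])
      u3 <- max(u3, 2L * HAIRPIN_FLANK + 16L + 20L + SPACER_LEN + 40L)
    tx <- c(rand_seq(u5, config$gc_content),
            c("A", "T", "G"),
            rand_seq(cds - 6L, config$gc_content),
            c("T", "G", "A"),
            rand_seq(u3, config$gc_content))
    tlen <- length(tx)

    # plant m6A motifs (HGGACNN; DNA alphabet, H = A/C/T) inside the CDS
    k6 <- rpois(1, config$m6a_per_transcript)
    if (k6 > 0) {
      lo <- u5 + 4L; hi <- u5 + cds - 12L
      if (hi - lo > 20L) {
        pos <- sort(sample(seq(lo, hi, by = 10L), min(k6, 3L)))
        for (p in pos) {
          tx[(p + 1):(p + 7)] <- c(sample(c("A", "C", "T"), 1), "G", "G",
                                   "A", "C", sample(c("A", "C", "G", "T"), 2,
                                                    replace = TRUE))
          m6a[[length(m6a) + 1L]] <- data.frame(
            transcript_id = tid, tpos = p + 3L, stringsAsFactors = FALSE)
        }
      }
    }

    # hairpin + spacer structure controls in the 3'UTR. The hairpin sits
    # inside A-only buffers spanning the pair-distance cap, so that within
    # reach of the stem the stem partners are the only pairing option: a
    # planted hairpin is an isolated hairpin, as for a synthesized oligo.
    if (has_hairpin[i]) {
      el0 <- u5 + cds + 10L
      tx[(el0 + 1):(el0 + HAIRPIN_FLANK)] <- "A"
      hp0 <- el0 + HAIRPIN_FLANK                  # 0-based tpos of stem5 start
      tx[(hp0 + 1):(hp0 + 16)] <- HAIRPIN_SEQ
      tx[(hp0 + 17):(hp0 + 16L + HAIRPIN_FLANK)] <- "A"
      sp0 <- hp0 + 16L + HAIRPIN_FLANK + 20L
      spacer <- rep("A", SPACER_LEN)
      spacer[(SPACER_LEN + 1L) %/% 2L] <- "C"     # lone candidate C, G-free
      tx[(sp0 + 1):(sp0 + SPACER_LEN)] <- spacer
      hairpins[[length(hairpins) + 1L]] <- data.frame(
        transcript_id = tid,
        stem5_start = hp0, stem5_end = hp0 + 6L,
        loop_start = hp0 + 6L, loop_end = hp0 + 10L,
        stem3_start = hp0 + 10L, stem3_end = hp0 + 16L,
        stringsAsFactors = FALSE)
      spacers[[length(spacers) + 1L]] <- data.frame(
        transcript_id = tid, tpos = sp0 + (SPACER_LEN - 1L) %/% 2L,
        stringsAsFactors = FALSE)
    }
    tx_seqs[i] <- paste(tx, collapse = "")

    # insert introns -> pre-mRNA, then place the locus on the genome
    n_int <- rpois(1, config$introns_per_gene)
    splits <- sort(sample(seq(50L, tlen - 50L), n_int))
    splits <- splits[!duplicated(splits)]
    pre <- character(0)
    exon_pre <- matrix(integer(0), ncol = 2)      # exon intervals, pre coords
    intron_pre <- matrix(integer(0), ncol = 2)
    last <- 0L; pre_len <- 0L
    for (s in c(splits, tlen)) {
      exon_pre <- rbind(exon_pre, c(pre_len, pre_len + (s - last)))
      pre <- c(pre, tx[(last + 1):s])
      pre_len <- pre_len + (s - last)
      if (s < tlen) {
        ilen <- max(60L, rpois(1, config$intron_mean))
        intron_pre <- rbind(intron_pre, c(pre_len, pre_len + ilen))
        pre <- c(pre, rand_seq(ilen, config$gc_content))
        pre_len <- pre_len + ilen
      }
      last <- s
    }
    pre_str <- paste(pre, collapse = "")
    locus <- if (strand == "-") revcomp_chr(pre_str) else pre_str

    to_genomic <- function(iv) {
      if (strand == "+") cursor + iv
      else cbind(cursor + pre_len - iv[, 2], cursor + pre_len - iv[, 1])
    }
    exons_g <- to_genomic(exon_pre)
    models[[i]] <- transcript_model(tid, gid, chrom, strand, exons_g)
    if (nrow(intron_pre)) {
      ig <- to_genomic(intron_pre)
      intron_ranges[[length(intron_ranges) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid, chrom = chrom,
        start = ig[, 1], end = ig[, 2], strand = strand,
        stringsAsFactors = FALSE)
    }
    # CDS genomic bounds from transcript coordinates
    cg <- transcript_to_genomic(models[[i]], c(u5, u5 + cds - 1L))
    models[[i]] <- transcript_model(tid, gid, chrom, strand, exons_g,
                                    cds_start = min(cg), cds_end = max(cg) + 1L)
    genome_parts[[length(genome_parts) + 1L]] <- strsplit(locus, "")[[1]]
    genome_parts[[length(genome_parts) + 1L]] <- rand_seq(gap,
                                                          config$gc_content)
    cursor <- cursor + pre_len + gap
  }

  genome <- c(setNames(paste(unlist(genome_parts), collapse = ""), chrom),
              setNames(vapply(seq_along(config$spike_lengths), function(j)
                paste(rand_seq(config$spike_lengths[j], config$gc_content),
                      collapse = ""), ""),
                paste0("spike", seq_along(config$spike_lengths))))

  db <- transcript_db(models)
  names(tx_seqs) <- names(db)
  hairpins <- if (length(hairpins)) do.call(rbind, hairpins) else
    data.frame(transcript_id = character(0))
  spacers <- if (length(spacers)) do.call(rbind, spacers) else
    data.frame(transcript_id = character(0), tpos = integer(0))
  m6a <- if (length(m6a)) do.call(rbind, m6a) else
    data.frame(transcript_id = character(0), tpos = integer(0))
  intron_ranges <- if (length(intron_ranges)) do.call(rbind, intron_ranges)
    else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    gene_id = character(0), transcript_id = character(0))

  expression <- expand.grid(gene_id = vapply(models, `[[`, "", "gene_id"),
                            sample_type = config$sample_types,
                            stringsAsFactors = FALSE)
  expression$rel_expr <- rlnorm(nrow(expression), 0, 0.4)
  silent <- runif(nrow(expression)) < config$silence_prob
  expression$rel_expr[silent] <- expression$rel_expr[silent] * 0.002

  sim <- structure(
    list(genome = genome, models = db, transcript_seqs = tx_seqs,
         truth = NULL, hairpins = hairpins, spacers = spacers,
         m6a_sites = m6a, expression = expression,
         intron_ranges = intron_ranges, config = config),
    class = "bs_simulation")
  sim$truth <- plant_methylation(sim, config)
  sim
}

# Enumerate all cytosines of the simulation on the transcript strand:
# exonic Cs via transcript sequences, intronic Cs via the genome.
enumerate_cytosines <- function(sim) {
  out <- list()
  for (tid in names(sim$models)) {
    m <- sim$models[[tid]]
    chars <- strsplit(sim$transcript_seqs[[tid]], "")[[1]]
    tpos <- which(chars == "C") - 1L
    if (length(tpos)) {
      seg <- segment_of_tpos(m, tpos)
      out[[length(out) + 1L]] <- data.frame(
        chrom = m$chrom, pos = transcript_to_genomic(m, tpos),
        strand = m$strand, transcript_id = tid, tpos = tpos,
        segment = seg, stringsAsFactors = FALSE)
    }
  }
  gchars <- strsplit(sim$genome[["chrT"]], "")[[1]]
  ir <- sim$intron_ranges
  for (j in seq_len(nrow(ir))) {
    span <- seq(ir$start[j], ir$end[j] - 1L)
    base_wanted <- if (ir$strand[j] == "+") "C" else "G"
    pos <- span[gchars[span + 1L] == base_wanted]
    if (length(pos))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ir$chrom[j], pos = pos, strand = ir$strand[j],
        transcript_id = ir$transcript_id[j], tpos = NA_integer_,
        segment = "intron", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

segment_of_tpos <- function(model, tpos) {
  if (is.null(model$segments)) return(rep("noncoding", length(tpos)))
  s <- model$segments
  ifelse(tpos < s$utr5[2], "utr5",
         ifelse(tpos < s$cds[2], "cds", "utr3"))
}

plant_methylation <- function(sim, config) {
  cs <- enumerate_cytosines(sim)
  cs$element <- "none"
  # structure controls: all hairpin stem Cs and the spacer C, level 1
  for (j in seq_len(nrow(sim$hairpins))) {
    h <- sim$hairpins[j, ]
    stem <- seq(h$stem5_start, h$stem5_end - 1L)
    sel <- cs$transcript_id == h$transcript_id & cs$tpos %in% stem
    cs$element[sel] <- "hairpin_stem"
  }
  for (j in seq_len(nrow(sim$spacers))) {
    sel <- cs$transcript_id == sim$spacers$transcript_id[j] &
      !is.na(cs$tpos) & cs$tpos == sim$spacers$tpos[j]
    cs$element[sel] <- "spacer"
  }
  ctrl <- cs[cs$element != "none", , drop = FALSE]
  free <- cs[cs$element == "none", , drop = FALSE]

  aug_of <- vapply(sim$models, function(m)
    if (is.null(m$segments)) NA_integer_ else m$segments$cds[1], 0L)
  in_aug <- !is.na(free$tpos) &
    abs(free$tpos - aug_of[free$transcript_id]) <= 25L
  in_aug[is.na(in_aug)] <- FALSE
  pick <- function() {
    sel <- logical(nrow(free))
    for (seg in names(config$meth_fraction)) {
      idx <- which(free$segment == seg)
      k <- round(config$meth_fraction[[seg]] * length(idx))
      if (k > 0) sel[sample(idx, k)] <- TRUE
    }
    if (config$meth_fraction_aug > 0) {
      idx <- which(in_aug)
      k <- round(config$meth_fraction_aug * length(idx))
      if (k > 0) sel[sample(idx, k)] <- TRUE
    }
    sel
  }
  sel_a <- pick()
  # sample type B keeps `truth_overlap` of A's sites and replaces the rest
  idx_a <- which(sel_a)
  keep <- if (length(idx_a)) sample(idx_a, round(config$truth_overlap *
                                                   length(idx_a))) else integer(0)
  sel_b <- logical(nrow(free))
  sel_b[keep] <- TRUE
  fresh_pool <- which(!sel_a)
  n_fresh <- length(idx_a) - length(keep)
  if (n_fresh > 0 && length(fresh_pool))
    sel_b[sample(fresh_pool, min(n_fresh, length(fresh_pool)))] <- TRUE

  truth <- rbind(
    cbind(ctrl, level = rep(1, nrow(ctrl)),
          in_a = rep(TRUE, nrow(ctrl)), in_b = rep(TRUE, nrow(ctrl))),
    cbind(free[sel_a | sel_b, , drop = FALSE],
          level = runif(sum(sel_a | sel_b), config$meth_level_range[1],
                        config$meth_level_range[2]),
          in_a = sel_a[sel_a | sel_b], in_b = sel_b[sel_a | sel_b]))
  names(truth)[names(truth) == "in_a"] <- paste0("in_", config$sample_types[1])
  names(truth)[names(truth) == "in_b"] <- paste0("in_", config$sample_types[2])
  rownames(truth) <- NULL
  truth
}

#' Simulate per-cytosine bisulfite pileups for one replicate
#'
#' At every cytosine the non-converted count is
#' k ~ Binomial(n, r(1 - delta) + (1 - r) epsilon) where r is the planted
#' level (0 for unmethylated Cs and all spike-in Cs), epsilon the
#' conversion error and delta the inappropriate-conversion rate. Coverage
#' n is negative-binomial around the gene's expression-scaled mean. The
#' replicate index perturbs only the sampling, never the truth.
#'
#' @param sim a `bs_simulation`
#' @param sample_type one of `config$sample_types`
#' @param replicate replicate index (1-based)
#' @return list with `main` and `spike` pileup data.frames, columns
#'   `chrom`, `pos` (0-based), `strand`, `n`, `k`
#' @export
simulate_pileups <- function(sim, sample_type, replicate) {
  config <- sim$config
  ti <- match(sample_type, config$sample_types)
  if (is.na(ti)) stopf("unknown sample type '%s'", sample_type)
  seed <- child_seed(config$seed, 100L * ti + replicate)
  with_seed(seed, {
    cs <- enumerate_cytosines(sim)
    truth <- sim$truth
    key <- site_key(cs$chrom, cs$pos, cs$strand)
    tkey <- site_key(truth$chrom, truth$pos, truth$strand)
    on_flag <- truth[[paste0("in_", sample_type)]]
    lvl <- setNames(ifelse(on_flag, truth$level, 0), tkey)
    r <- unname(lvl[key]); r[is.na(r)] <- 0

    expr <- sim$expression
    fac <- setNames(expr$rel_expr[expr$sample_type == sample_type],
                    expr$gene_id[expr$sample_type == sample_type])
    gene_of <- vapply(sim$models, `[[`, "", "gene_id")
    mu <- config$coverage_mean * unname(fac[gene_of[cs$transcript_id]])
    mu[cs$segment == "intron"] <- mu[cs$segment == "intron"] *
      config$intron_coverage_frac
    n <- rnbinom(length(mu), mu = mu, size = config$coverage_dispersion)
    p <- r * (1 - config$inappropriate_conversion) +
      (1 - r) * config$conversion_error
    k <- rbinom(length(n), n, p)
    main <- data.frame(chrom = cs$chrom, pos = cs$pos, strand = cs$strand,
                       n = n, k = k, stringsAsFactors = FALSE)

    spikes <- sim$genome[startsWith(names(sim$genome), "spike")]
    sp <- do.call(rbind, lapply(names(spikes), function(nm) {
      pos <- which(strsplit(spikes[[nm]], "")[[1]] == "C") - 1L
      data.frame(chrom = nm, pos = pos, strand = "+",
                 stringsAsFactors = FALSE)
    }))
    sp$n <- rnbinom(nrow(sp), mu = config$spike_coverage,
                    size = config$coverage_dispersion)
    sp$k <- rbinom(nrow(sp), sp$n, config$conversion_error)
    list(main = main, spike = sp)
  })
}

#' Simulate exon read counts per gene for expression estimation
#'
#' Counts scale with the same per-gene expression factors that drive pileup
#' coverage, so a gene silent in one sample type is silent in both views.
#'
#' @param sim a `bs_simulation`
#' @param sample_type sample type name
#' @return integer matrix genes x replicates of exon read counts
#' @export
simulate_expression_counts <- function(sim, sample_type) {
  config <- sim$config
  ti <- match(sample_type, config$sample_types)
  if (is.na(ti)) stopf("unknown sample type '%s'", sample_type)
  expr <- sim$expression
  fac <- setNames(expr$rel_expr[expr$sample_type == sample_type],
                  expr$gene_id[expr$sample_type == sample_type])
  genes <- vapply(sim$models, `[[`, "", "gene_id")
  tlen <- vapply(sim$models, `[[`, 0L, "transcript_length")
  mu <- config$coverage_mean * unname(fac[genes]) * tlen /
    config$read_length
  with_seed(child_seed(config$seed, 900L + ti), {
    # per-replicate library-size factor emulates sequencing-depth variation
    depth <- exp(rnorm(config$n_replicates, 0, 0.15))
    counts <- sapply(seq_len(config$n_replicates), function(rep)
      rnbinom(length(mu), mu = mu * depth[rep],
              size = config$coverage_dispersion))
    rownames(counts) <- unname(genes)
    colnames(counts) <- paste0(sample_type, "_rep", 1:config$n_replicates)
    counts
  })
}

# Map a transcript-coordinate interval to a genomic interval; NULL when it
# spans an exon junction (the genomic image is not contiguous).
tinterval_to_genomic <- function(model, t_start, t_end) {
  g <- transcript_to_genomic(model, seq(t_start, t_end - 1L))
  if (anyNA(g)) return(NULL)
  rg <- range(g)
  if (rg[2] - rg[1] != t_end - t_start - 1L) return(NULL)
  c(rg[1], rg[2] + 1L)
}

#' Generate planted feature tracks
#'
#' Builds miRNA target sites (22-nt windows in 3'UTRs with mirSVR scores),
#' RBP binding sites for several factors, and m6A peak intervals around the
#' planted HGGACNN motifs. The miRNA track supports three modes with known
#' effect direction for overlap testing: `"null"` (windows placed uniformly
#' in 3'UTRs, ignoring methylation), `"include"` (windows centred on planted
#' 3'UTR m5C sites) and `"exclude"` (windows placed only where they contain
#' no planted site).
#'
#' @param sim a `bs_simulation`
#' @param mirna_mode overlap mode of the miRNA track (see above)
#' @param sample_type sample type whose truth defines include/exclude
#' @param n_rbp_factors number of RBP factors
#' @return named list of [feature_track()]s: `mirna_targets`, one
#'   `rbp_<factor>` per factor, and `m6a_peaks`
#' @export
generate_feature_tracks <- function(sim,
                                    mirna_mode = c("null", "include",
                                                   "exclude"),
                                    sample_type = sim$config$sample_types[1],
                                    n_rbp_factors = 4L) {
  mirna_mode <- match.arg(mirna_mode)
  config <- sim$config
  with_seed(child_seed(config$seed, 7000L + match(mirna_mode,
                                                  c("null", "include",
                                                    "exclude"))), {
    truth <- sim$truth
    truth <- truth[truth[[paste0("in_", sample_type)]], , drop = FALSE]
    tkeys <- site_key(truth$chrom, truth$pos, truth$strand)

    mk_window <- function(m, t0, len) {
      t0 <- max(0L, min(t0, m$transcript_length - len))
      tinterval_to_genomic(m, t0, t0 + len)
    }

    mir <- list()
    for (tid in names(sim$models)) {
      m <- sim$models[[tid]]
      if (is.null(m$segments)) next
      u3 <- m$segments$utr3
      if (u3[2] - u3[1] < 30L) next
      n_sites <- 1L + rpois(1, 1)
      placed <- 0L; tries <- 0L
      while (placed < n_sites && tries < 30L) {
        tries <- tries + 1L
        if (mirna_mode == "include") {
          cand <- truth[truth$transcript_id == tid & !is.na(truth$tpos) &
                          truth$segment == "utr3" &
                          truth$element == "none", , drop = FALSE]
          if (!nrow(cand)) break
          t0 <- cand$tpos[sample.int(nrow(cand), 1)] - 10L
        } else {
          t0 <- sample(seq(u3[1], u3[2] - 22L), 1)
        }
        g <- mk_window(m, t0, 22L)
        if (is.null(g)) next
        span <- seq(g[1], g[2] - 1L)
        hits <- sum(tkeys %in% site_key(m$chrom, span, m$strand))
        if (mirna_mode == "exclude" && hits > 0) next
        if (mirna_mode == "include" && hits == 0) next
        mir[[length(mir) + 1L]] <- data.frame(
          chrom = m$chrom, start = g[1], end = g[2],
          name = sprintf("mir_%s_%d", tid, placed + 1L),
          score = runif(1, -2, 0.3), strand = m$strand,
          stringsAsFactors = FALSE)
        placed <- placed + 1L
      }
    }
    mirna <- feature_track("mirna_targets",
                           if (length(mir)) do.call(rbind, mir) else
                             data.frame(chrom = character(0),
                                        start = integer(0),
                                        end = integer(0)))

    rbp_names <- paste0("RBP", LETTERS[seq_len(n_rbp_factors)])
    rbp <- lapply(rbp_names, function(fac) {
      iv <- list()
      for (tid in sample(names(sim$models), max(3L,
                                                length(sim$models) %/% 2L))) {
        m <- sim$models[[tid]]
        len <- sample(30:80, 1)
        t0 <- sample(seq(0L, max(1L, m$transcript_length - len)), 1)
        g <- mk_window(m, t0, len)
        if (is.null(g)) next
        iv[[length(iv) + 1L]] <- data.frame(
          chrom = m$chrom, start = g[1], end = g[2],
          name = fac, score = 0, strand = m$strand,
          stringsAsFactors = FALSE)
      }
      feature_track(fac, if (length(iv)) do.call(rbind, iv) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0)))
    })
    names(rbp) <- paste0("rbp_", rbp_names)

    m6 <- list()
    for (j in seq_len(nrow(sim$m6a_sites))) {
      tid <- sim$m6a_sites$transcript_id[j]
      m <- sim$models[[tid]]
      g <- mk_window(m, sim$m6a_sites$tpos[j] - 50L, 100L)
      if (is.null(g)) next
      m6[[length(m6) + 1L]] <- data.frame(
        chrom = m$chrom, start = g[1], end = g[2],
        name = sprintf("m6a_%s_%d", tid, j), score = 0, strand = m$strand,
        stringsAsFactors = FALSE)
    }
    m6a <- feature_track("m6a_peaks", if (length(m6)) do.call(rbind, m6)
                         else data.frame(chrom = character(0),
                                         start = integer(0),
                                         end = integer(0)))
    c(list(mirna_targets = mirna), rbp, list(m6a_peaks = m6a))
  })
}

#' Simulate positioned bisulfite reads over one transcript
#'
#' Read-level layer used to exercise [pileup_from_reads()]: reads carry
#' per-base qualities and an orientation, and the first `mbias_len` bases
#' of forward reads show inflated non-conversion (the m-bias artifact that
#' 5' trimming removes).
#'
#' @param seq transcript sequence (character scalar, DNA alphabet)
#' @param rates numeric vector of per-position methylation levels (length
#'   `nchar(seq)`, 0 for unmethylated positions)
#' @param n_reads number of reads
#' @param read_length read length
#' @param conversion_error epsilon
#' @param mbias_len,mbias_rate length and extra non-conversion rate of the
#'   5' m-bias window on forward reads
#' @param quality_mean,quality_sd phred quality model
#' @param seed RNG seed
#' @return data.frame with columns `target`, `start` (0-based leftmost),
#'   `orientation` ("fwd"/"rev"), `seq`, `qual` (phred+33)
#' @export
simulate_reads <- function(seq, rates, n_reads = 200L, read_length = 50L,
                           conversion_error = 0.005,
                           mbias_len = 10L, mbias_rate = 0.3,
                           quality_mean = 38, quality_sd = 2, seed = 1L) {
  L <- nchar(seq)
  stopifnot(length(rates) == L, read_length <= L)
  chars <- strsplit(seq, "")[[1]]
  with_seed(seed, {
    starts <- sample(0:(L - read_length), n_reads, replace = TRUE)
    orient <- sample(c("fwd", "rev"), n_reads, replace = TRUE)
    out <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      idx <- starts[i] + seq_len(read_length)        # 1-based genome index
      base <- chars[idx]
      offset5 <- if (orient[i] == "fwd") seq_len(read_length) - 1L else
        rev(seq_len(read_length) - 1L)
      isC <- base == "C"
      p <- rates[idx] * 1 + (1 - rates[idx]) * conversion_error
      p[orient[i] == "fwd" & offset5 < mbias_len & isC] <-
        pmax(p[orient[i] == "fwd" & offset5 < mbias_len & isC], mbias_rate)
      conv <- isC & runif(read_length) >= p
      base[conv] <- "T"
      q <- pmin(41L, pmax(2L, round(rnorm(read_length, quality_mean,
                                          quality_sd))))
      out[[i]] <- data.frame(
        target = "tx", start = starts[i], orientation = orient[i],
        seq = paste(base, collapse = ""),
        qual = intToUtf8(q + 33L), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Write a simulation to disk
#'
#' Writes the genome FASTA, a GTF annotation, the ground-truth site TSV,
#' planted-element tables, and a JSON manifest.
#'
#' @param sim a `bs_simulation`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dna <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(dna, file.path(dir, "genome.fa"))
  writeLines(gtf_lines(sim$models), file.path(dir, "annotation.gtf"))
  write_sites(sim$truth, tsv_path = file.path(dir, "truth_sites.tsv"))
  write.table(sim$expression, file.path(dir, "expression_factors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(package = "bsm5c", seed = sim$config$seed,
                   n_genes = sim$config$n_genes,
                   sample_types = sim$config$sample_types,
                   files = c("genome.fa", "annotation.gtf",
                             "truth_sites.tsv", "expression_factors.tsv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

gtf_lines <- function(db) {
  unlist(lapply(db, function(m) {
    ex <- sprintf(
      "%s\tbsm5c\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      m$chrom, m$exons[, 1] + 1L, m$exons[, 2], m$strand, m$gene_id,
      m$transcript_id)
    if (is.na(m$cds_start)) return(ex)
    cs <- pmax(m$exons[, 1], m$cds_start)
    ce <- pmin(m$exons[, 2], m$cds_end)
    keep <- ce > cs
    cds <- sprintf(
      "%s\tbsm5c\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"%s\"; transcript_id \"%s\";",
      m$chrom, cs[keep] + 1L, ce[keep], m$strand, m$gene_id, m$transcript_id)
    c(ex, cds)
  }), use.names = FALSE)
}
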