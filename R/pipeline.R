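# End-to-end pipeline on simulated data, plus the command-line interface.

#' Write / read a pileup TSV
#'
#' Columns: `chrom`, `pos` (0-based), `strand`, `n`, `k`.
#' @param pileup pileup data.frame
#' @param path file path
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup[, c("chrom", "pos", "strand", "n", "k")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Run the full pipeline on simulated data
#'
#' Simulates a transcriptome for two sample types with three replicates
#' each, calls m5C candidates per replicate against the spike-in-estimated
#' conversion error, forms replicate consensus, applies the secondary
#' structure filter, classifies sites as unique/common with the four-way
#' decomposition, computes meta-gene profiles and segment enrichment, and
#' runs the overlap analyses. All outputs are plain-text tables under
#' `outdir`; the run is fully determined by `seed`.
#'
#' @param seed integer master seed
#' @param outdir output directory
#' @param config optional [sim_config()]; its seed is overridden by `seed`
#' @param iterations permutation iterations (default 10000)
#' @param engine structure-filter engine (default "maxpair")
#' @return invisibly, a list of the main result objects
#' @export
run_pipeline <- function(seed, outdir, config = NULL, iterations = 10000L,
                         engine = "maxpair") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config)) config <- sim_config(seed = seed)
  else { config$seed <- as.integer(seed) }
  types <- config$sample_types

  sim <- generate_transcriptome(config)
  write_simulation(sim, file.path(outdir, "sim"))

  # -- calling ------------------------------------------------------------
  calls <- list(); consensus <- list(); pileups <- list(); eps <- list()
  for (ty in types) {
    calls[[ty]] <- list(); pileups[[ty]] <- list()
    for (r in seq_len(config$n_replicates)) {
      pu <- simulate_pileups(sim, ty, r)
      est <- estimate_conversion_error(pu$spike)
      cl <- call_candidates(pu$main, est)
      pileups[[ty]][[r]] <- pu$main
      calls[[ty]][[r]] <- cl
      eps[[paste0(ty, r)]] <- est$epsilon
      write_sites(cl[cl$pass, c("chrom", "pos", "strand", "n", "k",
                                "rate", "p_value", "q_value")],
                  tsv_path = file.path(outdir,
                                       sprintf("calls_%s_rep%d.tsv", ty, r)))
    }
    consensus[[ty]] <- replicate_consensus(calls[[ty]],
                                           config$n_replicates)
  }

  # -- structure filter ---------------------------------------------------
  filtered <- list()
  for (ty in types) {
    ann <- annotate_structure(consensus[[ty]], sim$models, sim$genome,
                              fold_config(), engine)
    fl <- filter_paired_candidates(consensus[[ty]], ann)
    filtered[[ty]] <- fl$retained
    write_sites(fl$retained[, c("chrom", "pos", "strand", "mean_coverage",
                                "mean_rate")],
                bed_path = file.path(outdir, sprintf("m5c_%s.bed", ty)),
                tsv_path = file.path(outdir, sprintf("m5c_%s.tsv", ty)))
    dl <- fl$discarded[, c("chrom", "pos", "strand", "engine",
                           "dot_bracket_excerpt")]
    write.table(dl, file.path(outdir,
                              sprintf("structure_discards_%s.tsv", ty)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- expression ---------------------------------------------------------
  cnt <- do.call(cbind, lapply(types, function(ty)
    simulate_expression_counts(sim, ty)))
  groups <- rep(types, each = config$n_replicates)
  expr <- estimate_expression(cnt, groups)
  write.table(data.frame(gene_id = rownames(expr$mean_normalized),
                         round(expr$mean_normalized, 4)),
              file.path(outdir, "expression_mean_normalized.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # -- comparison ---------------------------------------------------------
  gene_of_tx <- vapply(sim$models, `[[`, "", "gene_id")
  comparison <- list()
  for (i in 1:2) {
    a <- types[i]; b <- types[3 - i]
    cls <- classify_unique_common(filtered[[a]], calls[[b]], a, b)
    uniq <- cls[cls$status == paste0("unique_", a), , drop = FALSE]
    asn <- assign_segment(uniq, sim$models)
    uniq$gene_id <- unname(gene_of_tx[asn$transcript_id])
    dec <- decompose_unique_sites(uniq, pileups[[b]], expr,
                                  type_b = b)
    cls$label <- NA_character_
    cls$label[match(site_key(dec$chrom, dec$pos, dec$strand),
                    site_key(cls$chrom, cls$pos, cls$strand))] <- dec$label
    comparison[[a]] <- cls
    write.table(cls, file.path(outdir, sprintf("comparison_%s.tsv", a)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- positional ---------------------------------------------------------
  positional <- list()
  for (ty in types) {
    asn <- assign_segment(filtered[[ty]], sim$models)
    mrna <- asn[asn$feature %in% c("utr5", "cds", "utr3"), , drop = FALSE]
    res <- list(assignment = asn)
    if (nrow(mrna)) {
      prof <- metagene_profile(mrna, sim$models)
      rnd <- sample_random_cs(sim$models, sim$genome, nrow(mrna),
                              seed = child_seed(seed, 31L),
                              transcripts = unique(mrna$transcript_id))
      prof_rnd <- metagene_profile(rnd, sim$models)
      write.table(data.frame(bin = prof$bins$bin,
                             percent_m5c = round(prof$bins$percent, 4),
                             percent_random = round(prof_rnd$bins$percent,
                                                    4)),
                  file.path(outdir, sprintf("metagene_%s.tsv", ty)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      enr <- lapply(c("utr5", "cds", "utr3", "aug25"), function(rg)
        segment_enrichment(mrna, sim$models, sim$genome, rg))
      enr_df <- data.frame(
        region = vapply(enr, `[[`, "", "region"),
        p_value = vapply(enr, `[[`, 0, "p_value"),
        odds_ratio = vapply(enr, `[[`, 0, "odds_ratio"),
        ci_low = vapply(enr, function(e) e$ci95[1], 0),
        ci_high = vapply(enr, function(e) e$ci95[2], 0),
        n_m5C = vapply(enr, `[[`, 0L, "n_m5C"))
      write.table(format(enr_df, digits = 6, trim = TRUE),
                  file.path(outdir, sprintf("enrichment_%s.tsv", ty)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res$metagene <- prof; res$enrichment <- enr
    }
    positional[[ty]] <- res
  }

  # -- overlap ------------------------------------------------------------
  tracks <- generate_feature_tracks(sim)
  mirna <- prepare_mirna_track(tracks$mirna_targets)
  rbp <- prepare_rbp_sites(tracks[grep("^rbp_", names(tracks))])
  overlap_rows <- list()
  ty <- types[1]
  asn <- positional[[ty]]$assignment
  u3 <- asn[asn$feature == "utr3", , drop = FALSE]
  if (nrow(u3) >= 2) {
    bg3 <- transcript_cytosines(sim$models, sim$genome,
                                unique(u3$transcript_id))
    bg3 <- bg3[bg3$feature == "utr3", , drop = FALSE]
    bg3 <- add_genomic_coords(bg3, sim$models)
    pr <- overlap_permutation_test(u3, mirna, bg3, iterations,
                                   seed = child_seed(seed, 41L))
    overlap_rows[["mirna_targets"]] <- pr
  }
  expressed_genes <- rownames(expr$mean_normalized)[
    expr$mean_normalized[, ty] > expr$expressed_min]
  expr_tx <- names(gene_of_tx)[gene_of_tx %in% expressed_genes]
  if (length(expr_tx)) {
    bge <- add_genomic_coords(
      transcript_cytosines(sim$models, sim$genome, expr_tx), sim$models)
    m5c_ty <- filtered[[ty]]
    for (nm in names(rbp)) {
      in_tr <- sum(sites_in_track(m5c_ty, rbp[[nm]]))
      sub <- m5c_ty[seq_len(min(nrow(m5c_ty), max(in_tr, 1L) * 50L)), ,
                    drop = FALSE]
      if (nrow(sub) > nrow(bge)) next
      overlap_rows[[nm]] <- overlap_permutation_test(
        sub, rbp[[nm]], bge, iterations,
        seed = child_seed(seed, 43L + match(nm, names(rbp))))
    }
  }
  if (length(overlap_rows)) {
    od <- data.frame(
      track = vapply(overlap_rows, `[[`, "", "track"),
      observed = vapply(overlap_rows, `[[`, 0L, "observed"),
      null_mean = vapply(overlap_rows, `[[`, 0, "null_mean"),
      null_sd = vapply(overlap_rows, `[[`, 0, "null_sd"),
      z_score = vapply(overlap_rows, `[[`, 0, "z_score"),
      p_high = vapply(overlap_rows, `[[`, 0, "p_high"),
      p_low = vapply(overlap_rows, `[[`, 0, "p_low"),
      iterations = vapply(overlap_rows, `[[`, 0L, "iterations"))
    write.table(format(od, digits = 6, trim = TRUE),
                file.path(outdir, "overlap_permutation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- m6A comparison -----------------------------------------------------
  m6a_hits <- scan_m6a_motif(sim$transcript_seqs)
  dist_rows <- list()
  for (ty in types) {
    asn <- positional[[ty]]$assignment
    mrna <- asn[asn$feature %in% c("utr5", "cds", "utr3"), , drop = FALSE]
    for (anch in c("AUG", "STOP")) {
      d5 <- codon_proximal_distribution(mrna, sim$models, anch)
      d6 <- codon_proximal_distribution(
        data.frame(transcript_id = m6a_hits$transcript_id,
                   tpos = m6a_hits$pos), sim$models, anch)
      dist_rows[[paste(ty, anch)]] <- data.frame(
        sample_type = ty, anchor = anch, bin_start = d5$bin_start,
        percent_m5c = round(d5$percent, 4),
        percent_m6a = round(d6$percent, 4))
    }
  }
  dist <- do.call(rbind, dist_rows)
  write.table(dist, file.path(outdir, "codon_proximal.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = seed,
    epsilon = eps,
    n_consensus = lapply(consensus, nrow),
    n_filtered = lapply(filtered, nrow),
    n_m6a_motifs = nrow(m6a_hits))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, calls = calls, consensus = consensus,
                 filtered = filtered, expression = expr,
                 comparison = comparison, positional = positional,
                 overlap = overlap_rows, m6a_hits = m6a_hits,
                 codon_proximal = dist))
}

add_genomic_coords <- function(cs, models) {
  cs$chrom <- vapply(cs$transcript_id, function(t) models[[t]]$chrom, "")
  cs$strand <- vapply(cs$transcript_id, function(t) models[[t]]$strand, "")
  cs$pos <- NA_integer_
  for (tid in unique(cs$transcript_id)) {
    sel <- cs$transcript_id == tid
    cs$pos[sel] <- transcript_to_genomic(models[[tid]], cs$tpos[sel])
  }
  cs
}

# ---- CLI ------------------------------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

cli_need <- function(opts, key) {
  if (is.null(opts[[key]]))
    stopf("missing required option --%s", gsub("_", "-", key))
  opts[[key]]
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `call`, `filter-structure`, `compare`,
#' `metagene`, `overlap`, `m6a-compare`, `pipeline`. Run with no
#' arguments for usage. The `pipeline` subcommand runs everything on
#' simulated data: `bsm5c pipeline --seed 1 --out results/`.
#'
#' @param args character vector of command-line arguments
#' @return exit status, invisibly
#' @export
bsm5c_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bsm5c <subcommand> [options]",
    "  simulate         --seed N --out DIR [--n-genes N]",
    "  call             --pileup TSV --spikein TSV --out TSV",
    "                   [--min-cov 10] [--min-rate 0.2] [--max-fdr 0.01]",
    "  filter-structure --sites TSV --gtf GTF --fasta FA --out TSV",
    "                   [--engine maxpair|mea]",
    "  compare          --consensus TSV --other-calls TSV,TSV,TSV --out TSV",
    "  metagene         --sites TSV --gtf GTF --fasta FA --out TSV",
    "  overlap          --sites TSV --track BED --background TSV --out TSV",
    "                   [--iterations 10000] [--seed 1]",
    "  m6a-compare      --sites TSV --gtf GTF --fasta FA --out TSV",
    "  pipeline         --seed N --out DIR [--iterations 10000]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  switch(cmd,
    simulate = {
      cfg <- sim_config(seed = as.integer(cli_need(opts, "seed")))
      if (!is.null(opts$n_genes)) cfg$n_genes <- as.integer(opts$n_genes)
      sim <- generate_transcriptome(cfg)
      write_simulation(sim, cli_need(opts, "out"))
    },
    call = {
      pu <- read_pileup(cli_need(opts, "pileup"))
      sp <- read_pileup(cli_need(opts, "spikein"))
      est <- estimate_conversion_error(sp)
      cl <- call_candidates(
        pu, est,
        min_cov = as.integer(opts$min_cov %||% 10L),
        min_rate = as.numeric(opts$min_rate %||% 0.2),
        max_fdr = as.numeric(opts$max_fdr %||% 0.01))
      write_sites(cl[, c("chrom", "pos", "strand", "n", "k", "rate",
                         "p_value", "q_value", "pass")],
                  tsv_path = cli_need(opts, "out"))
    },
    `filter-structure` = {
      sites <- read_sites(cli_need(opts, "sites"))
      models <- read_annotation(cli_need(opts, "gtf"))
      genome <- read_genome(cli_need(opts, "fasta"))
      ann <- annotate_structure(sites, models, genome, fold_config(),
                                engine = opts$engine %||% "maxpair")
      fl <- filter_paired_candidates(sites, ann)
      write_sites(fl$retained, tsv_path = cli_need(opts, "out"))
    },
    compare = {
      cons <- read_sites(cli_need(opts, "consensus"))
      paths <- strsplit(cli_need(opts, "other_calls"), ",")[[1]]
      other <- lapply(paths, function(p) {
        x <- read_sites(p); x$pass <- TRUE; x })
      cls <- classify_unique_common(cons, other, "A", "B")
      write.table(cls, cli_need(opts, "out"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    metagene = {
      sites <- read_sites(cli_need(opts, "sites"))
      models <- read_annotation(cli_need(opts, "gtf"))
      asn <- assign_segment(sites, models)
      mrna <- asn[asn$feature %in% c("utr5", "cds", "utr3"), ,
                  drop = FALSE]
      prof <- metagene_profile(mrna, models)
      write.table(prof$bins, cli_need(opts, "out"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    },
    overlap = {
      sites <- read_sites(cli_need(opts, "sites"))
      track <- read_track(cli_need(opts, "track"))
      bg <- read_sites(cli_need(opts, "background"))
      pr <- overlap_permutation_test(
        sites, track, bg,
        iterations = as.integer(opts$iterations %||% 10000L),
        seed = as.integer(opts$seed %||% 1L))
      write.table(data.frame(track = pr$track, observed = pr$observed,
                             null_mean = pr$null_mean,
                             null_sd = pr$null_sd, z_score = pr$z_score,
                             p_high = pr$p_high, p_low = pr$p_low,
                             iterations = pr$iterations),
                  cli_need(opts, "out"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    `m6a-compare` = {
      sites <- read_sites(cli_need(opts, "sites"))
      models <- read_annotation(cli_need(opts, "gtf"))
      genome <- read_genome(cli_need(opts, "fasta"))
      seqs <- vapply(models, spliced_sequence, "", genome = genome)
      hits <- scan_m6a_motif(seqs)
      asn <- assign_segment(sites, models)
      mrna <- asn[asn$feature %in% c("utr5", "cds", "utr3"), ,
                  drop = FALSE]
      rows <- list()
      for (anch in c("AUG", "STOP")) {
        d5 <- codon_proximal_distribution(mrna, models, anch)
        d6 <- codon_proximal_distribution(
          data.frame(transcript_id = hits$transcript_id,
                     tpos = hits$pos), models, anch)
        rows[[anch]] <- data.frame(anchor = anch,
                                   bin_start = d5$bin_start,
                                   percent_m5c = d5$percent,
                                   percent_m6a = d6$percent)
      }
      write.table(do.call(rbind, rows), cli_need(opts, "out"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    },
    pipeline = {
      run_pipeline(as.integer(cli_need(opts, "seed")),
                   cli_need(opts, "out"),
                   iterations = as.integer(opts$iterations %||% 10000L))
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path
#' @return named character vector of sequences
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
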