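# Secondary-structure filter: candidates predicted to be base-paired in the
# folded structure of their containing transcript (or a 300-nt genomic
# window for intronic/non-annotated sites) are discarded, because bisulfite
# conversion requires single-stranded cytosines and a structured C mimics
# methylation.

#' Folding configuration
#'
#' `temperature` and `gamma` parameterize the thermodynamic
#' maximum-expected-accuracy (MEA) engine (70 degrees C, the bisulfite
#' reaction temperature, and gamma = 0.1 which weights pairs
#' conservatively); the fallback maximum-base-pairing engine ignores both
#' and honours only `max_pair_distance` and its minimum hairpin loop of 3.
#'
#' @param temperature folding temperature in degrees C
#' @param gamma MEA gamma
#' @param max_pair_distance maximum allowed distance between paired bases
#'   (nt)
#' @param intron_window total window length around intronic/non-annotated
#'   candidates (nt)
#' @return object of class `fold_config`
#' @export
fold_config <- function(temperature = 70, gamma = 0.1,
                        max_pair_distance = 150L, intron_window = 300L) {
  stopifnot(gamma > 0, max_pair_distance >= 4)
  structure(list(temperature = temperature, gamma = gamma,
                 max_pair_distance = as.integer(max_pair_distance),
                 intron_window = as.integer(intron_window)),
            class = "fold_config")
}

# Spliced transcript sequence in transcript orientation from a genome
# (named character vector or DNAStringSet).
spliced_sequence <- function(model, genome) {
  g <- as.character(genome[[model$chrom]])
  parts <- apply(model$exons, 1, function(iv)
    substr(g, iv[1] + 1L, iv[2]))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- revcomp_chr(s)
  s
}

#' Extract the folding context of a candidate site
#'
#' Exonic candidates are folded in their full spliced transcript;
#' intronic/non-annotated candidates in a window of
#' `config$intron_window` nt centred on the site (truncated at contig
#' ends). The returned sequence is RNA (T mapped to U) on the site strand.
#'
#' @param site list or one-row data.frame with `chrom`, `pos`, `strand`
#' @param models a [transcript_db()]
#' @param genome named character vector (or DNAStringSet) of sequences
#' @param config a [fold_config()]
#' @return list: `sequence` (RNA), `offset` (0-based position of the
#'   candidate C in `sequence`), `context` ("transcript" or "window"),
#'   `transcript_id` (or `NA`)
#' @export
extract_fold_context <- function(site, models, genome,
                                 config = fold_config()) {
  hit_tid <- NA_character_; tpos <- NA_integer_
  for (tid in names(models)) {
    m <- models[[tid]]
    if (m$chrom != site$chrom || m$strand != site$strand) next
    tp <- genomic_to_transcript(m, site$pos)
    if (!is.na(tp)) { hit_tid <- tid; tpos <- tp; break }
  }
  if (!is.na(hit_tid)) {
    seq <- spliced_sequence(models[[hit_tid]], genome)
    off <- tpos
    ctx <- "transcript"
  } else {
    g <- as.character(genome[[site$chrom]])
    half <- config$intron_window %/% 2L
    w0 <- max(0L, site$pos - half)
    w1 <- min(nchar(g), site$pos + half)
    seq <- substr(g, w0 + 1L, w1)
    off <- site$pos - w0
    if (site$strand == "-") {
      seq <- revcomp_chr(seq)
      off <- nchar(seq) - 1L - off
    }
    ctx <- "window"
  }
  rna <- chartr("T", "U", toupper(seq))
  if (substr(rna, off + 1L, off + 1L) != "C")
    stopf("site %s:%d(%s): base in folding context is '%s', not C",
          site$chrom, site$pos, site$strand, substr(rna, off + 1L, off + 1L))
  list(sequence = rna, offset = off, context = ctx, transcript_id = hit_tid)
}

#' Predict a secondary structure in dot-bracket notation
#'
#' Pluggable engine contract: returns a balanced, non-crossing dot-bracket
#' honouring `config$max_pair_distance`. The `"maxpair"` engine (always
#' available) maximizes the number of canonical + wobble base pairs with a
#' minimum hairpin loop of 3 nt; it ignores `temperature` and `gamma`.
#' The `"mea"` engine shells out to ViennaRNA `RNAfold` for the
#' thermodynamic MEA structure at `config$temperature` with
#' `config$gamma`, and errors when `RNAfold` is not on the PATH.
#'
#' @param sequence RNA sequence (ACGU; T accepted and mapped to U)
#' @param config a [fold_config()]
#' @param engine "maxpair" or "mea"
#' @return dot-bracket string with attribute `engine`
#' @export
fold_mea <- function(sequence, config = fold_config(),
                     engine = c("maxpair", "mea")) {
  engine <- match.arg(engine)
  rna <- chartr("T", "U", toupper(sequence))
  if (grepl("[^ACGU]", rna))
    stopf("sequence contains non-RNA characters")
  db <- if (engine == "maxpair") {
    nussinov_fold_cpp(rna, config$max_pair_distance, 3L)
  } else {
    fold_rnafold(rna, config)
  }
  attr(db, "engine") <- engine
  db
}

fold_rnafold <- function(rna, config) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe))
    stopf("engine 'mea' requires ViennaRNA RNAfold on the PATH; use engine = 'maxpair'")
  out <- system2(exe, c(sprintf("--MEA=%g", config$gamma),
                        "-T", as.character(config$temperature),
                        sprintf("--maxBPspan=%d", config$max_pair_distance),
                        "--noPS"),
                 input = rna, stdout = TRUE)
  mea_line <- grep("MEA=", out, value = TRUE)
  if (!length(mea_line)) stopf("could not parse RNAfold MEA output")
  substr(mea_line[1], 1L, nchar(rna))
}

#' Annotate candidate sites with their predicted pairing state
#'
#' Folds each site's context ([extract_fold_context()]) and records
#' whether the candidate base is paired (non-'.') in the structure.
#' Contexts are cached so a transcript carrying several candidates is
#' folded once.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`
#' @param models a [transcript_db()]
#' @param genome named character vector of sequences
#' @param config a [fold_config()]
#' @param engine folding engine, see [fold_mea()]
#' @return data.frame: site columns plus `paired`, `engine`, `context`
#'   (transcript/window), `transcript_id`, `dot_bracket_excerpt`
#'   (structure within 20 nt of the site, site base bracketed)
#' @export
annotate_structure <- function(sites, models, genome,
                               config = fold_config(),
                               engine = c("maxpair", "mea")) {
  engine <- match.arg(engine)
  cache <- new.env(parent = emptyenv())
  n <- nrow(sites)
  paired <- logical(n); ctx <- character(n); tid <- character(n)
  excerpt <- character(n)
  for (i in seq_len(n)) {
    fc <- extract_fold_context(sites[i, , drop = FALSE], models, genome,
                               config)
    ckey <- if (fc$context == "transcript") fc$transcript_id else
      sprintf("w:%s:%d:%s", sites$chrom[i], sites$pos[i], sites$strand[i])
    db <- cache[[ckey]]
    if (is.null(db)) {
      db <- fold_mea(fc$sequence, config, engine)
      cache[[ckey]] <- db
    }
    ch <- substr(db, fc$offset + 1L, fc$offset + 1L)
    paired[i] <- ch != "."
    ctx[i] <- fc$context
    tid[i] <- if (is.na(fc$transcript_id)) NA_character_ else
      fc$transcript_id
    lo <- max(1L, fc$offset + 1L - 20L)
    hi <- min(nchar(db), fc$offset + 1L + 20L)
    excerpt[i] <- paste0(substr(db, lo, fc$offset),
                         "[", ch, "]",
                         substr(db, fc$offset + 2L, hi))
  }
  out <- sites
  out$paired <- paired
  out$engine <- engine
  out$context <- ctx
  out$transcript_id <- tid
  out$dot_bracket_excerpt <- excerpt
  out
}

#' Retain unpaired candidates; log discarded ones
#'
#' @param sites data.frame of candidate sites (`chrom`, `pos`, `strand`,
#'   plus any columns)
#' @param annotations output of [annotate_structure()] covering every site
#' @return list with `retained` (subset of `sites`) and `discarded`
#'   (discard log with structure context)
#' @export
filter_paired_candidates <- function(sites, annotations) {
  sk <- site_key(sites$chrom, sites$pos, sites$strand)
  ak <- site_key(annotations$chrom, annotations$pos, annotations$strand)
  m <- match(sk, ak)
  if (anyNA(m))
    stopf("missing structure annotation for %d site(s), e.g. %s",
          sum(is.na(m)), sk[which(is.na(m))[1]])
  paired <- annotations$paired[m]
  list(retained = sites[!paired, , drop = FALSE],
       discarded = annotations[m[paired], , drop = FALSE])
}
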