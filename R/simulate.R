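# Ground-truth simulator: toy transcriptome with paralog pairs, cell-cycle
# dependent poly(A) tails, capture-biased sequencing libraries, a toy genome,
# rRNA, ranked annotation tiers and a 3'UTR database.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Collects every knob of the synthetic dual-capture experiment. Defaults
#' describe the package's reference experiment: 1,000 transcripts, 6%
#' planted deadenylation (tail 150 nt in mitosis shortened to 10 nt in
#' interphase), 4% planted adenylation (the reverse), 10% of transcripts in
#' paralog pairs at ~93% nucleotide identity, log-normal abundances, and
#' 2e6 single-end 50 nt reads per library.
#'
#' @param n_genes number of transcripts in the pool (>= 10).
#' @param paralog_fraction fraction of transcripts that belong to a paralog
#'   pair (pairs are disjoint; each pair counts two transcripts).
#' @param paralog_identity_mean,paralog_identity_sd mean and sd of the
#'   pairwise nucleotide identity of paralog pairs (normal, truncated to
#'   (0.85, 0.995)).
#' @param rrna_fraction_total rRNA fraction of the un-captured total RNA pool
#'   (documentation of the biological setting; capture removes almost all of
#'   it).
#' @param rrna_carryover residual fraction of sequenced reads that still come
#'   from rRNA after mRNA capture.
#' @param read_length read length in nt (single-end).
#' @param n_reads reads per simulated library.
#' @param error_rate per-base substitution error rate.
#' @param duplicate_rate fraction of reads that are verbatim PCR re-emissions
#'   of another read.
#' @param anchor_len minimal poly(A) tail an anchored oligo-dT primer can
#'   engage; capture probability is exactly zero below it.
#' @param dt_half_saturation half-saturation constant (nt of tail beyond the
#'   anchor) of the saturating oligo-dT capture curve.
#' @param dt_pmax maximal oligo-dT capture probability.
#' @param pcap capture probability of a capped transcript in the cap-capture
#'   arm (tail-independent).
#' @param abundance_sigma sd of the log-normal molar abundances (log scale).
#' @param len_range transcript length range in nt (log-uniform).
#' @param frac_deadenylated,frac_adenylated fractions of transcripts with a
#'   planted tail change (long->short, short->long across the
#'   mitosis->interphase transition).
#' @param frac_short_both fraction with a sub-anchor tail in both states
#'   (invisible to oligo-dT capture altogether).
#' @param frac_uncapped fraction of uncapped transcripts (invisible to cap
#'   capture).
#' @param frac_ncrna fraction of non-coding transcripts (no constructed ORF,
#'   absent from the annotation tiers).
#' @param tail_long,tail_short planted long/short tail lengths in nt.
#' @param tier_fractions fractions of coding gene families whose protein is
#'   present in annotation tiers 1, 2 and 3; the remainder is absent from
#'   all tiers.
#' @param intron_prob probability that a gene's genomic copy carries one
#'   intron.
#' @param intron_len_range intron length range in nt.
#' @param seed integer seed; fully determines all simulator output.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_genes = 1000,
                       paralog_fraction = 0.10,
                       paralog_identity_mean = 0.931,
                       paralog_identity_sd = 0.0272,
                       rrna_fraction_total = 0.95,
                       rrna_carryover = 0.02,
                       read_length = 50,
                       n_reads = 2e6,
                       error_rate = 0.005,
                       duplicate_rate = 0.10,
                       anchor_len = 18,
                       dt_half_saturation = 30,
                       dt_pmax = 0.9,
                       pcap = 0.85,
                       abundance_sigma = 1.5,
                       len_range = c(300, 3000),
                       frac_deadenylated = 0.06,
                       frac_adenylated = 0.04,
                       frac_short_both = 0.05,
                       frac_uncapped = 0.05,
                       frac_ncrna = 0.05,
                       tail_long = 150,
                       tail_short = 10,
                       tier_fractions = c(0.70, 0.15, 0.10),
                       intron_prob = 0.3,
                       intron_len_range = c(100, 2000),
                       seed = 1) {
  cfg <- as.list(environment())
  fr <- c(paralog_fraction, rrna_fraction_total, rrna_carryover, error_rate,
          duplicate_rate, frac_deadenylated, frac_adenylated, frac_short_both,
          frac_uncapped, frac_ncrna, tier_fractions)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("all fractions must lie in [0, 1]")
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (frac_deadenylated + frac_adenylated + frac_short_both + frac_ncrna > 1)
    stop("planted class fractions exceed 1")
  if (sum(tier_fractions) > 1) stop("tier_fractions must sum to <= 1")
  if (dt_half_saturation <= 0) stop("dt_half_saturation must be positive")
  if (dt_pmax <= 0 || dt_pmax > 1) stop("dt_pmax must be in (0, 1]")
  if (len_range[1] < 2 * read_length) stop("transcripts must exceed 2 reads")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("dual-capture simulation config:", x$n_genes, "transcripts,",
      format(x$n_reads, big.mark = ","), "reads/library, seed", x$seed, "\n")
  invisible(x)
}

.random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

# a CDS of `n_codons` codons: ATG + non-stop interior + one stop
.random_cds <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- setdiff(codons, .STOP_CODONS)
  interior <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", interior, sample(.STOP_CODONS, 1L)), collapse = "")
}

#' Mutate a sequence to a target identity
#'
#' Applies substitutions only (no indels), so that the Hamming identity of
#' the result to the input is exactly `round(L * target_identity) / L`.
#'
#' @param sequence a DNA string.
#' @param target_identity target identity in (0, 1].
#' @return the mutated sequence.
#' @export
#' @examples
#' mutate_to_identity("ACGTACGTAC", 0.9)
mutate_to_identity <- function(sequence, target_identity) {
  if (length(sequence) != 1L) stop("sequence must be a single string")
  if (!is.finite(target_identity) || target_identity <= 0 ||
      target_identity > 1)
    stop("target_identity must be in (0, 1]")
  len <- nchar(sequence)
  n_mut <- len - round(len * target_identity)
  if (n_mut == 0L) return(sequence)
  pos <- sample.int(len, n_mut)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  old <- match(chars[pos], bases)
  new <- (old - 1L + sample.int(3L, n_mut, replace = TRUE)) %% 4L + 1L
  chars[pos] <- bases[new]
  paste(chars, collapse = "")
}

#' Oligo-dT capture probability as a function of poly(A) tail length
#'
#' A saturating hyperbola with a hard zero below the anchor length: anchored
#' oligo-dT priming requires `anchor_len` adenosines, and beyond that the
#' capture probability rises toward `pmax` with half-saturation at
#' `half_saturation` nt of tail past the anchor.
#'
#' @param tail_len poly(A) tail length(s) in nt (non-negative integers).
#' @param anchor_len minimal tail engaged by the anchored primer.
#' @param half_saturation half-saturation constant in nt.
#' @param pmax maximal capture probability.
#' @return capture probabilities in `[0, pmax]`, vectorized over `tail_len`.
#' @export
#' @examples
#' capture_probability_dt(c(10, 17, 47), half_saturation = 30, pmax = 1)
capture_probability_dt <- function(tail_len, anchor_len = 18,
                                   half_saturation = 30, pmax = 1) {
  stopifnot(all(tail_len >= 0))
  x <- tail_len - anchor_len + 1
  ifelse(tail_len < anchor_len, 0, pmax * x / (x + half_saturation))
}

#' Cap-capture probability
#'
#' Cap capture selects on the 5' cap structure only: a capped transcript is
#' captured with probability `pcap` regardless of its poly(A) tail; an
#' uncapped transcript is invisible.
#'
#' @param capped logical vector.
#' @param pcap capture probability for capped transcripts.
#' @return capture probabilities, vectorized over `capped`.
#' @export
capture_probability_cap <- function(capped, pcap = 0.85) {
  pcap * as.numeric(capped)
}

#' Simulate a ground-truth transcriptome
#'
#' Generates the transcript pool (with paralog pairs, planted poly(A)
#' regulation classes, capping status and log-normal abundances), a toy
#' genome containing one genomic copy of each gene (optionally with an
#' intron), an rRNA precursor, three ranked annotation tiers of reference
#' proteins, and a 3'UTR database.
#'
#' Coding transcripts are built as 5'UTR + CDS (ATG...stop, no interior
#' stop) + 3'UTR so that translated homology search and ORF prediction see
#' realistic structure. One reference protein is emitted per gene family
#' (paralog pairs share one entry, emulating scaffolding against a related
#' species' ortholog set) and assigned to tier 1, 2, 3 or no tier.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_transcriptome`: a list with elements
#'   `pool` (data frame: id, gene_id, paralog_group, biotype, sequence,
#'   abundance, tail_M, tail_IF, capped, truth_class), `genome` (list:
#'   `sequence`, `loci` data frame with 0-based half-open gene coordinates),
#'   `rrna`, `tiers` (list of 3 named protein vectors), `utr_db`, and
#'   `config`.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_genes

  len <- round(exp(runif(n, log(config$len_range[1]),
                         log(config$len_range[2]))))

  biotype <- rep("coding", n)
  n_nc <- round(config$frac_ncrna * n)
  if (n_nc > 0) biotype[sample.int(n, n_nc)] <- "ncRNA"

  # sequence construction
  utr5 <- pmin(pmax(round(0.10 * len), 30L), 150L)
  utr3 <- pmin(pmax(round(0.25 * len), 50L), 600L)
  sequence <- character(n)
  cds_start <- rep(NA_integer_, n)
  cds_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (biotype[i] == "coding") {
      n_cod <- (len[i] - utr5[i] - utr3[i]) %/% 3L
      if (n_cod < 30L) { n_cod <- 30L; utr3[i] <- 50L }
      u5 <- .random_dna(utr5[i])
      cds <- .random_cds(n_cod)
      u3 <- .random_dna(utr3[i])
      sequence[i] <- paste0(u5, cds, u3)
      len[i] <- nchar(sequence[i])
      cds_start[i] <- utr5[i]
      cds_end[i] <- utr5[i] + 3L * n_cod
    } else {
      sequence[i] <- .random_dna(len[i])
    }
  }

  # paralog pairs: partner's sequence is a substitution-mutated copy
  paralog_group <- rep(NA_character_, n)
  n_pairs <- floor(config$paralog_fraction * n / 2)
  if (n_pairs > 0) {
    coding_idx <- which(biotype == "coding")
    members <- sample(coding_idx, 2L * n_pairs)
    for (p in seq_len(n_pairs)) {
      a <- members[2L * p - 1L]; b <- members[2L * p]
      id_target <- 0
      while (id_target <= 0.85 || id_target > 0.995)
        id_target <- rnorm(1, config$paralog_identity_mean,
                           config$paralog_identity_sd)
      sequence[b] <- mutate_to_identity(sequence[a], id_target)
      len[b] <- len[a]
      utr5[b] <- utr5[a]; utr3[b] <- utr3[a]
      cds_start[b] <- cds_start[a]; cds_end[b] <- cds_end[a]
      paralog_group[c(a, b)] <- sprintf("pg%04d", p)
    }
  }

  # planted poly(A) regulation classes
  truth_class <- rep("unchanged", n)
  free <- sample.int(n)  # random order, classes assigned along it
  n_dead <- round(config$frac_deadenylated * n)
  n_aden <- round(config$frac_adenylated * n)
  n_short <- round(config$frac_short_both * n)
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- free[seq_len(k)]; free <<- free[-seq_len(k)]; out
  }
  idx_dead <- take(n_dead); idx_aden <- take(n_aden); idx_short <- take(n_short)
  truth_class[idx_dead] <- "deadenylated"
  truth_class[idx_aden] <- "adenylated"
  truth_class[idx_short] <- "short_both"

  base_tail <- sample(60:200, n, replace = TRUE)
  tail_M <- base_tail; tail_IF <- base_tail
  tail_M[idx_dead] <- config$tail_long;  tail_IF[idx_dead] <- config$tail_short
  tail_M[idx_aden] <- config$tail_short; tail_IF[idx_aden] <- config$tail_long
  tail_M[idx_short] <- config$tail_short; tail_IF[idx_short] <- config$tail_short

  capped <- rep(TRUE, n)
  n_uncap <- round(config$frac_uncapped * n)
  if (n_uncap > 0) capped[take(n_uncap)] <- FALSE

  abundance <- exp(rnorm(n, 0, config$abundance_sigma))
  abundance <- abundance / sum(abundance)

  id <- sprintf("tx%04d", seq_len(n))
  gene_id <- sprintf("g%04d", seq_len(n))
  pool <- data.frame(id = id, gene_id = gene_id,
                     paralog_group = paralog_group, biotype = biotype,
                     length = len, abundance = abundance,
                     tail_M = tail_M, tail_IF = tail_IF, capped = capped,
                     truth_class = truth_class,
                     cds_start = cds_start, cds_end = cds_end,
                     sequence = sequence, stringsAsFactors = FALSE)

  # toy genome: spacer + gene copies (intron optionally inserted mid-gene)
  pieces <- character(2L * n + 1L)
  loci <- data.frame(transcript_id = id, start = NA_integer_,
                     end = NA_integer_, has_intron = FALSE)
  pos <- 0L
  for (i in seq_len(n)) {
    spacer <- .random_dna(sample(200:500, 1L))
    pieces[2L * i - 1L] <- spacer
    pos <- pos + nchar(spacer)
    gseq <- sequence[i]
    if (runif(1) < config$intron_prob) {
      ilen <- sample(config$intron_len_range[1]:config$intron_len_range[2], 1L)
      # canonical GT...AG intron so the copy is recognizably spliced
      intron <- paste0("GT", .random_dna(ilen - 4L), "AG")
      cut <- sample(seq(100L, len[i] - 100L), 1L)
      gseq <- paste0(substr(gseq, 1L, cut), intron,
                     substr(gseq, cut + 1L, len[i]))
      loci$has_intron[i] <- TRUE
    }
    pieces[2L * i] <- gseq
    loci$start[i] <- pos
    pos <- pos + nchar(gseq)
    loci$end[i] <- pos
  }
  pieces[2L * n + 1L] <- .random_dna(300L)
  genome <- list(sequence = paste(pieces, collapse = ""), loci = loci)

  rrna <- c(rRNA = .random_dna(6000L))

  # annotation tiers: one protein per coding gene family
  fam <- ifelse(is.na(paralog_group), gene_id, paralog_group)
  coding <- which(biotype == "coding")
  fam_rep <- coding[!duplicated(fam[coding])]
  prot <- vapply(fam_rep, function(i) {
    cds <- substr(sequence[i], cds_start[i] + 1L, cds_end[i])
    p <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                            no.init.codon = TRUE))
    sub("\\*$", "", p)
  }, character(1))
  names(prot) <- paste0("ref_", fam[fam_rep])
  ord <- sample(length(prot))
  nt <- round(cumsum(c(0, config$tier_fractions)) * length(prot))
  tiers <- list(tier1 = prot[ord[seq(nt[1] + 1, nt[2])]],
                tier2 = prot[ord[seq(nt[2] + 1, nt[3])]],
                tier3 = prot[ord[seq(nt[3] + 1, nt[4])]])

  utr_db <- substr(sequence[coding], cds_end[coding] + 1L, len[coding])
  names(utr_db) <- paste0("utr3_", id[coding])

  structure(list(pool = pool, genome = genome, rrna = rrna, tiers = tiers,
                 utr_db = utr_db, config = config),
            class = "sim_transcriptome")
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  p <- x$pool
  cat("simulated transcriptome:", nrow(p), "transcripts (",
      sum(p$biotype == "coding"), "coding,",
      sum(!is.na(p$paralog_group)), "in paralog pairs )\n")
  cat("planted classes:",
      paste(names(table(p$truth_class)), table(p$truth_class),
            collapse = ", "), "\n")
  invisible(x)
}

.lib_seed <- function(config, state, method) {
  offset <- (match(state, c("M", "IF")) - 1L) * 2L +
    match(method, c("dT", "cap")) - 1L
  (config$seed %% 2^27L) * 8L + offset
}

#' Simulate a capture-biased sequencing library
#'
#' Samples reads from the transcript pool with weight proportional to
#' abundance times the capture probability of the chosen method in the
#' chosen cell-cycle state. Read starts are uniform over the transcript
#' (random-hexamer priming), strands are random (unstranded protocol),
#' substitution errors occur at `error_rate` per base, a `duplicate_rate`
#' fraction of reads are verbatim PCR re-emissions, and an `rrna_carryover`
#' fraction derive from the rRNA precursor.
#'
#' @param sim a [simulate_transcriptome()] result.
#' @param state `"M"` (mitotic/CSF-arrested) or `"IF"` (interphase).
#' @param method `"dT"` (oligo-dT capture) or `"cap"` (5'-cap capture).
#' @param n_reads number of reads (defaults to the config value).
#' @param seed RNG seed; by default derived deterministically from the
#'   config seed, state and method, so the four libraries of an experiment
#'   differ but the whole experiment is reproducible.
#' @return a data frame with columns `read_id`, `sequence`, `truth_id`
#'   (source transcript or `"rRNA"`), `truth_pos` (0-based offset on the
#'   source) and `truth_strand`; attributes `state`, `method`.
#' @export
simulate_library <- function(sim, state = c("M", "IF"),
                             method = c("dT", "cap"),
                             n_reads = NULL, seed = NULL) {
  state <- match.arg(state); method <- match.arg(method)
  config <- sim$config
  if (is.null(n_reads)) n_reads <- config$n_reads
  if (is.null(seed)) seed <- .lib_seed(config, state, method)
  set.seed(seed)
  pool <- sim$pool
  L <- config$read_length

  tails <- if (state == "M") pool$tail_M else pool$tail_IF
  p_cap <- if (method == "dT") {
    capture_probability_dt(tails, config$anchor_len,
                           config$dt_half_saturation, config$dt_pmax)
  } else {
    capture_probability_cap(pool$capped, config$pcap)
  }
  w <- pool$abundance * p_cap
  if (all(w == 0)) stop("empty capturable pool")

  n_dup <- round(config$duplicate_rate * n_reads)
  n_fresh <- n_reads - n_dup
  n_rrna <- rbinom(1L, n_fresh, config$rrna_carryover)
  n_tx <- n_fresh - n_rrna

  idx <- sample.int(nrow(pool), n_tx, replace = TRUE, prob = w)
  start <- floor(runif(n_tx) * (pool$length[idx] - L + 1L))
  seqs <- substring(pool$sequence[idx], start + 1L, start + L)
  truth_id <- pool$id[idx]

  if (n_rrna > 0L) {
    rlen <- nchar(sim$rrna[[1L]])
    rstart <- floor(runif(n_rrna) * (rlen - L + 1L))
    seqs <- c(seqs, substring(sim$rrna[[1L]], rstart + 1L, rstart + L))
    truth_id <- c(truth_id, rep("rRNA", n_rrna))
    start <- c(start, rstart)
  }
  perm <- sample.int(n_fresh)
  seqs <- seqs[perm]; truth_id <- truth_id[perm]; start <- start[perm]

  minus <- runif(n_fresh) < 0.5
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])

  n_err <- rbinom(1L, n_fresh * L, config$error_rate)
  if (n_err > 0L) {
    ridx <- sample.int(n_fresh, n_err, replace = TRUE)
    ppos <- sample.int(L, n_err, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    for (p in unique(ppos)) {
      rs <- ridx[ppos == p]
      old <- match(substr(seqs[rs], p, p), bases)
      new <- (old - 1L + sample.int(3L, length(rs), replace = TRUE)) %% 4L + 1L
      substr(seqs[rs], p, p) <- bases[new]
    }
  }

  if (n_dup > 0L) {
    src <- sample.int(n_fresh, n_dup, replace = TRUE)
    seqs <- c(seqs, seqs[src])
    truth_id <- c(truth_id, truth_id[src])
    start <- c(start, start[src])
    minus <- c(minus, minus[src])
  }

  out <- data.frame(
    read_id = sprintf("%s_%s_r%07d", method, state, seq_len(n_reads)),
    sequence = seqs, truth_id = truth_id, truth_pos = start,
    truth_strand = ifelse(minus, "-", "+"), stringsAsFactors = FALSE)
  attr(out, "state") <- state
  attr(out, "method") <- method
  out
}

#' Error-free tiling reads
#'
#' Emits every `step`-th window of length `read_length` from each sequence
#' (plus the final window), with no errors, duplicates or rRNA. This layout
#' gives uniform, abundance-independent coverage and is the reference input
#' for validating assembler reconstruction.
#'
#' @param sequences named character vector of template sequences.
#' @param read_length window length.
#' @param step distance between window starts; must be small enough that
#'   consecutive windows overlap by at least the largest assembly k.
#' @return a read-set data frame (same columns as [simulate_library()]).
#' @export
tile_reads <- function(sequences, read_length = 50, step = 7) {
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%05d", seq_along(sequences))
  lens <- nchar(sequences)
  keep <- lens >= read_length
  sequences <- sequences[keep]; lens <- lens[keep]
  starts <- lapply(lens, function(L)
    unique(c(seq(0L, L - read_length, by = step), L - read_length)))
  nper <- lengths(starts)
  idx <- rep(seq_along(sequences), nper)
  st <- unlist(starts, use.names = FALSE)
  data.frame(
    read_id = sprintf("tile_%s_%06d", names(sequences)[idx],
                      unlist(lapply(nper, seq_len))),
    sequence = substring(sequences[idx], st + 1L, st + read_length),
    truth_id = names(sequences)[idx], truth_pos = st, truth_strand = "+",
    stringsAsFactors = FALSE)
}
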