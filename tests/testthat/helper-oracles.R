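# Shared fixtures and independent oracles used across test files.

rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")

# independent Hamming count via character comparison
hamming_chr <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force both-strand containment merge oracle (set of kept sequences)
oracle_remove_contained <- function(seqs, min_len = 1) {
  seqs <- seqs[nchar(seqs) >= min_len]
  if (!length(seqs)) return(character(0))
  lens <- nchar(seqs)
  rc <- revcomp(seqs)
  kept <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    longer <- seqs[lens > lens[i]]
    if (length(longer) &&
        (any(grepl(seqs[i], longer, fixed = TRUE)) ||
         any(grepl(rc[i], longer, fixed = TRUE)))) next
    # equal-length duplicates (incl. reverse complements): keep lex smallest
    dup <- which(lens == lens[i] & (seqs == seqs[i] | seqs == rc[i]))
    kept[i] <- seqs[i] == min(seqs[dup])
  }
  sort(unique(seqs[kept]))
}

# random contig pool with planted containments, rc fragments and duplicates
random_contig_pool <- function(n_base, n_frag, n_dup, len_range = c(15, 80)) {
  pool <- vapply(seq_len(n_base), function(i)
    rdna(sample(len_range[1]:len_range[2], 1)), "")
  extra <- character(0)
  for (i in sample(n_base, n_frag, replace = TRUE)) {
    s <- pool[i]
    lo <- sample(nchar(s) - 8, 1)
    hi <- min(nchar(s), lo + sample(8:60, 1))
    frag <- substr(s, lo, hi)
    if (runif(1) < 0.5) frag <- revcomp(frag)
    extra <- c(extra, frag)
  }
  dups <- pool[sample(n_base, n_dup, replace = TRUE)]
  if (length(dups) > 1 && runif(1) < 0.7) dups[1] <- revcomp(dups[1])
  sample(c(pool, extra, dups))
}

# brute-force longest-ORF oracle built on Biostrings translation + regex
oracle_longest_orf <- function(sequence) {
  best <- 0L
  for (fr in 1:6) {
    s <- if (fr <= 3) sequence else as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    off <- (fr - 1L) %% 3L
    w <- 3L * ((nchar(s) - off) %/% 3L)
    if (w < 3L) next
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, off + 1L, off + w)),
      no.init.codon = TRUE))
    # every ORF: M up to (not including) the next stop, or sequence end
    ms <- gregexpr("M", pep, fixed = TRUE)[[1]]
    if (ms[1] == -1) next
    stops <- c(gregexpr("\\*", pep)[[1]], nchar(pep) + 1L)
    stops <- stops[stops > 0]
    for (m in ms) {
      stp <- min(stops[stops >= m])
      best <- max(best, stp - m)
    }
  }
  best
}

# brute-force pseudo-alignment oracle via Biostrings::matchPattern
oracle_align <- function(read, reference, max_mm = 2) {
  hits <- list()
  for (ri in seq_along(reference)) {
    subj <- Biostrings::DNAString(reference[[ri]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(read)))
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm)
      if (length(m)) {
        mm <- vapply(seq_along(m), function(k)
          hamming_chr(as.character(m[[k]]), pat), integer(1))
        for (k in seq_along(m))
          hits[[length(hits) + 1L]] <- list(ref = ri,
                                            pos = Biostrings::start(m)[k] - 1L,
                                            strand = strand, mm = mm[k])
      }
    }
  }
  if (!length(hits)) return(list(status = "unaligned"))
  mmv <- vapply(hits, `[[`, integer(1), "mm")
  best <- hits[mmv == min(mmv)]
  refs <- unique(vapply(best, `[[`, integer(1), "ref"))
  if (length(refs) > 1) return(list(status = "ambiguous", mm = min(mmv)))
  list(status = "aligned", ref = refs, mm = min(mmv))
}

# small cached simulation shared by several test files
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.sim_cache$small))
    .sim_cache$small <- simulate_transcriptome(
      sim_config(n_genes = 40, n_reads = 3e4, seed = 5))
  .sim_cache$small
}

medium_quant <- function() {
  if (is.null(.sim_cache$medium)) {
    sim <- simulate_transcriptome(
      sim_config(n_genes = 150, n_reads = 2e5, seed = 21))
    ref <- setNames(sim$pool$sequence, sim$pool$id)
    quant <- list()
    for (method in c("dT", "cap")) for (state in c("M", "IF")) {
      rd <- simulate_library(sim, state, method)
      quant[[paste(method, state, sep = "_")]] <-
        quantify_library(rd, ref, sim$rrna)
    }
    .sim_cache$medium <- list(sim = sim, quant = quant,
                              calls = polya_calls(
                                quant$dT_M$counts, quant$dT_IF$counts,
                                quant$cap_M$counts, quant$cap_IF$counts))
  }
  .sim_cache$medium
}
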