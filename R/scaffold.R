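# Tiered homology scaffolding: translated seed-and-extend search of contigs
# against ranked reference protein sets, sequential tier assignment,
# clustering by best reference, coverage fractions and set overlaps.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Six-frame translation
#'
#' Standard genetic code; frames +1..+3 on the given strand, -1..-3 on the
#' reverse complement; stop codons rendered as `*`; trailing partial codons
#' dropped.
#'
#' @param sequence a DNA string of length >= 3.
#' @return named character vector of six peptides
#'   (`+1`, `+2`, `+3`, `-1`, `-2`, `-3`).
#' @export
#' @examples
#' six_frame_translate("ATGAAA")
six_frame_translate <- function(sequence) {
  if (length(sequence) != 1L) stop("sequence must be a single string")
  L <- nchar(sequence)
  if (L < 3) stop("sequence shorter than one codon")
  one <- function(s, off) {
    w <- 3L * ((nchar(s) - off) %/% 3L)
    if (w == 0L) return("")
    sub <- substr(s, off + 1L, off + w)
    # no.init.codon: report the literal codon, not an initiator methionine
    as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                       no.init.codon = TRUE))
  }
  rc <- revcomp(sequence)
  setNames(c(one(sequence, 0L), one(sequence, 1L), one(sequence, 2L),
             one(rc, 0L), one(rc, 1L), one(rc, 2L)),
           c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# translate a set of sequences in all six frames; returns a data frame of
# peptides with their contig index and frame
.six_frame_table <- function(seqs) {
  dss <- Biostrings::DNAStringSet(seqs)
  rcs <- Biostrings::reverseComplement(dss)
  frames <- list()
  for (off in 0:2) {
    w <- 3L * pmax((Biostrings::width(dss) - off) %/% 3L, 0L)
    ok <- w > 0L
    pep <- rep("", length(dss))
    if (any(ok))
      pep[ok] <- as.character(Biostrings::translate(
        Biostrings::subseq(dss[ok], start = off + 1L, width = w[ok]),
        no.init.codon = TRUE))
    frames[[paste0("+", off + 1)]] <- pep
    pep2 <- rep("", length(dss))
    if (any(ok))
      pep2[ok] <- as.character(Biostrings::translate(
        Biostrings::subseq(rcs[ok], start = off + 1L, width = w[ok]),
        no.init.codon = TRUE))
    frames[[paste0("-", off + 1)]] <- pep2
  }
  data.frame(
    contig = rep(seq_along(seqs), times = 6L),
    frame = rep(c(1L, -1L, 2L, -2L, 3L, -3L), each = length(seqs)),
    peptide = unlist(frames, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Translated homology search (BLASTX-style)
#'
#' Searches all six reading frames of each contig against a protein
#' database: exact 4-mer peptide seeds, ungapped BLOSUM62 extension with
#' X-drop, bit scores from ungapped Karlin-Altschul statistics, and
#' e-value = (contig query residues x database residues) x 2^(-bits).
#' The best hit per (contig, reference) pair is retained and filtered at
#' `evalue_max`.
#'
#' @param contigs named character vector of contig DNA sequences.
#' @param protein_db named character vector of protein sequences.
#' @param evalue_max e-value threshold (default 1e-10, the scaffolding
#'   threshold).
#' @param word peptide seed length (4).
#' @param xdrop X-drop extension cutoff in raw score units.
#' @return data frame: `contig_id`, `reference_id`, `frame`, `score`,
#'   `bit_score`, `evalue`, `q_start`, `q_end` (nt on the contig, 0-based
#'   half-open), `s_start`, `s_end` (aa on the reference).
#' @export
translated_search <- function(contigs, protein_db, evalue_max = 1e-10,
                              word = 4, xdrop = 20) {
  if (length(protein_db) == 0) stop("protein_db must be nonempty")
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig%06d", seq_along(contigs))
  empty <- data.frame(contig_id = character(), reference_id = character(),
                      frame = integer(), score = integer(),
                      bit_score = numeric(), evalue = numeric(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      stringsAsFactors = FALSE)
  if (length(contigs) == 0) return(empty)
  ft <- .six_frame_table(contigs)
  sm <- .blosum62()
  hits <- rcpp_protein_search(ft$peptide, as.character(protein_db),
                              sm, paste(rownames(sm), collapse = ""),
                              as.integer(word), xdrop)
  if (nrow(hits) == 0) return(empty)
  contig <- ft$contig[hits$query]
  frame <- ft$frame[hits$query]
  qres <- tapply(nchar(ft$peptide), ft$contig, sum)  # residues per contig
  m <- as.numeric(qres[as.character(contig)])
  n_db <- sum(nchar(protein_db))
  bits <- .bits(hits$score, .ka$protein)
  ev <- .evalue(hits$score, m, n_db, .ka$protein)

  # peptide coords -> nt coords on the contig
  L <- nchar(contigs)[contig]
  off <- abs(frame) - 1L
  q_start <- ifelse(frame > 0, off + 3L * hits$qstart,
                    L - (off + 3L * hits$qend))
  q_end <- ifelse(frame > 0, off + 3L * hits$qend,
                  L - (off + 3L * hits$qstart))
  out <- data.frame(contig_id = names(contigs)[contig],
                    reference_id = names(protein_db)[hits$db],
                    frame = frame, score = hits$score, bit_score = bits,
                    evalue = ev, q_start = q_start, q_end = q_end,
                    s_start = hits$sstart, s_end = hits$send,
                    stringsAsFactors = FALSE)
  out <- out[out$evalue <= evalue_max, , drop = FALSE]
  # best hit per (contig, reference): lowest e-value, then score, then frame
  ord <- order(out$contig_id, out$reference_id, out$evalue, -out$score,
               out$frame)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out[, c("contig_id", "reference_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sequential tiered scaffolding
#'
#' Assigns contigs to ranked reference sets in order: every contig is
#' searched against tier 1; contigs with a passing hit are assigned to
#' their best tier-1 reference (lowest e-value, ties broken by score then
#' lexicographic reference id) and removed; the remainder proceed to tier
#' 2, then tier 3. Assignment is sequential, not global-best: a passing
#' tier-1 hit always wins over a stronger tier-2 hit. Assigned contigs are
#' renamed `<reference>.<n>`.
#'
#' @param contigs named character vector of contig DNA sequences.
#' @param tiers list of up to 3 named protein vectors, ranked.
#' @param evalue_max e-value threshold for a passing hit.
#' @return list with `assignments` (data frame: `contig_id`,
#'   `member_name`, `reference_id`, `tier`, `evalue`, `bit_score`,
#'   `s_start`, `s_end`), `clusters` (data frame: `reference_id`, `tier`,
#'   `n_members`, `coverage_fraction`), and `unassigned` (character vector
#'   of contig ids).
#' @export
tiered_scaffold <- function(contigs, tiers, evalue_max = 1e-10) {
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig%06d", seq_along(contigs))
  remaining <- contigs
  assignments <- list()
  for (t in seq_along(tiers)) {
    if (length(remaining) == 0 || length(tiers[[t]]) == 0) next
    hits <- translated_search(remaining, tiers[[t]], evalue_max)
    if (nrow(hits) == 0) next
    ord <- order(hits$contig_id, hits$evalue, -hits$score,
                 hits$reference_id)
    best <- hits[ord, ][!duplicated(hits$contig_id[ord]), , drop = FALSE]
    best$tier <- t
    assignments[[t]] <- best
    remaining <- remaining[!(names(remaining) %in% best$contig_id)]
  }
  if (length(assignments)) {
    asg <- do.call(rbind, assignments)
    # number members within each reference: by e-value, then contig id
    asg <- asg[order(asg$tier, asg$reference_id, asg$evalue,
                     asg$contig_id), , drop = FALSE]
    n_in <- stats::ave(seq_len(nrow(asg)), asg$reference_id,
                       FUN = seq_along)
    asg$member_name <- sprintf("%s.%d", asg$reference_id, n_in)
    rownames(asg) <- NULL
    ref_len <- setNames(nchar(unlist(tiers, use.names = FALSE)),
                        unlist(lapply(tiers, names)))
    cl <- split(asg, asg$reference_id)
    clusters <- do.call(rbind, lapply(cl, function(d) {
      data.frame(reference_id = d$reference_id[1], tier = d$tier[1],
                 n_members = nrow(d),
                 coverage_fraction = reference_coverage(
                   d[, c("s_start", "s_end")],
                   ref_len[[d$reference_id[1]]]),
                 stringsAsFactors = FALSE)
    }))
    rownames(clusters) <- NULL
    asg <- asg[, c("contig_id", "member_name", "reference_id", "tier",
                   "evalue", "bit_score", "s_start", "s_end")]
  } else {
    asg <- data.frame(contig_id = character(), member_name = character(),
                      reference_id = character(), tier = integer(),
                      evalue = numeric(), bit_score = numeric(),
                      s_start = integer(), s_end = integer(),
                      stringsAsFactors = FALSE)
    clusters <- data.frame(reference_id = character(), tier = integer(),
                           n_members = integer(),
                           coverage_fraction = numeric(),
                           stringsAsFactors = FALSE)
  }
  list(assignments = asg, clusters = clusters,
       unassigned = names(remaining))
}

#' Fraction of a reference covered by cluster members
#'
#' Length of the union of member reference ranges divided by the reference
#' length. Overlapping ranges are counted once.
#'
#' @param ranges two-column matrix or data frame of 0-based half-open
#'   ranges on the reference.
#' @param reference_length reference length (same units as the ranges).
#' @return coverage fraction in `[0, 1]`.
#' @export
#' @examples
#' reference_coverage(rbind(c(0, 40), c(60, 100)), 100)
reference_coverage <- function(ranges, reference_length) {
  ranges <- as.matrix(ranges)
  if (nrow(ranges) == 0) return(0)
  s <- pmax(pmin(ranges[, 1], reference_length), 0)
  e <- pmax(pmin(ranges[, 2], reference_length), 0)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) { tot <- tot + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
    else cur_e <- max(cur_e, e[i])
  }
  tot <- tot + (cur_e - cur_s)
  tot / reference_length
}

#' Overlap (Venn) counts of reference sets matched by different pipelines
#'
#' @param sets named list (>= 2 entries) of character vectors (e.g. the
#'   reference transcripts matched by each assembler:library pair).
#' @return data frame with one row per non-empty membership pattern:
#'   `region` (labels joined by `&`) and `count`.
#' @export
#' @examples
#' overlap_sets(list(A = c("g1", "g2"), B = c("g2", "g3")))
overlap_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                                 drop = FALSE]
  names(combos) <- names(sets)
  region <- apply(combos, 1, function(r)
    paste(names(sets)[as.logical(r)], collapse = "&"))
  count <- apply(combos, 1, function(r)
    sum(apply(member, 1, function(m) all(m == as.logical(r)))))
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Nucleotide homology test (identity and query-coverage rule)
#'
#' A contig is homologous to a reference transcript if its best local
#' ungapped nucleotide alignment (match +1, mismatch -1, either strand)
#' has identity of at least `min_identity` over the aligned span and the
#' span covers at least `min_query_cov` of the contig length.
#'
#' @param contig a DNA string.
#' @param reference_tx a DNA string.
#' @param min_identity minimal identity over the aligned span.
#' @param min_query_cov minimal fraction of the contig covered.
#' @param word,xdrop seed length and X-drop for the search.
#' @return logical.
#' @export
nucleotide_homology <- function(contig, reference_tx, min_identity = 0.80,
                                min_query_cov = 0.50, word = 11,
                                xdrop = 20) {
  tab <- nt_homology_table(setNames(contig, "q"), setNames(reference_tx, "s"),
                           min_identity, min_query_cov, word, xdrop)
  nrow(tab) > 0 && any(tab$pass)
}

#' Bulk nucleotide homology table
#'
#' Vectorized form of [nucleotide_homology()]: best local hit per
#' (contig, reference) pair with identity, query coverage and the pass
#' flag under the identity/coverage rule.
#'
#' @param contigs,references named character vectors of DNA sequences.
#' @inheritParams nucleotide_homology
#' @return data frame: `contig_id`, `reference_id`, `identity`,
#'   `query_coverage`, `score`, `pass`.
#' @export
nt_homology_table <- function(contigs, references, min_identity = 0.80,
                              min_query_cov = 0.50, word = 11, xdrop = 20) {
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig%06d", seq_along(contigs))
  if (is.null(names(references)))
    names(references) <- sprintf("ref%06d", seq_along(references))
  hits <- rcpp_nt_search(as.character(contigs), as.character(references),
                         as.integer(word), xdrop)
  if (nrow(hits) == 0) {
    return(data.frame(contig_id = character(), reference_id = character(),
                      identity = numeric(), query_coverage = numeric(),
                      score = integer(), pass = logical(),
                      stringsAsFactors = FALSE))
  }
  identity <- hits$matches / hits$span
  cov <- hits$span / nchar(contigs)[hits$query]
  out <- data.frame(contig_id = names(contigs)[hits$query],
                    reference_id = names(references)[hits$db],
                    identity = identity, query_coverage = cov,
                    score = hits$score,
                    pass = identity >= min_identity & cov >= min_query_cov,
                    stringsAsFactors = FALSE)
  out[order(out$contig_id, out$reference_id), , drop = FALSE]
}
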