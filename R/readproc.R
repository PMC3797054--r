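# Read preprocessing and quantification: deduplication, rRNA filtering,
# pseudo-alignment with a mismatch budget, counting, RPKM normalization.

#' Remove PCR duplicate reads
#'
#' Duplicates are defined on the raw sequence only: all reads with an
#' identical sequence are assumed to derive from PCR duplication and only
#' the first occurrence is kept. A read and its reverse complement are not
#' sequence-identical and are both retained.
#'
#' @param reads read-set data frame (needs a `sequence` column).
#' @return list with `reads` (unique reads, first occurrences) and
#'   `n_removed`.
#' @export
dedupe_reads <- function(reads) {
  dup <- duplicated(reads$sequence)
  out <- reads[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, n_removed = sum(dup))
}

#' Count and remove rRNA reads
#'
#' A read is rRNA if it aligns to either strand of any rRNA reference
#' sequence with at most `max_mismatches` mismatches.
#'
#' @param reads read-set data frame.
#' @param rrna_ref named character vector of rRNA reference sequences.
#' @param max_mismatches mismatch budget.
#' @return list with `kept` (non-rRNA reads), `rrna_count` and
#'   `rrna_fraction`.
#' @export
filter_rrna <- function(reads, rrna_ref, max_mismatches = 2) {
  if (length(rrna_ref) == 0) stop("rrna_ref must be nonempty")
  n <- nrow(reads)
  if (n == 0) return(list(kept = reads, rrna_count = 0L, rrna_fraction = NaN))
  res <- rcpp_pseudo_align(reads$sequence, as.character(rrna_ref),
                           as.integer(max_mismatches), 16L)
  is_rrna <- res$status != 2L  # aligned anywhere in the rRNA reference
  kept <- reads[!is_rrna, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rrna_count = sum(is_rrna),
       rrna_fraction = sum(is_rrna) / n)
}

#' Pseudo-align reads to a transcript reference
#'
#' Finds, per read, all loci on both strands of the reference transcripts
#' with at most `max_mismatches` substitutions (exact-seed lookup followed
#' by ungapped verification; three disjoint 16-nt seeds guarantee at least
#' one exact seed for any 50-nt read within a 2-mismatch budget). Only loci
#' at the minimal mismatch count are retained; a read whose minimal-score
#' loci fall on more than one distinct transcript is discarded as
#' ambiguous.
#'
#' @param reads read-set data frame.
#' @param reference named character vector of transcript sequences.
#' @param max_mismatches mismatch budget (default 2).
#' @param seed_len exact-seed length.
#' @return data frame of alignments (`read_id`, `transcript_id`, `position`
#'   0-based, `strand`, `mismatches`) with attributes `n_input`,
#'   `n_ambiguous`, `n_unaligned`.
#' @export
pseudo_align <- function(reads, reference, max_mismatches = 2,
                         seed_len = 16) {
  if (is.null(names(reference)))
    stop("reference must be a named character vector")
  max_rl <- max(nchar(reads$sequence), 0L)
  short <- nchar(reference) < max_rl
  if (any(short))
    warning(sum(short), " reference sequence(s) shorter than the read",
            " length cannot host alignments")
  res <- rcpp_pseudo_align(reads$sequence, as.character(reference),
                           as.integer(max_mismatches), as.integer(seed_len))
  ok <- res$status == 0L
  out <- data.frame(
    read_id = reads$read_id[ok],
    transcript_id = names(reference)[res$ref[ok]],
    position = res$pos[ok],
    strand = ifelse(res$strand[ok] > 0, "+", "-"),
    mismatches = res$mismatches[ok],
    stringsAsFactors = FALSE)
  attr(out, "n_input") <- nrow(reads)
  attr(out, "n_ambiguous") <- sum(res$status == 1L)
  attr(out, "n_unaligned") <- sum(res$status == 2L)
  out
}

#' Count aligned reads per transcript and normalize to RPKM
#'
#' RPKM = raw count / (transcript length in kb x total mapped reads / 1e6).
#' Transcripts with no aligned reads are present with zero counts.
#'
#' @param alignments output of [pseudo_align()].
#' @param reference_lengths named integer vector of transcript lengths.
#' @return data frame (`transcript_id`, `length`, `raw_count`, `rpkm`) with
#'   attribute `total_mapped`.
#' @export
count_and_normalize <- function(alignments, reference_lengths) {
  total <- nrow(alignments)
  if (total == 0) stop("zero total mapped reads")
  raw <- table(factor(alignments$transcript_id,
                      levels = names(reference_lengths)))
  raw <- as.integer(raw)
  rpkm <- raw / ((reference_lengths / 1000) * (total / 1e6))
  out <- data.frame(transcript_id = names(reference_lengths),
                    length = as.integer(reference_lengths),
                    raw_count = raw, rpkm = as.numeric(rpkm),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total_mapped") <- total
  out
}

#' Squared Pearson correlation between replicate count tables
#'
#' Computed on log2(RPKM + 1) over transcripts nonzero in either table,
#' the standard transform for RNA-seq reproducibility summaries.
#'
#' @param table_a,table_b count tables from [count_and_normalize()] over the
#'   same transcript universe.
#' @return squared Pearson correlation in `[0, 1]`.
#' @export
replicate_r2 <- function(table_a, table_b) {
  if (!setequal(table_a$transcript_id, table_b$transcript_id))
    stop("count tables cover different transcript universes")
  b <- table_b[match(table_a$transcript_id, table_b$transcript_id), ]
  sel <- table_a$rpkm > 0 | b$rpkm > 0
  if (sum(sel) < 3) stop("fewer than 3 shared expressed transcripts")
  cor(log2(table_a$rpkm[sel] + 1), log2(b$rpkm[sel] + 1))^2
}

#' Fraction of reads aligning to a reference
#'
#' Counts reads with any alignment (either strand, within the mismatch
#' budget), including reads whose best placement is ambiguous across
#' reference entries: a merged multi-k assembly retains near-duplicate
#' fragments by construction, so a multi-mapped read still demonstrates
#' that its transcript is represented. (Quantification, in contrast,
#' discards ambiguous reads.)
#'
#' @param reads read-set data frame (unique, non-rRNA reads).
#' @param reference named character vector of reference sequences.
#' @param max_mismatches mismatch budget.
#' @return alignment rate in `[0, 1]`.
#' @export
alignment_rate <- function(reads, reference, max_mismatches = 2) {
  if (nrow(reads) == 0) return(NaN)
  res <- rcpp_pseudo_align(reads$sequence, as.character(reference),
                           as.integer(max_mismatches), 16L)
  mean(res$status != 2L)
}

#' Full per-library quantification
#'
#' Deduplicates, removes rRNA, pseudo-aligns to the reference and returns
#' counts plus the library statistics the pipeline reports (percent rRNA,
#' alignment rate, read-fate partition).
#'
#' @param reads read-set data frame.
#' @param reference named character vector of transcript sequences.
#' @param rrna_ref named character vector of rRNA sequences.
#' @param max_mismatches mismatch budget.
#' @return list with `counts` (count table), `alignments`, and `stats`
#'   (named list: n_input, n_unique, n_duplicates, rrna_count,
#'   rrna_fraction, n_aligned, n_ambiguous, n_unaligned, alignment_rate,
#'   total_mapped).
#' @export
quantify_library <- function(reads, reference, rrna_ref, max_mismatches = 2) {
  dd <- dedupe_reads(reads)
  rr <- filter_rrna(dd$reads, rrna_ref, max_mismatches)
  aln <- pseudo_align(rr$kept, reference, max_mismatches)
  counts <- count_and_normalize(aln, setNames(nchar(reference),
                                              names(reference)))
  stats <- list(
    n_input = nrow(reads),
    n_unique = nrow(dd$reads),
    n_duplicates = dd$n_removed,
    rrna_count = rr$rrna_count,
    rrna_fraction = rr$rrna_fraction,
    n_aligned = nrow(aln),
    n_ambiguous = attr(aln, "n_ambiguous"),
    n_unaligned = attr(aln, "n_unaligned"),
    alignment_rate = nrow(aln) / max(nrow(rr$kept), 1L),
    total_mapped = attr(counts, "total_mapped"))
  list(counts = counts, alignments = aln, stats = stats)
}
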