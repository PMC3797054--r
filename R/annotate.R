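# Triage of transcripts without orthologs: six-frame longest-ORF
# prediction, 3'UTR matching, paralog-band detection within scaffold
# clusters, and genome-mapping filters.

#' Longest ORF over six frames
#'
#' An ORF runs from an ATG to the first in-frame stop, or to the end of the
#' sequence if no stop follows (assembly fragments frequently truncate
#' ORFs; open-ended ORFs are counted). Length in amino acids excludes the
#' stop. The maximum over all six frames is reported; ties go to the plus
#' strand first, then the lower frame number.
#'
#' @param sequence a DNA string.
#' @return list: `longest_orf_aa`, `frame` (1..3, -1..-3 or `NA`),
#'   `strand`, `has_orf50`.
#' @export
#' @examples
#' longest_orf("ATGAAATAA")
longest_orf <- function(sequence) {
  L <- nchar(sequence)
  best_aa <- 0L; best_frame <- NA_integer_
  if (L >= 3) {
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      s <- if (fr > 0) sequence else revcomp(sequence)
      off <- abs(fr) - 1L
      n_cod <- (L - off) %/% 3L
      if (n_cod < 1L) next
      starts <- seq(off + 1L, by = 3L, length.out = n_cod)
      codons <- substring(s, starts, starts + 2L)
      atg <- which(codons == "ATG")
      if (!length(atg)) next
      stops <- which(codons %in% .STOP_CODONS)
      # first stop at or after each ATG; open-ended if none
      nxt <- stops[findInterval(atg, stops) + 1L]
      aa <- ifelse(is.na(nxt), n_cod - atg + 1L, nxt - atg)
      m <- max(aa)
      if (m > best_aa) { best_aa <- as.integer(m); best_frame <- fr }
    }
  }
  list(longest_orf_aa = best_aa, frame = best_frame,
       strand = if (is.na(best_frame)) NA_character_
                else if (best_frame > 0) "+" else "-",
       has_orf50 = best_aa >= 50L)
}

#' ORF reports for a set of transcripts
#'
#' @param sequences named character vector of DNA sequences.
#' @return data frame: `transcript_id`, `longest_orf_aa`, `frame`,
#'   `strand`, `has_orf50`.
#' @export
orf_table <- function(sequences) {
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%06d", seq_along(sequences))
  reps <- lapply(sequences, longest_orf)
  data.frame(transcript_id = names(sequences),
             longest_orf_aa = vapply(reps, `[[`, integer(1),
                                     "longest_orf_aa"),
             frame = vapply(reps, `[[`, integer(1), "frame"),
             strand = vapply(reps, `[[`, character(1), "strand"),
             has_orf50 = vapply(reps, `[[`, logical(1), "has_orf50"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summary statistics of an ORF report set
#'
#' @param reports output of [orf_table()].
#' @return named numeric vector: `fraction_any_orf`, `mean_orf_aa`,
#'   `fraction_orf50`.
#' @export
orf_summary <- function(reports) {
  if (nrow(reports) == 0) stop("empty report set")
  c(fraction_any_orf = mean(reports$longest_orf_aa > 0),
    mean_orf_aa = mean(reports$longest_orf_aa),
    fraction_orf50 = mean(reports$longest_orf_aa >= 50))
}

#' Match transcripts against a 3'UTR database
#'
#' TRUE if the best local nucleotide alignment (either strand, match +1 /
#' mismatch -1, ungapped Karlin-Altschul e-value) against any database
#' entry passes `evalue_max`.
#'
#' @param transcripts named character vector of DNA sequences.
#' @param utr_db named character vector of 3'UTR sequences.
#' @param evalue_max e-value threshold (default 1e-30, a high-quality
#'   match).
#' @param word,xdrop seed length and X-drop.
#' @return named logical vector over `transcripts`.
#' @export
utr_match <- function(transcripts, utr_db, evalue_max = 1e-30, word = 11,
                      xdrop = 20) {
  if (length(utr_db) == 0) stop("utr_db must be nonempty")
  if (is.null(names(transcripts)))
    names(transcripts) <- sprintf("seq%06d", seq_along(transcripts))
  hits <- rcpp_nt_search(as.character(transcripts), as.character(utr_db),
                         as.integer(word), xdrop)
  out <- setNames(rep(FALSE, length(transcripts)), names(transcripts))
  if (nrow(hits)) {
    m <- nchar(transcripts)[hits$query]
    n_db <- sum(nchar(utr_db))
    ev <- .evalue(hits$score, m, n_db, .ka$nucleotide)
    ok <- unique(hits$query[ev <= evalue_max])
    out[ok] <- TRUE
  }
  out
}

#' Detect collapsed paralogs within a scaffold cluster
#'
#' Computes the best pairwise local nucleotide identity between cluster
#' members and flags pairs whose identity falls inside the paralog band —
#' by default (0.88, 0.995), roughly the cited ~93% +/- 2.7% paralog
#' identity distribution with 100% excluded so same-gene redundancy is not
#' miscalled. A cluster with at least one flagged pair contains collapsed
#' paralogs.
#'
#' @param cluster_members named character vector (>= 2 sequences for a
#'   non-trivial result).
#' @param band numeric length-2: open identity interval flagged as
#'   paralogous.
#' @param word,xdrop seed length and X-drop for the pairwise search.
#' @return list with `pairs` (data frame: `id1`, `id2`, `identity`,
#'   `flagged`) and `cluster_flagged`.
#' @export
detect_paralogs <- function(cluster_members, band = c(0.88, 0.995),
                            word = 11, xdrop = 20) {
  empty <- data.frame(id1 = character(), id2 = character(),
                      identity = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE)
  if (length(cluster_members) < 2)
    return(list(pairs = empty, cluster_flagged = FALSE))
  if (is.null(names(cluster_members)))
    names(cluster_members) <- sprintf("m%04d", seq_along(cluster_members))
  hits <- rcpp_nt_search(as.character(cluster_members),
                         as.character(cluster_members),
                         as.integer(word), xdrop)
  hits <- hits[hits$query != hits$db, , drop = FALSE]
  # symmetrize: keep the best-scoring orientation per unordered pair
  if (nrow(hits)) {
    a <- pmin(hits$query, hits$db)
    b <- pmax(hits$query, hits$db)
    ord <- order(a, b, -hits$score)
    hits <- hits[ord, , drop = FALSE]
    a <- a[ord]; b <- b[ord]
    first <- !duplicated(paste(a, b))
    hits <- hits[first, , drop = FALSE]
    a <- a[first]; b <- b[first]
    identity <- hits$matches / hits$span
    pairs <- data.frame(id1 = names(cluster_members)[a],
                        id2 = names(cluster_members)[b],
                        identity = identity,
                        flagged = identity > band[1] & identity < band[2],
                        stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
  } else pairs <- empty
  list(pairs = pairs, cluster_flagged = any(pairs$flagged))
}

# evaluate one diagonal block: exact per-base comparison of the query
# against the genome along the block's diagonal span
.eval_block <- function(q, genome, qlo, qhi, diag) {
  glo <- qlo + diag
  span <- qhi - qlo
  qs <- substr(q, qlo + 1L, qhi)
  gs <- substr(genome, glo + 1L, glo + span)
  mm <- rcpp_hamming(qs, gs)
  c(matches = span - mm, span = span)
}

#' Map transcripts to a genome and apply the mapping filters
#'
#' Candidate loci are found by exact 31-mer seeds grouped into genomic
#' clusters (gap above `max_intron` starts a new locus); within a locus,
#' seeds on a common diagonal form an ungapped block whose identity is
#' evaluated base-by-base, and colinear blocks separated by at most
#' `max_intron` on the genome are chained (introns). A mapping is kept if
#' identity >= `min_identity`, query coverage >= `min_coverage` and
#' score (matches - mismatches) >= `min_score`; a transcript with more
#' than `max_loci` candidate loci is dropped as multi-locus.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param genome genome sequence (single string, or a
#'   `sim_transcriptome` genome list).
#' @param max_intron maximal genomic gap chained as an intron (bp).
#' @param min_identity,min_coverage,min_score,max_loci filter thresholds.
#' @param word exact seed length.
#' @return list with `mappings` (data frame of kept loci:
#'   `transcript_id`, `start`, `end`, `strand`, `identity`,
#'   `query_coverage`, `score`, `n_loci_total`) and `verdicts` (named
#'   character: `mapped`, `unmapped` or `multi_locus`).
#' @export
genome_map_filter <- function(transcripts, genome, max_intron = 20000,
                              min_identity = 0.95, min_coverage = 0.80,
                              min_score = 1000, max_loci = 2, word = 31) {
  if (is.list(genome)) genome <- genome$sequence
  if (!nzchar(genome)) stop("genome must be nonempty")
  if (is.null(names(transcripts)))
    names(transcripts) <- sprintf("tx%06d", seq_along(transcripts))
  seeds <- rcpp_genome_seeds(as.character(transcripts), genome,
                             as.integer(word))
  verdicts <- setNames(rep("unmapped", length(transcripts)),
                       names(transcripts))
  rows <- list()
  for (qi in seq_along(transcripts)) {
    sq <- seeds[seeds$query == qi, , drop = FALSE]
    if (nrow(sq) == 0) next
    qlen <- nchar(transcripts[[qi]])
    q_fwd <- transcripts[[qi]]
    q_rev <- revcomp(q_fwd)
    # candidate loci = colinear chains of ungapped diagonal blocks; a
    # repeated copy re-aligns the same query span on another diagonal and
    # therefore opens a new chain (a distinct locus)
    chains <- list()
    for (st in unique(sq$strand)) {
      ss <- sq[sq$strand == st, , drop = FALSE]
      ss <- ss[order(ss$gpos), , drop = FALSE]
      breaks <- cumsum(c(1L, diff(ss$gpos) > max_intron))
      for (lc in split(ss, breaks)) {
        q <- if (st > 0) q_fwd else q_rev
        dg <- lc$gpos - lc$qpos
        blocks <- lapply(split(lc, dg), function(b) {
          qlo <- min(b$qpos); qhi <- max(b$qpos) + word
          d <- b$gpos[1] - b$qpos[1]
          list(qlo = qlo, qhi = qhi, glo = qlo + d, ghi = qhi + d,
               diag = d)
        })
        blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "qlo"),
                               vapply(blocks, `[[`, numeric(1), "glo"))]
        local_chains <- list()
        for (b in blocks) {
          placed <- FALSE
          for (ci in seq_along(local_chains)) {
            prev <- local_chains[[ci]][[length(local_chains[[ci]])]]
            ov <- prev$qhi - b$qlo
            if (ov <= word && b$glo + max(ov, 0) >= prev$ghi &&
                (b$glo + max(ov, 0)) - prev$ghi <= max_intron) {
              if (ov > 0) {  # clip small junction overlap off the new block
                b$qlo <- b$qlo + ov
                b$glo <- b$glo + ov
              }
              if (b$qhi > b$qlo) {
                local_chains[[ci]][[length(local_chains[[ci]]) + 1L]] <- b
              }
              placed <- TRUE
              break
            }
          }
          if (!placed) local_chains[[length(local_chains) + 1L]] <- list(b)
        }
        for (ch in local_chains)
          chains[[length(chains) + 1L]] <- list(blocks = ch, strand = st,
                                                q = q)
      }
    }
    n_loci <- length(chains)
    if (n_loci > max_loci) {
      verdicts[qi] <- "multi_locus"
      next
    }
    for (ch in chains) {
      ev <- vapply(ch$blocks, function(b)
        .eval_block(ch$q, genome, b$qlo, b$qhi, b$diag), numeric(2))
      matches <- sum(ev["matches", ])
      span <- sum(ev["span", ])
      score <- matches - (span - matches)
      identity <- matches / span
      coverage <- span / qlen
      if (is.finite(identity) && identity >= min_identity &&
          coverage >= min_coverage && score >= min_score) {
        verdicts[qi] <- "mapped"
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = names(transcripts)[qi],
          start = min(vapply(ch$blocks, `[[`, numeric(1), "glo")),
          end = max(vapply(ch$blocks, `[[`, numeric(1), "ghi")),
          strand = if (ch$strand > 0) "+" else "-",
          identity = identity, query_coverage = coverage,
          score = score, n_loci_total = n_loci,
          stringsAsFactors = FALSE)
      }
    }
  }
  mappings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), strand = character(), identity = numeric(),
               query_coverage = numeric(), score = integer(),
               n_loci_total = integer(), stringsAsFactors = FALSE)
  rownames(mappings) <- NULL
  list(mappings = mappings, verdicts = verdicts)
}
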