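# Minimal multi-k de Bruijn unitig assembler and the merge step: pooling
# sub-assemblies, exact containment removal (either strand) and the
# minimum-length filter. Containment is exact-substring only, so
# near-identical paralogs are never merged.

#' Build unitigs from a read set at one k
#'
#' Constructs the de Bruijn graph over canonical k-mers observed at least
#' `min_count` times (libraries are unstranded, so a k-mer and its reverse
#' complement are one node) and reports the maximal non-branching paths.
#' Output order is deterministic (lexicographic by canonical sequence).
#'
#' @param reads read-set data frame or character vector of read sequences.
#' @param k k-mer size (must be below the read length to be useful).
#' @param min_count minimal k-mer multiplicity; the default of 2 prunes
#'   singleton k-mers, which are dominated by sequencing errors. Use 1 for
#'   error-free input.
#' @param err_ratio relative branch-pruning threshold: a k-mer is dropped
#'   when its count falls below `err_ratio` times the best count among
#'   k-mers differing in one terminal base (the same-position alternatives
#'   a sequencing error creates). An absolute `min_count` alone cannot
#'   prune errors on deeply covered transcripts, where every error k-mer
#'   recurs; the relative rule scales with local coverage, as the error
#'   pruning of production assemblers does. Same-count alternatives (true
#'   paralog variants) are never pruned. Set to 0 to disable.
#' @return data frame of contigs: `id`, `sequence`, `k`, `length`.
#' @export
build_unitigs <- function(reads, k, min_count = 2, err_ratio = 0.125) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  if (length(seqs) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      k = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  utg <- rcpp_build_unitigs(seqs, as.integer(k), as.integer(min_count),
                            err_ratio)
  if (length(utg) == 0) {
    warning("no k-mer passed min_count at k = ", k, "; empty assembly")
    return(data.frame(id = character(), sequence = character(),
                      k = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(id = sprintf("utg_k%02d_%06d", k, seq_along(utg)),
             sequence = utg, k = as.integer(k), length = nchar(utg),
             stringsAsFactors = FALSE)
}

#' Multi-k assembly: union of per-k unitig sets
#'
#' Runs [build_unitigs()] for every k in `k_list` and pools the results,
#' tagged by k, assembler run and source library. Assemblies over a range
#' of k capture transcripts across a wide range of expression levels: small
#' k bridges low coverage, large k resolves repeats. The default k list
#' pairs an odd series (17-41, run A) with an even series (20-40, run B),
#' mirroring a two-assembler multi-k design.
#'
#' @param reads read-set data frame or character vector.
#' @param k_list integer vector of k values.
#' @param min_count minimal k-mer multiplicity per sub-assembly.
#' @param err_ratio relative branch-pruning threshold (see
#'   [build_unitigs()]).
#' @param source_library label (`"dT"`, `"cap"`, `"combined"`, ...).
#' @param assembler_run optional per-k run labels; defaults to `"A"` for
#'   odd k and `"B"` for even k.
#' @return data frame of contigs: `id`, `sequence`, `k`, `length`,
#'   `assembler_run`, `source_library`.
#' @export
assemble_multi_k <- function(reads, k_list = c(seq(17, 41, 2), seq(20, 40, 2)),
                             min_count = 2, err_ratio = 0.125,
                             source_library = NA_character_,
                             assembler_run = NULL) {
  if (length(k_list) == 0) stop("k_list must be nonempty")
  if (is.null(assembler_run))
    assembler_run <- ifelse(k_list %% 2 == 1, "A", "B")
  assembler_run <- rep_len(assembler_run, length(k_list))
  parts <- lapply(seq_along(k_list), function(i) {
    ctg <- build_unitigs(reads, k_list[i], min_count, err_ratio)
    if (nrow(ctg)) {
      ctg$assembler_run <- assembler_run[i]
      ctg$source_library <- source_library
    } else {
      ctg$assembler_run <- character(0)
      ctg$source_library <- character(0)
    }
    ctg
  })
  out <- do.call(rbind, parts)
  out$id <- sprintf("%s_%s", ifelse(is.na(out$source_library), "ctg",
                                    out$source_library), out$id)
  rownames(out) <- NULL
  out
}

#' Merge contigs by exact containment removal
#'
#' Drops contigs shorter than `min_len`, then drops every contig that is an
#' exact substring (on either strand) of a strictly longer contig; among
#' equal-length duplicates (including reverse-complement duplicates) the
#' lexicographically smaller sequence is kept. The result is an antichain
#' under the substring order. Because only 100%-identity containment is
#' merged, paralogous sequences (typically ~93% identical) are always
#' retained separately.
#'
#' @param contigs contig data frame (from [assemble_multi_k()]) or
#'   character vector of sequences.
#' @param min_len minimal contig length retained.
#' @return an object of class `merged_assembly`: list with `contigs` (the
#'   retained rows), `stats` (length-class counts), `n_input`,
#'   `n_removed_short`, `n_removed_contained`.
#' @export
remove_contained <- function(contigs, min_len = 100) {
  if (is.character(contigs)) {
    contigs <- data.frame(id = sprintf("ctg%06d", seq_along(contigs)),
                          sequence = unname(contigs),
                          length = nchar(contigs), stringsAsFactors = FALSE)
  }
  n_input <- nrow(contigs)
  long <- contigs[nchar(contigs$sequence) >= min_len, , drop = FALSE]
  n_short <- n_input - nrow(long)
  keep <- if (nrow(long)) rcpp_contained_keep(long$sequence) else logical(0)
  out <- long[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(contigs = out, stats = assembly_stats(out$sequence),
                 n_input = n_input, n_removed_short = n_short,
                 n_removed_contained = nrow(long) - nrow(out)),
            class = "merged_assembly")
}

#' @export
print.merged_assembly <- function(x, ...) {
  cat("merged assembly:", nrow(x$contigs), "contigs (from", x$n_input,
      "input;", x$n_removed_short, "below length floor,",
      x$n_removed_contained, "contained)\n")
  print(x$stats)
  invisible(x)
}

#' Length-class counts of an assembly
#'
#' Counts contigs strictly longer than 100 bp, 0.5 kb, 1 kb and 5 kb.
#'
#' @param x a `merged_assembly`, contig data frame, or character vector.
#' @return named integer vector
#'   `c(gt_100bp, gt_500bp, gt_1kb, gt_5kb)`.
#' @export
assembly_stats <- function(x) {
  if (inherits(x, "merged_assembly")) x <- x$contigs
  lens <- if (is.data.frame(x)) nchar(x$sequence) else nchar(x)
  c(gt_100bp = sum(lens > 100), gt_500bp = sum(lens > 500),
    gt_1kb = sum(lens > 1000), gt_5kb = sum(lens > 5000))
}
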