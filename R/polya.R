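# Dual-capture poly(A) inference: mitosis:interphase ratios per capture
# method, quadrant classification, end-bias assessment, dispersion
# summaries, and the in-silico anchored-RT (TVN) control.

#' Mitosis:interphase abundance ratio
#'
#' @param count_M,count_IF normalized abundances (RPKM) in the mitotic and
#'   interphase libraries.
#' @return `count_M / count_IF` (vectorized; `Inf` when only the interphase
#'   side is zero, `NaN` when both are zero — such transcripts are excluded
#'   upstream by the read floor).
#' @export
mif_ratio <- function(count_M, count_IF) count_M / count_IF

#' Quadrant classification of poly(A) regulation
#'
#' Joint interpretation of the oligo-dT and cap-capture M:IF ratios.
#' A change confined to the dT side indicates a poly(A) tail change (the
#' cap side controls for abundance); a cap-side change indicates cap-level
#' regulation (decapping/recapping) and takes precedence, keeping poly(A)
#' calls conservative. Boundaries are inclusive toward the called class.
#'
#' @param dt_ratio,cap_ratio M:IF ratios (RPKM scale).
#' @param fold fold-change threshold (quadrant boundary).
#' @param read_floor_ok logical: did the transcript pass the read floor?
#' @return character vector of classes: `deadenylation_candidate`,
#'   `adenylation_candidate`, `cap_dependent_change`, `unchanged`,
#'   `low_coverage`.
#' @export
classify_polya <- function(dt_ratio, cap_ratio, fold = 2,
                           read_floor_ok = TRUE) {
  n <- max(length(dt_ratio), length(cap_ratio), length(read_floor_ok))
  dt_ratio <- rep_len(dt_ratio, n)
  cap_ratio <- rep_len(cap_ratio, n)
  read_floor_ok <- rep_len(read_floor_ok, n)
  bad <- is.na(dt_ratio) | is.na(cap_ratio) | !read_floor_ok
  cap_out <- !bad & (cap_ratio >= fold | cap_ratio <= 1 / fold)
  out <- rep("unchanged", n)
  out[cap_out] <- "cap_dependent_change"
  out[!bad & !cap_out & dt_ratio >= fold] <- "deadenylation_candidate"
  out[!bad & !cap_out & dt_ratio <= 1 / fold] <- "adenylation_candidate"
  out[bad] <- "low_coverage"
  out
}

#' Per-transcript poly(A) regulation calls from four count tables
#'
#' Computes M:IF ratios on the RPKM scale for both capture methods, applies
#' the read floor and the quadrant rule.
#'
#' The read floor requires `floor` raw mitotic reads in the cap library
#' (the abundance control) and `floor` raw reads on whichever side of the
#' dT libraries carries the signal (the maximum of the mitotic and
#' interphase raw counts): a transcript whose tail sits below the oligo-dT
#' anchor in one state yields no dT reads at all in that state, so
#' requiring mitotic dT coverage alone would make adenylation
#' (short-to-long) changes structurally uncallable.
#'
#' @param dt_M,dt_IF,cap_M,cap_IF count tables from
#'   [count_and_normalize()] for the four libraries.
#' @param fold fold-change threshold.
#' @param floor minimal raw read count (see Details).
#' @return data frame (`transcript_id`, `dt_ratio`, `cap_ratio`,
#'   `read_floor_ok`, `class`).
#' @export
polya_calls <- function(dt_M, dt_IF, cap_M, cap_IF, fold = 2, floor = 100) {
  ids <- dt_M$transcript_id
  align <- function(tab) tab[match(ids, tab$transcript_id), ]
  dt_IF <- align(dt_IF); cap_M <- align(cap_M); cap_IF <- align(cap_IF)
  dt_ratio <- mif_ratio(dt_M$rpkm, dt_IF$rpkm)
  cap_ratio <- mif_ratio(cap_M$rpkm, cap_IF$rpkm)
  floor_ok <- cap_M$raw_count >= floor &
    pmax(dt_M$raw_count, dt_IF$raw_count) >= floor
  data.frame(transcript_id = ids, dt_ratio = dt_ratio,
             cap_ratio = cap_ratio, read_floor_ok = floor_ok,
             class = classify_polya(dt_ratio, cap_ratio, fold, floor_ok),
             stringsAsFactors = FALSE)
}

#' 5'/3' quartile coverage bias
#'
#' Counts, per transcript, reads whose 5'-most aligned base (on the
#' transcript's sense strand; for a minus-strand read this is its rightmost
#' covered position) falls in the first or last 25% of the transcript, and
#' reports the pseudocounted ratio (5' + 1)/(3' + 1). Near-1 ratios
#' indicate full-length mRNA recovery rather than end-biased fragments.
#'
#' @param alignments output of [pseudo_align()].
#' @param reference_lengths named integer vector of transcript lengths
#'   (transcripts shorter than 8 nt are skipped).
#' @param read_length read length used for the minus-strand 5' end.
#' @return data frame (`transcript_id`, `count_5p`, `count_3p`, `ratio`).
#' @export
end_bias <- function(alignments, reference_lengths, read_length = 50) {
  reference_lengths <- reference_lengths[reference_lengths >= 8]
  five_end <- ifelse(alignments$strand == "+", alignments$position,
                     alignments$position + read_length - 1L)
  lens <- reference_lengths[alignments$transcript_id]
  q <- floor(lens / 4)
  in5 <- five_end < q
  in3 <- five_end >= lens - q
  ids <- factor(alignments$transcript_id, levels = names(reference_lengths))
  c5 <- as.integer(tapply(in5, ids, sum, default = 0L))
  c3 <- as.integer(tapply(in3, ids, sum, default = 0L))
  c5[is.na(c5)] <- 0L; c3[is.na(c3)] <- 0L
  data.frame(transcript_id = names(reference_lengths),
             count_5p = c5, count_3p = c3,
             ratio = (c5 + 1) / (c3 + 1), stringsAsFactors = FALSE)
}

#' Mean and sd of M:IF ratios for one capture method
#'
#' Summarizes the dispersion of mitosis:interphase ratios over
#' floor-passing transcripts with finite ratios. The oligo-dT side is
#' expected to disperse more than the cap side when poly(A) tails are
#' regulated while abundances are constant.
#'
#' @param calls output of [polya_calls()].
#' @param side `"dT"` or `"cap"`.
#' @return named numeric vector `c(mean, sd)`.
#' @export
dispersion_summary <- function(calls, side = c("dT", "cap")) {
  side <- match.arg(side)
  x <- if (side == "dT") calls$dt_ratio else calls$cap_ratio
  x <- x[calls$class != "low_coverage" & is.finite(x)]
  if (length(x) < 10) stop("fewer than 10 floor-passing transcripts")
  c(mean = mean(x), sd = sd(x))
}

#' In-silico anchored-RT (TVN) control
#'
#' An anchored oligo-dT primer of 18 Ts followed by V and N requires at
#' least 18 adenosines to prime; this predicate is the in-silico analog of
#' the TVN PCR product marking a minimal poly(A) tail.
#'
#' @param tail_len poly(A) tail length(s) in nt.
#' @param anchor_len anchor length (18 Ts).
#' @return logical: primeable by the anchored primer.
#' @export
#' @examples
#' tvn_control(c(150, 10, 18))
tvn_control <- function(tail_len, anchor_len = 18) {
  tail_len >= anchor_len
}
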