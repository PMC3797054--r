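#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T; other characters
#'   become `N`).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  out <- rcpp_revcomp(as.character(x))
  names(out) <- names(x)
  out
}

#' Write sequences to a FASTA file
#'
#' @param x named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.null(names(x))) names(x) <- sprintf("seq%05d", seq_along(x))
  dss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dss), names(dss))
}

#' Write simulated reads to FASTQ
#'
#' Qualities are a fixed run of `I` (Phred 40): the pipeline never uses
#' quality scores, and the simulator does not model them.
#'
#' @param reads a read set (data frame with `read_id` and `sequence`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file as a read-set data frame
#'
#' @param path FASTQ file path.
#' @return data frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(dss), sequence = as.character(dss),
             stringsAsFactors = FALSE)
}

#' Write the simulation ground truth as TSV
#'
#' @param sim a [simulate_transcriptome()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(sim, path) {
  cols <- c("id", "gene_id", "paralog_group", "biotype", "abundance",
            "tail_M", "tail_IF", "capped", "truth_class")
  write.table(sim$pool[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
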