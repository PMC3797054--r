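mk_reads <- function(seqs) {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("deduplication keeps first occurrences of identical sequences", {
  rd <- mk_reads(c("ACGT", "ACGT", "ACGT", "TTTT"))
  dd <- dedupe_reads(rd)
  expect_equal(nrow(dd$reads), 2L)
  expect_equal(dd$n_removed, 2L)
  expect_equal(dd$reads$read_id, c("r001", "r004"))

  all_distinct <- mk_reads(c("AAAA", "CCCC", "GGGG"))
  dd2 <- dedupe_reads(all_distinct)
  expect_equal(dd2$n_removed, 0L)
  expect_identical(dd2$reads, all_distinct)

  # reverse complements are not sequence-identical
  rc_pair <- mk_reads(c("AACCG", "CGGTT"))
  expect_equal(nrow(dedupe_reads(rc_pair)$reads), 2L)
})

test_that("rRNA filtering removes reads within the mismatch budget only", {
  set.seed(11)
  rrna <- c(rRNA = rdna(500))
  exact <- substr(rrna[[1]], 101, 150)
  three_mm <- exact
  for (p in c(5, 20, 40))
    substr(three_mm, p, p) <- chartr("ACGT", "CGTA", substr(three_mm, p, p))
  expect_equal(hamming_chr(exact, three_mm), 3L)
  other <- rdna(50)
  rd <- mk_reads(c(exact, three_mm, other))
  fr <- filter_rrna(rd, rrna)
  expect_equal(fr$rrna_count, 1L)
  expect_equal(fr$kept$sequence, c(three_mm, other))
})

test_that("rRNA carryover is recovered within binomial tolerance", {
  cfg <- sim_config(n_genes = 30, n_reads = 5e4, rrna_carryover = 0.02,
                    duplicate_rate = 0, error_rate = 0, seed = 8)
  sim <- simulate_transcriptome(cfg)
  rd <- simulate_library(sim, "M", "cap")
  fr <- filter_rrna(rd, sim$rrna)
  tol <- 3 * sqrt(0.02 * 0.98 / nrow(rd))
  expect_lt(abs(fr$rrna_fraction - 0.02), tol)
  # agrees with the truth channel
  expect_equal(fr$rrna_count, sum(rd$truth_id == "rRNA"))
})

test_that("pseudo-alignment handles unique, ambiguous and unaligned reads", {
  set.seed(12)
  t1 <- rdna(300); t2 <- rdna(300)
  ref <- c(a = t1, b = t2)
  rd <- mk_reads(c(substr(t1, 51, 100), rdna(50)))
  aln <- pseudo_align(rd, ref)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$transcript_id, "a")
  expect_equal(aln$position, 50L)
  expect_equal(aln$mismatches, 0L)
  expect_equal(attr(aln, "n_unaligned"), 1L)

  # a read present verbatim in two references is ambiguous and discarded
  ref2 <- c(a = t1, b = paste0(substr(t1, 1, 100), rdna(100)))
  aln2 <- pseudo_align(mk_reads(substr(t1, 26, 75)), ref2)
  expect_equal(nrow(aln2), 0L)
  expect_equal(attr(aln2, "n_ambiguous"), 1L)
})

test_that("pseudo-aligner agrees with a brute-force Biostrings scan", {
  set.seed(13)
  ref <- setNames(vapply(1:5, function(i) rdna(400), ""), paste0("t", 1:5))
  # reads: exact, 1-2 mismatches, reverse strand, cross-reference duplicates,
  # and unalignable
  reads <- character(0)
  for (i in 1:20) {
    src <- sample(5, 1); pos <- sample(350, 1)
    r <- substr(ref[[src]], pos, pos + 49)
    nmm <- sample(0:3, 1)
    if (nmm > 0) for (p in sample(50, nmm))
      substr(r, p, p) <- chartr("ACGT", "GTAC", substr(r, p, p))
    if (runif(1) < 0.5) r <- revcomp(r)
    reads <- c(reads, r)
  }
  reads <- c(reads, replicate(5, rdna(50)))
  res <- dualcap:::rcpp_pseudo_align(reads, unname(ref), 2L, 16L)
  for (i in seq_along(reads)) {
    oc <- oracle_align(reads[i], ref, 2)
    status <- c("aligned", "ambiguous", "unaligned")[res$status[i] + 1L]
    expect_equal(status, oc$status, info = paste("read", i))
    if (oc$status == "aligned") {
      expect_equal(res$ref[i], oc$ref, info = paste("read", i))
      expect_equal(res$mismatches[i], oc$mm, info = paste("read", i))
    }
  }
})

test_that("most noiseless simulated reads align to their truth transcript", {
  cfg <- sim_config(n_genes = 25, n_reads = 2e4, error_rate = 0,
                    duplicate_rate = 0, rrna_carryover = 0,
                    paralog_fraction = 0, seed = 14)
  sim <- simulate_transcriptome(cfg)
  rd <- simulate_library(sim, "M", "cap")
  ref <- setNames(sim$pool$sequence, sim$pool$id)
  aln <- pseudo_align(rd, ref)
  hit <- rd$truth_id[match(aln$read_id, rd$read_id)] == aln$transcript_id
  expect_gte(mean(hit), 0.99)
})

test_that("RPKM follows the formula and is scale invariant", {
  aln <- data.frame(read_id = sprintf("r%02d", 1:12),
                    transcript_id = c(rep("t1", 10), rep("t2", 2)),
                    position = 0L, strand = "+", mismatches = 0L)
  lens <- c(t1 = 1000L, t2 = 500L, t3 = 800L)
  ct <- count_and_normalize(aln, lens)
  expect_equal(ct$raw_count, c(10L, 2L, 0L))
  # raw / (kb * total/1e6)
  expect_equal(ct$rpkm[1], 10 / (1 * 12 / 1e6))
  expect_equal(ct$rpkm[3], 0)
  expect_equal(sum(ct$raw_count), attr(ct, "total_mapped"))
  doubled <- count_and_normalize(rbind(aln, aln), lens)
  expect_equal(doubled$rpkm, ct$rpkm)
  expect_error(count_and_normalize(aln[0, ], lens), "zero total")
})

test_that("replicate R2 is 1 for identical or rescaled tables", {
  tab <- data.frame(transcript_id = paste0("t", 1:10), length = 500L,
                    raw_count = 1:10, rpkm = (1:10) * 3.7)
  expect_equal(replicate_r2(tab, tab), 1.0)
  # rescaling is linear in log space up to the +1 pseudocount
  tab2 <- tab; tab2$rpkm <- tab$rpkm * 2
  expect_equal(replicate_r2(tab, tab2), 1.0, tolerance = 1e-3)
  small <- tab[1:2, ]
  expect_error(replicate_r2(small, small), "fewer than 3")
})

test_that("technical replicates from one extract correlate strongly", {
  mq <- medium_quant()
  sim <- mq$sim
  ref <- setNames(sim$pool$sequence, sim$pool$id)
  rd <- simulate_library(sim, "M", "cap", n_reads = 1e5, seed = 901)
  half <- seq_len(nrow(rd)) <= nrow(rd) / 2
  qa <- quantify_library(rd[half, ], ref, sim$rrna)
  qb <- quantify_library(rd[!half, ], ref, sim$rrna)
  expect_gte(replicate_r2(qa$counts, qb$counts), 0.95)
})

test_that("alignment rate is high for a complete reference, lower for subsets", {
  cfg <- sim_config(n_genes = 30, n_reads = 1e4, error_rate = 0,
                    duplicate_rate = 0, rrna_carryover = 0, seed = 15)
  sim <- simulate_transcriptome(cfg)
  rd <- simulate_library(sim, "M", "cap")
  ref <- setNames(sim$pool$sequence, sim$pool$id)
  full <- alignment_rate(rd, ref)
  expect_gte(full, 0.99)
  set.seed(1)
  sub <- ref[sample(length(ref), 21)]
  expect_lt(alignment_rate(rd, sub), full)
})

test_that("read fates partition the library", {
  mq <- medium_quant()
  st <- mq$quant$dT_M$stats
  expect_equal(st$n_input, st$n_unique + st$n_duplicates)
  expect_equal(st$n_unique,
               st$rrna_count + st$n_aligned + st$n_ambiguous +
                 st$n_unaligned)
})
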