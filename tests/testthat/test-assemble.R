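test_that("unitigs reconstruct a simple sequence from overlapping k-mers", {
  # all canonical 6-mers of s are unique (no inverted repeat, no palindrome)
  s <- "ATGACAGGCCGGAAA"
  reads <- substring(s, 1:8, 8:15)  # all 8-mers
  utg <- build_unitigs(reads, k = 6, min_count = 1)
  expect_equal(nrow(utg), 1L)
  expect_true(utg$sequence %in% c(s, revcomp(s)))
})

test_that("disjoint sequences yield disconnected, non-chimeric unitigs", {
  set.seed(30)
  s1 <- rdna(120); s2 <- rdna(120)
  reads <- c(substring(s1, 1:91, 30:120), substring(s2, 1:91, 30:120))
  utg <- build_unitigs(reads, k = 21, min_count = 1)
  expect_gte(nrow(utg), 2L)
  for (u in utg$sequence) {
    in1 <- grepl(u, s1, fixed = TRUE) || grepl(revcomp(u), s1, fixed = TRUE)
    in2 <- grepl(u, s2, fixed = TRUE) || grepl(revcomp(u), s2, fixed = TRUE)
    expect_true(xor(in1, in2) || (in1 && in2 && nchar(u) < 21))
  }
})

test_that("empty or over-pruned input gives an empty assembly", {
  expect_equal(nrow(build_unitigs(character(0), 21)), 0L)
  set.seed(29)
  expect_warning(utg <- build_unitigs(rdna(25), 21, min_count = 2),
                 "min_count")
  expect_equal(nrow(utg), 0L)
})

test_that("multi-k pooling is a tagged union of per-k assemblies", {
  set.seed(31)
  s <- rdna(200)
  reads <- tile_reads(c(t = s), 50, 3)$sequence
  single <- assemble_multi_k(reads, k_list = 21, min_count = 1)
  expect_equal(sort(single$sequence),
               sort(build_unitigs(reads, 21, 1)$sequence))
  both <- assemble_multi_k(reads, k_list = c(21, 30), min_count = 1)
  expect_lte(nrow(both), nrow(build_unitigs(reads, 21, 1)) +
               nrow(build_unitigs(reads, 30, 1)))
  expect_setequal(unique(both$assembler_run), c("A", "B"))
})

test_that("a repeat fragmenting one k is rescued by another in the pool", {
  set.seed(32)
  rep25 <- rdna(25)
  s <- paste0(rdna(80), rep25, rdna(60), rep25, rdna(80))
  reads <- tile_reads(c(t = s), 50, 1)$sequence
  pooled <- assemble_multi_k(reads, k_list = c(21, 31), min_count = 1)
  # the 25-nt internal repeat branches the k=21 graph but not k=31
  expect_false(any(build_unitigs(reads, 21, 1)$sequence %in%
                     c(s, revcomp(s))))
  expect_true(any(pooled$sequence %in% c(s, revcomp(s))))
})

test_that("containment merge removes substrings and keeps paralogs", {
  m <- remove_contained(c("ACGTACGTAA", "ACGTACGT", "GTAC"), min_len = 1)
  expect_equal(m$contigs$sequence, "ACGTACGTAA")
  set.seed(33)
  a <- rdna(200); b <- mutate_to_identity(a, 0.93)
  mp <- remove_contained(c(a, b), min_len = 1)
  expect_setequal(mp$contigs$sequence, c(a, b))
  # idempotence
  m2 <- remove_contained(mp$contigs$sequence, min_len = 1)
  expect_setequal(m2$contigs$sequence, mp$contigs$sequence)
  # reverse-complement containment and equal-length duplicate tie-break
  s <- rdna(120)
  m3 <- remove_contained(c(s, revcomp(substr(s, 10, 80))), min_len = 1)
  expect_equal(m3$contigs$sequence, s)
  d <- "AAACCCGGGTTTAAA"
  m4 <- remove_contained(c(d, revcomp(d)), min_len = 1)
  expect_equal(m4$contigs$sequence, min(d, revcomp(d)))
})

test_that("containment merge equals the brute-force oracle on random pools", {
  set.seed(34)
  for (trial in 1:20) {
    n_base <- sample(20:60, 1)
    pool <- vapply(seq_len(n_base), function(i) rdna(sample(15:80, 1)), "")
    extra <- character(0)
    for (i in sample(n_base, 15, replace = TRUE)) {
      s <- pool[i]
      lo <- sample(nchar(s) - 8, 1); hi <- min(nchar(s), lo + sample(8:40, 1))
      frag <- substr(s, lo, hi)
      if (runif(1) < 0.5) frag <- revcomp(frag)
      extra <- c(extra, frag)
    }
    dups <- pool[sample(n_base, 3)]
    all_seqs <- sample(c(pool, extra, dups, revcomp(dups[1])))
    got <- sort(remove_contained(all_seqs, min_len = 1)$contigs$sequence)
    expect_identical(got, oracle_remove_contained(all_seqs, 1),
                     info = paste("trial", trial))
  }
})

test_that("length-class statistics use strict thresholds", {
  set.seed(35)
  lens <- c(120, 600, 1200)
  seqs <- vapply(lens, rdna, "")
  expect_equal(unname(assembly_stats(seqs)), c(3L, 2L, 1L, 0L))
  expect_equal(unname(assembly_stats(character(0))), c(0L, 0L, 0L, 0L))
  expect_equal(unname(assembly_stats(rdna(100))), c(0L, 0L, 0L, 0L))
})

test_that("error-free tiling reads reconstruct repeat-free transcripts verbatim", {
  set.seed(36)
  sim <- simulate_transcriptome(
    sim_config(n_genes = 25, n_reads = 1000, paralog_fraction = 0, seed = 37))
  pool <- setNames(sim$pool$sequence, sim$pool$id)
  tr <- tile_reads(pool, 50, 7)
  ctg <- assemble_multi_k(tr, k_list = c(21, 31, 41), min_count = 1)
  merged <- remove_contained(ctg)
  rf <- dualcap:::rcpp_mark_unique_kmers(unname(pool), 40L)
  hits <- dualcap:::rcpp_substring_hits(unname(pool), merged$contigs$sequence)
  recon <- seq_along(pool) %in% hits$query
  expect_true(all(recon[rf]))
})
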