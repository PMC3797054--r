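test_that("longest ORF: starts, stops, open ends and frame tie-breaks", {
  r <- longest_orf("ATGAAATAA")
  expect_equal(r$longest_orf_aa, 2L)
  expect_equal(r$frame, 1L)
  expect_equal(r$strand, "+")
  # no ATG on either strand -> 0
  expect_equal(longest_orf(strrep("C", 60))$longest_orf_aa, 0L)
  # open-ended ORF counted to the sequence end
  r2 <- longest_orf("ATGGGG")
  expect_equal(r2$longest_orf_aa, 2L)
  # has_orf50 boundary
  long_orf <- paste0("ATG", strrep("GCA", 49))  # M + 49 aa, open-ended
  expect_true(longest_orf(long_orf)$has_orf50)
  expect_false(longest_orf(paste0("ATG", strrep("GCA", 48)))$has_orf50)
})

test_that("longest ORF agrees with the translation-based oracle", {
  set.seed(50)
  for (i in 1:200) {
    s <- rdna(sample(60:400, 1))
    expect_equal(longest_orf(s)$longest_orf_aa, oracle_longest_orf(s),
                 info = s)
  }
})

test_that("extending an open reading frame never shortens the call", {
  set.seed(51)
  core <- paste0("ATG", paste(rep("GAA", 10), collapse = ""))
  prev <- longest_orf(core)$longest_orf_aa
  s <- core
  for (i in 1:10) {
    s <- paste0(s, "GAT")
    cur <- longest_orf(s)$longest_orf_aa
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("ORF summaries aggregate correctly", {
  reports <- data.frame(transcript_id = c("a", "b", "c"),
                        longest_orf_aa = c(10L, 50L, 60L),
                        frame = 1L, strand = "+",
                        has_orf50 = c(FALSE, TRUE, TRUE))
  os <- orf_summary(reports)
  expect_equal(unname(os), c(1.0, 40.0, 2 / 3))
  zero <- reports; zero$longest_orf_aa <- 0L
  expect_equal(unname(orf_summary(zero)), c(0, 0, 0))
})

test_that("random sequences almost always contain some ORF", {
  set.seed(52)
  seqs <- setNames(vapply(1:300, function(i) rdna(500), ""),
                   sprintf("r%03d", 1:300))
  os <- orf_summary(orf_table(seqs))
  expect_gte(os[["fraction_any_orf"]], 0.95)
})

test_that("3'UTR matching passes verbatim fragments and rejects noise", {
  set.seed(53)
  sim <- small_sim()
  frag <- substr(sim$utr_db[[2]], 1, 200)
  rand <- vapply(1:20, function(i) rdna(200), "")
  res <- utr_match(setNames(c(frag, rand), c("real", paste0("r", 1:20))),
                   sim$utr_db)
  expect_true(res[["real"]])
  expect_false(any(res[-1]))
  # 60% identity over 50 nt is far from the 1e-30 bar
  weak <- paste0(mutate_to_identity(substr(sim$utr_db[[2]], 1, 50), 0.60),
                 rdna(150))
  expect_false(utr_match(setNames(weak, "weak"), sim$utr_db)[[1]])
})

test_that("paralog band flags ~93% pairs but not duplicates or distant pairs", {
  set.seed(54)
  base <- rdna(100)
  par <- base
  for (p in c(10, 25, 40, 55, 70, 85, 95))  # 7 interior substitutions
    substr(par, p, p) <- chartr("ACGT", "CGTA", substr(par, p, p))
  expect_equal(hamming_chr(base, par), 7L)
  dp <- detect_paralogs(c(a = base, b = par))
  expect_equal(dp$pairs$identity, 0.93, tolerance = 0.01)
  expect_true(dp$cluster_flagged)
  expect_false(detect_paralogs(c(a = base, b = base))$cluster_flagged)
  far <- mutate_to_identity(base, 0.80)
  expect_false(detect_paralogs(c(a = base, b = far))$cluster_flagged)
  expect_equal(nrow(detect_paralogs(c(a = base))$pairs), 0L)
})

test_that("paralog detector recovers pairs across the identity band", {
  set.seed(55)
  flags <- logical(0)
  for (i in 1:40) {
    idt <- runif(1, 0.89, 0.99)
    a <- rdna(sample(400:1200, 1))
    b <- mutate_to_identity(a, idt)
    flags <- c(flags, detect_paralogs(c(a = a, b = b))$cluster_flagged)
  }
  expect_gte(mean(flags), 0.95)
})

test_that("genome mapping keeps bona fide loci and drops repeats and decoys", {
  set.seed(56)
  tx <- rdna(1400)
  genome1 <- paste0(rdna(300), tx, rdna(300))
  gm <- genome_map_filter(c(q = tx), genome1)
  expect_equal(unname(gm$verdicts), "mapped")
  expect_equal(gm$mappings$identity, 1.0)
  expect_equal(gm$mappings$query_coverage, 1.0)
  expect_equal(gm$mappings$score, 1400)
  expect_equal(gm$mappings$start, 300)

  genome3 <- paste0(rdna(100), tx, rdna(150), tx, rdna(150), tx, rdna(100))
  expect_equal(unname(genome_map_filter(c(q = tx), genome3)$verdicts),
               "multi_locus")

  decoy <- mutate_to_identity(tx, 0.90)
  expect_equal(unname(genome_map_filter(c(q = decoy), genome1)$verdicts),
               "unmapped")

  # an intron-split copy is chained and mapped at full coverage
  gsplit <- paste0(rdna(200), substr(tx, 1, 700),
                   paste0("GT", rdna(800), "AG"),
                   substr(tx, 701, 1400), rdna(200))
  gm2 <- genome_map_filter(c(q = tx), gsplit)
  expect_equal(unname(gm2$verdicts), "mapped")
  expect_gte(gm2$mappings$query_coverage, 0.95)
  # but not when the gap exceeds the intron cap
  gm3 <- genome_map_filter(c(q = tx), gsplit, max_intron = 500)
  expect_equal(unname(gm3$verdicts), "unmapped")
})

test_that("short perfect matches fail the score floor by design", {
  set.seed(57)
  tx <- rdna(600)
  genome <- paste0(rdna(100), tx, rdna(100))
  gm <- genome_map_filter(c(q = tx), genome)
  expect_equal(unname(gm$verdicts), "unmapped")  # score 600 < 1000
  gm2 <- genome_map_filter(c(q = tx), genome, min_score = 500)
  expect_equal(unname(gm2$verdicts), "mapped")
})
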