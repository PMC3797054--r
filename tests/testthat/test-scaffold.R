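test_that("six-frame translation matches codon-table expectations", {
  expect_equal(six_frame_translate("ATGAAA")[["+1"]], "MK")
  expect_equal(six_frame_translate("TTTCAT")[["-1"]], "MK")
  tr <- six_frame_translate("ATGAAATAG")
  expect_equal(tr[["+1"]], "MK*")
  expect_error(six_frame_translate("AC"), "codon")
  # frame-length arithmetic: total residues across 6 frames
  set.seed(40)
  for (L in c(9, 10, 11, 30)) {
    s <- rdna(L)
    tot <- sum(nchar(six_frame_translate(s)))
    expect_equal(tot, 2 * (L %/% 3) + 2 * ((L - 1) %/% 3) +
                   2 * ((L - 2) %/% 3))
  }
})

test_that("translated search finds planted homology and rejects noise", {
  set.seed(41)
  sim <- small_sim()
  cod <- sim$pool[sim$pool$biotype == "coding", ][1, ]
  contig <- setNames(cod$sequence, cod$id)
  prot <- setNames(sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cod$sequence, cod$cds_start + 1,
                                 cod$cds_end))))), "P1")
  hits <- translated_search(contig, prot)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$s_start, 0L)
  expect_equal(hits$s_end, nchar(prot[[1]]))
  expect_gt(hits$bit_score, 100)
  # frame is +1 relative to the CDS offset
  expect_equal((hits$q_start - cod$cds_start) %% 3, 0)

  # empirical null: random contigs vs unrelated proteins never pass 1e-10
  aas <- setdiff(rownames(dualcap:::.blosum62()), c("*", "X", "B", "Z"))
  null_prot <- setNames(vapply(1:10, function(i)
    paste(sample(aas, 150, TRUE), collapse = ""), ""), paste0("np", 1:10))
  null_ctg <- setNames(vapply(1:100, function(i) rdna(300), ""),
                       paste0("nc", 1:100))
  expect_equal(nrow(translated_search(null_ctg, null_prot)), 0L)
})

test_that("tier assignment is sequential, not global best", {
  set.seed(42)
  sim <- small_sim()
  cod <- sim$pool[sim$pool$biotype == "coding", ][2, ]
  contig <- setNames(cod$sequence, "ctg1")
  cds <- substr(cod$sequence, cod$cds_start + 1, cod$cds_end)
  prot_exact <- sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(cds))))
  # a weaker (but still passing) tier-1 homolog: mutated back-translation
  cds_weak <- mutate_to_identity(cds, 0.85)
  prot_weak <- gsub("\\*", "A", as.character(
    Biostrings::translate(Biostrings::DNAString(cds_weak))))
  sc <- tiered_scaffold(contig,
                        list(tier1 = c(ref_weak = prot_weak),
                             tier2 = c(ref_exact = prot_exact),
                             tier3 = character(0)))
  expect_equal(sc$assignments$tier, 1L)
  expect_equal(sc$assignments$reference_id, "ref_weak")
  expect_equal(sc$assignments$member_name, "ref_weak.1")

  # tier-1 miss falls through to tier 2
  sc2 <- tiered_scaffold(contig,
                         list(tier1 = c(unrelated = strrep("W", 200)),
                              tier2 = c(ref_exact = prot_exact),
                              tier3 = character(0)))
  expect_equal(sc2$assignments$tier, 2L)
  # no passing hit anywhere -> unassigned
  sc3 <- tiered_scaffold(setNames(rdna(300), "junk"),
                         list(tier1 = c(ref_exact = prot_exact)))
  expect_equal(sc3$unassigned, "junk")
})

test_that("fragments of the same gene cluster on the same reference", {
  set.seed(43)
  sim <- simulate_transcriptome(
    sim_config(n_genes = 30, n_reads = 1000, paralog_fraction = 0,
               frac_ncrna = 0, tier_fractions = c(1, 0, 0), seed = 44))
  p <- sim$pool
  frags <- list()
  for (i in seq_len(nrow(p))) {
    cds_mid <- (p$cds_start[i] + p$cds_end[i]) %/% 2
    frags[[paste0(p$id[i], "_a")]] <- substr(p$sequence[i], 1, cds_mid + 80)
    frags[[paste0(p$id[i], "_b")]] <- substr(p$sequence[i], cds_mid - 80,
                                             p$length[i])
  }
  frags <- unlist(frags)
  sc <- tiered_scaffold(frags, sim$tiers)
  gene <- sub("_[ab]$", "", sc$assignments$contig_id)
  byg <- split(sc$assignments$reference_id, gene)
  both <- byg[lengths(byg) == 2]
  same <- vapply(both, function(x) x[1] == x[2], logical(1))
  expect_gte(mean(same), 0.95)
  expect_gte(length(both) / nrow(p), 0.9)
})

test_that("reference coverage is a clipped union", {
  expect_equal(reference_coverage(rbind(c(0, 40), c(60, 100)), 100), 0.8)
  expect_equal(reference_coverage(rbind(c(0, 50), c(25, 75)), 100), 0.75)
  expect_equal(reference_coverage(rbind(c(0, 100)), 100), 1.0)
  expect_equal(reference_coverage(matrix(numeric(0), ncol = 2), 100), 0)
  # adding a member never decreases coverage
  set.seed(45)
  r <- cbind(s <- sample(0:80, 10), s + sample(5:20, 10, TRUE))
  covs <- vapply(1:10, function(k)
    reference_coverage(r[1:k, , drop = FALSE], 100), numeric(1))
  expect_true(all(diff(covs) >= 0))
  expect_true(all(covs >= 0 & covs <= 1))
})

test_that("overlap counts enumerate every membership region", {
  v <- overlap_sets(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(v$count[v$region == "A"], 1L)
  expect_equal(v$count[v$region == "B"], 1L)
  expect_equal(v$count[v$region == "A&B"], 1L)
  same <- overlap_sets(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(same$count[same$region == "X&Y"], 2L)
  expect_equal(sum(same$count), 2L)
  disj <- overlap_sets(list(X = "a", Y = "b"))
  expect_equal(disj$count[disj$region == "X&Y"], 0L)
  expect_error(overlap_sets(list(A = "a")), "at least 2")
})

test_that("nucleotide homology applies the identity and coverage rules", {
  set.seed(46)
  ref <- rdna(1000)
  expect_true(nucleotide_homology(substr(ref, 200, 500), ref))
  mut <- mutate_to_identity(substr(ref, 200, 500), 0.70)
  expect_false(nucleotide_homology(mut, ref))
  half <- paste0(substr(ref, 1, 120), rdna(200))
  expect_false(nucleotide_homology(half, ref))  # 37% coverage at identity 1
})
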