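test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 20, n_reads = 2000, seed = 1)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a$pool, b$pool)
  expect_identical(a$genome, b$genome)
  expect_identical(a$tiers, b$tiers)
  la <- simulate_library(a, "M", "dT")
  lb <- simulate_library(b, "M", "dT")
  expect_identical(la, lb)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(n_genes = 5), "n_genes")
  expect_error(sim_config(rrna_carryover = 1.5), "fractions")
  expect_error(sim_config(paralog_fraction = -0.1), "fractions")
  expect_error(sim_config(dt_pmax = 0), "dt_pmax")
})

test_that("mutate_to_identity hits the exact Hamming target", {
  expect_identical(mutate_to_identity("ACGTACGTAC", 1.0), "ACGTACGTAC")
  set.seed(1)
  m <- mutate_to_identity("ACGTACGTAC", 0.9)
  expect_equal(hamming_chr("ACGTACGTAC", m), 1L)
  s100 <- rdna(100)
  m100 <- mutate_to_identity(s100, 0.93)
  expect_equal(hamming_chr(s100, m100), 7L)
  expect_error(mutate_to_identity("ACGT", 0), "target_identity")
})

test_that("oligo-dT capture curve: hard zero below anchor, saturating above", {
  expect_equal(capture_probability_dt(10, 18, 30, 1), 0)
  expect_equal(capture_probability_dt(17, 18, 30, 1), 0)
  expect_equal(capture_probability_dt(47, 18, 30, 1), 0.5)
  tails <- 0:400
  p <- capture_probability_dt(tails, 18, 30, 0.9)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p <= 0.9))
})

test_that("cap capture depends only on the cap, never the tail", {
  expect_equal(capture_probability_cap(TRUE, 0.8), 0.8)
  expect_equal(capture_probability_cap(FALSE, 0.8), 0)
})

test_that("paralog pairs land near the target identity distribution", {
  sim <- simulate_transcriptome(
    sim_config(n_genes = 100, paralog_fraction = 0.5, n_reads = 1000,
               seed = 7))
  grp <- split(seq_len(nrow(sim$pool)), sim$pool$paralog_group)
  expect_equal(length(grp), 25L)
  ids <- vapply(grp, function(ii)
    1 - hamming_chr(sim$pool$sequence[ii[1]], sim$pool$sequence[ii[2]]) /
      nchar(sim$pool$sequence[ii[1]]), numeric(1))
  expect_lt(abs(mean(ids) - 0.931), 3 * 0.0272)
  none <- simulate_transcriptome(
    sim_config(n_genes = 20, paralog_fraction = 0, n_reads = 1000, seed = 2))
  expect_true(all(is.na(none$pool$paralog_group)))
})

test_that("a pool with only sub-anchor tails is invisible to oligo-dT", {
  cfg <- sim_config(n_genes = 12, n_reads = 1000, frac_deadenylated = 0,
                    frac_adenylated = 0, frac_short_both = 1,
                    frac_ncrna = 0, seed = 3)
  sim <- simulate_transcriptome(cfg)
  expect_error(simulate_library(sim, "M", "dT"), "empty capturable pool")
  expect_silent(rd <- simulate_library(sim, "M", "cap"))
})

test_that("noiseless reads are exact substrings of their truth source", {
  cfg <- sim_config(n_genes = 15, n_reads = 2000, error_rate = 0,
                    duplicate_rate = 0, rrna_carryover = 0, seed = 4)
  sim <- simulate_transcriptome(cfg)
  rd <- simulate_library(sim, "IF", "cap")
  expect_true(all(nchar(rd$sequence) == 50))
  src <- setNames(sim$pool$sequence, sim$pool$id)[rd$truth_id]
  frag <- substring(src, rd$truth_pos + 1, rd$truth_pos + 50)
  minus <- rd$truth_strand == "-"
  expect_identical(rd$sequence[!minus], unname(frag[!minus]))
  expect_identical(rd$sequence[minus], unname(revcomp(frag[minus])))
})

test_that("cap libraries sample equal-abundance transcripts evenly", {
  cfg <- sim_config(n_genes = 10, n_reads = 1e5, abundance_sigma = 0,
                    frac_deadenylated = 0, frac_adenylated = 0,
                    frac_short_both = 0, frac_uncapped = 0, frac_ncrna = 0,
                    error_rate = 0, duplicate_rate = 0, rrna_carryover = 0,
                    seed = 6)
  sim <- simulate_transcriptome(cfg)
  rd <- simulate_library(sim, "M", "cap")
  cnt <- table(rd$truth_id)
  expect_equal(length(cnt), 10L)
  expect_lt(max(cnt) / min(cnt), 1.1)
})

test_that("truth labels always resolve and tails are state-consistent", {
  sim <- small_sim()
  rd <- simulate_library(sim, "M", "dT", n_reads = 5000)
  expect_true(all(rd$truth_id %in% c(sim$pool$id, "rRNA")))
  p <- sim$pool
  expect_identical(p$abundance, p$abundance)  # abundance shared across states
  expect_true(all(p$tail_M >= 0 & p$tail_IF >= 0))
  expect_true(all(p$tail_M[p$truth_class == "deadenylated"] >
                    p$tail_IF[p$truth_class == "deadenylated"]))
  expect_true(all(p$tail_M[p$truth_class == "adenylated"] <
                    p$tail_IF[p$truth_class == "adenylated"]))
})

test_that("tiling reads cover both sequence ends at uniform length", {
  s <- setNames(rdna(433), "t1")
  tr <- tile_reads(s, 50, 7)
  expect_true(all(nchar(tr$sequence) == 50))
  expect_equal(min(tr$truth_pos), 0L)
  expect_equal(max(tr$truth_pos), 433L - 50L)
})
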