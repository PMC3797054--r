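---
title: "Dual mRNA-capture RNA-seq: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual mRNA-capture RNA-seq: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dualcap)
```

# The scientific problem

Most mRNA-seq protocols purify mRNA away from ribosomal RNA by
hybridizing the poly(A) tail to oligo-dT. Capture efficiency, however,
depends on tail length, and anchored oligo-dT priming fails outright
below the anchor length (18 adenosines). Two consequences follow:

1. **Short-tailed mRNAs are under-sampled or invisible** to oligo-dT
   libraries, so a de novo transcriptome assembled from them is
   incomplete.
2. **Apparent abundance changes in oligo-dT libraries confound true
   abundance with tail length.** In a transcriptionally silent system —
   the frog egg extract arrested in meiotic metaphase ("M") versus the
   same extract released into interphase ("IF") — abundances cannot
   change, so any oligo-dT abundance change is evidence of tail-length
   regulation.

Capturing the same RNA through its 5' 7-methyl-guanosine cap (with a
cap-binding protein) is tail-independent. Pairing the two capture
chemistries therefore yields both a *control arm* (cap) that reports
abundance and a *sensor arm* (dT) that reports abundance × tail
capture. `dualcap` implements this dual-capture design end-to-end on
synthetic data: a generative model of the experiment, read processing
and quantification, the quadrant classifier for poly(A) regulation, a
multi-k de Bruijn assembler with a containment merge that preserves
paralogs, tiered translated-homology scaffolding, and the triage of
transcripts without orthologs.

# The generative model

`sim_config()` / `simulate_transcriptome()` generate a ground-truth
pool whose defaults define the package's reference experiment:

* **1,000 transcripts**, lengths log-uniform on 300–3,000 nt. Coding
  transcripts (95%) are built as 5'UTR + ORF + 3'UTR with a real start
  codon, no interior stop, and a stop codon, so translated search and
  ORF prediction see realistic structure; 5% are non-coding (no
  constructed ORF, absent from annotation tiers).
* **Paralog pairs**: 10% of transcripts belong to a pair whose second
  member is a substitution-only mutant of the first, with pairwise
  identity drawn from a normal distribution centered at 93.1%
  (sd 2.72%), truncated to (85%, 99.5%) — the hallmark of an
  allotetraploid transcriptome, and the reason the assembly merge
  demands 100% identity.
* **Planted regulation**: 6% of transcripts are deadenylated across the
  M→IF transition (tail 150 → 10 nt) and 4% adenylated (10 → 150 nt);
  5% carry a sub-anchor tail in both states (invisible to dT
  altogether) and 5% are uncapped (invisible to cap capture).
  Unregulated transcripts keep one tail length (uniform 60–200 nt) in
  both states. Abundances are log-normal (σ = 1.5, a wide but realistic
  dynamic range) and identical between states — transcriptional
  silence is the model's central assumption.
* **Capture model**: oligo-dT capture probability is a saturating
  hyperbola of tail length with a hard zero below the 18-A anchor,
  `p(L) = pmax · x/(x + h)` with `x = L − anchor + 1`, half-saturation
  `h = 30` nt, `pmax = 0.9`. Cap capture is `pcap = 0.85` for capped
  transcripts and 0 otherwise, independent of tail. The hyperbola is
  the simplest monotone model consistent with anchored-oligo chemistry;
  both parameters are exposed in the config. Cap-capture efficiency is
  not quantified by the underlying experiments, so `pcap` is a free
  parameter; the analysis depends only on its tail independence.
* **Libraries**: single-end 50 nt reads, starts uniform along the
  transcript (random-hexamer priming), strands random (unstranded
  protocol), per-base substitution errors at 0.5%, 10% of reads
  re-emitted verbatim (PCR duplicates), 2% residual rRNA; qualities are
  a constant `I` since nothing downstream uses them. 2×10⁶ reads per
  library, four libraries (M/IF × dT/cap), all deterministic under the
  config seed.

The simulator also emits a toy genome (one genomic copy per gene,
optionally split by a canonical GT…AG intron), a 6 kb rRNA precursor,
three ranked annotation tiers holding one reference protein per gene
*family* (70% / 15% / 10% of families; 5% absent everywhere — so
paralog pairs legitimately collapse onto a single ortholog entry, which
is what the paralog detector later has to diagnose), and a 3'UTR
database.

What the generator deliberately does **not** model: splice isoforms,
RNA secondary structure, fragment-size selection, quality-score
realism, positional coverage bias, or indel errors. Passing tests on
this synthetic data therefore demonstrate the pipeline's logic —
capture-bias arithmetic, graph construction, merge semantics, threshold
behavior — not robustness to every artifact of real libraries.

# Read processing and quantification

Reads are deduplicated on exact sequence (all identical reads are
treated as PCR duplicates), counted against rRNA and removed, then
pseudo-aligned to the reference with at most 2 substitutions on either
strand. The aligner uses three disjoint 16-nt exact seeds (offsets
0/17/34): with ≤2 mismatches in a 50-nt read at least one seed is
clean, by pigeonhole, so the seed stage is lossless. All minimal-
mismatch loci are found; a read whose best loci span more than one
transcript is discarded as ambiguous for *quantification* (fractional
assignment would break count integrality; the choice is conservative
for paralog-rich references). The *alignment rate*, in contrast,
counts any read with an alignment within budget, ambiguous or not —
against an intentionally redundant multi-k merged assembly a
multi-mapped read still shows its transcript is represented, which is
what a library-level "% aligned" measures.

Counts are normalized to RPKM (reads per kb per million mapped), and
replicate agreement is summarized as squared Pearson correlation of
log2(RPKM + 1) over transcripts expressed in either replicate — log
space with a pseudocount of one, the standard RNA-seq transform.

# The quadrant classifier

For each transcript the M:IF ratio is computed on the RPKM scale in
both arms. With `fold = 2`:

* cap ratio outside [0.5, 2] → **cap_dependent_change** (candidate
  decapping/recapping; takes precedence so poly(A) calls stay
  conservative),
* else dT ratio ≥ 2 → **deadenylation_candidate**,
* else dT ratio ≤ 0.5 → **adenylation_candidate**,
* otherwise **unchanged**. Boundaries are inclusive toward the called
  class.

**The read floor.** Ratios are only trusted for well-covered
transcripts. The floor implemented here requires ≥100 raw mitotic reads
in the cap library *and* ≥100 raw reads on the better-covered side of
the two dT libraries. The asymmetry on the dT side is forced by the
capture model: a transcript whose tail sits below the anchor in one
state yields exactly zero dT reads in that state, so demanding mitotic
dT coverage for every call would make short-to-long (adenylation)
changes structurally uncallable — the evidence for them lives in the
interphase dT library. The cap-side mitotic floor is kept as the
abundance control. Sensitivity and precision in
`evaluate_against_truth()` are reported over floor-passing
("evaluable") transcripts, because the classifier is defined only
there; unconditional sensitivities are reported alongside. Under the
log-normal abundance model roughly a tenth of transcripts sit below
the floor at 2×10⁶ reads per library.

Planted deadenylated transcripts produce an infinite dT ratio (zero
interphase dT signal); these are excluded from the dispersion summary
(mean and sample sd over finite ratios of floor-passing transcripts),
which is why the dT arm disperses strongly while the cap arm stays
tightly centered near 1 — the package's analog of the dT-versus-cap
variance asymmetry that motivates the dual-capture readout. The
`tvn_control()` predicate (tail ≥ 18) is the in-silico analog of the
anchored-RT (TVN) PCR control: transcripts whose control flips between
states should, and do, show elevated dT ratios.

End bias is assessed by assigning each read to the transcript quartile
containing its 5'-most base *on the sense strand* (for a minus-strand
read, its rightmost covered position) and reporting
(5' + 1)/(3' + 1) pseudocounted ratios. Under the uniform-start model
this statistic is symmetric — the strand-aware assignment exactly
cancels the edge effect that read length would otherwise induce — so a
median near 1 is the expected null, and deviations in real data would
indicate degraded or end-biased input.

# Assembly and the containment merge

`build_unitigs()` constructs the de Bruijn graph over canonical k-mers
(a k-mer and its reverse complement are one node — the libraries are
unstranded) and emits maximal non-branching paths, in deterministic
lexicographic order. Two pruning rules remove error k-mers:

* an absolute floor (`min_count = 2`) for the sparse regime, and
* **relative branch pruning** (`err_ratio = 1/8`): a k-mer is dropped
  when its count is below one-eighth of the best count among k-mers
  differing in one terminal base. Those are exactly the same-position
  alternatives a sequencing error creates at the ends of an error
  bubble. An absolute floor alone cannot work across a four-decade
  abundance range: on a transcript at thousands-fold coverage every
  specific error k-mer recurs and would otherwise shatter precisely
  the contigs that attract the most reads. Equal-count alternatives —
  true paralog variants under balanced coverage — are never pruned.

`assemble_multi_k()` unions per-k assemblies over the default k list
(odd 17–41 as run A, even 20–40 as run B, mirroring a two-assembler
multi-k design): small k bridges low coverage, large k resolves
repeats, and a transcript fragmented at one k is frequently rescued at
another. `remove_contained()` then drops contigs below 100 nt and
every contig that is an *exact* substring (either strand) of a longer
contig, keeping the lexicographically smaller of equal-length
duplicates. Containment at 100% identity — never "almost identical" —
is the load-bearing choice: ~93%-identical paralog pairs can never be
merged into one sequence, at the cost of a deliberately redundant
assembly. An O(n²) brute-force both-strand scan serves as the oracle
for this operation in the tests.

One caveat surfaced by the oracle work: canonical k-mer graphs fold a
sequence onto its reverse complement, so a transcript containing an
inverted repeat of length ≥ k−1 (or a k-mer palindrome at even k) is
*not* reconstructible as a single unitig at that k — the graph
legitimately branches. Reconstruction guarantees are therefore stated
for transcripts whose canonical (k−1)-mers are unique across the pool
("repeat-free"), checked at the largest odd k (41). Paralog pairs
typically share 40-mer runs and fall outside the guarantee, by design:
their variant-containing fragments are preserved separately, which the
zero-collapse check verifies.

# Tiered scaffolding and homology

`translated_search()` is a BLASTX-style translated search: all six
reading frames (literal translation, stops as `*`, no initiator-codon
substitution), exact 4-mer peptide seeds, ungapped BLOSUM62 extension
with an X-drop of 20, bit scores from ungapped Karlin–Altschul
statistics (λ = 0.3176, K = 0.134), and
e-value = (contig residues × database residues) · 2^(−bits). Gapped
alignment and HSP chaining are out of scope; only threshold behavior at
the 1e-10 (scaffolding) and 1e-30 (UTR) cutoffs matters to the
pipeline, and the empirical nulls in the tests confirm random
sequence never crosses them.

`tiered_scaffold()` assigns contigs *sequentially*: tier 1 first, the
remainder to tier 2, then tier 3 — a passing tier-1 hit always beats a
stronger tier-2 hit. This mirrors ranked annotation transfer (a
well-annotated close relative first, gene predictions second, a
distant proteome last) and makes tier-1 assignments independent of the
content of later tiers. Members are renamed `<reference>.<n>` and
best-hit ties are broken deterministically (e-value, then score, then
reference id). Cluster coverage is the union of member reference
ranges over the reference length. `nucleotide_homology()` implements
the 80%-identity / 50%-query-coverage rule on the best ungapped local
nucleotide alignment (+1/−1 scoring, either strand).

# Triage of unannotated transcripts

* `longest_orf()` scans all six frames for ATG-to-stop ORFs;
  an ORF left open by the sequence end **is** counted, because
  assembly fragments frequently truncate real ORFs and dropping them
  would bias lengths down (a documented switch of interpretation —
  the external predictor this replaces does not publish its exact
  rule, so the definition here is stated and oracle-tested rather
  than claimed identical). A brute-force
  translation-and-regex enumeration is the oracle.
* `utr_match()` reuses the nucleotide search with ungapped
  Karlin–Altschul statistics (λ = ln 3 exactly for +1/−1 scoring at
  equal base frequencies; K ≈ 0.35, an approximation acceptable
  because only the 1e-30 threshold matters).
* `detect_paralogs()` flags member pairs whose best local identity
  falls in the open band (0.88, 0.995) — roughly the paralog identity
  mean ± 2 sd, with 100% excluded so same-gene redundancy (identical
  or rc-identical contigs) is never miscalled as paralogy.
* `genome_map_filter()` finds candidate loci from exact 31-mer seeds,
  evaluates each diagonal block base-by-base, chains colinear blocks
  across genomic gaps up to 20 kb (introns; small junction overlaps
  are clipped), and applies four filters: identity ≥ 95%, query
  coverage ≥ 80%, score (matches − mismatches) ≥ 1000, and at most 2
  candidate loci. A repeated copy re-aligns the same query span on a
  new diagonal and therefore opens a new candidate locus, which is how
  3-copy plants are recognized as multi-locus. The score floor
  deliberately discards perfect matches shorter than 1 kb — that is
  the filter's published semantics, not an accident, and the tests pin
  it. The mapper is block-based, not a spliced aligner; that is
  sufficient for filter semantics on substitution-only toy genomes.

# Numerical and engineering choices

Coordinates are 0-based half-open throughout. All tie-breaks are
deterministic (documented per function). The read-level and k-mer
kernels are in C++ (Rcpp): 2-bit packed k-mers with a 64-bit fast path
for k ≤ 31 and 128-bit arithmetic above, hashed seed indexes for
alignment and containment, and strided w-mer indexes for substring
queries. Every kernel is shadowed by an independent R-side oracle in
the test suite (Biostrings `matchPattern` for the aligner, vectorized
`grepl` for containment, translation + regex for ORFs).

Problem sizes used by the packaged checks: the reference dual-capture
experiment (1,000 transcripts, 4 × 2×10⁶ reads) for the poly(A) arm;
tiling error-free reads over the same pool for assembler
reconstruction; a 300-transcript / 2×10⁵-read experiment with 20%
sub-anchor-tail and 10% uncapped transcripts for the combined-capture
gain; 100 random pools of ≤500 contigs for the containment oracle; and
1,000 random sequences for the ORF oracle. These sizes give stable
statistics for every rate while keeping a full run in minutes on one
core.

# Known limitations

* The capture model is phenomenological; absolute tail lengths are not
  estimated (the method detects relative change only), and gel-based
  assays have no in-silico counterpart beyond the TVN predicate.
* Ambiguous-read discarding slightly deflates counts for paralog
  pairs; fractional assignment is noted as a switchable alternative
  but not implemented.
* The assembler has no bubble popping, scaffolding with paired ends,
  or coverage-based isoform resolution; redundancy is resolved only by
  exact containment.
* Translated search reports a single best HSP per contig–reference
  pair; multi-HSP chaining across frame shifts is not attempted.
* Relative branch pruning can, in principle, erase variant k-mers of a
  paralog whose partner is more than ~8× more abundant in a noisy
  library; the preservation guarantee is stated for balanced coverage.
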