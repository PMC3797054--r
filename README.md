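# dualcap

Dual mRNA-capture RNA-seq analysis on synthetic data: inference of
poly(A) tail-length regulation from paired oligo-dT / 5'-cap capture
libraries, multi-k de novo assembly with a paralog-preserving
containment merge, tiered translated-homology scaffolding, and triage
of transcripts without orthologs.

## Who this is for and what it does

Oligo-dT selection — the standard way to purify mRNA away from rRNA —
captures an mRNA with efficiency that depends on its poly(A) tail, and
anchored priming fails entirely below ~18 adenosines. Capturing the
same RNA through its 5' cap is tail-independent. In a
transcriptionally silent system (egg extract arrested in meiotic
metaphase, "M", versus the same extract released into interphase,
"IF") abundances cannot change, so the two capture arms disentangle
two phenomena:

* the **cap arm** reports abundance (the control),
* the **dT arm** reports abundance × tail capture (the sensor),

and their mitosis:interphase (M:IF) ratio pair classifies each
transcript by a **quadrant rule** at a two-fold threshold:

| cap M:IF in [1/2, 2] | dT M:IF ≥ 2 | dT M:IF ≤ 1/2 | call |
|---|---|---|---|
| yes | yes | — | deadenylation candidate |
| yes | — | yes | adenylation candidate |
| no  | — | — | cap-dependent change (decapping/recapping) |
| yes | no | no | unchanged |

Because each capture method also sees a different subset of the
transcriptome (dT misses sub-anchor tails, cap misses uncapped RNAs),
the package also implements the assembly side of the design: a
multi-k de Bruijn unitig assembler (canonical k-mers, odd k 17–41 and
even k 20–40 runs), a merge that removes only contigs contained at
**100% identity** in a longer contig — so ~93%-identical paralog pairs
(the signature of an allotetraploid transcriptome) are never
collapsed — BLASTX-style tiered scaffolding against ranked reference
protein sets (e-value ≤ 1e-10, sequential tier precedence), and
annotation triage of the remainder: six-frame longest-ORF prediction,
3'UTR matching (e ≤ 1e-30), paralog-band detection (identity in
(0.88, 0.995)), and genome-mapping filters (identity ≥ 95%, coverage
≥ 80%, score ≥ 1000, ≤ 2 loci, introns ≤ 20 kb).

Everything runs against a ground-truth simulator
(`simulate_transcriptome()` / `simulate_library()`) that generates the
whole experiment — transcript pool with paralog pairs and planted tail
regulation, capture-biased libraries with errors/duplicates/rRNA, toy
genome, annotation tiers — so every stage is testable without any
download. The simulator is first-class, tested code: its capture model
(saturating tail-dependent dT curve with a hard zero below the 18-A
anchor; tail-independent cap capture) is the package's generative
counterpart of the analysis assumptions.

## Worked example

```r
library(dualcap)

cfg <- sim_config(n_genes = 120, n_reads = 1e5, seed = 42)
run <- run_all(cfg, k_list = c(21, 25, 31, 20, 26, 30))
print(run)
#> dual-capture pipeline run (seed 42 )
#>   rRNA fractions: dT_M=0.026 dT_IF=0.027 cap_M=0.026 cap_IF=0.027
#>   M:IF dispersion: dT sd = 0.236 ; cap sd = 0.083
#>
#>   adenylation_candidate deadenylation_candidate            low_coverage
#>                       5                       4                      35
#>               unchanged
#>                      76
```

The class counts are the quadrant calls over the 120 transcripts: the
planted tail changes are recovered (subject to the 100-read floor —
`low_coverage` marks transcripts too weakly covered to call), the dT
arm disperses ~3× more than the cap arm, and residual rRNA sits near
the simulated 2% carryover.

```r
ev <- evaluate_against_truth(run)
ev$deadenylation[c("sensitivity", "precision")]   # 1, 1  (4 evaluable of 7 planted)
ev$adenylation[c("sensitivity", "precision")]     # 1, 1
round(ev$assembly_recall, 3)
#>       dT      cap combined
#>    0.900    0.917    0.967
run$report$tier_yield           # contigs assigned per annotation tier
#>   1   2   3
#> 203  40  35
round(run$annotate$orf_summary, 3)
#> fraction_any_orf      mean_orf_aa   fraction_orf50
#>            0.989           49.728            0.207
```

`assembly_recall` is the fraction of truth transcripts matched (at 80%
identity over 50% of the contig) by each merged assembly: the combined
dT∪cap assembly recovers more of the transcriptome than either capture
method alone, which is the design's central claim. Of the contigs
left unassigned by the tiered scaffold, almost all encode *some* ORF
(as random sequence does), a fifth encode ≥50 aa, and the ORF/UTR/
genome triage decides which are plausible novel transcripts versus
fragments.

Individual stages are exported (`dedupe_reads()`, `filter_rrna()`,
`pseudo_align()`, `count_and_normalize()`, `polya_calls()`,
`build_unitigs()`, `remove_contained()`, `translated_search()`,
`tiered_scaffold()`, `longest_orf()`, `genome_map_filter()`, ...) and
compose exactly as `run_all()` does; see the methods vignette
(`vignettes/dual-capture-methods.Rmd`) for the models, thresholds and
design rationale.

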