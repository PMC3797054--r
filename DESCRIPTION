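Package: dualcap
Title: Dual mRNA-Capture RNA-Seq: Poly(A) Tail Regulation Calling and De
    Novo Transcriptome Assembly Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of combined oligo-dT and 5'-cap mRNA
    capture sequencing experiments. Generates ground-truth toy
    transcriptomes with paralog pairs, cell-cycle dependent poly(A) tail
    lengths and capture-method dependent sampling bias; quantifies
    libraries by pseudo-alignment with a mismatch budget; infers poly(A)
    tail length regulation from dual-capture mitosis:interphase count
    ratios via quadrant classification; assembles reads with a multi-k de
    Bruijn unitig assembler and merges sub-assemblies by exact containment
    removal so near-identical paralogs survive; scaffolds contigs against
    tiered reference protein sets with a translated seed-and-extend
    search; and triages unannotated transcripts by six-frame ORF
    prediction, 3'UTR matching and genome-mapping filters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
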