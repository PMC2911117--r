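Package: repeatenrich
Title: Enrichment Analysis of Repetitive Elements from Short-Read ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates ChIP-seq enrichment of annotated repetitive elements
    (transposable elements, satellites, tRNA repeats) from short single-end
    reads. Reads are aligned with full sensitivity at a small mismatch budget
    against repeat assemblies built from canonical (consensus) sequences and
    RepeatMasker-annotated genomic instances, and assigned to a repeat type
    only when every equal-best alignment falls within that type. Fold
    enrichment over an input library is estimated under a Poisson model with
    a non-informative half-count prior, with F-distribution confidence
    intervals and capped Z-scores; an input-free relative normalization
    scores each repeat type against the trimmed Gaussian of its scaled read
    proportions across many chromatin marks. A greedy read-set phylogeny
    groups homologous repeat sequences bottom-up to maximize the number of
    uniquely assignable reads, annotating every node with the reads gained
    and its enrichment estimate. A seeded simulator generates genomes with
    planted repeat families, positional sequencing-error models and SNPs for
    calibration and mis-assignment-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
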