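# repeatenrich

Estimating ChIP-seq enrichment of repetitive elements — transposable
elements, endogenous retroviruses, satellites, tRNA repeats — from short
single-end reads, for epigenomics groups who need the half of the genome
that unique-alignment pipelines throw away.

## What it does

Standard ChIP-seq analysis discards multi-mapping reads, so the chromatin
state of repeats goes unmeasured. `repeatenrich` keeps a multi-mapped read
whenever **all** of its equal-best alignments fall within a single repeat
type, aligning reads against per-type *repeat assemblies* built from the
canonical (consensus) sequence plus every RepeatMasker-annotated genomic
instance with 13-bp flanks, with segments separated by 80-`N` spacers.
Alignment is full-sensitivity ungapped search at a ≤1-mismatch budget
(pigeonhole seeding, every hit reported). An optional masking step drops
reads that also map outside the annotated instances of their type.

Fold enrichment of a repeat set over an input library is a ratio of
Poisson rates with a half-count prior:

θ̂ = C·(s + ½) / (S·(c + ½)),  with CI bounds λ(x) = θ̂ · F[x; 2(s+½), 2(c+½)]

where `s`, `c` are ChIP and control reads assigned to the set and `S`, `C`
the effective dataset sizes (reads mapping to genome or canonical
sequences). Significance is also reported as a signed Z-score capped at
±10 (Z = 3.1 ⇔ one-sided P = 10⁻³). For experiments without an input
library, a repeat type is instead scored against the trimmed Gaussian of
its scaled read proportions across many chromatin marks (Beta-posterior
resampling, top-5 marks trimmed).

A greedy **enrichment phylogeny** merges repeat sets bottom-up by read-set
similarity (Jaccard index of aligned reads), so reads ambiguous between
related types become uniquely assignable at internal nodes; every node
carries the unique reads *gained* by its merge (branch length
`log10(1 + gain)`) and its own enrichment estimate. Instance-level trees do
the same for the individual copies of one type. A seeded simulator
generates genomes with planted repeat families, positional sequencing-error
models and SNPs, for calibration and mis-assignment-rate studies.

## Worked example

Simulate a small genome with a fourfold-enriched ERV-like family and a null
SINE-like family, then recover both:

```r
library(repeatenrich)

fam <- data.frame(name = c("ERVtest", "SINEtest"), canonical_len = c(400, 250),
                  n_instances = c(3, 2), divergence = 0.1,
                  frac_unannotated = 0, theta = c(4, 1))
d <- synth_dataset(synth_spec(fam, genome_bg_len = 12000L,
                              n_chip = 4000L, n_input = 4000L, seed = 42))

inst <- extract_instance_sequences(d$genome, d$instances, flank_bp = 13)
asm  <- build_assembly(d$canonicals, inst, mode = "combined")

chip_hits  <- align_all_hits(d$chip, asm)
input_hits <- align_all_hits(d$input, asm)
chip_asg   <- assign_to_types(chip_hits, d$chip$read_id)
input_asg  <- assign_to_types(input_hits, d$input$read_id)

S <- effective_dataset_size(d$chip, d$genome, d$canonicals)   # 4000
C <- effective_dataset_size(d$input, d$genome, d$canonicals)  # 4000
sc <- count_reads_by_type(chip_asg, fam$name)
cc <- count_reads_by_type(input_asg, fam$name)
estimate_enrichment(sc$type, sc$n_assigned, cc$n_assigned, S, C)
#>     set_id    s   c    S    C   mle ci_low ci_high zscore significant
#> 1  ERVtest 1359 332 4000 4000 4.089  3.634    4.62  10.00        TRUE
#> 2 SINEtest  157 177 4000 4000 0.887  0.715    1.10  -1.04       FALSE
```

The planted fourfold enrichment is recovered (θ̂ = 4.09, 95% CI 3.63–4.62,
Z capped at 10) and the null family is correctly not called (CI spans 1).
The enrichment phylogeny over the same hits shows where reads become
uniquely assignable:

```r
tree <- annotate_tree(build_tree(fam$name, chip_hits), input_hits, S = S, C = C)
tree$nodes[, c("node_id", "n_unique", "gain", "mle", "zscore")]
#>    node_id n_unique gain   mle zscore
#> 1  ERVtest     1359 1359 4.089  10.00
#> 2 SINEtest      157  157 0.887  -1.04
#> 3    node1     1516    0 2.976  10.00
write_newick(tree, "ervtest_tree.nwk")  # plus ervtest_tree.nwk.tsv annotations
```

The two families are well separated at this divergence, so the root merge
gains no additional reads (`gain = 0`); closely related types would show
large gains at their common ancestor.

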