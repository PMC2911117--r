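---
title: "Estimating chromatin enrichment of repetitive elements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chromatin enrichment of repetitive elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatenrich)
```

# The problem

Standard ChIP-seq analysis keeps only uniquely aligned reads, which silences
exactly the part of the genome where transposable elements, endogenous
retroviruses, satellites and other repeats live. Yet a read that aligns to
several places can still be informative: if *every* equally good alignment
falls within copies of the same repeat type, the read unambiguously reports
on that type, even though its precise genomic copy is unknown. This package
estimates per-repeat-type (and per-repeat-set) enrichment by exploiting
that observation.

# Repeat assemblies

Alignment targets are built per repeat type from two sources: the canonical
(consensus) sequence from a Repbase-style library, and the genomic instances
annotated by RepeatMasker, each extended by `flank_bp` of genomic context.
The default flank is 13 bp — half of a typical short read — so that a read
straddling an instance boundary can still align within the flanked instance;
without flanks such boundary reads would be lost, and with much larger
flanks unique flanking sequence would start to dominate. The flank is a
parameter (`floor(read_length / 2)` is the natural choice for other read
lengths).

In the `combined` mode each repeat type becomes one record: canonical, then
every flanked instance, separated by blocks of 80 `N`s. Because any base
outside `{A,C,G,T}` mismatches everything, no read of up to the spacer
length can bridge two segments at a ≤1-mismatch budget, so a record behaves
like a bag of independent segments while keeping per-type bookkeeping
trivial. `canonical` and `instance` modes keep only the respective halves,
which is what the canonical-vs-instance agreement analysis compares.
Coordinates are 0-based half-open internally; RepeatMasker input (1-based
inclusive, `C` for minus strand) is converted on read, and BED exports are
0-based half-open. Minus-strand instances are stored as plus-strand genomic
slices; strand is handled by aligning each read in both orientations.
Overlapping annotations of different types are kept verbatim — the
assignment rule resolves any resulting ambiguity, and no merging rule is
imposed.

# Alignment and read assignment

`align_all_hits()` reports *every* ungapped placement of every read, both
strands, with at most `max_mismatch` (default 1) mismatches. Full
sensitivity comes from pigeonhole seeding: a read is split into
`max_mismatch + 1` contiguous seeds, so at the budget at least one seed
matches exactly; seeds are batch-matched exactly (Biostrings `PDict`) and
candidate placements verified by direct comparison. Quality strata are
defined solely by mismatch count — for ungapped equal-length alignments
there is no other score. Reads containing `N` take a slower general path in
which non-ACGT letters mismatch everything (consistent with the spacers).

A read is then **assigned** to a repeat type when all of its best-stratum
hits fall within that type's record (multiple positions within the type are
fine); reads whose best stratum spans two or more types are
**cross-type ambiguous** and excluded from per-type counts (they are
retained with their hit-type sets, because merged tree nodes can recover
them); reads with no hits are **unmapped**. PCR duplicates are not
collapsed by default. The optional **masking** step additionally discards an
assigned read when it has an equal-or-better genome alignment outside the
flanked annotated instances of its type — protecting against un-annotated,
typically fragmented repeat copies that RepeatMasker's thresholds missed.
Strictly worse outside hits do not mask.

The effective dataset size `S` (or `C` for the control) is the number of
reads mapping at least once to the genome or the canonical sequences; it is
deliberately not the raw read count, so unsequenceable junk does not dilute
the enrichment denominators.

# Enrichment model

With `s` ChIP and `c` control reads assigned to a set, and dataset sizes
`S` and `C`, fold enrichment is modelled as a ratio of Poisson rates with a
non-informative half-count prior:

$$\hat\theta = \frac{C\,(s + \tfrac12)}{S\,(c + \tfrac12)},\qquad
\lambda(x) = \hat\theta \cdot F\!\left[x;\, 2(s+\tfrac12),\, 2(c+\tfrac12)\right]$$

The CI is `[λ(α/2), λ(1−α/2)]` after sorting — both quantiles are computed
and ordered, which makes the code independent of the F-distribution tail
convention. Under Gamma posteriors for the two rates this is exactly the
posterior interval of the ratio, and its frequentist coverage at the
default α = 0.05 is ≈95% (the test suite and the acceptance script verify
this by simulation). A set is *significant* when the CI excludes 1.

Significance is also reported as a signed Z-score: a two-sided exact
binomial test of `s` among `s + c` reads against the null proportion
`S/(S+C)`, mapped to the normal quantile scale,
`Z = sign(θ̂ − 1) · Φ⁻¹(1 − p/2)`, capped at ±10. The scale is anchored so
Z = 3.1 corresponds to a one-sided P of 10⁻³. The cap exists because at
repeat-scale counts P-values underflow; any |Z| = 10 should be read as
"≤ 2·10⁻²³", not as a measurement.

Two enrichment coefficients (for instance canonical-only vs instance-only
estimates of one type) are compared as a ratio of binomial proportions
adjusted for dataset size, with an approximate Bayesian interval in the
Price–Bonett style: +1/2 adjustments on all four counts and a log-scale
variance of `1/(x+½) − 1/(n+½)` per proportion. The pair is "consistent"
when the ratio CI contains 1. The construction is validated in the tests
against a parametric-bootstrap oracle rather than against closed-form
values, which the method's description does not supply.

# Clustering and over-representation

For heatmaps, repeat types are clustered on transformed profiles: cells
without significant enrichment are set to 0, and significant *depletion* is
also set to 0 for clustering while being retained (in blue) for display.
The profile scale is log2(θ̂), chosen because "negative values" then
correspond exactly to depletion; clustering uses Ward's method (`ward.D2`)
on Euclidean distances, which is deterministic given the input order, and
input order does not change the partition. Family over-representation
within a cluster is an upper-tail hypergeometric test, Bonferroni-corrected
across the families tested (the conservative reading of a "corrected"
P-value; the correction method is a parameter).

# Input-free relative normalization

When no input library exists, each repeat type is scored against the other
marks: the percentage `100·s/S` of each mark's reads assigned to the type
is computed; each percentage is resampled 100× from the Beta posterior of
the proportion under the Jeffreys prior, `Beta(s+½, S−s+½)` (matching the
half-count prior of the enrichment model — the method's description names
only "the Beta distribution"); the five marks with the highest point ratios
are excluded (ranked by point ratio, the simplest reading of "highest
percentage ratios"); and a Gaussian (μ, σ) is fitted on *all pooled
resampled draws* of the remaining marks. Every mark — including the trimmed
ones, which are precisely the enrichment candidates — is scored as
`Z = (ratio − μ)/σ`.

Two consequences deserve emphasis. First, the method rests on the
assumption that most marks are not enriched at a given repeat; it therefore
cannot call depletion (negative Z-scores are reported but flagged
non-callable). Second, the pooled draws widen σ beyond the between-mark
spread of the point ratios while the trimming biases μ and σ downward;
under a pure null (all marks drawn from one proportion) these effects
nearly cancel at the 3.1 anchor, and the measured null exceedance rate
P(Z > 3.1) is of the order of the nominal 10⁻³ (the test suite checks
this). When several strongly enriched marks occupy all trimmed slots, the
remaining-null fit keeps the widened σ without the trimming bias, and the
scoring becomes conservative — a deliberate property for an enrichment
screen without a proper control. The alternative reading of the procedure
(fitting the Gaussian to the per-mark means of the draws) was rejected
because it overshoots the anchor by an order of magnitude in the null
configuration.

# The enrichment phylogeny

Repeat types sharing sequence also share reads; grouping them recovers the
cross-ambiguous reads. For a set of sequences (a tree node), a read is
*unique* when every best-stratum hit targets a member. The tree is built
greedily bottom-up: at each step the two nodes with the highest read-set
similarity — the Jaccard index of their aligned read sets, i.e. shared
reads over reads aligning to either set — are merged. (The quantity is
described as a "distance" with a shared/total ratio; the total is read as
the union, since the intersection reading would make the ratio identically
1. Classic additive-distance neighbor joining is not applicable because
read-set distances are not additive; greedy agglomeration of the most
similar pair is what "bottom-up grouping by highest similarity" denotes.)
Similarities are recomputed exactly from the merged read sets rather than
via a Lance–Williams update, keeping the semantics literal at desk scale,
and ties are broken lexicographically on smallest member names so the
topology is independent of input order.

Each node's *gain* is its unique-read count minus its children's — the
reads that become uniquely assignable exactly at that merge. Gains are
provably non-negative and sum to the root's unique count (every uniquely
assignable read is gained exactly once); both invariants are asserted on
every constructed tree. Topologies and unique counts use ChIP reads;
the control enters only through per-node enrichment annotation (a flagged
alternative would pool both). Newick exports use branch length
`log10(1 + gain)` so that informative merges are visible across four orders
of magnitude, with a companion TSV carrying gains, counts, MLEs, CIs and
Z-scores per node id.

Instance-level trees take the annotated instances of one type as leaves.
Reads with any best-stratum hit outside the considered instance set are
discarded first. Hits on the type's *own canonical segment* are ignored for
this rule: the consensus is a summary of the very instances under study,
not a distinct genomic locus a read could have originated from — treating
it as "outside" would discard essentially all reads of any type whose
instances sit close to consensus, which contradicts the method's use on
young, homogeneous repeat families.

# The synthetic-data generator

`synth_dataset()` emulates the study conditions at desk scale: random
canonical sequences per family; full-length instances derived by i.i.d.
per-base divergence (default levels around 5–12% in the tests, the range
where instances are distinguishable but still share reads); optional
truncated copies planted in the genome but omitted from the annotation, to
exercise masking; 32-bp reads. Input reads are uniform over the genome.
ChIP reads sample read-start positions with weight θ over each family's
copy footprint — where the footprint of a copy includes every start whose
read window overlaps it, mirroring the fact that immunoprecipitated
fragments overlapping a locus boundary carry its signal — and the
background weight is renormalized so total ChIP weight equals input weight.
With that renormalization the realized ChIP/input proportion ratio of a
family is exactly its planted θ; without it θ would be deflated by the
ratio of total weights, which is material when planted footprints are a
non-trivial fraction of a desk-scale genome.

The error model follows the empirical short-read profile: per-position
substitution rates rising from 5.4·10⁻³ at the first base to 1.0·10⁻² at
the last (linear interpolation; only the endpoints are specified by the
profile), with a configurable conditional substitution matrix defaulting to
uniform over the three alternative bases. SNPs are planted i.i.d. at
8.3·10⁻⁵ per base by default. Generator calibration (positional rates, SNP
counts within binomial 3σ) is asserted in the tests. What the generator
does *not* emulate: fragment-length and shift structure (the estimator
never uses positional information within a set), GC and mappability biases,
copy-number variation between cells, and nested/recombined repeat
structures. Passing tests therefore demonstrate correctness of the
estimators under the stated sampling model, not robustness to every
artifact of real libraries.

# Numerical and scale choices

Problem sizes in the tests are chosen for a desk-scale suite: genomes of
roughly 7–20 kb with 2–4 planted families, read sets of 3,000–5,000 per
library, 100-fold coverage for error-model sampling, 10,000 replicates for
CI coverage, and 1,500 repeat types for the null-calibration run of the
relative normalization. Degenerate inputs are defined rather than left to
chance: empty read sets give similarity 0; a σ of 0 is floored at
10⁻¹²·max(μ, 1); zero counts are handled by the half-count priors
throughout; a single-leaf tree is a degenerate tree with a warning; types
with no instances contribute canonical-only records in combined mode.
Reads shorter than `2·(max_mismatch + 1)` bases are reported unalignable
rather than erroring.

# Limitations

Estimates are averages over a set of homologous sequences; they say nothing
about variability within the set and can be driven by a few copies — the
instance-level trees are the tool for looking inside a type. The greedy
tree is not globally optimal (direct optimization over hierarchies is
computationally prohibitive); it is a heuristic whose merges are locally
most informative. Enrichment for two marks at one repeat type does not
imply co-occurrence at the same loci, since signal is pooled over
instances. The input-free normalization cannot call depletion and assumes
most marks are null per repeat. De-novo repeat discovery is out of scope:
only annotated repeat types are analyzed.
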