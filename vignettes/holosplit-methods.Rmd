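---
title: "Methods: partitioning, deduplication, and phase-specific expression in holobiont transcriptomes"
author: "holosplit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning, deduplication, and phase-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holosplit)
```

# The problem

A de novo transcriptome assembled from coral gonad RNA is a holobiont
assembly: host contigs, symbiont (Symbiodiniaceae) contigs, and contigs from
other associated organisms are interleaved in one FASTA file. holosplit
covers the post-assembly analysis chain: partition the contigs by origin,
collapse redundant haplotypes into a reference set, account for annotation
coverage, detect genes upregulated in specific phases of oogenesis and
spermatogenesis, and test gene-set over-representation. This vignette
records the models, the parameters that matter, the numerical conventions,
and the choices made where the design was genuinely open.

# Partitioning model

Each contig is scored against two pooled reference databases (host genomes;
symbiont transcriptomes). The decision rule is:

* hits in exactly one database → exclusive assignment to that class;
* hits in both → the class of the single best hit over the combined hit set;
* no hits → *other*.

**Top-hit criterion.** "Top hit" is ranked by bitscore; ties fall through to
lower e-value, then longer alignment, then host before symbiont. The
bitscore-first choice follows the common convention of taxonomic binning by
tabular alignment output; the full chain exists only to make assignment
deterministic — a property asserted by the order-invariance tests. With
real aligner output the final host-before-symbiont tie is essentially never
reached; with the built-in k-mer screen it resolves exact containment ties.

**Evidence sources.** The package consumes standard 12-column tabular
alignment files at an e-value cutoff of 1e-3 (inclusive: a row at exactly
the cutoff is kept). Running the aligner itself is out of scope. For
self-contained work the k-mer containment screen stands in: for contig $c$
and database $D$, containment is the fraction of $c$'s distinct canonical
21-mers present in $D$, a pseudo-hit is emitted when containment ≥ 0.2, and
its pseudo-bitscore is containment × length($c$) / k so that longer,
better-contained contigs rank higher. k = 21 is the usual sketching scale
at which random 21-mer collisions are negligible; 0.2 tolerates several
percent sequence divergence (at 3% divergence the expected containment is
$0.97^{21} \approx 0.53$) while rejecting unrelated sequences, whose
expected containment is near zero.

**GC diagnostics.** Host and symbiont transcriptomes differ in base
composition (GC modes near 41.5% and 50.6% in anthozoan holobionts), so
per-class GC histograms are a cheap independent check on the split. Bins
are 1 percentage point wide with edges at integers; the mode is the centre
of the maximal-count bin, lowest bin on ties; GC is computed over
unambiguous bases only, so N-rich contigs do not smear the histogram. A
class with no members gets an empty histogram and an `NA` mode rather than
an error.

**Ledger.** Branch counts are kept in a ledger whose conservation
identities (`exclusive + ambiguous + no_hit = total`,
`ambiguous_to_host + ambiguous_to_symbiont = ambiguous`,
`final = exclusive + ambiguous_resolved`) are recomputed and checked on
every construction, so inconsistent bookkeeping fails loudly instead of
propagating.

# Identity and deduplication

Assemblies retain near-identical contigs from different individuals or
haplotypes. The reduction cascade is greedy incremental clustering in the
CD-HIT family: cluster at 97% nucleotide identity; translate each surviving
representative via its longest ORF; cluster the peptides at 95% identity.

**Identity definition.** Identity = matches / length of the shorter
sequence, from the optimal semi-global alignment (shorter sequence global,
longer local) under unit scoring (match +1, mismatch −1, gap −1, linear).
Among alignments of optimal score, the one with the most matches defines
the identity; this lexicographic objective is computed exactly by a
compiled dynamic programme, making the value deterministic — a plain
"optimal alignment" is not unique and different optimal alignments can
carry different match counts. The shorter-sequence denominator is the
convention of the clustering tools this mirrors: a perfect substring has
identity 1 regardless of the longer sequence's length.

**Greedy order and representatives.** Sequences are processed in
descending length (ties by id); each joins the first cluster whose
representative it matches at the threshold, else founds a new cluster.
Representatives are therefore the longest member (lexicographic id on
ties) and every member is within the threshold of its representative by
construction.

**Prescreen admissibility.** A k-mer filter (k = 8 nt, 3 aa) skips
alignments that provably cannot reach the threshold: if identity ≥ t, at
most $d = \lfloor(1-t)L_s\rfloor$ positions of the shorter sequence differ
and each can destroy at most $k$ of its $L_s - k + 1$ k-mers, so at least
$(L_s - k + 1) - dk$ k-mer positions must occur in the longer sequence.
Observing fewer proves identity < t. The filter can therefore never cause
a false merge or a false split; the suite verifies clustering with and
without it is identical.

**ORF handling.** The longest ORF over all six frames requires an ATG
start and a terminal stop (the stop is excluded from the peptide, included
in the nucleotide span); coordinates are 0-based half-open on the forward
strand; ties break by frame order +1, +2, +3, −1, −2, −3 then leftmost
start. A stop-to-stop mode is available behind `require_start = FALSE`.
Representatives without an ORF of ≥ 30 aa bypass protein clustering and
are retained: silently dropping ORF-less contigs would shrink the
reference set as a side effect of a translation heuristic.

# Read cleaning

Phred+33 reads are 3′-trimmed before filtering: trailing bases are removed
while the mean quality of the terminal 4-base window is below Q20. The
window form is a documented choice — a bare per-base Q20 threshold is the
stated criterion, but the trimming algorithm around it is not specified
anywhere, and a 4-base mean window is the common compromise between
chopping on single bad calls and keeping long bad tails. A per-read mean
mode (`mode = "mean_read"`) is available since the criterion could equally
be read per-read. After trimming, reads with N fraction strictly above 5%
(the boundary value is retained) or length below 25 bp are removed.

# Expression model

**Normalisation.** TMM follows the published scheme exactly: per sample
versus a reference column (the sample whose upper-quartile count fraction
is closest to the mean), log2 ratios M and average abundances A over genes
positive in both, double trimming (30% on M, 5% on A), precision-weighted
mean, factors rescaled to geometric mean 1. The implementation is verified
against edgeR's `calcNormFactors` to 1e-10. Two properties worth noting
because they are easy to over-state: factors are exactly 1 for a pure
depth difference only in the two-sample case (with more samples the
count-dependent precision weights move third-party factors slightly), and
column rescaling changes factors marginally through the same weights —
the M values themselves are depth-invariant. A sample whose composition is
inflated (a few genes carrying much of the library) receives a factor
below 1: its non-inflated genes have negative M after library-size
adjustment, and the factor is 2 to the trimmed mean M.

**Outlier samples.** Whole samples are screened by average-linkage
clustering on 1 − Pearson correlation of log2(CPM+1); a sample is flagged
when its first merge height exceeds median + 3 × MAD of all merge heights.
This replaces a visual dendrogram call with a reproducible rule; the
multiplier is configurable. The log transform is applied because raw CPM
correlations are dominated by a handful of highly expressed genes.

**Differential expression.** Per gene, a fixed-effects one-way ANOVA of
log2(CPM+1) across the four ordered phases, BH-adjusted within each sex
(the two sexes are analysed separately end to end, so adjustment within
sex matches the analysis unit). The log transform is a deliberate choice:
untransformed CPM violates the homoscedasticity the F test assumes.
Degenerate genes with no variation at all get p = 1; genes with zero
within-phase variance but distinct means get p = 0. A negative-binomial
GLM likelihood-ratio backend was considered and not implemented: the ANOVA
path is fully specifiable and testable without per-gene dispersion
estimation, and the result surfaces (statistic, p, q, flags) are identical
in structure, so swapping the engine later does not change the interface.

**Phase-specific sets.** A gene is specific to phase p iff it is DE and
its mean CPM in p strictly exceeds every other phase — ties disqualify, so
a gene can be specific to at most one phase. The high-fold-change filter
additionally requires the *minimum* over other phases of
log2((mean_p + 1)/(mean_q + 1)) to exceed the threshold (5 for ovaries, 8
for testes). Per-phase minimum, rather than comparison to the pooled mean
of the other phases, is the stricter and more literal reading of
"upregulated relative to the other three phases"; the pseudo-CPM of 1 on
both sides keeps ratios finite when a phase is silent and biases the
filter conservatively for weakly expressed genes.

**Heatmap export.** Row Z-scores use the population (1/n) standard
deviation; constant rows become zeros rather than NaN.

# Enrichment

Over-representation uses the exact upper hypergeometric tail
P(X ≥ k) for k foreground genes annotated with a term, against the
annotated universe. A term passes when fold enrichment (k/n)/(K/N)
strictly exceeds 4 and p < 0.05 — the filter operates on the raw p by
design; a BH column is emitted for information only. The plain one-sided
hypergeometric (Fisher) tail is used rather than any service-specific
modified score, and the output records that choice. Ontology-graph
propagation is out of scope: the term map is taken as given.

# The synthetic holobiont

The generator produces every input the pipeline consumes, with ground
truth, under the study design the analysis targets:

* **Sequences.** Host and symbiont references are i.i.d. bases at GC 41.5%
  and 50.6%; contigs (500 by default, 300–1500 bp) are reference
  subsequences with 3% point divergence, in proportions 55% host / 28%
  symbiont / 11% foreign / 6% host–symbiont chimeras. Twelve duplicate
  groups (2–5 members, copies re-mutated at 0.5% and length-staggered)
  emulate haplotype redundancy. 3% divergence keeps contigs confidently
  assignable (expected 21-mer containment ≈ 0.53) while making
  *independent* contigs from the same reference fall well below the 97%
  clustering threshold (expected pairwise identity ≈ 0.94). Because the
  reference pool is finite, the generator can still occasionally produce
  an incidental pair above 97% true identity; evaluation therefore checks
  that every planted group is recovered exactly and counts such extra
  merges separately instead of calling them errors.
* **Counts.** Negative binomial with variance μ + φμ², φ = 0.1 (a typical
  bulk RNA-seq scale), log-normal baselines (meanlog log 50, sdlog 1.5),
  library factors uniform on [0.7, 1.3], over 2 sexes × 4 phases × 3
  colonies. Planted mature-phase genes (40 female at log2 effect 6, 30
  male at effect 9 — flanking the 5 and 8 filter thresholds) and 10 genes
  per remaining phase at effect 3. Planted genes draw from a
  moderately-expressed baseline (meanlog log 100, sdlog 0.5) so that the
  fold-change filter, which operates on pseudo-counted CPM means, acts on
  expressed genes as it does in real data. One sample per sex is an
  outlier generated from a permuted gene profile — a corruption that depth
  normalisation cannot absorb, mirroring whole-sample removal rather than
  library-size artefacts.
* **Terms.** 50 random terms of 10–60 genes plus 2 planted terms per sex
  drawing 60% of their genes from that sex's planted mature set, giving
  large true fold enrichment by construction.

What the generator does *not* emulate — isoform structure, positionally
correlated errors, GC–coverage coupling, adapter contamination, real
ontology topology — bounds what passing tests show: they validate the
statistical machinery under the stated model, not robustness to every
artefact of real libraries.

# Determinism and problem sizes

All generation is driven by a single integer seed fanned out to
independent per-stage seeds; reruns are bit-identical, and the pipeline
report is reproducible end to end. The default problem sizes (500 contigs,
2000 genes, 24 samples; 20 simulation seeds for the enrichment recovery
rate; null calibrations at 2000 genes) were chosen so the entire suite and
the acceptance script each complete in minutes on a single CPU while
leaving the recovery metrics well away from small-sample noise.

# Known limitations

* The greedy clustering is quadratic in cluster count per query; it
  targets partitioned desk-scale sets, not 10^5-contig assemblies in
  minutes.
* Assignment accuracy degrades as contig divergence approaches the k-mer
  screen's tolerance; with real aligner hit tables the screen is bypassed
  entirely.
* The ANOVA path tests location shifts of log-CPM; very low counts with
  strong mean–variance coupling are better served by a count-model
  backend.
* Enrichment p-values are exact but unadjusted by design; with thousands
  of terms the raw-p filter is permissive, which is why the fold filter is
  joint.
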