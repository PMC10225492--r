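---
title: "Methods: comparative genomics of genome miniaturization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of genome miniaturization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`minigenomics` implements the computational core of a comparative-genomics
study of genome size reduction: why one lineage (in the motivating system, a
gliding scallop; in birds, a hummingbird) carries a much smaller genome than
its relatives, and which genomic features absorb the difference. The package
covers five analysis stages — genic/intergenic partitioning, transposable
element (TE) dynamics, gene-family contraction, relative-gene-length
statistics with pathway enrichment, and expression/co-expression summaries —
plus a synthetic-data module that generates every input format with planted
ground truth. The `analysis/` scripts in the repository run the stages in
order over one simulated six-species study set.

Everything upstream of these stages (assembly, gene prediction, repeat
masking, ortholog inference, substitution-rate estimation) is out of scope:
their outputs (GFF3, RepeatMasker `.out`, ortholog tables, rate tables) are
the package's inputs.

# Models and procedures

## Genic/intergenic partition

The genic region of a genome is the strand-agnostic union of annotated
`gene`-type spans, with overlapping and bookended intervals merged
(`IRanges::reduce`); the intergenic region is the remainder, so
`genic + intergenic = genome size` holds exactly by construction (genome
size is defined as the sum of the annotated sequence lengths, not an
assembly-header claim). Merging overlapping genes before summing is a
deliberate choice: the alternative (summing raw spans) double-counts nested
and overlapping genes and breaks the conservation identity. Coordinates are
1-based inclusive throughout (GFF3 convention); half-open arithmetic is
internal only. Exon/intron structure is ignored — the partition contrasts
gene territory with intergenic territory, nothing finer.

Cross-species comparison (`compare_partitions`) reports means and sample
SDs (n−1) of genic and intergenic sizes and the Pearson correlation of
genome size with intergenic size. Pearson (not Spearman) is used because
the downstream claims are about the linear co-variation of sizes.

## TE divergence and insertion-time dating

Each TE copy carries an observed divergence *d* from its family consensus
(the RepeatMasker `% div` column / 100). The Jukes–Cantor correction

$$K = -\tfrac{3}{4}\,\ln(1 - \tfrac{4d}{3})$$

converts *d* into substitutions per site, undoing multiple hits; it is
undefined at saturation (d ≥ 0.75), where the package raises an error
rather than returning a value. Insertion time is $T = K / (2r)$ with *r*
the lineage substitution rate per site per million years: the copy and the
consensus diverge along two lineages, hence the factor 2. If a
Kimura-corrected divergence file is supplied instead of raw `% div`, the
correction should be skipped (the functions are separable precisely for
this; `jc_correct` is only ever applied to raw mismatch proportions).

Divergence landscapes bin summed copy bp into half-open divergence bins
`[iw, (i+1)w)` per class (DNA/LINE/LTR/SINE, mapped from the class/family
column by prefix; simple repeats, low-complexity and satellite records are
excluded as non-TE). The matrix total equals the total retained copy bp — a
conservation property the tests enforce. Compartment assignment uses the
copy midpoint against the genic union: unambiguous for copies straddling a
boundary, and consistent with the per-base oracle at the midpoint.

## Gene-family contraction

Domain counting uses set semantics over gene–domain pairs: a gene carrying
several copies of one domain contributes a single count to that family. For each
family the focal species' `(count, total − count)` is tested against the
comparator species' average count and average total — both rounded to the
nearest integer, since the Fisher exact test needs integer tables — in a
two-sided test; direction (contracted/expanded) is read from which side the
focal proportion falls, and only assigned below the significance level.
A pooled-comparator variant (summing instead of averaging) is available
behind the `comparator` argument; rounding the mean is the default because
averaging keeps the comparator column on the same scale as the focal
column. Raw p < 0.05 is the default decision rule; Benjamini–Hochberg
q-values are always reported and can drive the call via `adjust = "BH"`.
The background column is the total of domain-bearing genes (the test is
about family membership among genes, not genomic bp).

## Size-reducing genes and enrichment

For single-copy ortholog groups, gene length is standardized as
$\lambda = \text{length} / \text{genic size of the species}$, making
lengths comparable between compact and inflated genomes; the
classification is invariant to any common rescaling of the genic sizes.
A group is *size-reducing* when the focal species' λ is strictly below the
mean λ of the comparators, *size-increasing* when strictly above, neutral
on ties; incomplete groups (missing a species) are excluded. Gene length
is the annotated genomic span (end − start + 1) by default; precomputed
transcript lengths can be supplied instead, since the input table carries
lengths, not coordinates.

Note what this classifier is: a sign test against the comparator mean with
no margin. On null groups with symmetric noise it calls ~50% of groups one
way or the other; that is faithful to its definition and is why, in the
recovery experiments below, recall of planted reductions is essentially
perfect while precision is dominated by the planted-to-null ratio. Users
who need a conservative call should filter on effect size
(`lambda_focal / comparator_mean`) downstream.

Pathway over-representation is the one-sided hypergeometric tail
$p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$ with the
background restricted to annotated genes, plus BH q-values. The same test,
with a module as the query and a gene set as the "pathway", serves as the
module enrichment check.

## Expression and co-expression

TPM divides each gene's count by its length and rescales each sample to
one million, so columns sum to 1e6 exactly (all-zero samples are flagged
and left zero). Cross-species expression ratios average replicates within
a tissue first, then divide the focal mean by the comparator-species mean;
zero comparator means yield `NA`, excluded from summaries. Cumulative
family expression sums member-gene mean TPM in a tissue. A gene is
tissue-specific when its mean TPM in the target tissue is ≥ 2× the best
other tissue and ≥ 1 TPM — stated defaults, both exposed.

The co-expression network is a deliberately miniature re-implementation of
the weighted-correlation approach: unsigned adjacency
$a_{ij} = |\mathrm{cor}(g_i, g_j)|^{\beta}$ on log2(TPM+1) with β = 6
(the common unsigned default; log transform stabilizes variance), zero
diagonal, zero-variance genes dropped. Modules come from average-linkage
hierarchical clustering of the dissimilarity 1 − a with a *static* cut;
clusters under `min_size` (30) are pooled as unassigned. Topological
overlap and dynamic tree cutting are intentionally omitted. The default
cut height is 0.99: with a power-6 unsigned adjacency, uncorrelated pairs
sit at dissimilarity ≈ 0.99 (for ~12 samples) and genuinely co-expressed
pairs well below 0.9, so the informative range of the cut is compressed
toward 1 — a cut at, say, 0.25 would require |r| ≥ 0.95 between merged
genes and leave realistic modules undetected. The known cost of a static
cut near the noise floor is that large background clusters can form; they
do not absorb planted modules (the tests measure this), but module lists
should be read together with their enrichment statistics.

Intramodular connectivity is $k_{within}(i) = \sum_{j \in M, j \ne i}
a_{ij}$; hub genes are the top `min(40, |M|−1)` by k_within with ties
broken by gene id, so rankings are deterministic.

# The synthetic-data generators

The generators produce inputs in the same formats the readers parse
(GFF3 + seqlen TSV, RepeatMasker `.out`, ortholog/domain/count TSV, GMT),
so every file round-trips through the package's own I/O. All are
deterministic given `seed` and restore the caller's RNG state. One
practical rule: give different generators different seeds — two generators
run on the same literal seed draw correlated `sample()` indices, which can
make "null" structures echo planted ones.

*Genomes* (`gen_genome_set`): one chromosome per species; gene lengths are
a uniform random composition of the genic target and gaps a composition of
the remainder, so the requested genic fraction is hit exactly (up to
rounding) and genes never overlap. Infeasible packings error out.

*TE copies* (`gen_te_copies`): for age T, the total consensus–copy
distance is K = 2rT (both lineages collapsed onto the copy, matching how
dating reads a copy against a consensus). Each site mismatches with the
exact Jukes–Cantor probability $p = \tfrac{3}{4}(1 - e^{-4K/3})$;
divergence is the realized binomial mismatch proportion. No literal
nucleotide strings are evolved — the mismatch distribution is all that
divergence estimation observes. Saturating parameter combinations error.

*Orthologs* (`gen_ortholog_table`): per-group lognormal baseline lengths
(meanlog 8, sdlog 0.6; median ≈ 3 kb, right-skewed like real gene
lengths), multiplicative mean-1 lognormal noise per (group, species) with
relative SD `noise_sd`, and planted groups scaled by (1 − effect) in the
focal species only.

*Domain counts* (`gen_domain_counts`): per-domain gamma means shared
across species with Poisson per-species counts (marginally overdispersed,
like real family sizes); planted domains scale the focal mean by the fold.

*Expression* (`gen_expression`): log2-scale means with baseline
U(6, 9) and signal amplitude 2.5, so Poisson count noise is small relative
to the planted structure. Module members load on a shared latent factor
with loading √cor (giving the stated expected pairwise correlation);
designated hubs load at 1.0 — hubs *are* the genes that track the module
program, which is what makes them recoverable by connectivity ranking at
small sample sizes. Module factors are drawn mutually orthogonal across
samples and orthogonal to the tissue-indicator subspace: with only 12
samples, two independent random factors can correlate > 0.6 by chance, and
a factor aligned with a tissue indicator collides with the planted
tissue-specific genes — either collision would make distinct planted
truths unidentifiable by *any* method, which is a generator artifact, not
a property worth testing. Tissue-specific genes get +5 log2 over a low
baseline in their tissue only.

*Pathways* (`gen_pathways`): one planted pathway overlaps the target set
at the stated proportion; the rest sample the universe uniformly.

What the simulations do **not** emulate: nucleotide-level sequence
content, read-level noise, isoforms, batch effects, correlated gene-length
evolution, phylogenetic non-independence among comparator species, or
tissue-correlated module programs. Passing the recovery tests therefore
shows the statistics are implemented correctly and identifiable under
clean planted structure — not that they are robust to everything real data
does.

# Verification and problem sizes

The test suite checks every operation against an independent oracle where
one exists: a per-base boolean-marking oracle for interval unions (50
random genomes up to 1 Mb with up to 200 overlapping genes), closed-form
JC expectations and an exact round-trip identity for the dating chain
(grid of 1000 divergences; simulated recovery of ages 10/50/100 MY from
500 × 2 kb copies per age within 10%), log-factorial full-support
enumeration for the Fisher and hypergeometric tails (margins ≤ 40,
backgrounds ≤ 60, agreement to 1e-12), and planted-truth recovery for the
classifier, family test (5-fold contractions at baseline 100 all flagged;
null families ≤ 10% at α = 0.05), tissue-specificity (recall ≥ 0.9), and
the co-expression chain (three modules of 100/80/60 genes at
within-correlation 0.7 among 1500 genes and 12 samples: ≥ 90% of module
genes majority-matched, ≥ 9/10 hubs per module in the top-10). These
problem sizes keep the full suite under a minute on one CPU while leaving
each statistic enough data to be measured meaningfully.

# Known limitations

- The size-shift classifier has no margin; its false-positive rate on
  noisy null groups is ~50% by construction (see above). This is the
  published definition, kept faithfully.
- The static tree cut near the adjacency noise floor produces background
  clusters at small sample sizes; module calls should be read with their
  enrichment p-values.
- The comparator "average" in the family test is rounded to an integer
  before testing; with very small comparator counts the rounding step can
  move the table by one unit. The pooled variant avoids this at the cost
  of weighting large comparators more.
- `family_shift_test` uses raw p < 0.05 by default to match the original
  decision rule; with hundreds of families, users wanting FDR control
  should pass `adjust = "BH"`.
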