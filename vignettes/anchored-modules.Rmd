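---
title: "Anchored susceptibility modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored susceptibility modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchornet)
```

anchornet implements an integrated-genomics workflow for panels of inbred
mouse strains: it builds a haplotype-block map from strain SNP genotypes,
asks whether copy-number variant regions (CNVRs) are tagged by those
haplotypes, maps cis-eQTLs against both marker types, tests whether the
pre-exposure transcriptional state of the panel predicts a binary disease
phenotype (susceptible vs resistant), and assembles *anchored
co-expression modules*: sets of genes correlated with an "anchor" gene
that is both differentially expressed between phenotype classes and
linked to a local (cis) genetic variant — the configuration in which the
anchor is a plausible upstream driver of the module. This vignette
explains the models behind each stage, the tunable parameters, the design
decisions taken where the method leaves room, and what the synthetic-data
generator does and does not emulate.

## Haplotype-block construction

Classical inbred strains are genetic mosaics: along a chromosome, each
strain carries one of a small number of ancestral haplotypes, and the
identity of that haplotype changes at discrete boundaries. `build_blocks()`
recovers this structure by growing blocks left-to-right along each
chromosome:

1. A block starts as a single SNP; strains are grouped exactly by
   genotype (`single-SNP blocks` may therefore report more haplotypes
   than the 2–6 clustering range).
2. The next consecutive SNP is appended and strains are re-clustered by
   `assign_haplotypes()`: Partitioning Around Medoids (PAM, from the
   `cluster` package) on the *unnormalized* SNP-difference distance
   (positions typed in both strains where alleles differ), for every
   cluster count k in 2–6, choosing k by the maximum average silhouette.
3. Each cluster gets a consensus haplotype — the modal allele at each
   position over typed strains — and the *error count* is the number of
   typed genotypes the consensus fails to predict.
4. If the error count exceeds `max_errors` (default 1), the most recently
   added SNP is removed, the stored result of the previous iteration
   becomes the finalized block, and a new block starts at the offending
   SNP.

Blocks therefore tile the informative SNPs contiguously, and every
emitted block predicts all typed genotypes with at most one error.
Informative SNPs are those outside CNVRs, with minor allele frequency of
at least 5% over typed strains, and missing in fewer than 25% of strains
(both thresholds are arguments to `filter_informative()`; the missingness
threshold is inclusive — a SNP untyped in exactly 25% of strains is
dropped).

Numerical conventions, chosen for determinism: PAM uses its deterministic
BUILD initialization (no random restarts); silhouette ties across k go to
the smallest k (parsimony); consensus ties go to the lexicographically
smallest allele; a singleton cluster's silhouette is 0; strains untyped
across an entire block get a missing label and never contribute to
distances, consensus votes, or error counts; a strain pair with no
co-typed SNP has undefined distance — an error in normalized mode, 0 with
a warning in unnormalized mode.

**Label refinement.** Under missing data the pairwise distance can be
uninformative: a strain typed at one SNP of a two-SNP window is at
distance zero from any partially typed medoid, and PAM's medoid search
actively prefers such strains (their many zero distances make them look
central). The block error rule, however, is about consensus
predictiveness, which remains well defined for sparsely typed strains. So
for each candidate k, `assign_haplotypes()` refines the PAM clustering
(and a second deterministic start seeded from the k most frequent
fully-typed allele patterns) by iteratively reassigning each typed strain
to the consensus haplotype it mismatches least, and selects k by the
average silhouette of the *refined* assignment. The grow/split rule, the
error bound, and the silhouette criterion are unchanged; the refinement
only repairs assignments that the distance matrix cannot resolve. Without
it, planted-block recovery (below) degrades badly at 10% missingness.

## CNVR tagging: pooled multi-allelic R²

Whether a haplotype system captures a CNVR's genotype is measured by
`pooled_r2()`: the haplotype-frequency-weighted average
$\sum_h p_h\, r^2_h$, where $r^2_h$ is the squared Pearson correlation
between the indicator of haplotype $h$ and the indicator of the
copy-number class that $h$ tags best. Copy-number classes are unordered
(they are treated as factors throughout), so correlating against a class
indicator rather than the raw copy number is the coherent choice: it
makes the statistic 1 when haplotype labels coincide with copy-number
classes under any relabeling, and it reduces to the classical $r^2$ in
the biallelic two-class case. `tag_cnvrs()` considers blocks whose
interval lies within 250 kb of the CNVR (overlap counts as distance 0)
and calls the CNVR tagged when the best pooled R² strictly exceeds 0.80.

## Phenotype-predictive clustering

`cluster_permutation_test()` quantifies how tightly susceptible strains
cluster in expression space. On strain median profiles (known-phenotype
strains only), with 1 − Pearson correlation as the distance, the
statistic is

$$ T = \frac{\text{mean distance among susceptible strains}}
            {\text{mean susceptible-resistant distance}}, $$

small when susceptible strains sit close together. The null is built by
permuting phenotype labels across strains; the p-value is the add-one
proportion of permutations with $T_{perm} \le T_{obs}$, one-sided toward
clustering, and can never be 0. A within/between ratio is *small* under
clustering, so the rejection direction must be "≤"; a "≥" counting rule
would make small p-values impossible for exactly the clustered
configurations the test is designed to detect, which is why this
direction is fixed here and documented explicitly.

## Differential expression

`differential_expression()` contrasts susceptible against resistant
strains (unknown-phenotype strains excluded). The unit of analysis is the
strain, not the array: per probe, a linear model of per-strain mean
expression on susceptibility status is fitted with weights equal to each
strain's replicate array count, so strains profiled more deeply carry
proportionally more information without replicate pseudo-replication.
Residual variances are moderated by empirical Bayes (limma's `eBayes`,
shrinking toward a pooled prior with augmented degrees of freedom);
`moderated = FALSE` gives the ordinary per-probe t, which with one
replicate per strain reduces exactly to the classical equal-variance
two-sample t-test. FDR comes from Storey q-values (`qvalues()`):
$\hat\pi_0$ from the smoother method over the λ grid 0.05–0.95 (cubic
spline, read off at λ = 0.95, clamped to (0, 1]; for fewer than 100
p-values the smoother is unreliable and $\pi_0$ defaults to 1, which
reduces the procedure to Benjamini–Hochberg). Probes detected on arrays
are pre-filtered with `detection_filter()`: the default keeps probes
detected in *every* replicate array of at least three strains, with
single-array strains excluded from the requirement since they cannot
demonstrate replicate-consistent detection.

## cis-eQTL mapping

Expression traits (per-strain means) are tested against haplotype-block
labels and CNVR genotypes as unordered factors in a one-way ANOVA
(`marker_association()`), for every marker whose midpoint lies within the
cis window of the probe's gene position. Genotype classes carried by a
single strain are merged into the nearest class first — by consensus-string
Hamming distance for haplotypes, by copy-number difference for CNVRs — to
avoid zero-degree-of-freedom cells.

Significance is calibrated by a relatedness-weighted strain permutation
(`weighted_permutation_p()`): trait values are re-assigned to genotype
classes by drawing strain orders without replacement with probability
proportional to per-strain weights, and the p-value is the add-one
fraction of permuted F statistics at or above the observed one. The
weights (`compute_strain_weights()`) are
$w_s = 1/(1 + \sum_{t \ne s} K_{st})$ with
$K_{st} = 1 - $ normalized SNP distance, normalized to mean 1: genetically
unique strains anchor the null more, near-duplicate strains less. This
particular weighting is this package's documented choice of a
relatedness correction — the idea (permutation nulls that respect strain
relatedness) is standard, the exact functional form is ours, and uniform
weights are available via `weights = "uniform"`.

A trait is called eQTL-linked when the Benjamini–Hochberg-adjusted
permutation p of its most significant marker falls below `alpha`
(default 0.05), controlling the FDR across traits. A raw per-record
threshold (`significance = "nominal"`) is available but not the default:
with several candidate markers per trait, a nominal per-record α gives a
familywise false-link rate of roughly $1-(1-\alpha)^m$ per trait, which
would swamp the anchor definition on any panel with many differentially
expressed probes.

## Anchored modules

Anchors are probes that are differentially expressed (q < 0.05) *and*
eQTL-linked (`define_anchors()`). For each anchor, `build_module()`
correlates every other probe with the anchor across all arrays, converts
r to p through the t transform with n − 2 degrees of freedom, and admits
probes at q < 1%. Correlation across arrays (rather than strain medians)
is the default because replicate arrays carry independent noise that the
correlation test should see; `use_strain_medians = TRUE` gives the
alternative.

Module validation uses a recombinant inbred (RI) panel, in which the
genome is reshuffled by recombination: true anchor→target relationships
survive the shuffle, chance correlations do not. `trim_module()` fits
each target on the anchor across RI lines within each hematopoietic
compartment, adjusts within compartment by Benjamini–Hochberg, and keeps
targets significant (FDR < 25%) in at least one compartment. Raising the
trim threshold never shrinks the kept set. Anchors themselves are
validated by `validate_in_ri()`: every SNP within the cis window is
tested against the anchor's RI expression, Holm-adjusted within each
anchor-compartment family.

Each module is summarized by its eigengene (`eigengene()`): the first
right singular vector of the probe-standardized member-by-array matrix,
unit norm, sign fixed so it correlates positively with the module's mean
standardized profile (the principal component sign is otherwise
arbitrary). A single-member module returns that member's standardized
profile. Eigengenes are tested for susceptibility association with the
same moderated model used for probes (`module_susceptibility()`), and the
module-module network (`module_network()`) keeps edges with eigengene
correlation strictly above 0.5, dropping low and negative correlations.
Modules with fewer than three post-trim targets are retained but flagged
minimal.

## The synthetic panel generator

`simulate_panel()`, `simulate_expression()` and `simulate_ri_panel()`
plant a complete ground truth so that every stage can be audited. The
defaults describe a study-sized panel: 20 strains, 120 SNPs in ~20
haplotype blocks (mean 6 SNPs) across 5 chromosomes, 4 ancestral
haplotypes per block, 5% missing genotypes, a per-cell mutation rate of
0.005 so the one-error tolerance is actually exercised, 8 CNVRs (half in
perfect LD with their host block, half independent), 150 probes on 3
replicate arrays per strain with noise SD 0.5 (log-expression units), 5
anchors with 20 trans targets each at effect sizes twice the noise SD,
and a quarter of strains with masked (unknown) phenotype. The RI
generator produces mosaic lines (Poisson recombination breakpoints,
default 3 per chromosome) and regenerates expression from the same
planted effects with independent noise in each compartment.

Planting truth that is *recoverable in principle* requires care, and the
following construction rules exist purely to make the planted structure
well-posed — they were fixed while designing the generator, not tuned
against test outcomes:

- **Pattern geometry.** Within a block, ancestral haplotypes are given
  binary codes; the first SNPs lay down the code bits (guaranteeing
  distinct consensus strings), the next the parity bit, after which every
  pair of haplotypes differs on at least two of the available
  bipartitions, and later SNPs cycle through them. Haplotype classes are
  exactly balanced. This keeps clusters separable in every left-anchored
  window the block grower passes through, even with sporadic missing
  calls — random per-SNP bipartitions instead produce windows in which
  two haplotypes differ at a single SNP, where no clustering method can
  distinguish "merge" from "split" reliably.
- **Boundary identifiability.** Adjacent blocks receive strain
  assignments whose joint refinement exceeds 6 classes, and the leading
  bipartition of each block must split enough of the previous block's
  classes (both sides ≥ 2 strains) that absorbing even one SNP across a
  planted boundary costs more than one consensus error. With 2 ancestral
  haplotypes such a guarantee is impossible (any two adjacent 2-class
  blocks refine to ≤ 4 ≤ 6 classes and simply merge), which is why the
  default is 4.
- **Susceptibility architecture.** A latent balanced bipartition of the
  strains defines susceptibility; the blocks refining it (one per
  chromosome, at the chromosome middle) host the phenotype-linked
  anchors. Placing them on different chromosomes means they segregate
  independently in the RI cross — exactly the property that lets
  trimming tell one module's targets from another's. Anchor class
  effects are split by bipartition side with clear within-side spread:
  the side component makes the anchor differentially expressed, the
  within-side component gives each anchor a signature unique to its own
  locus (without it, all susceptibility modules collapse into a single
  super-module).
- **Unambiguous anchor status.** Non-anchor probes are placed more than
  one cis window away from every anchor/susceptibility block interval,
  and LD-linked CNVRs are hosted off the susceptibility blocks. A
  phenotype-driven target probe within cis reach of a phenotype-linked
  locus (or of a fragment of one, after a block split) is *genuinely*
  cis-associated and differentially expressed — indistinguishable from an
  anchor by any method — so leaving such placements in would make
  "planted anchor" an ill-defined notion rather than a harder test.
  For the same reason, susceptibility blocks use class codes in which no
  single code bit reproduces the susceptibility bipartition (and the
  parity split, which would, is omitted there): no individual SNP of a
  susceptibility block is phenotype-aligned on its own, so a short block
  fragment that breaks off at a boundary carries no side signal, while
  the full multi-SNP haplotype still does — which is, after all, the
  point of haplotype-level association.

On the miniature genome (chromosomes of roughly 0.3 Mb) the pipeline's
default cis window is 50 kb, about one haplotype block — the analogue of
a 2 Mb window on a real mouse chromosome; `map_cis_eqtls()` itself
defaults to 2 Mb for real-scale data.

What the generator does **not** emulate: realistic linkage
disequilibrium decay (blocks are independent by design), array probe
effects, batch or normalization artifacts, structured (run-length)
missingness, dominance or epistasis, and trans-eQTL architecture beyond
the planted anchor→target links. Tests passing on these panels show the
machinery is correct and calibrated under the stated model; they do not
certify performance on real arrays.

## Operating characteristics

The `evaluate_*` family re-derives the package's operating
characteristics from scratch; the test suite asserts on them and
`scripts/acceptance.R` reports them. Problem sizes are chosen so a full
audit runs on a laptop: 200 small genotype-like panels for the
exhaustive-oracle comparison (≤ 6 strains, ≤ 8 SNPs, where all set
partitions can be enumerated), 100 simulated panels for planted-block
recovery (10% missingness, 0.005 mutation) and for tagging specificity,
500 null simulations each for the cluster-test and eQTL-permutation
calibration, 100 planted-mixture data sets for DE FDR/recall (6 vs 6
strains, effects of 3 noise SD), 25 RI panels of 50 lines for validation
power, and 20 end-to-end pipeline runs for module recovery (mean Jaccard
between planted and trimmed target sets). The exhaustive references — the
set-partition boundary oracle, the full enumeration of the cluster-test
null, the closed-form biallelic r², and the direct SVD recomputation of
eigengenes — are independent of the code paths they check.

Two subtleties in the oracle comparison deserve note. First, the
exhaustive reference caps the cluster count at one less than the number
of strains — the same cap PAM operates under — because otherwise any
panel of at most six strains is trivially feasible via all-singleton
haplotypes and the reference never splits. Second, the block grower
selects its cluster count by silhouette, not by error count, so its
chosen clustering can carry more consensus errors than the exhaustive
minimum and split a window the oracle would keep; that is how the
algorithm is designed to behave, not a defect. Boundary agreement is therefore
asserted on *decision-consistent* panels — those where the chosen
clustering and the exhaustive optimum agree on every split decision, so
that any boundary difference would expose a genuine bookkeeping error —
and the rate of decision consistency is reported alongside (around 20%
on these deliberately noisy miniature fixtures, where most windows
contain a mutated cell the exhaustive search can isolate but a
silhouette-guided clustering often cannot).

## Known limitations

The block grower is greedy and order-dependent (left-to-right), as
block-partitioning procedures of this family are; it does not revisit
earlier boundaries. PAM with silhouette selection can merge haplotypes
that differ at a single SNP of a short window; the consensus refinement
mitigates but cannot eliminate this, and the planted-recovery figures
quantify what remains. The relatedness weighting is a documented
stand-in, not an estimate of a kinship model. The q-value
smoother needs a few hundred p-values to estimate π₀ usefully; below 100
it deliberately falls back to BH. Coordinates are 1-based inclusive
everywhere, and all tabular outputs state this in their headers.
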