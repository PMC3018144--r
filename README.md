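# anchornet

Integrated genomics for inbred strain panels: haplotype-block maps,
CNVR tagging, cis-eQTL mapping, and anchored co-expression modules
associated with a binary phenotype.

## The problem

In panels of classical inbred mouse strains, susceptibility to a disease
(for example, leukemia following alkylator chemotherapy) varies by strain
and is partly genetic. A productive way to dissect such a trait is to
integrate three layers of data on the same strains: SNP genotypes,
inherited copy-number variant regions (CNVRs), and expression profiles of
the tissue at risk. `anchornet` implements that workflow end to end, for
analysts working with strain panels who want each statistical step to be
explicit, tested, and reproducible:

1. **Haplotype map.** SNPs are grown left-to-right into haplotype blocks:
   within a block, strains are clustered into 2–6 ancestral haplotypes
   (PAM, cluster count by maximum average silhouette) and the block is
   extended while the consensus haplotypes predict every typed genotype
   with at most one error.
2. **CNVR tagging.** Whether a block captures a CNVR's genotype is scored
   by the pooled multi-allelic R², the haplotype-frequency-weighted
   average `sum_h p_h * r2_h` of squared correlations between each
   haplotype indicator and the best-matching copy-number class.
3. **Phenotype-predictive clustering.** The ratio of mean expression
   distance among susceptible strains to the mean susceptible–resistant
   distance (1 − Pearson on strain medians), with an add-one permutation
   p-value over strain-label shuffles.
4. **Differential expression.** Per-probe moderated t-tests
   (empirical-Bayes variance shrinkage) on replicate-weighted strain
   means, with Storey q-value FDR.
5. **cis-eQTL mapping.** One-way ANOVA of strain-mean expression on
   haplotype or CNVR genotype factors within a cis window, with a
   relatedness-weighted strain permutation null and per-trait
   best-marker selection.
6. **Anchored modules.** Anchors are probes both differentially expressed
   and cis-eQTL-linked; each seeds a module of correlated probes
   (FDR < 1%), trimmed by replication against the anchor in an
   independent recombinant inbred panel (FDR < 25% in ≥ 1 compartment),
   summarized by its eigengene (first principal component) and scored for
   phenotype association.

A first-class synthetic-data generator plants all of this structure —
ancestral haplotype mosaics, missing genotypes, CNVRs in and out of LD,
cis and trans effects, a phenotype — so every stage can be audited
against known truth. See the vignette
(`vignettes/anchored-modules.Rmd`) for the models, parameter choices and
design decisions.

## Worked example

```r
library(anchornet)

sim <- simulate_panel(seed = 1)                  # 20 strains, 120 SNPs, CNVRs
se  <- simulate_expression(sim, seed = 1)        # 150 probes x 60 arrays + phenotype
ri  <- simulate_ri_panel(se$truth, seed = 1)     # 50 recombinant inbred lines

res <- run_anchored_pipeline(
  sim$geno, sim$cnvrs, se$expr, se$panel,
  se$truth$expression$probe_positions, ri = ri, seed = 1)
```

Output (as printed by the code above):

```
genotype_matrix: 20 strains x 120 SNPs on 5 chromosome(s); 5.0% untyped
expression_matrix: 150 probes x 60 arrays (20 strains); 98.0% detected
blocks: 22 | cluster-test ratio 0.207, p = 0.0016 | DE probes q<0.05: 105
anchors: P0001, P0002, P0003, P0004, P0005, P0084
 module_id anchor n_initial n_trimmed comp1 comp2 susceptibility_q
       A_1  P0001       105        22    20    22         1.22e-12
       A_2  P0002       104        48    40    47         1.24e-13
       A_3  P0003       104        20    20    20         4.33e-13
       A_4  P0004       104        25    25    20         6.76e-13
       A_5  P0005       105        43    42    41         1.24e-13
       A_6  P0084       105        20    20    20         1.78e-12
CNVRs tagged: 4 of 8 | anchors validated in RI: 5 of 6
```

Reading this: the builder recovered 22 haplotype blocks from the 20
planted ones; expression clustering separates susceptible from resistant
strains far better than chance (within/between distance ratio 0.21,
permutation p ≈ 0.002); 105 probes are differentially expressed at
q < 0.05 (the 5 planted anchors and their 100 phenotype-driven targets);
six probes are both DE and cis-linked and become anchors — the five
planted ones plus one borderline false discovery. Each anchor's initial
module of ~105 correlated probes is trimmed to the ~20–48 probes whose
association with the anchor replicates in the recombinant inbred panel
(per-compartment counts shown), and every trimmed module's eigengene is
strongly associated with susceptibility. The four CNVRs planted in
perfect LD with a haplotype block are tagged (pooled R² > 0.8); the four
independent ones are not.

The same stages are scriptable from a shell through the bundled CLI
(`inst/scripts/anchornet`), with subcommands `simulate`, `haplomap`,
`tagcnvr`, `clustertest`, `de`, `eqtl`, `modules` and `run-all`; every
run writes a log echoing its seed and parameters.

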