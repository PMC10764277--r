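# magpheno

Metabolic phenotype prediction and growth association for
metagenome-assembled genomes (MAGs).

## The problem

Microbiome-directed nutritional interventions pose a chain of questions that
each need their own statistical machinery: *which* gut bacterial genomes
(MAGs, reconstructed from faecal shotgun sequencing) track a child's
ponderal growth (weight-for-length Z score, WLZ); *what* those genomes can
metabolize (binary metabolic phenotypes inferred from gene content); *which
expressed pathways* respond to treatment; and *whether the genomic loci
behind those pathways* (polysaccharide utilization loci, PULs, in
Bacteroidota) are conserved in the growth-associated strains. `magpheno`
implements that chain as a reproducible pipeline for methodologists and
microbiome analysts, together with a synthetic-data generator that produces
every input with known ground truth, so each stage — and the pipeline end to
end — is validated against planted answers.

## What is inside

* **Annotation** — functional roles for MAG proteins from tabular alignment
  hits: top-50 hits by bitscore, multi-domain splitting by 1-D clustering of
  alignment coordinates, a per-domain Gaussian-KDE identity threshold (the
  highest prominent local minimum of the identity density), majority-rule
  role calls with an outgroup veto; domains under 35 aa are dropped.
* **Phenotypes** — the binary phenotype matrix (BPM) by three strategies
  reconciled into consensus calls with confidence grades: per-pathway
  decision trees (`rpart`), tuned random forests, and neighbour-group
  Hamming matching over MinHash/Mash genome distances
  (d = −(1/k)·ln(2j/(1+j)), grouping cap 0.1, groups ≥ 4); a positive
  neighbour vote rescues the correlated false negatives that gene dropout
  induces in the other two methods.
* **Association** — per-MAG linear mixed models
  `WLZ ~ β₁·MAG + β₂·week + (1|PID)` and treatment models
  `MAG ~ β₁·group + β₂·week + β₃·group×week + (1|PID)` (lme4/lmerTest,
  REML, Satterthwaite tests), behind the printed filters
  (> 5 TPM in > 40% of samples; transcripts ≥ 5 CPM in ≥ 35%; transcript
  zeroing below 0.5 TPM DNA), variance stabilization, TMM + negative
  binomial quasi-likelihood differential expression (edgeR), the ranking
  metric sign(logFC)·−log₁₀(p), and BH FDR.
* **Enrichment** — pre-ranked GSEA: weighted running-sum enrichment score,
  gene-label permutation null, sign-stratified p and NES, q < 0.1 rule,
  ≥ 10-gene pathway sets, leading-edge extraction.
* **PULs** — detection seeded at adjacent SusC/SusD pairs, conservation
  classification (conserved / structurally distinct / absent) from > 90%
  global-alignment identity and identical ORF organization, the
  {1, 0.5, 0} profile encoding, and Pearson correlation of profile
  distances with growth-association coefficients.
* **Pipeline** — `runEndToEnd()` orchestrates everything with one seed,
  strict config validation, per-stage checksums and a machine-readable
  report of recovery metrics against the generator's truth.

## Worked example

Simulate a cohort under the default study conditions (60 reference genomes
in 10 clades, 20 metabolic phenotypes, 30 MAGs at 90% completeness, 40
participants sampled at weeks 0–12 in two arms, planted WLZ and
treatment×week effects), then ask which MAGs track growth and whether the
growth-associated MAGs respond to treatment:

```r
library(magpheno)

cfg    <- simulationConfig(seed = 42)
pg     <- generateReferenceCollection(cfg)
cohort <- simulateCohort(pg, cfg)
pg
#> ReferencePangenome with 60 genomes, 20 phenotypes, 63 functional roles
cohort
#> SyntheticCohort: 30 MAGs, 1127 transcripts, 200 samples from 40 participants

assoc <- magWlzAssociation(cohort)            # WLZ ~ MAG + week + (1|PID)
head(assoc[order(assoc$q), ], 6)
#>  feature estimate    se     t        p        q
#> MAG_G001    0.976 0.102  9.58 5.32e-18 1.54e-16
#> MAG_G003    0.950 0.104  9.10 1.11e-16 1.61e-15
#> MAG_G005   -0.892 0.109 -8.18 3.45e-14 3.34e-13
#> MAG_G006   -0.824 0.112 -7.37 4.59e-12 3.33e-11
#> MAG_G002    0.650 0.114  5.69 4.68e-08 2.71e-07
#> MAG_G004    0.663 0.120  5.50 1.15e-07 5.57e-07
sum(assoc$q < 0.05)
#> [1] 8
```

The generator planted β₁ = ±0.5 on eight MAGs (`cohortTruth(cohort)$beta1`);
exactly those eight head the table, with the right signs. `estimate` is per
SD of variance-stabilized abundance. Now rank all MAGs by how much faster
they grow under treatment (the β₃ t-statistic) and test whether the
WLZ-associated MAG sets are enriched at the extremes:

```r
treat <- magTreatmentModels(cohort, ref_level = "RUSF")
sets  <- list(wlz_positive = assoc$feature[assoc$q < 0.05 & assoc$estimate > 0],
              wlz_negative = assoc$feature[assoc$q < 0.05 & assoc$estimate < 0])
gseaPreranked(rankFeatures(treat$feature, treat$t3), sets,
              n_perm = 2000, seed = 42, min_size = 3)[, 1:6]
#>          set size     ES   NES      p      q
#> wlz_positive    4  0.877  1.48 0.0175 0.0175
#> wlz_negative    4 -0.920 -1.78 0.0035 0.0070
```

MAGs positively associated with growth are significantly enriched among
those whose abundance rises faster under the microbiome-directed food
(positive NES), and the negatively associated set shows the mirror-image
depletion — the planted treatment response, recovered end to end. A single
call runs the whole pipeline (annotation, consensus phenotypes, association,
transcript enrichment, PUL conservation) and reports recovery metrics:

```r
report <- runEndToEnd(runConfig(simulation = cfg, seed = 42))
str(report$metrics)
```

## Vignette

`vignettes/magpheno-methods.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical choices
(tie-breaks, degenerate inputs, the identity-denominator convention), and
known limitations.
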