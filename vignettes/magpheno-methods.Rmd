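---
title: "Methods: metabolic phenotypes and growth association for MAGs"
author: "magpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic phenotypes and growth association for MAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`magpheno` implements, as a tested and reproducible pipeline, the
computational core of a class of microbiome intervention studies: relate the
gene content and gene expression of metagenome-assembled genomes (MAGs) to a
longitudinal clinical outcome — here ponderal growth, measured as the
weight-for-length Z score (WLZ) — in a two-arm feeding trial. The pipeline
has six stages: synthetic-data generation, functional annotation, consensus
metabolic-phenotype prediction, longitudinal association modelling,
pre-ranked gene set enrichment analysis (GSEA), and polysaccharide
utilization locus (PUL) conservation analysis. Every stage can be exercised
end to end on generated data with known ground truth, which is how the test
suite and the acceptance script validate it.

# Functional annotation

MAG proteins are annotated from tabular alignment hits (DIAMOND/BLAST
outfmt-6 dialect) against a reference database of role-labelled proteins
plus an outgroup of proteins outside any curated subsystem.

Per query, the workflow is:

1. **Top hits.** The 50 highest-bitscore hits are retained; ties at the
   boundary are broken by lexicographic subject id so the selection is
   deterministic and the whole procedure is invariant to input order.
2. **Domain splitting.** Alignment start and end coordinates are clustered
   independently by density-based one-dimensional clustering (points chain
   while consecutive gaps are at most 10 residues; clusters need at least 2
   points; singletons are noise). Rounded cluster means become candidate
   boundaries; each start is paired with the last end before the next start.
   Hits are attributed to the domain they overlap most, and domains shorter
   than 35 residues are discarded. The mean (not the median) is the centre
   statistic; with the coordinate jitter of real alignments the two are
   nearly identical, and the mean is smooth in the inputs.
3. **Identity threshold.** Per domain, a Gaussian kernel density (Silverman
   rule-of-thumb bandwidth, 512 grid points over [0, 100]) is fitted to the
   percent-identity distribution of the attributed hits, and the
   highest-identity interior local minimum is used to discard
   lower-confidence hits. Two guards make the "no minimum, keep everything"
   fallback reachable in practice: minima at negligible density
   (below $10^{-6}$ of the peak) or outside the data range are ignored, and
   a minimum must be a *prominent* valley — its density at most 0.7 of the
   smaller flanking peak. Without the prominence condition, sampling wiggles
   on a perfectly unimodal identity sample produce spurious "minima" that
   would discard half the genuine hits; with it, well-separated modes are
   still split even at a dozen hits (valley ratios near 0.55) while
   unimodal wiggles (ratios above 0.77) are not. The threshold is computed
   per (query, domain), and the length filter is applied before
   thresholding.
4. **Majority rule with outgroup veto.** Surviving hits vote by reference
   role; outgroup hits vote as a single bloc against annotating. The
   plurality wins; vote ties are resolved by larger summed bitscore and
   abstain if still tied; an outgroup plurality leaves the domain
   unannotated. Gene fragments are annotated through exactly the same path
   as whole genes.

# Consensus metabolic phenotypes

The binary phenotype matrix (BPM) — genomes by metabolic pathways, with 1
meaning a complete functional pathway — is predicted by three strategies and
reconciled:

* **Pathway rules**: one classification tree per phenotype (`rpart`, Gini
  impurity, no pruning, depth capped at the number of roles in the pathway)
  over role presence/absence in the reference genomes. Deterministic, but by
  construction it inherits every false negative that MAG incompleteness
  induces: a dropped gene reads as an absent role.
* **Random forest**: per phenotype, 200 trees with a small grid search
  (`mtry` in {sqrt(p), p/3}, minimum node size in {1, 3}) selected by
  out-of-bag error; leave-one-out accuracy across the reference genomes is
  reported on request. Tree diversity makes the forest partially robust to
  single-gene dropout.
* **Neighbour groups**: genomes are sketched by bottom-`s` MinHash
  (k = 21, sketch size 1000 — community defaults) and grouped with their
  close relatives by single-linkage under a Mash distance cap of 0.1
  (approximately ANI >= 90%); groups smaller than 4 dissolve. Within a
  group, and per phenotype, the MAG adopts the phenotype of the reference
  genome with the smallest Hamming distance on the roles *required by that
  pathway* — even if some genes are absent from the MAG. Equidistant
  references with conflicting phenotypes abstain, as does a MAG in no group.

**Reconciliation.** Unanimity gives the common value at high confidence.
With a participating neighbour vote, a 2-vs-1 split resolves by majority at
medium confidence — with one deliberate exception: a *positive* neighbour
vote overrides negative rule and ML votes. The two gene-content methods see
the same incomplete gene set, so their false negatives are strongly
correlated, and the neighbour-group strategy exists precisely to rescue
those; a symmetric majority would let the two correlated failures outvote
the rescue. The override is one-directional: a negative neighbour vote never
vetoes two positive gene-content votes, because observed complete pathways
are strong direct evidence. When the neighbour vote abstains, rules/ML
agreement is medium confidence and an irreconcilable disagreement defaults
to the machine-learning value at low confidence. The confidence grades are
this package's concrete scheme.

Downstream, gene annotations are filtered to *intact* pathways: a gene
survives only if its role belongs to at least one pathway called 1 in that
genome.

# Longitudinal association models

MAG abundances (TPM) are filtered by the strict rule "> 5 TPM in > 40% of
samples"; transcript counts by the inclusive rule ">= 5 counts per million
in >= 35% of samples"; and transcripts of a MAG whose DNA abundance in a
sample is below 0.5 TPM are zeroed in that sample (strict `<`) before any
library computation (CPM is computed after zeroing).

Counts are variance-stabilized by median-of-ratios size factors followed by
a shifted log2. This layer is a deliberate surrogate: it is monotone, finite
on zeros, and flattens the mean-variance trend of overdispersed counts; no
equivalence to any particular published transform is claimed or needed,
because only rank and threshold behaviour is load-bearing downstream.

The association models are random-intercept linear mixed models fitted by
REML with `lme4`, with Satterthwaite t-tests from `lmerTest`:

$$\mathrm{WLZ} \sim \beta_1(\mathrm{MAG}) + \beta_2(\mathrm{week}) + (1 \mid \mathrm{PID})$$
$$\mathrm{MAG}_i \sim \beta_1(\mathrm{group}) + \beta_2(\mathrm{week}) + \beta_3(\mathrm{group} \times \mathrm{week}) + (1 \mid \mathrm{PID})$$

The second form is reused unchanged for WLZ-response-quartile contrasts and
for glycosidic-linkage models; `ref_level` controls which group is the
reference so that $\beta_3 > 0$ means "grows faster under treatment". In
`magWlzAssociation()` each MAG's variance-stabilized abundance is
standardized before fitting, so $\beta_1$ is per SD of abundance and
comparable across MAGs. When the between-participant variance is estimated
at the boundary the fixed effects coincide with ordinary least squares; the
test suite asserts this to $10^{-6}$. Multiple testing uses
Benjamini-Hochberg throughout, with q < 0.05 for associations and q < 0.1
for enrichments.

Transcript-level differential expression uses edgeR: TMM normalization
(log-ratio trim 0.3, abundance trim 0.05, factors at geometric mean 1),
trended negative-binomial dispersions, and quasi-likelihood F-tests on a
`~ group * week` design (no participant term, matching standard practice
for this model class). The GSEA ranking metric is
$\mathrm{sign}(\log \mathrm{FC}) \times -\log_{10} p$, with p clipped at
$10^{-300}$ and ties in the ranked list broken by feature id so enrichment
is deterministic.

# Pre-ranked GSEA

The enrichment score is the classic weighted Kolmogorov-Smirnov running
sum (weight 1): member steps rise by $|r|^w$ normalized over member weights,
non-members fall by $1/(N - m)$; the score is the extremum. The null is
built from random same-size member sets (the pre-ranked convention), 10,000
permutations by default. P-values are sign-stratified,
$(1 + \#\{\text{same-sign } |ES_{null}| \ge |ES|\})/(1 + n_{perm})$, with
ties counted as exceedances; NES divides by the mean same-sign null
magnitude; BH runs across scored sets. Pathway sets need at least 10
members after intersecting the ranked universe (smaller sets are skipped
with a reason, not errored); MAG sets (positively / negatively
WLZ-associated) use a lower floor because the scaled-down cohorts carry far
fewer MAGs than a real study. Leading-edge members are those at or before
the peak (positive ES) or at or after the minimum (negative ES). The
implementation is checked exactly against a naive brute-force running sum,
against an independent GSEA implementation, and against exhaustive
enumeration of all $\binom{8}{3}$ member sets on a toy universe.

# PUL conservation

PULs are detected by seeding at adjacent SusC/SusD transporter pairs and
extending over CAZyme and regulator ORFs, bridging at most 2 unrelated ORFs;
overlapping seeds merge. Conservation of a reference PUL in a query genome
is classified from anchored homologue search: every component ORF is matched
to its best query ORF by global alignment identity. Identity is matches
divided by the *full end-to-end alignment length* — terminal gaps count, so
a fragment can never reach high identity against a full-length protein;
this denominator convention is what makes the "missing or fragmented"
clause operative. The category is

* `conserved`: every component matched above 90% identity, in identical
  order (a strand-flipped, order-reversed block still counts), with no
  extra component ORFs inside the block;
* `structurally_distinct`: a homologous block exists (at least two anchored
  components) but components are missing or fragmented (two or more partial
  matches jointly covering at least 80% of the reference ORF) or extra
  components are inserted;
* `absent`: fewer than two anchors.

Profiles encode categories as 1 / 0.5 / 0 over the reference PUL order;
genome-to-reference Euclidean distances are related to per-genome growth
association coefficients by Pearson correlation with a two-sided t-test
(requiring at least 3 genomes and non-degenerate variance).

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions used throughout the package:

* **Reference collection**: 60 genomes, 20 phenotypes with 2-4 required
  roles per pathway variant (a deliberate scale-down of a curated reference
  of thousands of genomes and ~100 pathways), phenotype prevalence clamped
  into [0.3, 0.7]. Genomes fall into 10 clades: each protein family has a
  base sequence, a per-clade variant (10% per-site divergence, which puts
  between-clade Mash distances beyond the 0.1 grouping cap) and per-genome
  copies (pairwise within-family identity ~0.95). Carrier status is
  assigned per clade with a 10% per-genome flip rate, reflecting the
  empirical observation that close relatives tend to possess or lack entire
  pathway variants — the premise that makes neighbour-group rescue work.
  Non-carriers hold sparse (8%) incomplete subsets of pathway roles. The
  truth BPM is recomputable from emitted gene content, exactly.
* **MAG degradation**: genes retained independently at completeness 0.9,
  split into two fragments at rate 0.05, contaminants drawn from other
  genomes at rate 0.02 with full provenance (matching the common ">= 90%
  complete, <= 5% contaminated" quality gate). Contaminants are tagged but
  visible downstream, as in real MAGs.
* **Cohort**: 40 participants, study weeks 0/2/4/8/12, two arms. MAG
  abundances are log-normal with participant-level offsets (the spec of the
  real data's abundance distribution is unknown; log-normal is a modelling
  choice, not a claim), normalized to TPM per sample, with counts drawn
  negative-binomially (dispersion 0.5). WLZ is baseline -2.5 + participant
  intercept (SD 0.3) + 0.015/week + planted $\beta_1$ effects on the
  standardized variance-stabilized abundance scale + noise (SD 0.25), so
  mixed-model recovery is well-posed. Planted $\beta_3$ effects tilt MAG
  abundance trajectories (and, for configured pathways, member transcripts
  of positively planted MAGs) between arms.
* **Alignment hits and annotation fixtures**: hits are simulated directly
  (identity distributions, coordinate jitter, bitscores increasing with
  identity and length) rather than by running an aligner; identity is the
  only sequence property the annotation path consumes.
* **PUL variants**: conserved copies are point-mutated at 3% per site
  (comfortably above the 90% identity bar), structurally distinct variants
  carry exactly one recorded defect, absent variants are omitted; a study
  generator plants a monotone decay of conservation against the association
  coefficient.

What the generator does **not** emulate: read-level sequencing, assembly
and binning artefacts beyond Bernoulli gene dropout, realistic phylogenetic
sequence evolution (mutations are i.i.d. per site), compositional coupling
beyond TPM normalization, and real pathway curation noise. Green tests
therefore demonstrate correctness of the algorithms under their stated
sampling models, not performance on real sequencing data.

# Numerical choices and degenerate inputs

* All randomness flows from one top-level seed through named substreams, so
  adding a stage never perturbs another; every generator and the pipeline
  are bit-reproducible under a fixed seed (checksummed in the tests).
* Determinism at ties: hit selection by subject id; ranked lists by feature
  id; grid search by listed order; domain attribution to the earlier domain.
* Degenerate inputs error early and by name: empty identity vectors,
  constant responses, rank-deficient designs, all-zero samples (named), one
  -level group factors, transcripts without a MAG of origin, mismatched
  sketch parameters, fewer than 3 genomes for correlation.
* Mash distance caps at 1 for disjoint sketches; $d = -(1/k)\ln(2j/(1+j))$
  otherwise.
* The pipeline validates its configuration (unknown keys rejected) before
  any stage runs, writes per-stage outputs with md5 checksums, skips
  rewriting up-to-date outputs unless forced, and leaves an `INCOMPLETE`
  marker on failure.

# Problem sizes

The test suite runs the full study conditions where the property demands it
(60 genomes / 20 phenotypes / 20 seeds for consensus recovery; 100
replicates for effect recovery; 500 null fits for type-I calibration; 50
seeds for the conservation-association decay) and deliberately small
configurations (12-20 genomes, 200-400 permutations) where only plumbing,
determinism or error paths are at stake. The acceptance script scales the
consensus check to 5 seeds; all other checks run at full size.

# Known limitations

* The cohort-level $\beta_1$ recovery carries a small omitted-variable bias
  (~0.1-0.2 absolute on the per-SD scale) because several planted MAGs
  contribute to one WLZ trajectory while models are fitted one MAG at a
  time, and TPM normalization couples abundances compositionally. Rank and
  sign recovery — what the downstream enrichment consumes — are unaffected.
* Treatment models fit one REML LMM per feature; no empirical-Bayes
  moderation across features is applied, and no numeric equivalence to
  moderated implementations is claimed.
* The variance-stabilizing layer is a surrogate (see above).
* Neighbour-group prediction inherits the quality of the grouping: if
  clade structure is absent (every genome equidistant), the rescue
  degrades gracefully to the rules/ML consensus but loses its advantage.
* PUL substrate prediction is out of scope; family labels are taken as
  input.
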