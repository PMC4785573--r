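---
title: "famibd: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famibd: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famibd)
```

`famibd` re-implements, as a tested pipeline, the analysis design used for
multiplex inflammatory bowel disease (IBD) families: identify genomic
segments shared identical by descent (IBD, the genetics sense) by all
affected relatives, filter rare candidate variants inside and outside
those segments, and quantify the burden of known common risk variants
through subtype-specific polygenic risk scores (PRS).  This vignette
documents the models behind each step, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the published description left the design
open.

## 1. Segment sharing in deep pedigrees

### Point-sharing probability

For a set of relatives connected to a common ancestral couple, the
probability that all of them carry a copy of one of the couple's four
haplotypes at a fixed genomic point is computed by exact enumeration of
inheritance vectors on the minimal transmission subgraph
(`point_sharing_probability`).  Each meiosis transmits one of the parent's
two strands with probability 1/2; meioses out of the ancestral couple
resolve both founder strands.  The couple is contracted to a single node
for the meiosis count `m` (parent–child 1, full sibs 2, first cousins 4).
The enumeration reproduces the classical kinship values: full sibs share
at a point with probability 3/4, an avuncular pair 1/2, first cousins 1/4,
and on lineal chains the probability at least halves with each added
meiosis.

Enumeration is bounded at `m ≤ 26` (the work is `2^(m + c)` with `c` the
number of couple children, evaluated in vectorized chunks); beyond the
bound the error message directs the caller to the Monte-Carlo estimator.

### Genome-wide probability

`genome_sharing_probability` models the genome as
`N = C + m·ρ` segments — one starting segment per chromosome plus one per
expected crossover across the `m` connecting meioses — each sharing
independently with the point probability `p`:

\[ P(\ge 1\ \text{shared segment}) = 1 - (1 - p)^N
   \quad\text{(binomial form; a Poisson form } 1 - e^{-pN}
   \text{ is available by flag).} \]

`ρ` defaults to 35.3 crossovers per meiosis, the genome-wide human
autosomal recombination rate, allocated to the 22 GRCh37 autosomes
proportionally to physical length.

**Validity.** The independence assumption is exact when chromosomes do not
recombine (`ρ = 0`, `N = C`) and accurate when the point probability is
small and segments are few — exactly the regime of the deep-family
application, where `p ≈ 2^{2-m}` is tiny and the product `pN` is small.
On short, crossover-dense maps with close relatives the approximation
carries an `O(ρ)` bias that we measured against the package's own
gene-drop oracle: e.g. for a 6-meiosis collateral chain on a one-chromosome
map with `ρ = 2` the model gives 0.568 where the simulated truth is 0.499.
The acceptance suite therefore checks oracle equivalence in the
few-segment regime (and on the first-cousin worked example at `ρ = 2`,
where the bias is within Monte-Carlo noise at 2,000 simulations), and a
separate regression test bounds the sparse-map bias at 0.035.  Users
applying the model to close relatives on dense maps should prefer
`gene_drop_sharing_mc` directly.

### Pedigree reconstructions

The two deep study families are shipped as `family1_pedigree()` and
`family2_pedigree()`.  The published pedigree drawings are not
machine-readable, so these are reconstructions constrained by the textual
description: family 1 has five affected members (four CD, one UC) in two
sibships whose branch parents are 5 and 6 meioses below one ancestral
couple (an 11-meiosis path, "distant relationship over 10 generations"),
giving `m = 15`; family 2 has four distantly related affected branch
members (one CD, three UC) 4, 4, 5 and 6 meioses below a common couple
(`m = 19`), plus the separately descended UC individual 2-V-1 who is
excluded from sharing analyses.  With these graphs the model yields
genome-wide sharing probabilities of 0.0651 (family 1) and 0.0053
(family 2) — 0.07 and 0.01 at two decimals.  The reconstruction, not the
formula, is the principal source of uncertainty here: one meiosis more or
less changes the leading digit, which is why the pedigrees are fixed,
documented objects rather than user defaults.

### Observed sharing

`shared_segments` scans rare alleles (population frequency ≤ 3% by
default, mirroring the candidate-variant rarity bound): maximal runs with
at least `min_support` sites carried by *all* targets and at most
`max_conflicts` rare alleles private to a strict subset are reported as
segments (0-based half-open intervals; widening the conflict budget never
shrinks a segment).  For nuclear families, `infer_inheritance_states`
classifies each informative site into the four canonical states
(identical / haploidentical-paternal / haploidentical-maternal /
nonidentical) by exhaustive compatibility of the children's genotypes with
parental strand transmissions, then smooths the votes with a running mean
over `window` informative sites (default 10).  Sites where both parents
are homozygous carry no vote.  Ties extend the preceding state; a tie at
the start of a chromosome prefers the haploidentical states over
"identical", claiming only the sharing the sites prove.  At zero
genotyping error the inferred boundaries recover ≥ 95% of simulated
crossovers within a window-sized tolerance; recall degrades smoothly as
per-site error rises.

## 2. Gene-drop simulation

`gene_drop` drops uniquely labelled founder haplotypes through a pedigree.
Per meiosis and chromosome the crossover count is Poisson with the map's
expectation and positions are uniform on physical length: no crossover
interference and no hotspot structure, because the analysis consumes only
a genome-wide rate; autosomes only.  Haplotypes are segment tracks
labelled with founder-haplotype ids, so identity by descent is known
exactly in every simulation — the simulator doubles as the oracle for the
analytic sharing model and as the truth source for breakpoint-recovery
tests.  Founder genotypes come from a `founder_model`: independent loci at
stated population frequencies (no linkage disequilibrium between loci),
with optional rare variants planted heterozygously on named founders to
create family-private candidates.  Controls are unrelated Hardy–Weinberg
draws (`simulate_controls`).

Affection in simulations follows a logistic liability
(`disease_model`): `P(affected) = logit^{-1}(β₀ + β₁·score)`, with the
subtype label taken from the larger of the CD/UC scores and flipped with a
configurable mixing probability (default 0.1), since the study families
mix subtypes.  This generative stand-in exists so case/control statistics
have a known truth; the real genetic architecture of the disease is
unknown and nothing in the pipeline depends on the stand-in being right.

## 3. Polygenic risk scores and statistics

The score is `s = Σ g_i ln(OR_i)` over the loci carrying an odds ratio for
the requested subtype — the natural log of the product of carried odds
ratios: homozygous risk variants contribute twice, absent ones not at all.
A genome with no risk alleles scores exactly 0.  Risk alleles are oriented
against ref/alt (a locus whose risk allele matches neither errors by
name); missing genotypes contribute 0 risk alleles (a decision — the
source is silent; best-guess allele counts, not dosages).  The three NOD2
loci (p.R702W 2.023, p.G908R 3.500, p.L1007fs 4.255) supplement the
140 CD / 133 UC lists (110 loci shared, union 163).

Statistics follow the published analysis:

* **Wilcoxon rank-sum**, one-sided with the fixed direction "cases
  greater" (the published comparison reports enrichment of high scores in
  cases).  Mid-ranks for ties; exhaustive enumeration of rank assignments
  when `n₁+n₂ ≤ 12`, otherwise a normal approximation with tie and
  continuity corrections.  Degenerate all-equal input returns p = 1 with a
  warning.
* **AUC** as the Mann–Whitney probability with ties counting one half —
  identical to the trapezoidal area under the empirical ROC.
* **Nagelkerke pseudo R²**: intercept-only and intercept+score logistic
  fits by IRLS to tolerance 1e-8;
  `R²_CS = 1 − (L₀/L₁)^{2/n}` rescaled by `1 − L₀^{2/n}`.  Perfect
  separation produces a capped fit with a warning.
* **Transmission ratio**: observed offspring score over the parental mean.
  The parental mean is the exact expectation under the additive log-scale
  score, because each parental allele transmits with probability 1/2
  (homozygous parental loci transmit deterministically and are already
  absorbed by the mean).  Offspring with expected score 0 are excluded and
  counted; offspring with only one scored parent are excluded (decision;
  source silent).  Affected and unaffected offspring ratios are compared
  with a Welch two-sided t-test (unequal group sizes make the
  equal-variance form inappropriate).

## 4. Candidate-variant filter

A variant survives iff quality ≥ 35, population allele frequency ≤ 3%,
consequence in the functional whitelist (loss-of-function, missense,
splice, miRNA-binding, promoter, enhancer), its gene lies within 2 network
nodes of the disease concept, and it passes at least one enabled zygosity
model with every required affected member carrying.  The proprietary
disease knowledge base behind the published gene sets is abstracted to a
user-supplied gene→distance table, which is exactly the "distance to
disease" column of the published candidate table.  Consequence classes are
input annotations, never computed.  Unaffected carriers never disqualify a
candidate.  "Presence in other families" is a post-hoc annotation, not a
filter.

Zygosity models: `het` (all required affecteds heterozygous);
`hom_recessive` (all required affecteds homozygous while every genotyped
parent of one is heterozygous); compound heterozygotes are paired per
gene — two heterozygous candidates pair in each affected who carries both,
with trans phase proven when each parent carries exactly one of the two;
a pair proven cis anywhere is discarded, a pair with no phase information
is emitted as `comp_het_unphased` ("Comp-het?").  A gene qualifies when
its pairs jointly cover every required affected, which accommodates the
published pattern of one anchor variant pairing with different partners in
different siblings.  Pairing across two genes sits behind a flag, off by
default.  Restricting the required-carrier set (`restrict_targets`) only
ever enlarges the candidate set.

One published row lists a variant at 8.5% population frequency despite the
stated ≤ 3% rule; the implementation applies the stated rule and the
discrepancy (possibly a frequency-database update) is documented here, not
replicated.

## 5. The synthetic cohort: what a green test establishes

`simulate_cohort` emulates the *structure* of the study: the five
reconstructed pedigrees with 38 sequenced members (15 CD, 7 UC — the
per-family descriptions sum to one UC fewer than the cohort headline;
we keep the per-family counts and fill to 38 with unaffected members),
1,096 unrelated controls, the 140/133/110 locus bookkeeping with NOD2
added, risk-allele frequencies uniform on 0.1–0.5 and odds ratios uniform
on 1.05–1.35 (the common-variant effect-size range of genome-wide
association loci), and 2 family-private rare variants planted per family.

It deliberately does **not** emulate: linkage disequilibrium between loci;
ascertainment (affection statuses are fixed by the reconstruction, not
generated from genotypes, so the simulated families show *no* systematic
score elevation and the demo pipeline's case/control AUC is ≈ 0.5);
sequencing error beyond a configurable flip/missingness rate; and the X
chromosome.  Consequently the published cohort statistics — AUC 0.85,
Nagelkerke 39%, Wilcoxon P = 1.7e-06, which depend on 38 private genomes
and 1,096 private controls — are *not* reproduction targets; green tests
establish that the machinery is correct (oracle equivalence, parameter
recovery, truth-table exactness), not that the synthetic world reproduces
the study's effect sizes.

## 6. Numerical and interface conventions

* All internal intervals are 0-based half-open (BED); all user-facing VCF
  positions 1-based.  The conversion is its own inverse and round-trips.
* Multi-allelic VCF rows are split into bi-allelic records; allele counts
  are recomputed against each alternate.
* Segment BED output merges overlapping or abutting segments with
  identical carrier sets.
* Every simulation takes an explicit integer seed; the same seed yields
  byte-identical outputs, and the pipeline manifest records a
  path-independent hash of the configuration.
* The enumeration chunk size (`chunk_bits`, default 2^18 vectors) trades
  memory for speed and does not affect results.

## 7. Known limitations

* The genome-wide sharing model's independence approximation biases
  upward on crossover-dense maps for close relatives (section 1); use the
  Monte-Carlo estimator there.
* The deep-family reconstructions fix the meiosis counts that the
  published drawings imply but do not state; the headline sharing
  probabilities inherit that reconstruction.
* Inheritance-state inference is defined for one child pair at a time;
  larger sibships are analysed pairwise.
* The rare-allele segment scan has no haplotype-frequency model and is not
  a population-scale IBD detector.
* No liftover, no CRAM/BAM input, no genotype imputation, no LD-aware
  score adjustment, and no heritability estimation.
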