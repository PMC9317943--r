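---
title: "Multi-allelic QTL dissection and optimal cross design: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-allelic QTL dissection and optimal cross design: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qtlallele)
```

This vignette is the package's own account of its methods: the models, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
decisions a maintainer would want written down.

## The phenotype model

Plot-level observations follow the joint randomized-block model over
environments,

$$y_{ijk} = \mu + t_i + r_{j(i)} + g_k + (gt)_{ik} + \varepsilon_{ijk},$$

with environment $t_i$, replication-within-environment $r_{j(i)}$, the
genotype-by-environment interaction $(gt)_{ik}$ and the error
$\varepsilon_{ijk} \sim N(0, \sigma^2)$ treated as random.
`fit_joint_anova()` reports the sequential (in the balanced case,
orthogonal) decomposition; genotype and environment are tested against the
interaction mean square, the other terms against error.
`estimate_variance_components()` estimates $(\sigma_g^2, \sigma_{gt}^2,
\sigma^2)$ by REML (through `lme4`), with the closed-form balanced
expected-mean-square solution available as `method = "anova"` and used as
the fallback when REML fails; negative solutions are truncated at zero.
Entry-mean heritability is the plug-in
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_{gt}^2/n_t + \sigma^2/(n_t n_r))$,
its genotype-by-environment counterpart replaces the numerator by
$\sigma_{gt}^2/n_t$, and $GCV = 100\,\sigma_g/\mu$.

Unbalanced data are handled by degrading gracefully: cell means with a
harmonic-mean replication count and a warning, not a full mixed-model
machinery — the designs this package targets are balanced.

The maturity-group summary letters use Fisher's LSD at $\alpha = 0.05$ on
accession means pooled by group. The choice of LSD (rather than Tukey or
Duncan) is a design decision: it is the simplest procedure consistent with a
GLM analysis, and nothing in the downstream pipeline depends on it. Letters
mark maximal runs of groups, ordered by decreasing mean, containing no
significant pair.

## SNPLDB markers

Inbred panels are (nominally) homozygous, so each accession contributes one
haplotype. After filtering (missing rate > 20%, heterozygosity > 20%,
MAF < 0.01 — boundaries: a SNP at exactly the MAF floor is kept) and
k-nearest-haplotype majority-vote imputation (k = 5 within a 20-SNP window;
residual heterozygous calls are set missing first, since hets in inbred
lines are noise), adjacent SNPs are merged greedily left-to-right into a
block while **every pairwise** |D′| inside the candidate block exceeds 0.7
and the physical span stays within 200 kb. The all-pairs criterion and the
span cap are design decisions: the all-pairs rule makes the partition
deterministic and insensitive to the order in which SNPs join; the cap
bounds worst-case haplotype lengths and is configurable because nothing in
the method fixes it. Model-based phasing/imputation is deliberately absent:
homozygous material makes it unnecessary.

Haplotypes observed across accessions are the marker's alleles; haplotypes
rarer than 1% (mirroring the MAF floor) are pooled into the closest common
haplotype by Hamming distance, ties resolved toward the more frequent and
then lexicographically. Consequently every allele of every marker has
frequency ≥ 1% and the allele codes 1, 2, … are ordered by decreasing
frequency, with code 1 the reference allele in all model fits.

|D′| uses the standard normalization $|D|/D_{max}$ with
$D_{max} = \min(p_A q_B, q_A p_B)$ for $D \ge 0$ and
$\min(p_A p_B, q_A q_B)$ otherwise; it is undefined (an error) for a
monomorphic SNP, which cannot occur after filtering.

## The restricted two-stage multi-locus scan

Stage 1 tests each marker by a joint F test of its allele main effect *and*
allele-by-environment interaction against the covariate-only model
(intercept, environment, top 10 eigenvectors of the genetic-similarity
matrix), keeping markers with $p \le 0.05$. Including the interaction in
stage 1 is a design decision: loci whose effect exists only as QEI would
otherwise never reach stage 2. The phenotype entering the scan is the
accession-by-environment mean — replication effects average out and the
design matrix stays small.

Stage 2 is forward–backward stepwise selection over the preselected
markers' main and QEI terms, entered separately, at $\alpha = 0.01$ for both
entry and stay, under one restriction that defines the method: **the total
phenotypic variance explained by the selected QTL terms may not exceed the
trait heritability.** A term whose entry would cross the cap is not
admitted. The cap is checked against $R^2 = (RSS_{cov} - RSS_{model})/TSS$
after every forward step and asserted in the tests.

Numerical decisions:

* Forward ties break on larger partial F, then smaller genomic coordinate —
  determinism over elegance.
* Rank-deficient candidate columns are absorbed by the QR factorization
  (aliased allele columns effectively drop against the reference-allele
  constraint); a marker adding no rank to the covariates is skipped with a
  warning.
* Per-locus $R^2$ is the sequential increment in selection order, which
  telescopes exactly to the joint QTL $R^2$ — no rescaling step is needed,
  and the per-locus values are non-overlapping by construction. The
  convention (sequential rather than partial) is a documented choice;
  partial Type-III-style $-\log_{10} p$ values are reported alongside.
* Allele effects are reported as deviations with frequency-weighted zero
  mean per locus, so the model intercept is the population mean and
  genotypic predictions are intercept + summed allele effects. QEI
  estimates are reported but excluded from prediction — under randomly
  varying environments they carry no usable breeding signal.
* Stage-2 candidates always include both terms of every preselected marker
  (whether a marker whose main effect failed should still offer its QEI
  term is genuinely open; including both is the permissive choice and the
  default).

## Allele-evolution bookkeeping

Between an "old" and a "new" subpopulation, per locus: inherited = old ∩
new, emerged = new \ old, excluded = old \ new, each split by effect sign.
Presence needs one carrier by default (`min_count` raises the floor) — the
literal reading of emergence/exclusion; a zero effect counts as positive,
a deterministic tie rule. Fractions use the new-group total for inherited
and emerged and the old-group total for excluded; the set identities
(inherited + emerged = new, inherited + excluded = old) are asserted on
every call.

## Cross simulation

All $n(n-1)/2$ unordered crosses are enumerated once. Per cross, homozygous
progenies are simulated at the detected loci:

* **Linkage model** (default): per progeny and chromosome the crossover
  count is Poisson with the chromosome map length in Morgans as its mean —
  the only reading under which expected crossover counts are correct —
  crossover positions are uniform on the map, and parental segments
  alternate from a fair-coin phase. The progeny is that single recombinant
  gamete doubled (a doubled-haploid population). A `progeny_model = "ril"`
  switch instead walks a Markov chain along the loci with the effective
  recombination $R = 2r/(1+2r)$ of selfed lines, $r$ from Haldane's map
  function. The doubled-gamete default matches the Poisson-per-gamete
  description directly; which of the two a breeding program should use
  depends on how its homozygous progenies are actually derived.
* **Independent model**: every locus takes either parental allele with
  probability 1/2. For loci on distinct chromosomes the two models agree,
  which the tests verify.

No crossover interference is modelled (Poisson/Haldane). Predicted progeny
value = intercept + summed main-effect alleles. Percentiles use linear
interpolation of order statistics (position $1 + (n-1)p$, R's type 7) —
fixed and documented for reproducibility. Each cross draws from its own RNG
stream seeded by the global seed and the unordered parent pair, so results
are independent of enumeration order and stable under parallel or partial
reruns.

Scope summaries report, per maturity-group scope and pooled: the mean, min
and max of the P95, the superior-cross count (P95 above the scope's maximum
observed value), the recombination potential (mean P95 − population mean)
and the transgressive potential (max P95 − maximum observed). Whether the
predicted value should add the grand mean or an environment-specific
intercept is open; the grand mean is used, consistent with effects centered
against it.

## Candidate genes

QTL spans are extended by 200 kb (the LD-decay scale of cultivated soybean
panels) and clipped at chromosome ends; genes overlap by ≥ 1 bp. Gene-local
classes are haplotype strings over SNPs inside the gene ± 5 kb (capturing
proximal regulatory variants), rare classes pooled below 1%; a per-SNP
alternative sits behind `mode = "per_snp"`. Independence is tested by
Pearson chi-square without continuity correction after pooling classes
whose expected counts fall below 5 (the standard validity rule — the method
itself names none) into an "other" class, margin-wise, smallest classes
first. No multiplicity correction is applied to the candidate decision
($\alpha = 0.05$ per test is the method's setting); Benjamini–Hochberg
adjusted p values are reported informationally.

## The synthetic-data generator

`generate_population()` emulates the statistical structure the analysis
assumes, not the biology that produced it:

* **Genome**: 20 chromosomes (default), each with 25 well-separated blocks
  of 4 SNPs. Within a block, 12 founder haplotypes descend from a random
  mutation tree — every SNP's derived allele marks a nested (laminar)
  carrier set — so all within-block SNP pairs pass the four-gamete test and
  have |D′| = 1, while blocks assort independently. Block assembly
  therefore recovers the generator's blocks exactly (the 200 kb span cap
  keeps sampling noise between distant blocks from merging them). Founder
  frequencies decay geometrically (ratio 0.65), yielding 2–5 common
  haplotypes per 4-SNP block with a mean near 3.5; more alleles require
  more SNPs per block (a block with $S$ SNPs supports at most $S+1$
  distinct haplotypes).
* **Structure**: maturity groups (default sizes proportional to
  21/43/79/157/45/16 of 361) get mildly perturbed founder frequencies
  (Dirichlet, concentration 50) — enough stratification that the
  eigenvector correction has something to do, not enough to mimic deep
  population splits.
* **QTLs**: 40 blocks (default) carry per-haplotype effects drawn
  $N(0, 0.4^2)$ trait units, centered to a frequency-weighted zero mean, so
  effects of both signs occur. Allele counts emerge from the haplotype
  tree; the configured range [2, 10] acts as an admissible-range constraint
  on QTL blocks rather than an exact per-locus draw.
  `equalize_qtl_variance = TRUE` rescales each locus to equal realized
  variance — the right design for recovery experiments where "k planted
  QTLs jointly explaining X%" should mean k equally detectable loci, and
  the setting used in the package's recovery tests.
* **Phenotypes**: with realized genotypic variance $V_g$ and targets
  $(h^2, h^2_{gei})$, the interaction and error variances are solved as
  $\sigma_{gt}^2 = n_t\, h^2_{gei}\, D$ and
  $\sigma^2 = n_t n_r (1 - h^2 - h^2_{gei})\, D$ with $D = V_g / h^2$, so
  the realized entry-mean ratios hit the targets up to sampling noise
  (within ±0.05 at n ≥ 300, verified over seeds). Defaults: 2 environments
  × 4 replications, $h^2 = 0.83$, $h^2_{gei} = 0.12$, trait mean 40.8 —
  the scale of a protein-content trial. Environment and replication
  variances (0.25, 0.05) only add realism; they cancel from entry-mean
  heritability.

What the generator does **not** emulate: coalescent LD decay between and
within blocks, genotyping error and realistic missingness (tests inject
missingness explicitly where they need it), selection footprints, linked
QTLs inside one block, and non-Gaussian error. Passing recovery tests on
this generator therefore demonstrates the statistical machinery — filters,
block assembly, structure correction, selection, simulation arithmetic —
not robustness to real-data pathologies.

## Problem sizes in the tests

The suite validates at deliberately reduced scale: recovery runs use 400
accessions with 100 markers and 5 equal-variance QTLs over 10 seeds; null
calibrations use 500 markers × 20 seeds (stage 1) and 1,000 permutations
(chi-square); the simulator check uses 50,000 gametes at 20 cM; the
end-to-end run uses 100 accessions, 2 chromosomes and 5 QTLs with the full
2,000 progenies per cross. These sizes are the package's choice of a
convincing-but-quick validation design; every threshold they test at is
stated in the test itself.

## Known limitations

* The stepwise scan refits by QR per candidate; it is comfortable at
  thousands of markers and hundreds of accessions, but a panel with 10⁵
  markers would want the preselection stage parallelized.
* Variance components assume the balanced randomized-block layout;
  severely unbalanced trials should be analyzed with a dedicated
  mixed-model package before entering the scan with accession means.
* The cross simulator treats detected loci as the whole genetic
  architecture; undetected polygenic background inflates neither progeny
  means nor variances, so absolute progeny values are optimistic exactly
  where the QTL model under-explains $h^2$.
* Gene–QTL association inherits chi-square's asymptotics; with very small
  subpopulations the pooling rule can leave a 2×2 table and low power.
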