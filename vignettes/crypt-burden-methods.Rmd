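---
title: "Models and methods behind cryptburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cryptburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptburden)
```

# The analysis problem

Whole-genome sequencing of individually microdissected clonal units of
normal tissue — intestinal crypts being the canonical example — reads out
the somatic mutations of each unit's ancestral stem cell. In cohorts
carrying germline base-excision-repair defects (biallelic *MUTYH*
mutations), the scientific questions are quantitative: how many somatic
substitutions per year does each genotype accumulate, which mutational
processes (SBS1/5-like clocks versus the oxidative C>A signatures SBS18
and SBS36) produce them, how do mutations distribute over the shared
ancestry of crypts from one patient, and how do rates in other tissues
measured by duplex sequencing compare.

`cryptburden` implements that analysis as a reusable pipeline over
multi-sample variant pileups, and pairs it with a seeded synthetic-cohort
generator so that every stage can be exercised and validated without
access to controlled patient-level sequencing data.

# Variant classification

The substrate is a pileup: variant sites by samples, with variant-read
(NV) and total-read (NR) counts. Classification proceeds per patient:

1. **Artefact thresholds.** Variants must carry a median mutant-read
   alignment score of at least 140 (`min_asmd`) and no clipped mutant
   reads (`max_clipped = 0`). These are pass-through annotations computed
   upstream of the count table; read-level filters (overlapping-read and
   cruciform-structure artefacts of low-input libraries) cannot be
   re-derived from counts and are assumed already applied.
2. **Aggregate exact binomial test.** Read counts are summed across all
   samples of the patient. Under a germline heterozygous variant the
   aggregate VAF is 0.5, and at several-hundred-fold aggregate depth the
   one-sided binomial tail `P(X <= nv | nr, 0.5)` separates germline
   variants from somatic ones crisply. The significance cut-off
   `binomial_alpha` defaults to 1e-5; it is a configurable choice, since
   only the test itself (not its threshold) is dictated by the procedure.
3. **Beta-binomial overdispersion.** Variants that fail the germline test
   are genuine somatic calls only if their per-sample VAFs are
   *heterogeneous* — present clonally in a subset of crypts and absent in
   the rest. The overdispersion parameter rho of a beta-binomial with
   mean fixed at the pooled VAF is maximised over a 100-point log-spaced
   grid on [1e-6, 0.89]; variants with rho > 0.1 are somatic, the
   remainder artefact-filtered. Fixing the mean at the pooled VAF keeps
   the likelihood one-dimensional and exact on the grid; it mirrors the
   aggregate-based procedure rather than a joint two-parameter fit.

Sex chromosomes (expected germline VAF 1 in males) are out of scope for
the shipped tests; `expected_vaf` is exposed for that use.

# Sensitivity correction

Calling sensitivity is modelled from its two dominant determinants,
coverage and clonality: depth is Poisson around the sample mean, variant
reads binomial at the sample's median VAF, and a mutation is callable
when at least `min_alt_reads = 4` reads support it (the caller's
requirement). Both a Monte-Carlo estimator and the exact enumeration
`sum_d Pois(d; lambda) P(Bin(d, vaf) >= 4)` (depth truncated at the
1 - 1e-12 Poisson quantile) are provided; they agree within Monte-Carlo
error and the exact form is the default in pipelines. The phrase
"truncated binomial" in descriptions of this procedure is ambiguous
between truncating the Poisson depth support at zero and zero-truncating
the variant reads; both readings are implemented behind
`truncate_depth`, with the untruncated default, because sensitivity is
the probability that a real mutation yields four or more reads at a site
that may also, legitimately, have zero depth. Corrected burden is raw
burden divided by sensitivity.

# Crypt phylogenies

Crypts of one patient share ancestry; somatic mutations are irreversible
presence characters on that ancestry. A rooted binary topology minimising
the Camin-Sokal parsimony score (only 0 to 1 changes, no reversals) is
found by branch-and-bound stepwise addition: tips are added in
lexicographic order, every insertion point is explored, and partial
scores — which can only grow as tips are added — prune the search. The
search is exact up to 12 samples; beyond that an average-linkage
agglomerative topology on Hamming distances is used. Ties break
deterministically because only strictly better trees replace the
incumbent in a fixed enumeration order. Bootstrap support is not
computed; topology uncertainty is outside the desk-scale scope.

The binary presence rule for tree building is NV >= 3 and VAF >= 0.2,
configurable; it is deliberately more permissive than the caller's
4-read rule so that the tree sees borderline shared variants.

Mutations are then mapped to branches by maximum likelihood: branch `b`
implies expected VAF `clonality_vaf` (default 0.5) in samples descended
from `b` and `error_rate` (default 0.01, the assumed false-positive VAF)
elsewhere; the branch maximising the product of binomial read-count
likelihoods wins, with a softmax posterior reported. A `root` trunk
branch carries mutations present in every sample. Per-branch catalogues
are subsampled to at most 2500 mutations and branches under 100
mutations are excluded, reflecting the cost profile of signature
extraction and the noise floor of small branches.

# Mutational signatures

De novo extraction uses non-negative matrix factorisation minimising the
generalised Kullback-Leibler divergence by multiplicative updates (the
NMF route validated against hierarchical-Dirichlet-process extraction in
this literature; the Gibbs sampler itself is out of scope). The best of
several seeded restarts is kept; convergence is declared at a relative
divergence change under 1e-6 or 10,000 iterations. The factorisation
rank is a configuration choice; a stability scan can be layered on top
but a fixed small rank matches how these cohorts are analysed.

Each de novo component is decomposed into reference signatures by an
expectation-maximisation update on mixture weights,
`w_r <- w_r * sum_c S_rc m_c / sum_j w_j S_jc`, renormalised each step.
A component is *accepted* as deconvoluted when the reconstruction's
cosine similarity reaches `acceptance_cosine = 0.95` — the qualitative
"fully deconvoluted" judgement made quantitative; components failing it
should be retained in their de novo form, which is how bespoke
unmatched components are represented.

Exposures are refitted per branch against the patient-restricted
reference subset, and any signature below a 10% exposure fraction is
iteratively pruned (smallest first, refitting after each removal) to
prevent over-fitting. Exposures are reported in absolute mutation
counts, summing to the branch total.

The 83-channel indel classification reuses the same machinery; the
classifier bins simulated indels by type, length, repeat-unit count and
microhomology, to the depth needed for spectra, not as a general
reference-genome annotator.

# Burden modelling

Genotype rates come from a through-origin linear mixed-effects model:
`burden ~ 0 + age:genotype + (1 | patient)`, REML-fitted. There is no
fixed intercept (a newborn crypt carries ~0 somatic mutations) and
patient-level heterogeneity enters as a random intercept — the
random-slope alternative is statistically appealing but unidentifiable
at 2-4 patients per genotype. Confidence intervals use t quantiles with
patients-minus-slopes degrees of freedom, because slope uncertainty is
dominated by between-patient variation and normal quantiles undercover
with 2-5 patients per group; this calibration is verified by a coverage
simulation in the test suite. When every patient contributes exactly one
observation (duplex per-individual burdens) the random intercept is
unidentifiable and the model degrades to the corresponding fixed-effects
least-squares fit.

Fold-changes between genotype rates are ratios of slopes with a
delta-method CI on the log scale. Paired tissue comparisons (e.g.
oxidative-signature-attributed rates in intestine versus blood) use a
through-origin linear regression across individuals. Group comparisons
of signature proportions use the two-sided Wilcoxon rank-sum test, exact
below 50 observations per group.

# Duplex-sequencing normalisation

Duplex (single-molecule) burdens must be projected onto genomic
trinucleotide frequencies because restriction-enzyme fragmentation and
SNP masking skew the interrogated contexts. With `t_i` interrogated
bases in context `i`: `f_i = t_i / sum(t)` for experiment and genome,
`r_i = f_i^g / f_i^e`, corrected substitution counts
`s'_ij = s_ij r_i`, and corrected per-base burden
`beta' = sum(s') / sum(t)`. The implementation is context-count
agnostic, so the two-context worked example in the tests runs through
the same code as the production 32-context catalogue. Per-cell burdens
multiply `beta'` by a diploid genome size, default 6.2e9 bases (two
copies of ~3.1e9); the constant is configurable and recorded in output
metadata since the appropriate value depends on the reference build and
callable fraction.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, not the sequencing process:

* each patient's realised rate is genotype rate plus a truncated Normal
  deviation (`rate_sd_patient`, SBS/yr) — the study-scale heterogeneity
  between individuals of one genotype;
* crypt ancestry is a random rooted binary topology whose internal
  nodes sit in the first `1 - private_fraction` of the lifetime
  (default 0.1), giving the long terminal branches characteristic of
  crypt phylogenies; branch-wise mutation counts are Poisson in branch
  duration, so each crypt's total burden is exactly Poisson(age x rate);
* mutation contexts are drawn from the patient's signature mixture over
  the built-in fixture profiles (SBS1/5/18/36/88- and OGG1-like shapes;
  the two oxidative fixtures are constructed with cosine similarity in
  (0.3, 0.9) — correlated, as the real pair is, but separable);
* germline variants appear in every crypt of a patient at VAF 0.5,
  early-embryonic variants on internal branches at VAF 0.5, clonal
  somatic variants at `clonality_vaf` (default 0.5) in carrying crypts;
* depth is Poisson(`mean_coverage`, default 28) and variant reads are
  binomial — no sequencing-error base calls, no alignment artefacts, no
  copy-number structure, no reference genome (contexts are drawn
  directly from profiles; there are no real coordinates).

Passing tests on these cohorts therefore demonstrate the statistical
correctness of the estimators under the generating model — unbiased
burden recovery, calibrated CIs, accurate tree and branch recovery,
signature identifiability — not robustness to alignment artefacts,
subclonality or contamination in real data, which the upstream caller
and the artefact annotations are responsible for.

`simulate_duplex()` draws substitution counts with expectation
`t_i x rate x m_ij / f_i^g`, which makes the corrected burden `beta'` an
unbiased estimator of the generating per-base rate by construction of
the normalisation formulas — the property the recovery tests check.

# Numerical choices and degenerate inputs

* rho grid: 100 log-spaced points on [1e-6, 0.89]; all-zero NV returns
  the grid minimum; fewer than two covered samples is untestable (NA).
* Zero aggregate depth marks a variant untestable, classified
  artefact-filtered rather than invented.
* NMF uses epsilon-guarded divisions (1e-12) and rescales exposures so
  per-sample reconstruction totals match inputs exactly.
* EM weight updates run to an L1 change under 1e-10; pruning removes
  one signature at a time, smallest first.
* Parsimony tie-break: first optimum in the deterministic enumeration.
* Pileup subsetting and classification are invariant to sample order;
  every random routine takes an explicit seed and is reproducible.

# Problem sizes

The shipped tests and the acceptance script run cohorts of 2-8 patients
with 6-15 crypts each at rates between 2 and 1446 mutations/yr,
Monte-Carlo sensitivity at 1e5 draws, NMF on 12 catalogues of 2000
mutations, and duplex catalogues of 1e6-1e9 interrogated bases. These
sizes give Monte-Carlo error comfortably inside the assertion tolerances
while keeping a full run in minutes on one core; all of them scale up by
configuration.

# Known limitations

* The germline test cannot separate somatic mutations shared by *every*
  crypt of a patient (root-trunk mutations) from germline variants —
  the same ambiguity the aggregate procedure has on real data.
* No read-level simulation: artefact thresholds are exercised as
  pass-through flags only.
* The greedy agglomerative fallback above 12 samples is not guaranteed
  optimal (scores are still reported against the exact criterion).
* dN/dS-based driver discovery, CNV/SV calling and telomere analysis are
  out of scope; driver classification is the rule-based catalogue route.
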