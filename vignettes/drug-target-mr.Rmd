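---
title: "Methods: linking drug-target gene expression to clinical outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking drug-target gene expression to clinical outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

# Overview

`targetmr` implements a two-arm design for asking whether the gene targets
of a drug class influence a clinical outcome such as epilepsy:

1. **Pharmacovigilance arm.** Spontaneous adverse-event reports are mined
   for disproportionate reporting of the outcome among users of the drug
   class, via the reporting odds ratio (ROR).
2. **Genetic arm.** Expression of each target gene, instrumented by its
   cis-eQTLs, is tested for a causal effect on the outcome with two-sample
   Mendelian randomization (MR), corroborated by summary-data-based MR
   (SMR) with the HEIDI linkage test, Bayesian colocalization, and
   meta-analysis across outcome GWAS sources.

The two arms answer different questions — "is the adverse event reported
unusually often with these drugs?" versus "does genetically proxied target
expression shift outcome risk?" — and agreement between them strengthens a
causal reading that neither supports alone.

Everything is exercised on synthetic data with known ground truth: the
package ships a generator for LD-structured summary statistics and for
case-report streams, so each stage's operating characteristics (type-I
error, bias, robustness, HEIDI calibration, colocalization accuracy) are
verified by the test suite rather than assumed.

# Pharmacovigilance arm

Deduplicated case reports (one row per case, the latest version kept) are
cross-classified into the 2×2 table with cells `a` (target drug, target
event), `b` (target drug, other events), `c` (other drugs, target event),
`d` (other drugs, other events). The disproportionality statistic is

$$\mathrm{ROR} = \frac{a/c}{b/d} = \frac{ad}{bc},\qquad
95\%\ \mathrm{CI} = \exp\!\left(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right).$$

A **signal** requires at least 3 target-drug/target-event reports *and* a
CI lower bound strictly above 1. Both halves matter: the count floor keeps
single-digit coincidences from flagging, and the CI rule demands
statistical disproportion, not just a point estimate above 1.

```{r ror}
ror_signal(two_by_two(10, 90, 20, 380))
```

Numerical choices:

* **Zero cells** get the Haldane–Anscombe 0.5 correction on all four
  cells, flagged via `corrected`, keeping the ROR finite without hiding
  that a correction happened. The signal count floor always uses the
  *uncorrected* `a`.
* **Percent formatting** in characteristic tables rounds half away from
  zero to one decimal (`46.55 -> 46.6`), the convention of published
  summary tables, rather than R's round-half-to-even.
* **Deduplication** keeps the highest report version per case, ties broken
  by latest year then input order; identical duplicate rows collapse
  silently, *conflicting* duplicates are an error naming the case. One
  event counts once per case.
* Only **primary-suspect** drug reports count as exposed by default
  (`suspect_only = TRUE`); concomitant mentions fall into the comparator
  rows.

# Genetic arm

## Instrument selection

For each gene, candidate instruments are its cis-eQTLs, filtered in a
fixed order so that every input SNP is accounted for exactly once (kept,
or dropped with a stage and reason):

| filter | default | rationale |
|---|---|---|
| cis window | gene body ± 1 Mb (inclusive) | standard cis-eQTL definition |
| MAF | > 0.01 (strict) | rare variants have unstable effect estimates |
| eQTL p | < 1e-5 (strict) | relevance assumption; applied to the exposure side only |
| LD clump | r² < 0.3 within 10 Mb | enough independence for IVW; looser than GWAS clumping because cis regions are small |
| harmonization | drop palindromic (A/T, C/G), mismatched, incomplete records | strand cannot be resolved from summary data |
| Steiger | r²(exposure) > r²(outcome), strict | direction-of-effect guard |
| F-statistic | beta²/se² > 10, strict | weak-instrument guard |

All thresholds are strict inequalities, so boundary cases are excluded;
this makes behaviour at published cutoffs unambiguous and is asserted in
the tests. Clump ties at equal p-value break by smaller position then
lexicographic SNP id, making the greedy pass deterministic and
input-order-independent; for ≤ 10 SNPs the greedy result provably equals
exhaustive search over admissible subsets (tested against an enumeration
oracle). SNP-gene distance is measured from the gene body (start/end),
not the TSS. The variance explained used by the Steiger filter is
`b² / (b² + se²·n)` (the allele-frequency factor cancels); when the sample
size is missing on either side the pair is *kept with a warning*, never
silently dropped.

## MR estimators

With harmonized per-SNP effects `(bx_i, by_i)` the package fits:

* **Wald ratio** (single instrument): `by/bx`, SE `se_y/|bx|`
  (first-order delta; second-order available via a flag).
* **IVW** (primary): weighted regression through the origin, weights
  `1/se_y²`; fixed-effect by default, with a multiplicative
  random-effects option that inflates the SE by `max(1, sqrt(Q/df))`.
  Fixed-effect is the default because the sensitivity suite is run
  alongside and flags heterogeneity explicitly; silently switching models
  would hide it.
* **MR-Egger**: WLS with a free intercept after orienting all `bx > 0`;
  the intercept estimates directional pleiotropy, the slope is a
  pleiotropy-adjusted effect; inference on t(nsnp − 2), residual scale
  floored at 1 (the usual MR-Egger convention — heterogeneity may widen,
  never narrow, the interval).
* **Weighted median**: interpolated weighted median of Wald ratios,
  weights `1/se(ratio)²`; consistent when ≥ 50% of weight is valid.
* **Weighted mode**: argmax of the weighted kernel density of ratios;
  bandwidth = multiplier × 0.9·min(sd, mad)·n^(−1/5) (modified Silverman);
  consistent when the largest ratio cluster is valid.

The median and mode SEs come from a seeded parametric bootstrap (default
1000 replicates) redrawing both `bx` and `by`; seeding makes every
pipeline run reproducible. P-values are normal for Wald/IVW/median/mode
and t-distributed where a regression degree of freedom exists (Egger).
Estimates are reported as OR = exp(beta) with `exp(beta ± 1.96·se)`
intervals. No multiple-testing correction is applied across genes;
nominal p-values are reported and downstream gating is explicit.

The sensitivity suite computes Cochran's Q (weights `bx²/se_y²`,
chi-squared on nsnp − 1 df), the Egger intercept test, and leave-one-out
IVW refits.

## SMR and HEIDI

SMR uses only the top cis-eQTL: `b_smr = by/bx` there, with
`T = z_x² z_y²/(z_x² + z_y²)` on chi-squared(1). A small SMR p-value can
reflect either one shared causal variant or two distinct variants in LD;
HEIDI separates these by testing whether `b_smr` is constant across
surrounding eQTL SNPs. Eligibility defaults follow the method's published
practice: exposure p < 1.57e-3 (chi-squared > 10), LD with the top SNP
0.05 ≤ r² ≤ 0.9, at most 20 SNPs by ascending exposure p, at least 3 to
run (otherwise NA with the count reported). The covariance of the ratio
differences is obtained by the delta method from the LD matrix; the
statistic is referred to a weighted chi-squared mixture whose weights are
the eigenvalues of the correlation matrix of the differences, with the
tail evaluated by the Liu–Tang–Zhang moment-matched noncentral
chi-squared approximation — more accurate in the far tail than a plain
chi-squared reference and fully deterministic. "Passing HEIDI" is read as
p ≥ 0.01 (no detected linkage heterogeneity).

## Colocalization

Per-SNP evidence is Wakefield's log approximate Bayes factor
`0.5·log(1−r) + 0.5·z²·r` with shrinkage `r = sd₀²/(sd₀² + se²)`. Under a
single-causal-variant assumption per trait, the five hypothesis sums
(H0 none, H1/H2 one trait, H3 both-distinct, H4 both-shared) are
accumulated entirely in log space (log-sum-exp) so regions with |z| > 30
do not overflow. Priors default to p1 = p2 = 1e-4, p12 = 1e-5, and effect
priors 0.15 (quantitative) / 0.2 (case-control log-odds) — the method's
conventional defaults, all exposed as arguments. The verdict is
`possible` when PP.H4 > 0.5 and `highly_likely` when PP.H4 ≥ 0.8. With
one SNP, H3 is exactly zero. Records missing beta/se fall back to
reconstructing |z| from the p-value and the SE from allele frequency and
sample size.

## Meta-analysis

Per-source primary MR estimates for the same gene-outcome pair are pooled
by fixed-effect inverse variance (default), with DerSimonian–Laird
random effects behind a flag; Q, I² and tau² are reported either way.
Fixed-effect is the default for the same reason as in IVW: with two
sources, tau² is essentially unidentified, and heterogeneity is reported
rather than absorbed. When a source supplies p instead of se, the SE is
back-derived as `|beta|/Φ⁻¹(1 − p/2)`; bound-style values ("<0.01") are
rejected rather than guessed.

## Pipeline

`run_gene_outcome()` chains the stages per gene × outcome: instrument
selection, the primary estimate (Wald ratio for one instrument, IVW
otherwise, assists from nsnp ≥ 3), sensitivity, then — when the primary
p-value passes the follow-up gate (default p < 0.05, configurable to
`"all"` or `"none"`) — SMR/HEIDI and colocalization over the *un-clumped*
cis region (those methods model LD; pruning would discard their input).
An empty instrument set yields an explicit `no_instruments` status row
rather than an error, and every filtered SNP lands in a dropped-SNP
ledger written alongside the results. `consistency_sweep()` re-runs
clumping + MR across r² thresholds 0.3/0.2/0.05/0.01 and reports sign
agreement, since a result that flips sign with the clumping choice is not
trustworthy.

# The synthetic-data generator

`simulate_summary_stats()` works at the z-score level of the two-sample
summary-data setting: marginal effects are `LD %*% joint effects`,
estimated z-scores are drawn jointly with covariance equal to the LD
matrix (independently for the exposure and outcome samples, matching the
non-overlapping-samples design), and `se = 1/sqrt(2·maf·(1−maf)·n)`.
The outcome's joint effects are `theta·(eQTL effects) + pleiotropy`, so
`theta`, per-SNP validity, and LD structure are all known truth. LD is
AR(1) (`rho^|i−j|`), a standard stand-in for decaying local correlation.
`simulate_reports()` draws case reports with a known reporting risk
ratio, realistic missingness (e.g. ~79% missing weight), and injected
duplicate versions.

Default conditions — 20-SNP regions, n = 30,000 exposure / 50,000
outcome, eQTL effects 0.25–0.45 expression-SD per allele, 10,000 reports
at a 2% baseline event rate — are of the scale of blood-eQTL consortia,
disease GWAS, and drug-class report streams, and are fixed once in
`sim_config()`; validation suites use 100–1000 seeded replicates per
property, sizes chosen so the whole suite runs in well under a minute per
property on a laptop.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: genotype-level sampling (no weak-instrument
attenuation beyond what the drawn z-scores imply), allele-frequency
mismatch between panels, strand ambiguity needing EAF-based resolution
(palindromes are simply excluded), sample overlap between exposure and
outcome, population stratification, MedDRA coding noise, and
under-reporting structure in the pharmacovigilance stream. Results on
real data additionally depend on the reference panel's fidelity to the
GWAS population, which has no synthetic counterpart here.

# Degenerate inputs and edge policies

* 2×2 tables: all-zero is an error; any zero cell triggers the 0.5
  correction.
* `ivw()` on one SNP errors and points to `wald_ratio()`; Egger, median
  and mode require nsnp ≥ 3.
* `beta_exp = 0` at a Wald/SMR top SNP is an error (undefined ratio).
* HEIDI with < 3 eligible SNPs returns NA plus the count, with a warning.
* Identical ratios give Q = 0, q_pval = 1; a single meta study passes
  through with a warning.
* LD matrix lookups fail loudly, naming the first missing SNP.

# Known limitations

* The HEIDI tail approximation is moment-matched, not exact; its observed
  rejection rate at the 0.01 level is ≈ 0.008–0.01 under the null in the
  shipped calibration suite (slightly conservative).
* The weighted-mode bandwidth rule is a convention; mode estimates on
  small instrument sets are sensitive to it, which is why the mode is an
  assist, never primary.
* Colocalization assumes one causal variant per trait; multi-causal
  regions dilute PP.H4.
* The ROR is a reporting-disproportionality measure, not an incidence
  ratio: it inherits all spontaneous-reporting biases, which the
  simulated report stream deliberately does not model.
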