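---
title: "Bidirectional two-sample Mendelian randomization with bimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample Mendelian randomization with bimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The design and its assumptions

Two-sample Mendelian randomization estimates the causal effect of an
exposure trait on an outcome trait from two independent GWAS
summary-statistic tables. A SNP is a valid instrument when it is (a)
associated with the exposure (relevance), (b) associated with the outcome
only through the exposure (exclusion restriction), and (c) independent of
confounders (exchangeability). Under these assumptions and log-linear
associations, the per-SNP Wald ratio Γ̂ⱼ/γ̂ⱼ estimates the causal effect
α on the log-odds scale, and the estimators in this package are different
ways of pooling the J ratios that trade efficiency against robustness to
violations of (b) — horizontal pleiotropy.

Running the design in both directions (each trait in turn as exposure)
asks whether an observed association reflects A→B causation, B→A
causation, or neither. The two directions are fully independent analyses:
each selects and clumps instruments on its own exposure table.

## Instrument screening

`select_instruments()` applies five stages in a fixed order: genome-wide
significance, palindrome removal, LD clumping, MAF filtering, and a
confounder exclusion list. The order follows the screening narrative of
typical MR reports (significance first, confounder exclusions last); the
MAF filter sits between clumping and exclusions since no convention
pins it down. Each stage only removes records, so audit counts are
monotone; the audit is returned with the selected records.

Design choices worth knowing:

* The *clumping window* is interpreted as ± `clump_window_kb` around the
  index SNP (a 1 Mb span at the 500 kb default), the dominant convention
  in clumping tools. Ties on p-value break by smaller position, then
  variant id, so output is deterministic.
* Pairs absent from the LD matrix count as unlinked (r² = 0). With no
  matrix at all this degrades to distance-only behaviour and a warning is
  emitted; supplying a reference panel matrix is strongly recommended.
* Palindromic (A/T, C/G) variants are always dropped, never rescued by
  allele-frequency inference: when the outcome study may be reported on
  either strand, a frequency close to 0.5 cannot resolve orientation, and
  a silent misorientation flips the sign of Γ̂.
* Exclusion lists are static files (one id per line, `#` comments). No
  online confounder database is queried, which keeps runs reproducible;
  curate the list once from the discovery literature or a phenome-wide
  lookup and commit it alongside the analysis.
* Duplicate variant ids within one table keep the smallest p-value.

`harmonize()` aligns outcome to exposure effect alleles, trying a direct
match, an allele swap (Γ̂ negated, frequency complemented), and both
again after strand complementation; anything else is dropped with a
reason code. Harmonization is idempotent, and the swap transform is an
involution — both properties are tested.

## Estimators

All estimators consume the same harmonized tibble and return a one-row
(or two-row, for Egger) tibble with the log-odds estimate, SE, 95% Wald
CI, two-sided p, and odds-ratio transform. Log-odds is the working scale
everywhere; exponentiation happens only in the reporting columns.

**IVW.** First-order weights wⱼ = (se(Γ̂ⱼ)/|γ̂ⱼ|)⁻², i.e. the
exposure-side sampling error is ignored in the weight. This is the
convention that makes IVW a weighted regression of Γ̂ on γ̂ through the
origin, and it is accurate when instruments are strong (the per-SNP F
statistics in the diagnostics quantify this). The random-effects variant
is *multiplicative*: the fixed SE is inflated by max(1, √(Q/(J−1))), so
the point estimate never changes and the SE never shrinks below the
fixed-effect SE. `model = "auto"` applies the usual reporting rule —
random effects iff the Q test p < 0.05.

**Medians.** The weighted median interpolates the inverse-variance
weighted empirical CDF of the ratios at standardized cumulative weights
pⱼ = (Sⱼ − wⱼ/2)/S; with equal weights it reduces exactly to the sample
median. SEs come from a parametric bootstrap (each ratio resampled at its
own SE, default 1000 replicates, explicit seed), so repeated runs with
one seed are bit-identical.

**MR-Egger.** Before fitting, every instrument is oriented so γ̂ⱼ ≥ 0
(both coordinates sign-flipped where needed): Egger is the one estimator
here that is not invariant to allele recoding, and the conventional
orientation makes the intercept interpretable as average directional
pleiotropy. Inference uses t(J−2) with the same multiplicative
overdispersion idea as IVW, hence the J ≥ 3 requirement.

**MR-PRESSO.** The observed statistic is the weighted leave-one-out
residual sum of squares; its null distribution is rebuilt by parametric
simulation of *both* sides (γ*ⱼ around γ̂ⱼ, Γ*ⱼ around the leave-one-out
prediction), recomputing the leave-one-out slopes inside every replicate.
Empirical p-values carry the +1 correction, so the smallest reportable p
is 1/(n_sim+1) — with the default n_sim = 1000 and a Bonferroni outlier
threshold 0.05/J, outlier detection saturates for J beyond ~50, in which
case raise n_sim. The corrected estimate is fixed-effect IVW on the
unflagged instruments; the distortion test compares the relative raw-vs-
corrected shift against random outlier assignments of the same size.

**MR-RAPS.** The profile score divides each residual by
√(se(Γ̂ⱼ)² + β²se(γ̂ⱼ)² + τ²), which (unlike IVW) accounts for
exposure-side error, and passes it through a Huber score with k = 1.345
(95% Gaussian efficiency) so single aberrant SNPs have bounded influence.
The root of the estimating equation is found by bracketed root-finding
seeded at the IVW estimate with bracket doubling; if no sign change is
found, a 4001-point grid scan of the integrated Huber loss localizes the
minimizer and supplies a bracket, and a boundary minimum raises a
non-convergence error reporting the bracket. With
`overdispersion = TRUE`, τ² ≥ 0 is profiled by matching the mean squared
Huber score to its standard-normal expectation, alternating with β
updates to numerical convergence (1e-10). The SE is the sandwich form
of the estimating equation with a central-difference Jacobian.

**GRS.** The summary-data genetic risk score estimate with score weights
ω, outcome effects β and SEs se is α = Σωβse⁻²/Σω²se⁻² with
se(α) = √(1/Σω²se⁻²). With ω = γ̂ this is *identical* to fixed-effect
IVW — both are the weighted through-origin regression — which is exactly
why it serves as a secondary validation: it checks the data plumbing
(harmonization, weights, sign conventions) rather than adding a new
estimand. The SE uses the square root shown above; a version without the
root would not be dimensionally consistent, and the root is required for
the GRS–IVW identity to extend to the SEs.

## Diagnostics and reporting rules

Cochran's Q uses the same first-order weights as IVW (not exact or
modified weights), keeping the heterogeneity statistic consistent with
the pooling it gates; Q's p < 0.05 selects the random-effects model. The
Egger intercept t-test at 0.05 flags directional pleiotropy. Per-SNP
instrument strength is F = (γ̂/se(γ̂))², with the weak-instrument flag
raised when any F ≤ 10 (the strict "> 10" convention; no n·R²
approximation is used since the summary data supports the per-SNP form
directly). Leave-one-out refits flag any instrument whose omission flips
the estimate's sign or moves it outside the full-set CI. Flags annotate
reports; they never gate estimation — methods run even when diagnostics
object, as sensitivity panels are most needed exactly then.

## The synthetic generator

`sim_config()` / `simulate_instruments()` generate summary-level data
only: true exposure effects γⱼ ~ N(0.15, 0.05²), SEs uniform on
0.005–0.01 (exposure) and 0.01–0.02 (outcome), outcome effects
αγⱼ + uⱼ, and observed effects drawn at the reported SEs. These defaults
describe a strongly instrumented exposure (per-SNP F in the hundreds,
like the large cancer GWAS meta-analyses this design is applied to) with
a causal effect of 0.2 unless overridden. Pleiotropy regimes: `none`,
`balanced` (mean-zero uⱼ), `directional` (nonzero mean), and
`inside_violation` (uⱼ = ρ·sd·(γⱼ−mean)/sd(γ) + √(1−ρ²)·noise, a one-knob
violation of the InSIDE condition that Egger and PRESSO rely on).
Contamination adds `outlier_scale` × se(Γ̂) to a random
`outlier_fraction` of outcome effects. One seed governs a documented
draw order; partial redraws are unsupported (regenerate instead).

Two deliberate departures from pure sampling:

* `observation_noise = FALSE` sets the observed effects equal to the
  truth while keeping reported SEs positive — the noiseless limit in
  which every estimator must return α exactly, used to pin down algebra.
* In `simulate_raw_tables()` the planted instruments' observed exposure
  effects are drawn from the normal law *conditioned* on exceeding the
  significance threshold (exact truncated sampling). Real instrument
  sets are ascertained the same way by their discovery GWAS; here it
  also makes planted-truth recovery and audit counts exact by
  construction.

`simulate_raw_tables()` additionally plants, in known numbers:
sub-threshold decoys, palindromic instruments, LD satellites (same
observed effect as their index with 1.25× its SE, so the index always
wins the clump), low-MAF variants, and exclusion-listed variants — each
failing exactly one screening stage, with the expected audit in the
truth record.

What the generator does *not* emulate: real LD structure (blocks are
synthetic and block-diagonal), sample overlap between the two GWAS,
winner's-curse inflation of effect sizes, allele-frequency differences
between studies, and infinitesimal polygenic background. Passing tests
therefore demonstrate correctness of the estimators and pipeline on the
stated generative model, not robustness to those real-data features.

## Numerical choices and conventions

* P-values are floored at 1e-300 to stay in (0, 1]; normal reference for
  IVW/medians/RAPS/GRS, t(J−2) for Egger.
* Ratio SEs use the first-order delta method; second-order weights are
  not implemented.
* Greedy clumping ties break by position then id; chromosome sort is
  numeric-first.
* All stochastic routines (median bootstrap, PRESSO, generator) take
  explicit integer seeds and restore the session RNG state afterwards;
  `run_pair()` derives per-method seeds from its base seed by fixed
  offsets. Report bundles contain no timestamps, so identical
  plan + seed reruns are byte-identical.
* Under-instrumented pairs (< 3 harmonized instruments) produce an
  explicit status record, never a silent skip; single-instrument IVW
  requires an explicit override flag.

## Problem sizes used in the test-suite calibrations

The statistical calibration tests run at: type-I error, J = 25 with 2000
null replicates (99% binomial band 0.037–0.065 around the nominal 0.05);
bias/coverage, J = 50 with 500 replicates at α ∈ {0, 0.1, 0.4};
robustness, J = 30 with 500 replicates at 30% contamination; PRESSO
planted-outlier recovery, J = 20 with 100 seeded runs at n_sim = 1000.
These sizes give binomial standard errors comfortably inside the asserted
bands while keeping the default suite quick to run.

One robustness property deserves a caveat: after removing a single
planted 10-SE outlier, the corrected PRESSO estimate is closer to the
truth than the raw estimate only *on average*. In any one run the
corrected estimate carries sampling noise of order 1/√(J−1) ratio-SE
units against an outlier pull of order 10/J, so the per-run comparison
fails with probability ≈ Φ(−10√(J−1)/(2J)) — a floor of a few percent at
its optimum over J, and roughly one run in seven at J = 20 (more once
variation in instrument weights is accounted for) — whatever the
implementation. The per-run
form of this check is asserted in the acceptance suite at its stated
frequency bound and is expected to fail there; the aggregate behaviour
(flagging the outlier, average improvement) is what the method actually
guarantees.

## Limitations

No proxy-SNP search, genome-build liftover, GWAS-VCF parsing, LD
estimation from genotype panels, Steiger directionality filtering,
multivariable MR, or power calculation. Effect sizes are treated as
log-odds throughout; continuous-trait tables work identically but the
odds-ratio columns should then be ignored.
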