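---
title: "IBD rate difference scans with OU multiple-testing corrections"
author: "ibddiff authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IBD rate difference scans with OU multiple-testing corrections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibddiff)
```

## The model

Identity-by-descent (IBD) mapping asks whether affected individuals share
more long haplotype segments around a locus than unaffected individuals.
`ibddiff` works on the output of an IBD segment detector: a table of
segments between haplotypes of distinct individuals, each with physical
endpoints and a genetic length, retained above a detection cutoff (2.0 cM by
default; shorter segments are detected too unreliably to count).

On a grid of focal positions spaced δ apart in genetic distance, the
case-case and control-control sharing rates are

Ȳᵍₘ = (# distinct haplotype pairs in group *g* with a segment overlapping
position *m*) / (C(2n, 2) − n),

for n diploid group members. The denominator counts unordered haplotype
pairs between distinct individuals: within-individual pairs (homozygosity by
descent) are excluded because the statistic concerns sharing *between*
individuals. A pair contributes at most once per position however many of
its segments overlap it, which keeps the rate interpretable as a sharing
probability. Segment intervals are half-open `[start_bp, end_bp)`, so
abutting segments never double-cover a position and BED export needs no
coordinate shift.

Each rate track is standardized and the scan statistic is the standardized
difference Z̃Δₘ = Z̃¹ₘ − Z̃⁰ₘ, itself restandardized to unit variance (the
difference of two independent unit-variance tracks has variance 2, which the
test suite verifies empirically). Under the null — one genome-wide mean
sharing rate for both groups — Z̃Δₘ is approximately standard normal at each
position, and the track along the genome is modeled as a stationary
Ornstein-Uhlenbeck (OU) process: Gaussian, Markov, with autocovariance
exp(−θd) at genetic distance d Morgans. Both Gaussian marginals and
exponential autocovariance decay are asymptotic properties that hold well
for large cohorts (thousands of samples) in large populations; the test
suite checks them on synthetic data at the default generator scale.

## Robust standardization

Real tracks contain extreme outliers — selective sweeps inflate sharing, and
low-mappability or marker-sparse regions deflate it. Moments are therefore
estimated in two passes:

1. per group, an initial median and standard deviation over all M positions
   give a cutoff of median + 4·sd;
2. positions where *either* group's rate exceeds its cutoff are masked, and
   revised means/standard deviations over the unmasked positions standardize
   each track at *all* positions;
3. the difference track is restandardized with its own unmasked mean/sd.

Masked positions keep reportable statistic values (`EXCLUDED = 1` in the
scan table) but never enter moment or θ estimation. By default they also
cannot form or extend significant regions; `test_excluded = TRUE` lifts
that restriction. This matters in practice: a strong sweep-like spike
exceeds its own mask cutoff by construction, so confounding checks that
should *see* such loci (the randomized-phenotype rerun, the synthetic
confounder tests) are run with `test_excluded = TRUE`. The difference-track
moments are computed over unmasked positions only; computing them over all
positions would let a single extreme locus shrink every other z-value.

## Estimating θ and ρ

The decay parameter θ (per Morgan) is estimated from the scan itself:
autocovariances of the standardized difference track are computed at lags
k·δ for k = 1, 2, … up to 4.0 cM — beyond that the exponential signal is
usually below sampling noise — using the mean-zero product form over
within-chromosome, unmasked position pairs. Ordinary least squares of
log(acov) on lag through the origin gives θ̂ = −slope. Non-positive
autocovariances are dropped before the log (the only option compatible with
a log-linear model); if none are positive, estimation fails loudly. Because
the regression has no intercept, the track must be unit-variance
standardized first — the scan guarantees this, and `estimate_theta` is exact
on noiseless exponentials. The cross-correlation ρ between the standardized
case and control tracks is their sample correlation over unmasked positions;
it feeds the two-dimensional simulation threshold.

Accuracy expectations are set by an OU identity worth remembering: a track
of M positions has only about M(1−a)/(1+a) effectively independent values,
with a = e^(−θδ) — roughly M·θδ for small θδ — so correlation-type estimates carry
standard errors of a few hundredths even at 50,000 positions. The test
suite's tolerances are set at ≈3σ of these effective sample sizes, not of
the raw position counts.

## Multiple-testing corrections

Three corrections are provided, all returning the per-test level α* and
critical value z\* = Φ⁻¹(1 − α*):

- **Bonferroni**: α* = α/M. Very conservative for dense grids.
- **Analytic (discrete-spacing)**: solves
  1 − exp{−C(1−Φ(z)) − θLzφ(z)·ν(z√(2θδ))} = α
  by Brent-type root-finding on z ∈ [1, 10] (expanded to [0.1, 20] if
  needed, |residual| < 1e-12). ν(·) corrects the continuous-path excursion
  intensity for the discrete test grid; the two-term rational approximation
  ν(y) ≈ (2/y)(Φ(y/2)−½) / ((y/2)Φ(y/2)+φ(y/2)) is used in production,
  with the infinite-series definition retained in the tests as an
  independent oracle (they agree to about 2% over the operating range, the
  known accuracy of the rational form).
- **Simulation**: simulates genomes of cross-correlated OU pairs (θ₁, θ₀,
  ρ), restandardizes each difference track exactly as the scan does, and
  takes the conservative upper order statistic ⌈(1−α)·n_sims⌉ of the
  genome-wide maxima. Default n_sims = 1000. Deterministic under a fixed
  seed.

When θ₁ ≠ θ₀ the analytic route needs one θ for the difference track; the
package estimates θ directly from the difference track rather than averaging
the group estimates, since the difference track is what is thresholded.

A two-sided option exists for cohorts not ascertained on the phenotype
(protective haplotypes deplete case sharing). Its exact construction was a
genuinely open design point; both natural routes are implemented —
analytically, doubling both exponent terms of the excursion formula (each
tail contributes its own crossing intensity), and by simulation on maxima of
|Z̃Δ| (the default, preferred because it makes no symmetry approximation).
For symmetric nulls the two-sided level-α threshold is close to the
one-sided level-α/2 threshold, which the tests verify.

## The OU simulator

The simulator uses the exact AR(1) discretization x_{k+1} = a·x_k +
√(1−a²)·ε_k with a = e^(−θδ) and a stationary N(0,1) start per chromosome:
no burn-in, no Euler error at any spacing. The two-dimensional version
shares innovations with correlation r = ρ(1−a₁a₀)/(s₁s₀), which makes the
same-position cross-correlation exactly ρ (r = ρ when θ₁ = θ₀). For unequal
decay parameters the cross-lag structure is not uniquely determined by the
marginal and same-position constraints; the shared-innovation construction
is a documented modeling choice and the innovation correlation is returned
with the result. A requested ρ whose implied |r| exceeds 1 is refused with
an explanation.

## The synthetic IBD generator

The generator emulates the *statistical* footprint of detected IBD segments
without coalescent machinery: for every between-individual haplotype pair,
segments initiate as a Poisson process with rate λ per Morgan and have
length min_cm + Exp(mean ℓ), so every generated segment survives the
detection cutoff and the stationary pair-sharing probability at any position
is λ(ℓ + min_cm)/100 — a closed form the tests use as an oracle.
Initiations are drawn on an interval extended left of each chromosome so
coverage is stationary right up to the chromosome ends (bp coordinates are
clipped; the recorded genetic length is the full detected length).
Physical coordinates use a linear 1 cM/Mb map.

Defaults are the package's reference study conditions: 1250 cases and 1250
controls on ten 100 cM chromosomes, λ = 0.025/Morgan (mean sharing
probability ≈ 1e-3, sparse and realistic for ≥ 2 cM segments), cutoff
2.0 cM. Two perturbations support power and confounding experiments:
`inject_risk_locus` gives a random fraction q of case-case haplotype pairs
one extra segment overlapping a locus (the locus uniformly placed within the
segment — the stationary overlap geometry); `inject_carrier_confounder`
draws ⌊f·2n⌋ carrier haplotypes *ignoring phenotype* and connects every
between-individual carrier pair at the locus, emulating a sweep that
inflates sharing in cases and controls alike.

What the generator does **not** emulate: demography-driven segment length
distributions (bottlenecks, growth), detection noise at segment endpoints,
admixture or cryptic relatedness structure, and the heavy non-Gaussian tails
real sweeps produce. Tests passing on synthetic data therefore validate the
scan's statistical machinery — rate computation, masking, θ estimation,
threshold calibration — not robustness to every artifact of real cohorts.

## Numerical and scale choices

- Grid positions anchor at each chromosome's first map position; spacing is
  uniform in cM within chromosome (default 0.05 cM). A chromosome shorter
  than one step contributes a single position.
- Map interpolation is piecewise linear; queries outside the anchor span
  clamp to the terminal anchor (grids never query outside the span).
- Gzip input is detected from magic bytes, not file extension.
- Label permutation halves the cohort; odd counts give the extra sample to
  controls.
- Monte-Carlo test sizes: the FWER acceptance check uses 500 OU genomes of
  the 10 × 100 cM / 0.02 cM reference layout; threshold agreement uses 1000
  simulations per θ ∈ {25, 50, 100}; θ recovery uses 20 genomes of 35
  Morgans (laid out as 10 × 350 cM chromosomes) at 0.05 cM. Synthetic-IBD
  Monte-Carlo properties (null FWER, confounder type-1-error growth,
  permuted-label quiescence) run on 100+100-sample, 4 × 100 cM datasets with
  binomial two-standard-error margins matched to their replicate counts —
  these sizes keep each property's Monte-Carlo margin honest while the whole
  suite stays fast; the generator's *defaults* remain the full reference
  conditions.
- All stochastic APIs take an explicit integer seed (R's default Mersenne
  Twister); a run is reproducible from its logged seed alone.

## Known limitations

- The scan assumes panmixia within the analyzed cohort; population structure
  and admixture inflate sharing and must be handled upstream (ancestry
  stratification, relatedness pruning). The randomized-phenotype rerun
  detects, but does not correct, such inflation.
- Positive selection confounds the one-sided test: sweeps inflate case-case
  and control-control sharing symmetrically in expectation, but the chance
  carrier imbalance between groups produces genuine false positives at
  sweeping loci (the synthetic confounder tests reproduce this, with the
  type-1-error fraction growing in carrier frequency). Pairing the
  case-control scan with the one-sample selection scan is the recommended
  check.
- The analytic correction is mildly conservative (empirical FWER ≈ 0.045 at
  nominal 0.05 for θ = 50 on exact OU tracks in this package's own
  validation; lighter-tailed real rate differences are more conservative
  still), and more so for slowly-decaying tracks (θ ≤ 25).
- θ̂ from a single genome carries a few percent relative error at
  biobank-scale grids; thresholds inherit that uncertainty. The simulation
  threshold with (θ₁, θ₀, ρ) is the more faithful, slower alternative.
- Segment endpoint coordinates are taken at face value from the detector;
  endpoint uncertainty is not propagated.
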