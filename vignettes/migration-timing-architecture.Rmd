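---
title: "Dissecting the genomic architecture of spring migration timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the genomic architecture of spring migration timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spring arrival date in long-distance migratory songbirds is a heritable,
climate-sensitive phenotype. Given a cohort of wild birds that were (i)
tracked with light-level geolocators, yielding an ordinal arrival date per
individual, and (ii) genotyped genome-wide by low-coverage resequencing,
this package asks three questions:

1. How much phenotypic variance does the genome explain (PVE), and do any
   individual SNPs carry strong association signal (posterior inclusion
   probabilities, PIP)?
2. Can a polygenic score (PGS) built by clumping + p-value thresholding
   predict an individual's arrival timing out of sample?
3. Do phenotype-extreme groups (earliest vs latest migrants) show localized
   genomic differentiation beyond what population structure explains
   (net differentiation, ΔFST), accompanied by the reduced nucleotide
   diversity (π) and Tajima's D expected under a selective sweep?

Every stage runs on a bundled synthetic-cohort generator, so the entire
pipeline is testable end to end without any external download. The
`analysis/` scripts execute the stages in order; `run_pipeline()` wires them
together behind one config and one seed.

# The synthetic cohort generator

The generator (`sim_config()`, `simulate_cohort()`) is first-class, tested
code: it defines the statistical conditions every downstream claim is tested
under.

**Population structure.** Allele frequencies follow the Balding–Nichols
model: per locus, an ancestral frequency is drawn uniformly on
[0.05, 0.95] (keeping most loci past the MAF filter so filter tests are
non-degenerate), and each population's frequency is Beta-distributed with
mean `p_anc` and variance `fst * p_anc * (1 - p_anc)`. One parameter thus
maps directly onto the FST scale used by the scans. Genotypes are binomial
draws (two trials) from the population frequency; missing calls are masked
independently at `missing_rate` (default 0.20, matching the maximum
missingness tolerated by the filters).

**The planted sweep.** A contiguous region (default 2 Mb, carrying 13
planted genes) uses an elevated `sweep_fst` (default 0.5) and a minor-allele
frequency multiplied by `sweep_diversity_factor` (default 0.3) in the
"early" group, which depresses heterozygosity, π and Tajima's D there. This
is a frequency-distortion emulation, not a coalescent simulation: it is
desk-scale and sufficient to produce the three signatures the scans look
for. Two modes control *what* the sweep differentiates:

* `sweep_mode = "population"`: the early (lowest-latitude) population —
  a structure-driven signal that the ΔFST subtraction should cancel;
* `sweep_mode = "phenotype"`: a latent early/late timing morph assigned to
  individuals independently of population, with a configurable additive
  effect on arrival date (default 30 days) — a phenotype-linked signal that
  the subtraction should *not* cancel.

The paired modes exist because the pipeline's discriminating property — ΔFST
keeps phenotype-linked differentiation and removes structure-driven
differentiation — can only be asserted on simulations where the truth is
known in both directions.

**The phenotype.** Arrival date is
`intercept + cline_slope·latitude + covariate terms (sex, year, age) +
morph effect + Σ βⱼ·dosageⱼ + noise`, with `n_causal` loci (default 50) and
standard-normal effect sizes. The noise vector is orthogonalized against the
realized genetic values and rescaled so that
`var(g) / (var(g) + var(e))` equals `target_pve` *exactly* — recovery tests
are then sharp even at small n. The fixed cline and covariate part sits
outside that ratio deliberately: it is the component the downstream models
absorb with covariates and PC1. Defaults emulate the study scale: 87
individuals, a ~5 day/degree cline spanning roughly 131 days between a
Florida-like and an Alberta-like population, and `target_pve = 0.74`.
Phenotypes are simulated from the pre-masking (complete) genotype matrix:
with 20% independent missingness essentially no locus is complete across a
cohort, so drawing causals from observed-complete loci would be impossible;
the complete matrix is returned alongside the masked one.

**What the generator does not emulate:** linkage disequilibrium from
recombination, allele-frequency spectra under demography, sequencing-read
error, or imputation error. Tests passing on these cohorts show the
estimators and the pipeline logic are correct under the stated generative
model; they do not certify performance on real low-coverage data.

# Geolocation

Threshold geolocation uses the classical decomposition: longitude from the
sunrise/sunset midpoint (solar noon at longitude λ falls at
`12 − EoT/60 − λ/15` UTC), latitude from day length via the sunrise
equation at a configurable sun-elevation threshold (default −6°, civil
twilight — delegated to external tools and unstated in most field studies).
Declination and the equation of time use Spencer's low-precision Fourier
series (|error| < 0.5° and < 1 min, ample here). Near the equinoxes the
day-length/latitude relation degenerates; a day is flagged
`equinox_unreliable` when |dφ/d(day length)| exceeds 35°/hour — ordinary
days sit at 3–27°/hour across the breeding range while the weeks around an
equinox explode past 40, so the bound isolates the genuine degeneracy (at
the bound a one-minute twilight error already moves latitude by ~0.6°) —
and flagged days are
excluded from arrival detection rather than interpolated — downstream logic
should not consume fabricated latitudes. Polar day/night (no sunrise-
equation root) errors distinctly. Arrival is the first date from which the
great-circle distance to the colony stays within `radius_km` (default
200 km) for `persistence_days` (default 3) consecutive ok-quality days; "no
qualifying date" is an explicit not-found, never a sentinel value. No
movement or state-space smoothing is applied — the stage stays transparent
and testable, and a smoother is an extension point, not a default.

# Variant QC

Filters run in a fixed, documented order — biallelic, QUAL > 20, MQ > 20,
missingness ≤ 20%, MAF > 0.05 (strict, so a variant at exactly 0.05 is
removed), exact Hardy–Weinberg — with first-failure attribution; the
surviving set is order-invariant because each criterion is intrinsic to the
variant. Records lacking an MQ INFO key fail the MQ filter (conservative;
VCF dialects vary). MAF and HWE are computed on all samples jointly. The
HWE test is the two-sided exact test conditioning on allele counts,
computed by the standard stable recurrence over same-parity heterozygote
counts; the test suite checks it against full enumeration for every
genotype table up to n = 30. The HWE cutoff is unstated in most study
methods; the default here is 1e-6, conventional for sequencing data, and
configurable. Missing dosages are then mean-imputed (2× the non-missing
allele frequency), which preserves per-variant allele frequencies exactly;
haplotype-based imputation is deliberately out of scope, and mean dosage is
adequate for the linear models downstream.

# The Bayesian sparse linear mixed model

After absorbing covariates `W` (intercept, sex, year, age, PC1) the model is

    y = X β + u + ε,   u ~ N(0, σ² λ_u K),   ε ~ N(0, σ² I)

with spike-and-slab β: SNP j is included with probability π, and included
effects are N(0, σ² λ_β). `K` is the standardized genomic relatedness
matrix `X Xᵀ / p` (unit-variance columns, so all loci weigh equally).
Hyperpriors follow the conventional choices: h (total genetic variance
fraction) and ρ (sparse share) uniform on (0, 1); log π uniform on
[log(1/p), 0].

**Sampling scheme.** Covariates are handled by rotating onto an orthonormal
basis of the complement of col(W) — equivalent to a flat prior on the
covariate coefficients — and the polygenic term is diagonalized in the
eigenbasis of the rotated GRM. β, u and σ² (Jeffreys prior) are integrated
analytically, so the Metropolis–Hastings chain moves only over the
inclusion indicators and (h, ρ, log π). Indicator proposals mix uniform
draws with draws weighted ∝ 1/rank of marginal association (with the exact
Hastings correction), which finds large effects quickly without changing
the stationary distribution. Incremental cache updates make an indicator
move O(k·m) plus one k×k Cholesky.

**Effect-size calibration.** With k SNPs included, the slab variance is
`λ_β = h ρ / ((1−h) · max(k, πp) · v̄)`, so the included set is expected to
carry the sparse share of variance whatever its size. Calibrating by the
realized set rather than by πp alone prevents the regime where a large π
makes effects so small that inclusions become likelihood-free and the
indicator count simply tracks the prior.

**PVE.** Per retained sample, σ², β and u are drawn from their exact
conditionals and PVE is computed on the realized, covariate-adjusted
sample: `var(Xβ + u) / (var(Xβ + u) + σ²)` — the quantity a re-analysis of
fixed data reports, not an expectation over hypothetical cohorts. The 89%
equal-tailed interval is the 5.5%/94.5% posterior quantiles. Convergence is
monitored with a split-chain R-hat on the PVE and h traces and surfaced via
a warning and a diagnostics field, never silently.

**Chain defaults.** 8,000 iterations, 2,000 burn-in, thinning 6, with 10
indicator updates per iteration and the sparse set capped at 75 — at the
desk scale this package targets (n ≈ 100–150, p ≈ 5,000) this gives 1,000
retained samples, split R-hat typically near 1, and a fit in well under a
minute. Indicator-proposal ranks adapt to residual associations during
burn-in only (the kernel is frozen before any retained draw). All controls
are arguments.

**Honest limitations at toy scale.** At n ≈ 100 with p ≫ n and flat
hyperpriors, the PVE likelihood is weakly identified: posterior medians
track the truth with substantial spread, intervals are wide (as the study
context leads one to expect), and under a pure-noise phenotype the
posterior does not collapse to zero — the model cannot rule out moderate h,
and the strongest of p null marginal associations can retain non-trivial
inclusion probability. The test suite measures exactly these behaviors
on generated cohorts; see the power/calibration tests for the quantitative
statements.

# Polygenic scores

The PGS pipeline is the classical clumping + thresholding design.
Summary statistics come from covariate-adjusted per-SNP regression
(Frisch–Waugh residualization, exact t-based p-values). Clumping is greedy
in ascending p-value order (ties: position, then index): a variant is
indexed unless it sits within 250 kb of an existing index on the same
scaffold with r² > 0.1 (defaults; the source pipelines leave them to the
user). The p-value threshold is selected from the grid
{5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1} by incremental R² on an
internal 75/25 split of the *training* data — tuning on the evaluation fold
would inflate R², so the leak-free choice is made and documented. The final
model re-estimates statistics on the full training fold at the winning
threshold.

Cross-validation repeats 100 random 85/15 partitions (74/13 at n = 87).
Reported R² is the squared Pearson correlation between the held-out score
and the covariate-residualized phenotype — incremental over a
covariates-only model by construction. Held-out scores are standardized
against the training fold's score distribution before per-individual
averaging, so predictions are comparable across repetitions that select
different SNP sets. Deciles (1 = lowest PGS) use a deterministic remainder
rule: with n = 87, the seven extra members go to the lowest deciles, giving
sizes 9,9,9,9,9,9,9,8,8,8. Both the cross-validated mean R² and the
full-sample single-fit R² are emitted, since a headline number can refer to
either summary.

# Selection scans

Windows tile each scaffold from coordinate 0 in non-overlapping 5 kb steps
(terminal short windows retained). Window FST is the Weir–Cockerham (1984)
variance-components estimator in ratio-of-sums form, `Σa / Σ(a+b+c)` —
standard practice for windowed scans; per-site components are retained for
testing and an average-of-ratios variant would be a one-line change.
Missing genotypes are excluded site-wise; a site needs ≥ 2 genotyped
diploids per group. Negative window values are kept: clamping would bias
the genome-wide null that the outlier scaling relies on. ΔFST subtracts the
population-contrast scan (southernmost vs northernmost) from the
phenotype-contrast scan (10 earliest vs 10 latest) window-by-window, with
validity flags propagating monotonically.

π is per-site unbiased heterozygosity `2p(1−p)·2m/(2m−1)` summed over
variant sites and divided by the window span; Tajima's D uses the 1989
constants at the haplotype count, with haplotypes derived from diploid
genotypes assuming Hardy–Weinberg within group (no phasing — a documented
limitation). With missing data the constants use the rounded mean genotyped
haplotype count over the window's segregating sites; windows with no
segregating site are flagged invalid, not zero.

Outlier regions are windows with robust Z `(x − median)/MAD` above 4,
merged across gaps of at most 2 windows, with a *minimum of 3 outlier
windows per region*: a region is a sustained elevation (the motivating
signal spans hundreds of windows), and the minimum-run rule keeps
single-window spikes — which ΔFST produces preferentially where FST itself
is high, because the estimator's sampling variance grows with
differentiation — from being called regions. A flat scan has MAD 0 and, by
the documented fallback, no outliers. Gene overlap uses half-open interval
intersection (a gene ending exactly at a region start does not overlap).

# Numerical and design notes

* All randomness is seeded; `derive_seed()` fans a single global seed out
  to stages via a Lehmer-style hash kept inside 32-bit range, so one number
  reproduces a whole pipeline run byte-for-byte.
* The collapsed BSLMM marginal likelihood is validated in the tests against
  a dense matrix-inversion oracle; FST, π and Tajima's D are validated
  against independently coded brute-force oracles at 1e-10–1e-12.
* Estimator edge cases are explicit errors or flags, never sentinel
  numbers: all-missing variants (imputation), monomorphic variants
  (marginal scan), polar/equinox days (geolocation), S = 0 windows
  (Tajima's D), MAD = 0 scans (region detection).
* Problem sizes in the test suite are chosen for a desk-scale run:
  oracle fixtures at 2×10 diploids × 50 sites; FST calibration at 2×50
  × 20k loci; ΔFST discrimination at 2×50 × 12k loci × 100 paired seeds;
  BSLMM recovery at n = 150, p = 5,000, 10 seeds per true PVE; PGS
  cross-validation at n = 300, p = 2,000 with 100 partitions.
* The pipeline treats scaffolds as given and does not attempt homology
  assignment to any reference karyotype; "chromosome" labels are out of
  scope.

# Known limitations

Mean imputation ignores LD information; the generator produces unlinked
loci, so clumping's LD handling is exercised by synthetic correlated
columns in tests rather than by realistic LD decay; the BSLMM's PVE
identification at n ≲ 100 is weak by nature and its null behavior at toy
scale is reported honestly by the calibration tests; and twilight
estimation assumes clean light curves — shading models and calibration
against real loggers are out of scope.

One interaction deserves emphasis: an exact-HWE filter computed on the
pooled sample preferentially removes strongly phenotype-differentiated
sites, because a 50/50 split of highly differentiated groups produces a
heterozygote deficit (the Wahlund effect). In the synthetic cohorts this
can erase the planted sweep before the scans ever see it; the scan
analysis therefore runs on all biallelic sites and reports how many sites
the HWE stage would have removed and where. On real data the same tension
argues for a lenient HWE cutoff (or per-population testing) whenever
selection scans are downstream.
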