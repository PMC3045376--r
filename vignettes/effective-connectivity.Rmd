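---
title: "Effective connectivity of a moral-cognition ROI network: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective connectivity of a moral-cognition ROI network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roisem)
```

# The scientific problem

`roisem` implements a model-based connectivity analysis for block-design
fMRI at the region-of-interest level, built around a four-node network of
moral cognition: the frontal pole (FP), left posterior superior temporal
sulcus (pSTS), posterior cingulate cortex/precuneus (PCC) and rostral
anterior cingulate cortex (rACC). The question the pipeline addresses is
whether the *mode* of directed interaction between these regions — not just
their activation magnitude — differs when a reader implicitly detects
care-ethics versus justice-ethics moral issues, and whether individual
moral-development scores (an mMJI-like scale, roughly 300–400) are
predicted by specific path strengths.

Because the original acquisition data are not available, the package ships
a first-class synthetic-cohort generator so that every downstream stage is
testable end to end, and every validation claim in this vignette is a
claim about what the tests and the acceptance script actually compute on
synthetic data.

# The generative model

## Task paradigm

The block design presents 41 story segments of 15 s each (615 s): 6 care,
6 justice, 6 strategic and 6 tactical segments, plus 17 neutral segments.
Non-neutral categories appear as adjacent same-category pairs, and
consecutive pairs are separated by one neutral segment. `make_paradigm()`
reproduces this layout; neutral segments beyond the mandatory separators
are placed deterministically under the seed (the first two surplus
segments go to the sequence start and end — sides chosen by the seed — and
any remainder widens randomly chosen separator slots). The separator rule
is the only layout constraint the design states, so surplus placement is a
package choice, fixed once and documented here.

The repetition time is nowhere specified by the design; the default is
`tr = 2` s, a common value for whole-brain 3T EPI, and it is configurable
everywhere.

## Structural dynamics and haemodynamics

Each condition `c` has a linear structural system over the four ROIs:

    x_t = B_c x_t + e_t,   e_t ~ N(0, diag(Psi_c))

so the neural signal is `x_t = (I - B_c)^{-1} e_t` with implied covariance
`Sigma_c = (I - B_c)^{-1} diag(Psi_c) (I - B_c)^{-T}`. Innovations are
temporally white; `B` switches at segment boundaries; scans outside any
segment use the neutral innovation variances with all paths off. Each
node's neural series is convolved with the canonical double-gamma HRF
(peak delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio
1/6, 32 s support, unit peak) and observed with additive Gaussian
measurement noise.

Defaults, chosen once as plausible study conditions and not revisited:

* `Psi = 1` per node and condition (innovation variance sets the scale);
* `noise_sd = 0.5` — ROI-average measurement noise at roughly 5–10% of the
  convolved signal variance, i.e. a relatively clean eigenvariate series;
* `subject_sd = 0.25` — between-subject jitter on every nonzero path
  coefficient. Jitter draws that would destabilise a subject's system
  (spectral radius ≥ 0.95) are redrawn, a generative constraint that keeps
  every simulated subject stationary;
* behaviour score = `350 + slope · (subject's justice pSTS→PCC path) +
  N(0, 20²)`, with `slope = sqrt(0.6/0.4) · 20 / 0.25 ≈ 98` so that the
  linked path accounts for 60% of the score variance at the default
  jitter. The base and spread straddle the stage-3/4 boundary of the
  moral-development scale (median ≈ 359) without claiming to reproduce it;
* 17 subjects per cohort, the sample size implied by the study's
  `F(1, 15)` statistics.

## Reference condition networks and stabilisation

`condition_models()` encodes the published path-coefficient matrices of
the best-fitting neutral (6 paths), care (7 paths) and justice (7 paths)
condition networks, oriented `B[target, source]`. Two facts make the raw
care and justice matrices unusable as generating truth:

1. **Loop gains at or above one.** The care pSTS↔FP pair multiplies to
   ≈ 1.0006 and the justice pSTS↔rACC pair to ≈ −4.6, so `I - B` is
   singular or the system non-stationary. `stabilize_paths()` therefore
   shrinks both members of every reciprocal pair by 0.7 and, when the
   spectral radius still exceeds 0.85, rescales the whole matrix to
   radius 0.85. Shrinking reciprocal pairs alone is *not* sufficient for
   the justice network; the global rescale is the package's fix, and it
   preserves topology and sign structure exactly.
2. **Under-identification.** A 7-path model on 4 nodes has
   `q = 7 + 4 = 11` free parameters against `4·5/2 = 10` covariance
   moments (`df = -1`). Moreover, purely reciprocal loops without
   exogenous instruments are locally non-identified even when `df ≥ 0`:
   distinct coefficient sets reproduce the same covariance, and the
   observed information is singular. `fit_sem()` surfaces both situations
   instead of hiding them — the former through the `df` precondition, the
   latter through `converged = FALSE` backed by an information-rank check.

For recovery simulations the package therefore provides
`justice_recovery_model()`: the maximal recursive (acyclic) subnetwork of
the justice model — FP→pSTS, rACC→pSTS, pSTS→PCC, rACC→PCC (`df = 2`).
Both colliders (FP→pSTS←rACC and pSTS→PCC←rACC) are protected, so its
Markov-equivalence class is a singleton and the topology is recoverable
from its covariance in principle.

# The analysis stages

## ROI GLM

`build_design_matrix()` convolves each condition's boxcar with the
canonical HRF at scan resolution, adds discrete-cosine drift regressors up
to a 128 s high-pass cutoff, and a constant. Note that the response to a
sustained 15 s block peaks ≈ 12 s after block onset (the discrete
convolution of a 15 s boxcar with the canonical HRF), well after the 5 s
impulse peak — tests pin this against an independently coded convolution.
`fit_glm()` is ordinary least squares with contrast t-statistics
`t = c'β̂ / sqrt(σ̂² c'(X'X)^{-1} c)`. Event-level response modelling
(button presses) is not simulated; block-level regressors are the stated
approximation.

`group_contrast_correlation()` regresses behaviour scores on per-subject
contrast values (Pearson r, r², F-test p); `median_split_compare()` splits
at the median score with ties assigned to the low group (a deterministic
rule the analysis needs and the design does not state) and compares groups
with Welch's t-test, since split sizes can differ.

## PPI

`first_eigenvariate()` summarises a region by the first left singular
vector of the column-centred member matrix, scaled to the SD of the mean
series and signed to correlate positively with it. The psychological
vector codes the contrast conditions +1/−1 (a symmetric choice; the
analysis convention is not dictated by the design) and is mean-centred
over coded scans. Two interaction constructions are provided:

* `multiply` (default): centred seed × psychological vector, the
  construction contemporary with the original SPM-era analyses;
* `deconvolve`: the seed is deconvolved to neural scale by
  ridge-regularised least squares against the HRF convolution operator
  (penalty chosen by generalised cross-validation), modulated, and
  reconvolved.

Both modes agree in the sign of the interaction slope on block-modulated
targets; the null calibration of the interaction t-test is verified at
α = 0.05 and 0.01 over 1,000 simulations. "Adjustment by effects of
interest" of the seed is interpreted minimally as residualisation against
drift and constant only.

## SEM engine

`fit_sem()` minimises the maximum-likelihood discrepancy

    F_ML = ln|Sigma| + tr(S Sigma^{-1}) - ln|S| - p

over free path coefficients and residual variances. Recursive models are
solved in closed form by per-node regressions on `S` (the exact MLE for
recursive systems with uncorrelated errors). Non-recursive models use a
quasi-Newton optimiser on `(b, log psi)` with analytic gradients — using
`Sigma^{-1} = A' diag(psi)^{-1} A`, `A = I - B`, so no matrix inversion of
`Sigma` is ever formed — followed by a damped Newton polish to a gradient
tolerance of 1e-8, with a damped-regression start and seeded random
restarts. Standard errors come from the inverse observed information of
the fit function, `acov = (2/(n-1)) H^{-1}`; `converged` is `FALSE`
whenever the gradient tolerance is unmet *or* the information matrix is
not positive definite (local non-identification), never an exception.
Covariances use the `n - 1` denominator and `chi² = (n-1) F_ML`, matching
the conventions of the classic SEM packages this index panel comes from:
RMSEA, model AIC (`chi² + 2q`), GFI/AGFI/PGFI, SRMR, and `min_t`, the
smallest |t| among free paths. When `df = 0`, RMSEA, AGFI and PGFI are
reported as not applicable (`NA`) rather than risking division by zero.

Condition samples are pooled from task blocks shifted forward by 6 s
(hemodynamic delay) with the first two and last samples of each shifted
block dropped (transition effects). The whole block window moves — a 15 s
block contributes the same number of samples it covers — rather than
shrinking the window to the original block end; with `tr = 2` this yields
4–5 samples per block, ~27 per subject and condition, ~460 pooled across
a 17-subject cohort.

## Exhaustive search

`enumerate_models()` generates every directed-edge subset (no self-loops),
by default filtered to `df ≥ 0` — 2,510 candidates on 4 nodes — in a
deterministic order. `exploratory_search()` fits each, excludes
non-converged fits (with reasons), and ranks by AIC (default), with ties
resolved at 1e-6 resolution by RMSEA, then fewer edges, then enumeration
order. The explicit tie rule matters: on an exact covariance every
saturated-equivalent model attains `chi² = 0`, and covariance-equivalent
models attain identical fit by construction, so "the" best model is only
defined up to its equivalence class. A stability diagnostic (spectral
radius of `B̂`) is always reported, and non-recursive candidates are
admitted but flagged through the identification check described above.

## What AIC-ranked search can and cannot recover

On an *exact* covariance from an identified recursive truth, the truth
attains the minimal AIC deterministically: supersets fit no better and pay
2 per extra parameter, sparser or wrong models have positive discrepancy.
The package's tests verify this.

On *sampled* covariances the situation is fundamentally different, and it
is worth being precise because it shapes the validation design. If the
truth has `df = d`, then adding any `k` edges yields a model that fits no
worse; the truth outranks such a superset only if its sampled chi-square
exceeds the superset's by less than `2k`. Under a perfectly specified
model the truth's chi-square is ~`chi²_d`, so even an oracle fitter wins
against the single-edge supersets with probability at most about
`P(chi²_1 < 2) ≈ 0.84` — an upper bound that no implementation can beat,
at any sample size. In the full BOLD pipeline three further effects
inflate the sparse truth's chi-square at pooled `n ≈ 460`: (i) the pooled
covariance mixes 17 subjects' jittered coefficient matrices, (ii) HRF
convolution autocorrelates samples so the nominal `n` overstates the
information, and (iii) measurement noise adds a diagonal component no
off-diagonal-generating topology absorbs. Consequently AIC systematically
prefers just-identified supersets of the truth on cohort data, and the
measured "truth ranks first" rate is far below the idealised expectation —
the acceptance suite measures and reports this rate honestly rather than
tuning the conditions until it looks good. The stepwise brain–behaviour
analysis below does not suffer from this, because it conditions on a fixed
(group) topology rather than selecting one.

## Group inference

Pathwise condition comparisons are paired t-tests across subjects on
per-subject confirmatory coefficients, judged against the Bonferroni
per-comparison level `alpha/n`. This subject-resolved construction is the
only self-consistent reading available: group-level coefficient tables
with per-path SDs do not determine a comparison statistic, and the
package does not attempt to reproduce any particular printed comparison
value. Paths absent from one condition's model are marked not comparable,
never dropped silently.

`confirmatory_fit_cohort()` refits a fixed group topology per subject
(failures isolated and logged), and `stepwise_regress()` implements the
classic p-value stepwise procedure — entry at `p < 0.05`, removal at
`p > 0.10`, partial F with df `(1, n-k-1)` — iterated to a fixed point,
with an empty selection being a valid outcome.

# Validation design and problem sizes

The test-suite and acceptance script compute, among others:

* closed-form identities (`F_ML(diag(2,1), I) = 1 - ln 2`; RMSEA = 0.3 at
  `chi² = 100, df = 10, n = 101`; AIC = `chi² + 2q`; GFI = 1 and SRMR = 0
  at a perfect fit);
* noiseless recovery of recursive topologies to 1e-4, and of an
  identified feedback system (with an instrument) to 1e-6;
* equivalence of the search ranking with an independently coded
  brute-force re-fit-and-sort oracle over all 42 three-node models;
* end-to-end cohort recovery: 17 subjects, pooled justice-condition
  covariance (~460 samples), full 2,510-model search — 10–12 replicates
  (each search fits every candidate; sizes keep the suite within desk
  runtimes) — plus 100 replicates of the confirmatory-fit + stepwise
  chain, where the score-driving pSTS→PCC path is expected first;
* type-I calibration of the PPI interaction test and the group
  correlation over 1,000 null simulations each, judged against binomial
  95% intervals at the nominal α.

What passing these tests shows — and what it does not: the synthetic
generator produces stationary, HRF-convolved, white-innovation Gaussian
data with block-homogeneous dynamics. Real BOLD has coloured physiological
noise, nonstationary coupling within blocks, regional HRF variability and
motion artefacts, none of which are emulated; conclusions about the
pipeline's behaviour on real data are correspondingly limited.

# Known limitations

* Latent-variable or multi-group (stacked) SEM, Bayesian model averaging
  and modification indices are out of scope; the search is over observed
  ROI path models only.
* The AIC-first-rank ceiling on sampled covariances (above) is a property
  of the selection rule, not of this implementation; users wanting
  topology recovery guarantees should rank on exact or very-low-noise
  covariances, or treat the ranked list (not its first element) as the
  inferential object.
* Purely reciprocal feedback models are admitted by enumeration but are
  locally non-identified without instruments; they are excluded from
  rankings via the information-rank check, which mirrors how such fits
  fail to converge to stable solutions in classic SEM software.
* The printed reference coefficient matrices are used as generating truth
  only after stabilisation; the package makes no claim that the raw
  printed values are jointly realisable as a stationary linear system.
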