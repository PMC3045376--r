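# roisem

Model-based connectivity analysis of block-design fMRI at the
region-of-interest level, centred on a four-node network of moral
cognition: frontal pole (FP), left posterior superior temporal sulcus
(pSTS), posterior cingulate cortex/precuneus (PCC) and rostral anterior
cingulate cortex (rACC). The package asks the network-level question —
does the *direction and strength* of interregional influence differ
between care-ethics and justice-ethics moral cognition, and do individual
moral-ability scores track specific path strengths? — and provides every
stage needed to answer it on simulated cohorts:

- **Synthetic cohorts**: a 41-segment block paradigm (6 care, 6 justice,
  6 strategic, 6 tactical, 17 neutral segments of 15 s), condition-specific
  linear structural systems `x = Bx + e` driving BOLD through the
  canonical double-gamma HRF, between-subject coefficient jitter, and a
  behaviour score (mMJI-like, ~300–400) linked to chosen path strengths.
- **ROI GLM**: HRF-convolved condition regressors with DCT drift,
  OLS contrasts, brain–behaviour correlation and median-split comparison.
- **PPI**: seed eigenvariate extraction, psychophysiological-interaction
  regressors (product or deconvolution construction), per-target
  interaction tests, group paired tests.
- **SEM engine**: maximum-likelihood fitting of path models to condition
  covariances, `F_ML = ln|Σ| + tr(SΣ⁻¹) − ln|S| − p`, with the classic
  fit panel (χ² = (n−1)F, RMSEA, model AIC = χ²+2q, GFI/AGFI/PGFI, SRMR,
  min |t|), closed-form solutions for recursive models, seeded
  multi-start optimisation with analytic gradients for feedback models,
  and an information-rank check that flags non-identified solutions.
- **Exhaustive exploratory search**: every directed-edge subset with
  df ≥ 0 (2,510 candidate models on 4 nodes), ranked by AIC with a
  deterministic tie rule.
- **Group inference**: pathwise paired comparisons under Bonferroni
  control, per-subject confirmatory fits of a group model, and p-driven
  stepwise regression (entry p<0.05, removal p>0.10) of path coefficients
  onto behaviour scores.

## Worked example

Fit the identified justice subnetwork to a synthetic cohort and ask which
path predicts the behaviour score:

```r
library(roisem)

rec <- justice_recovery_model()         # FP->pSTS, rACC->pSTS, pSTS->PCC, rACC->PCC
gm  <- default_generating_model()
gm$B_by_condition$justice <- rec$B
par <- make_paradigm(seed = 1)          # 41 segments, 615 s, tr = 2 s
cohort <- simulate_cohort(gm, par, n_subjects = 17, seed = 7)

# pooled justice-condition covariance (blocks shifted 6 s, trimmed 2+1)
cs <- lapply(cohort, function(s)
  extract_condition_blocks(s$timeseries, par, "justice"))
pooled <- do.call(rbind, lapply(cs, `[[`, "samples"))
fit <- fit_sem(cov(pooled), nrow(pooled), rec$model)
fit

# per-subject confirmatory fits, then stepwise regression onto the scores
conf   <- confirmatory_fit_cohort(cs, rec$model, seed = 1)
scores <- sapply(cohort, `[[`, "score")
stepwise_regress(conf$coefficients, scores)
```

which prints (numbers from this exact seed):

```
sem_fit: 4 nodes, 4 paths; F_ML = 0.02695, chi^2(2) = 12.34, n = 459
  converged: TRUE; stability (spectral radius): 0.000
   parameter estimate      se       t
1   FP->pSTS  3.65640 0.09341  39.145
2  pSTS->PCC  0.94263 0.02044  46.120
3 rACC->pSTS -3.88270 0.09507 -40.840
4  rACC->PCC -0.04245 0.11114  -0.382
5     psi_FP  2.53155 0.16729  15.133
6   psi_pSTS  9.97269 0.65901  15.133
7    psi_PCC  8.29165 0.54793  15.133
8   psi_rACC  2.44368 0.16148  15.133
  AIC 28.34  RMSEA 0.106  SRMR 0.08591  GFI 0.9  AGFI 0.5  PGFI 0.18  min|t| 0.382

stepwise_result: selected pSTS->PCC; r^2 = 0.321 (n = 17)
 step action      path       p r_squared
    1  enter pSTS->PCC 0.01768    0.3212
```

The group fit recovers the three strong generating paths (true values
3.72, 0.945, −4.18); the weak rACC→PCC path (true 0.201) is washed out by
sampling noise and subject heterogeneity at this cohort size — its |t| of
0.4 correctly reports that. The stepwise procedure singles out the
score-driving pSTS→PCC path; the observed r² (0.32 here) is the 60%
generating linkage attenuated by per-subject estimation error. `exploratory_search(cov(pooled), nrow(pooled),
nodes = gm$nodes)` ranks all 2,510 candidate models by AIC;
`run_pipeline(run_config(), out_dir)` composes every stage (simulate →
GLM → PPI → block extraction → per-condition search → path comparisons →
confirmatory fits → stepwise) and writes TSV/JSON reports plus a
deterministic manifest. A thin command-line wrapper with `semfit`,
`semsearch`, `simulate` and `run` subcommands lives in
`inst/scripts/roisem.R`.

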