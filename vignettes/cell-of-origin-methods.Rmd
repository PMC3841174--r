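---
title: "Methods: cell-of-origin signatures, mixture stratification, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-of-origin signatures, mixture stratification, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coosig)
```

## The scientific question and the model

Epithelial ovarian carcinomas may arise from at least two normal
epithelia: the ovarian surface epithelium (OCE) and the non-ciliated
fallopian tube epithelium (FNE). If a tumor retains a residual
transcriptional imprint of its cell of origin, a signature that separates
normal FNE from normal OCE cells should also separate tumors into
fallopian-tube-like (FT-like) and ovary-like (OV-like) subgroups. coosig
implements that chain of reasoning as a pipeline:

1. **Paired differential expression.** Expression of paired,
   donor-matched FNE and OCE cell lines (two patients, one array per
   patient and cell type) is compared per probeset. Arrays from the same
   patient are correlated; a single consensus intra-patient correlation
   $\rho$ is estimated and used in per-probeset generalized least squares
   (GLS) fits of the model
   $x_{gj} = \mu_g + \beta_g \cdot \mathrm{FNE}_j + \varepsilon_{gj}$,
   with working covariance $(1-\rho)I + \rho$ within a patient block.
2. **Empirical-Bayes moderation.** With four arrays there are only two
   residual degrees of freedom per probeset, so per-probeset variances
   $s^2_g$ are shrunk toward a prior: assuming
   $\sigma^2_g \sim d_0 s_0^2/\chi^2_{d_0}$, the posterior variance is
   $\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ and the moderated
   $\tilde t_g = \hat\beta_g / (\tilde s_g \sqrt{v_g})$ has $d_0 + d_g$
   degrees of freedom. $(d_0, s_0^2)$ are estimated by moment matching of
   $\log s^2_g$ against the scaled-F model via digamma/trigamma
   identities, with the trigamma inversion done by bisection to $10^{-10}$
   (deterministic; no optimizer). Benjamini–Hochberg adjustment controls
   the FDR at $q < 0.05$.
3. **Signature.** Per direction, probesets are ranked by ascending $p$,
   then descending $|\tilde t|$, then probeset id — a total order, since
   the selection rule "most significant" needs a tie-break. The top
   $k = 5$ per direction with unique gene symbols form a 10-probeset
   signature with weights $+1$ (FNE-up) and $-1$ (OCE-up). A tumor's
   score is $S_j = \sum_i w_i x_{ij}$ over the signature probesets
   present in its matrix; probesets absent from a platform are dropped
   and counted in `n_used` (never imputed).
4. **Mixture stratification.** Scores are fit with a two-component
   Gaussian mixture by EM (10 restarts, absolute log-likelihood tolerance
   $10^{-8}$, monotonicity asserted each iteration). Both the shared- and
   separate-variance families are fit and BIC
   ($-2\log L + k\log n$) selects between them. The higher-mean component
   is FT-like; hard labels use the Bayes rule (posterior $\ge 0.5$).
5. **Clinical association and survival.** Grade and stage (ordinal)
   are tested by proportional-odds likelihood-ratio tests, histologic
   subtype by Fisher's exact test (full enumeration when affordable,
   seeded Monte-Carlo otherwise), survival by the log-rank test and by
   multivariate Cox regression (Efron ties) adjusting for grade, stage,
   serous subtype, age and residual disease.
6. **Permuted-signature null.** The score → mixture → association chain
   is repeated with random $\pm1$ signatures drawn from the annotated
   probeset universe (symbol-unique, seeded); the fraction of
   permutations reaching $p < \alpha$ per clinical variable is the
   negative control a genuine signature must beat.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| consensus trim | 0.15 | fraction per tail | robust consensus over per-probeset correlations |
| FDR threshold | 0.05 | q-value | "adjusted P < 0.05" significance gate |
| `k_per_direction` | 5 | probesets | the 10-probeset signature; 10 gives the 20-probeset robustness variant |
| mixture restarts | 10 | — | escape EM local optima; seeded, reproducible |
| EM tolerance | 1e-8 | abs. log-lik | convergence; monotonicity asserted |
| `variance_mode` | auto | shared/separate | BIC picks the 1-D variance family |
| glog trim | 0.10 | fraction | least-trimmed affine calibration fit |
| Cox ties | Efron | — | better small-sample behavior than Breslow |
| `n_permutations` | 1000 | — | null ensemble size (100 in the pipeline default for runtime) |
| `alpha` | 0.05 | — | permutation-null summary level |

## The consensus-correlation estimator

The contract is a consensus value: per-probeset within-block correlations
mapped by `atanh`, 15%-trimmed-mean averaged, mapped back by `tanh`, and
clamped to $(-0.99, 0.99)$. The per-probeset statistic needs care in the
two-patient design: after removing cell-type means the residual vectors
have one degree of freedom per cell type, and a naive Pearson correlation
of the within-block pairs degenerates to $\pm 1$ (its trimmed-mean
consensus is badly biased — $\approx 0.71$ when the truth is $0.5$). We
therefore use the intraclass moment form
$r_g = \sum_p e_{pF} e_{pO} \big/ \tfrac12\!\left(\sum_p e_{pF}^2 + \sum_p e_{pO}^2\right)$,
which is continuous in the data and recovers $\rho = 0.5$ with bias
below $0.01$ (SD $\approx 0.026$ at 2000 probesets, two patients).

## Normalization: what the glog calibration is and is not

The original analyses normalize probe-level arrays with vsn's robust
maximum-likelihood fit. Probe-level data are out of scope here, so the
package implements the same *model class* on probeset summaries: a
per-array affine calibration $(y - a_s)/b_s$ followed by a shared
generalized log $\mathrm{glog}_2(y, c) = \log_2\!\big((y + \sqrt{y^2 + c})/2\big)$.
The affine parameters come from a deterministic least-trimmed regression
of each array's order statistics on the mean order statistic (10%
trimming), and $c$ from a deterministic grid search minimizing the slope
of row-SD versus intensity rank — the variance-stabilization criterion.
This reproduces the qualitative behavior (scale correction, flat
variance, log-like top end) but is not a reimplementation of vsnrma;
exact reproduction of published probeset lists is therefore not expected,
and all tests of downstream stages use matrices that are already on the
log scale. Datasets are never co-normalized: each cohort is calibrated
independently.

## What the synthetic data emulates — and what it does not

`simulate_paired_cell_lines()` generates the stated paired design: two
patients by two cell types, one array each, intra-patient correlation
$\rho = 0.5$, per-probeset variances drawn from a scaled inverse
chi-square with $(d_0 = 4, s_0^2 = 0.05)$ so the moderation model holds
*exactly* (making prior recovery a valid test), baseline $\log_2$
intensities $\mathcal N(8, 1.5^2)$, and 600 planted probesets per
direction at $\delta = 2$ — the order of magnitude of the published
significant lists on a 54,675-probeset platform.

`simulate_tumor_cohort()` plants the class signal only in the signature
probesets: each is shifted by $w_i\delta/2$ toward its class pole, so the
score is exactly a two-Gaussian mixture with separation
$\sqrt{k}\,\delta/\sigma$ score-SDs (the defaults $\delta = 1,
\sigma = 0.5, k = 10$ give $\approx 6.3$, a clearly bimodal cohort;
mixing proportion 0.6 FT-like, matching serous-dominated cohorts).
Grade/stage are proportional-odds draws (odds ratio 4 for FT-like),
subtype is serous with odds ratio 8, survival is exponential with
proportional hazards (baseline median 36 months, hazard ratio 2 for
FT-like) under independent exponential censoring tuned to a 30% censored
fraction.

What the generators do **not** emulate: probe-level noise and background,
stromal contamination of non-microdissected tumors, platform differences
between cohorts, correlated non-signature genes, and non-proportional
hazards. A green test therefore establishes that the *statistical
machinery* is correct under its own assumptions — not that the published
cohort-level numbers are reproduced, which requires the deposited arrays.

## Numerical choices and degenerate inputs

- Trigamma inversion and the EM both have explicit tolerances
  ($10^{-10}$, $10^{-8}$) and caps; EM collapse ($\sigma \to 0$) aborts
  the restart, and only if every restart collapses does the fit error.
- When the spread of $\log s^2_g$ is at or below chi-square sampling
  noise, $d_0 = \infty$: all variances shrink to $s_0^2$ (logged).
- The Mann-Whitney variant is the tie-corrected normal approximation
  *without* continuity correction — the variant whose p-values match the
  published two-group count tables at printed precision; with all values
  tied it reports $p = 1$ with a warning.
- Fisher's exact test enumerates 2×2 tables exactly; 2×K tables are
  enumerated when the enumeration bound is below $10^6$ and otherwise
  sampled with fixed margins under a seed.
- Scores never impute: a missing value among used signature probesets is
  an error, and platform-absent probesets are reported, not guessed.
- Labels at exactly posterior 0.5 go to FT-like (a measure-zero tie).

## Design choices where the design was open

- **Label rule**: posterior $\ge 0.5$ (the Bayes rule); whether the
  original classification used the posterior or the density crossing is
  unstated — the two coincide for shared-variance components.
- **Tie-break for "most significant"**: $p$, then $|\tilde t|$, then
  probeset id; some total order is required and none is stated.
- **Replicates**: the generator supports technical replicates per
  patient × cell type but defaults to one array, the deposited design.
- **Permutation count**: 1000 by default ($n$ unstated in the source
  analyses); $\alpha = 0.05$.
- **Calibration world for the permutation null**: the binomial bound on
  the false-positive fraction assumes (near-)independent permutations.
  Random signatures scored on one shared expression matrix produce
  correlated label vectors when class-linked probesets occupy a
  noticeable fraction of the universe, so the calibration test uses the
  configuration the claim is actually about — clinical covariates
  independent of an expression matrix that carries no class signal
  ($\delta = 0$, 1000-probeset universe).

## Known limitations

- The glog calibration is an array-affine approximation of vsn, applied
  to probeset summaries; published probeset counts (632/525) are not
  expected to reproduce exactly even on the deposited data.
- The consensus correlation is a moment estimator, not per-probeset REML;
  it matches the consensus contract and recovers the truth in the stated
  design, but individual per-probeset correlations are noisy by nature.
- Ordinal regressions with extremely unbalanced mixture splits (a handful
  of samples in one class) can be flagged for separation; the LRT p is
  still reported with `converged = FALSE`.
- The 2×K Monte-Carlo Fisher p has resolution $1/(B+1)$; raise
  `mc_iterations` when small p-values matter.
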