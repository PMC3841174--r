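# coosig — cell-of-origin expression signatures for ovarian tumor stratification

Epithelial "ovarian" carcinomas may originate in the ovarian surface
epithelium (OCE) or in the non-ciliated fallopian tube epithelium (FNE).
If tumors keep a transcriptional imprint of their normal cell of origin,
a signature separating normal FNE from normal OCE cells should also
split tumor cohorts into fallopian-tube-like (FT-like) and ovary-like
(OV-like) subgroups with different clinical behavior. `coosig` is an R
package for the full analysis, aimed at computational biologists working
with bulk expression cohorts:

- **Paired differential expression** between donor-matched FNE/OCE
  lines: consensus intra-patient correlation ρ, per-probeset generalized
  least squares, empirical-Bayes moderated t
  (t̃ = β̂ / (s̃ √v), s̃² = (d₀s₀² + d s²)/(d₀ + d)), Benjamini–Hochberg
  FDR.
- **Signature building and scoring**: the top k = 5 probesets per
  direction with unique gene symbols, weights wᵢ ∈ {+1, −1}; a sample's
  score is S = Σᵢ wᵢ xᵢ (higher = more FT-like), with platform-absent
  probesets dropped and counted, never imputed.
- **Mixture stratification**: two-component 1-D Gaussian mixture by EM
  with seeded restarts, shared/separate variance chosen by BIC, labels by
  the posterior-0.5 Bayes rule.
- **Clinical statistics**: proportional-odds tests for grade/stage,
  Fisher's exact test (enumeration or seeded Monte-Carlo) for subtype,
  Welch t, tie-corrected Mann-Whitney (no continuity correction — the
  variant that reproduces published count-table p-values), log-rank, and
  multivariate Cox regression with Efron ties.
- **Permuted-signature null**: the whole score→classify→associate chain
  repeated with random ±1 signatures as a negative control.
- **Synthetic-data generators** for both the paired design and tumor
  cohorts, with recorded truth, so every stage is testable offline; a
  glog-based variance-stabilizing calibration and quantile normalization
  for raw matrices; GEO Series Matrix / TSV readers and a config-driven
  pipeline with a run log.

## Worked example

Simulate the paired two-patient design, derive the signature, score a
simulated 200-tumor cohort, classify, and test the split:

```r
library(coosig)

cl  <- simulate_paired_cell_lines(
  cell_line_sim_config(n_probesets = 2000, n_de_per_direction = 50,
                       seed = 7))
de  <- paired_diffexp(cl$matrix, cl$design)
sig <- select_signature(de)                     # 5 FNE-up + 5 OCE-up
co  <- simulate_tumor_cohort(cohort_sim_config(n_tumors = 200, seed = 8),
                             sig)
sc  <- score_samples(co$matrix, sig)
m   <- fit_two_component_mixture(sc$score, seed = 1)
m
#> Two-component Gaussian mixture (shared variance)
#>   pi(FT-like) = 0.560
#>   mu: OV-like -5.134, FT-like 4.953
#>   sigma: OV-like 1.677, FT-like 1.677
#>   logL = -523.794, BIC = 1068.781, n = 200
```

The fit recovers the simulated world: ρ̂ = 0.497 (truth 0.5), variance
prior (d̂₀ = 3.54, ŝ₀² = 0.046; truth 4, 0.05), and the mixture means
±5 with π̂ = 0.56 (truth 0.6) — every label agrees with the latent
class. The subgroups then separate clinically:

```r
proportional_odds_assoc(co$clinical$grade, m$labels)
#> proportional-odds LRT: statistic = 44.06, p = 3.186e-11 (n = 88/112)
logrank_test(co$clinical$dfs_time, co$clinical$dfs_event, m$labels)
#> log-rank: statistic = 16.88, p = 3.973e-05 (n = 88/112)
```

i.e. FT-like tumors are higher grade and progress earlier (the cohort
was simulated with hazard ratio 2; the adjusted Cox fit estimates
HR = 2.71 for the FT-like class, Wald p = 3.8e-05). The permuted-
signature null stays at chance:

```r
permutation_signature_null(co$matrix, co$clinical,
                           n_permutations = 50, seed = 2)
#> Permuted-signature null: 50 permutations (1 failed)
#>   subtype: fraction p < 0.05 = 0.041
#>   grade: fraction p < 0.05 = 0.020
#>   stage: fraction p < 0.05 = 0.041
```

The printed two-group count tables of the xenograft experiments are
exact anchors of the Mann-Whitney implementation:

```r
mann_whitney_tiecorrected(rep(0, 13), c(rep(1, 3), rep(0, 3)))$p
#> [1] 0.00684766   # printed as 0.007
```

A config-driven run of the whole chain (every stage written as TSV plus
a run log):

```r
run_pipeline("my_run.cfg", out_dir = "results_run")
# or from a shell:
#   Rscript -e 'coosig::coosig_cli()' all --config my_run.cfg --out results_run
```

## Documentation

`vignettes/cell-of-origin-methods.Rmd` describes the model, the
estimators and their numerical choices, what the synthetic data does and
does not emulate, and known limitations.
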