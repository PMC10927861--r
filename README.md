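# ftlmeta

Random-effects meta-analysis of controlled broiler-feeding trials of
fermented tropical leaf meal (FTLM) supplementation — and of any two-arm
trial base reported as per-arm means, SDs (or SEs) and replicate counts.

Trials of FTLM in broilers report outcomes in incompatible units (feed
intake in g/day, FCR unitless, villus height in µm, muscle pH, …) across
different strains, leaf species, fermentation microbes, doses and rearing
phases. `ftlmeta` pools them the way this literature does:

* **Effect sizes** — Hedges' *g*, the bias-corrected standardized mean
  difference: *g = J·(x̄ₜ − x̄꜀)/sₚ* with *J = 1 − 3/(4m−1)*,
  *m = nₜ + n꜀ − 2*, and sampling variance
  *(nₜ+n꜀)/(nₜn꜀) + g²/(2(nₜ+n꜀))*.
* **Pooling** — DerSimonian–Laird random-effects with Cochran's *Q*,
  *I²* and *τ²* heterogeneity; fixed-effect pooling as the building
  block; exact *Q* decomposition over subgroup splits.
* **Moderator analysis** — restricted subgroup tables (per-level *τ²*)
  and univariable mixed-effects meta-regression with the omnibus *Q*ₘ
  test and *R²* (percent of heterogeneity accounted for).
* **Publication bias** — Rosenberg's weighted fail-safe number *N*fs and
  the *N*fs > 5n + 10 robustness rule.
* **Synthetic ensembles** — a generator with known true parameters
  (μ, τ², moderator shifts) producing extraction tables with exactly the
  sampling structure the variance formula assumes, so the whole pipeline
  is validated by parameter recovery.

See `vignettes/methods.Rmd` for the statistical details and design
decisions.

## Worked example

```r
library(ftlmeta)

cfg <- simulation_config(k = 80, mu = 0.33, tau2 = 0.1, seed = 42)
sim <- simulate_ensemble(cfg)          # 80 synthetic ADG comparisons
eff <- compute_effects(sim$records)    # Hedges' g + variance per row

re <- random_effects_pool(eff)
re$pooled
#> random-effects pool: SMD = 0.28 [0.16, 0.40], z = 4.58, P < 0.001, k = 80
re$heterogeneity
#> Q = 102.24 (df = 79, P = 0.040), I2 = 23%, tau2 = 0.069

assess_robustness(eff)
#> fail-safe N = 479, n = 80, threshold 5n+10 = 410 -> robust (OS P < 0.001, TS 0.05)

fit_meta_regression(sim$records, "dose_bin", "ADG")
#> meta-regression of ADG on dose_bin: k = 80, QM = 1.00 (df = 2, P = 0.606), R2 = 0%, residual I2 = 24%
```

Reading: the pooled SMD of 0.28 (true μ was 0.33) says treated birds gain
about a quarter of a within-arm SD more than controls; the CI excludes 0
and the fail-safe number (479) exceeds the 5n+10 threshold (410), so the
result would withstand publication bias; *I²* = 23% with τ̂² = 0.069
(true 0.1) indicates modest between-trial heterogeneity, and dose bin
explains none of it in this draw (R² = 0, P = 0.606 — correctly, since
this world has no dose effect).

With real data, replace the simulation with a CSV in the extraction
dialect (`study_id, country, strain, leaf_type, microbes, dose_g_per_kg,
phase_start_day, phase_end_day, outcome, mean_c, sd_c, se_c, n_c,
mean_t, sd_t, se_t, n_t`; one of `sd`/`se` may be empty per arm):

```r
rec <- read_comparisons("extraction.csv")
run_pipeline(list(csv = "extraction.csv", outcomes = c("FI", "ADG"),
                  out = "report/"))
```

which writes forest, subgroup, meta-regression and bias tables as CSV
plus `summary.json`. The same pipeline is scriptable:

```sh
Rscript exec/ftlmeta simulate --k 200 --seed 7 --out report/
Rscript exec/ftlmeta analyze --csv extraction.csv --outcomes FI,ADG --out report/
```

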