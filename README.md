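# ichneutro

Neutrophil-subset severity analysis for spontaneous intracerebral
hemorrhage (sICH), as a tested R package.

sICH outcomes are shaped by neutrophil-mediated secondary brain injury,
visible radiologically as perihematomal edema (PHE). This package
re-implements the computational pipeline of a pilot cohort study of a
"rogue" DEspR+CD11b+ neutrophil subset: every numeric stage between raw
measurements and the published correlation tables, runnable and testable
end to end without any external data.

**Who it is for:** researchers who want to audit, reproduce, or extend the
severity analysis — or reuse its stages (CT volumetry, NET scoring, flow
quadrant counting, rank-correlation reporting) on their own data.

## What it computes

* **Cohort** — the packaged 13-patient table (`ich_cohort()`): ICH score,
  90-day mRS, GCS, IPH/PHE volumes, modified Graeb score, NLR, and
  DEspR+CD11b+ / NET+ neutrophil counts, with validation and derived
  flags.
* **CT volumetry** — bedside ABC/2 (`abc2_volume()`, with the ellipsoid
  convention `V = A·B·(n_slices·t)/2` ml) and semiautomated
  dual-clustering segmentation of brain, hemorrhage and edema
  (`ct_volumetry()`), with NIfTI I/O.
* **NET scoring** — nuclear segmentation and the circularity index
  `4π·A_MEC / P²` (minimum enclosing circle over the whole nucleus with
  its DNA extrusions, Crofton-traced perimeter); NET-positive below 0.8
  (`segment_nuclei()`, `circularity_index()`, `scan_slide()`).
* **Flow gating** — polygon gating of the neutrophil scatter cloud,
  isotype-quantile quadrant thresholds, Q2 double-positive counting
  (`gate_neutrophils()`, `quadrant_thresholds()`, `quadrant_counts()`).
* **Severity statistics** — midrank Spearman `r`, Bonferroni correction,
  Fisher-z power `Φ(√(n−3)·atanh|ρ| − z₁₋α/₂)`, Mann–Whitney U (exact or
  approximate), Hedge's g, and composite markers summed with neutrophil
  counts on the K/µl scale (`spearman()`, `correlation_power()`,
  `composite_marker()`, `severity_table2/3/4()`, `run_report()`).
* **Synthetic data** — seeded generators for CT phantoms, smear images,
  flow mixtures and Gaussian-copula cohorts, each with closed-form ground
  truth, so the image and flow stages are certified property-style.

## Worked example

```r
library(ichneutro)

co <- ich_cohort()
nrow(co)                                  # 13
round(100 * mean(co$ivh))                 # 85  (% with intraventricular blood)

# the radiological pair: IPH vs PHE volume
round(spearman(co$iph_vol, co$phe_vol), 2)        # 0.78

# neutrophil markers vs 90-day outcome
round(spearman(co$rogue_n_count, co$mrs_90d), 2)  # 0.83
round(spearman(co$nlr, co$mrs_90d), 2)            # 0.81

# combinatorial severity markers vs 90-day mRS
severity_table4(co)[, c("x", "r")]
#>                                         x         r
#> 1                               ich_score 0.9174081
#> 2                           ich_score+nlr 0.9010920
#> 3                 ich_score+rogue_n_count 0.9209899
#> 4                   ich_score+net_n_count 0.9209899
#> 5 ich_score+nlr+rogue_n_count+net_n_count 0.9408878

# power at the strong-correlation boundary
correlation_power(0.71, n = 13, alpha = 0.05)     # 0.801
```

The ICH score alone correlates 0.917 with 90-day mRS; adding NLR and the
two neutrophil counts (in K/µl) raises it to 0.941 — the package's
composite convention reproduces all published combinatorial rows to three
decimals.

A synthetic end-to-end imaging run:

```r
ph  <- generate_ct_phantom(phantom_spec(noise_sd = 3, seed = 1))
res <- ct_volumetry(ph$volume)
round(res$volumes_ml, 2)   #  brain 111.53   iph 4.18   phe 5.06
round(ph$analytic_ml, 2)   #  brain 111.52   hematoma 4.19   edema 5.01
```

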