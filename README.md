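# tapscreen

Screening-level analysis of point-of-consumption (tapwater) chemistry
surveys for mixed regulated and unregulated contaminants — for exposure
scientists and water-quality analysts who need to go from a long-format
table of sample × analyte results to benchmark exceedance counts,
mixture risk screens and group comparisons, reproducibly.

The package implements the full survey workflow:

* **QA/QC** — regional field-blank censoring (results at or below the
  highest regional blank value become non-detects) and fixed-constant
  non-detect substitution for the statistics stage.
* **Regulatory screening** — per-constituent detection frequency,
  median/range over detected values, and exceedance counts against MCLs
  and MCLGs, with *de facto* exceedance of zero-valued MCLGs by every
  detection and a TTHM aggregate for the four regulated trihalomethanes.
* **ΣEAR** — the cumulative exposure-activity ratio under a
  concentration-addition model. For each detected organic with an exact
  CAS match in a ToxCast-style ACC table,
  `EAR = C (µM) / ACC (µM)`, and per sample
  `ΣEAR = Σ_chem max_assay EAR` (an endpoint-wise alternative
  `max_endpoint Σ_chem EAR` is also provided). ΣEAR > 1 flags exposure
  expected to modulate a molecular target in vitro; ΣEAR > 0.001 is the
  precautionary screening level.
* **ΣTQ (hazard index)** — `TQ = C / benchmark` against each analyte's
  most protective health benchmark, with zero MCLGs replaced by
  surrogates (0.1 µg/L; 0.0001 µg/L for PFOA/PFOS) before minimisation;
  `ΣTQ = Σ TQ`, classed high-risk at ≥ 1 and negligible below 0.1. The
  EPA four-PFAS mixture hazard index (≥ 2 detected components, HI > 1)
  is included with user-supplied component benchmarks.
* **Group statistics** — one-way PERMANOVA (pseudo-F from Anderson's
  partition of squared Euclidean distances, permutation p with the
  +1/+1 convention), gated Kruskal–Wallis (tie-corrected H) and Dunn
  post hoc with Bonferroni correction and compact letter displays.
* **Synthetic study generator** — a five-region, 60-sample campaign
  preset (12/6/10/10/22 samples; 5 private wells; 251 organic + 32
  inorganic analytes) with detection probabilities and lognormal
  concentration bodies calibrated to published occurrence statistics, so
  every stage is testable without field data.

## Worked example

```r
library(tapscreen)
ds <- generate_study(preset_california(), seed = 1)
ds$measurements <- censor_to_blanks(ds$measurements, ds$blanks, ds$samples)

tq <- study_sum_tq(ds)
table(tq$class)
#>    high_risk intermediate
#>           56            4

ear <- study_sum_ear(ds)
round(summary(ear$sum_ear), 4)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.0001  0.0573  0.1684  0.2605  0.3697  1.1569

head(tq[order(-tq$sum_tq), ], 3)
#>   sample_id sum_tq class     n_individual_tq_over_1 top_driver
#> 1 site_060    329. high_risk                      4 bromoform
#> 2 site_059    260. high_risk                      6 uranium
#> 3 site_058    260. high_risk                      4 PFOA
```

Reading: 56 of 60 synthetic samples carry a contaminant mixture whose
summed toxicity quotients exceed 1 — a high probability of aggregated
risk, driven mostly by zero-MCLG disinfection byproducts screened against
their 0.1 µg/L surrogate — while the cumulative bioactivity screen puts
the median sample at ΣEAR ≈ 0.17, above the 0.001 precautionary level but
below the in-vitro activity level of 1.

The numbered scripts under `analysis/` run the same stages as a
narrated workflow (`01_simulate.R` → `04_group_stats.R`), writing
delimited tables and a JSON manifest under `results/`. The packaged ACC
table is a synthetic, schema-compatible stand-in for an invitroDB export;
supply a real export (columns `analyte_cas, assay_endpoint_id, acc_um,
exclusion_reason`) for production screening.

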