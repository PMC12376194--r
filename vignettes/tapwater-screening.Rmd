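---
title: "Screening tapwater for mixed-contaminant exposure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tapwater for mixed-contaminant exposure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapscreen)
```

## The problem

Point-of-consumption tapwater carries mixtures of regulated contaminants
(disinfection byproducts, nitrate, arsenic, a handful of PFAS) and
unregulated ones (most pharmaceuticals, many pesticides and PFAS). Single
constituents rarely exceed their enforceable standards, yet mixtures of
many low-level detections can still be biologically active. `tapscreen`
implements the screening workflow used in synoptic tapwater surveys: each
sample is characterised by what was detected, how those detections compare
to health benchmarks individually, and how the whole mixture scores under
two additive screening statistics — a bioactivity-weighted one (ΣEAR) and
a benchmark-weighted one (ΣTQ). Group differences among regions, system
sizes and source waters are then tested with distribution-free permutation
methods.

All concentrations are held internally in µg/L. Native reporting units
(ng/L for PFAS, mg/L for nitrate-N and fluoride) are fixed power-of-ten
rescalings recorded on the analyte catalogue and restored in reports.

## QA/QC: blank censoring and non-detect substitution

Field blanks travel with each region's sampling kits. When an analyte is
detected in a region's blank(s), every tapwater result from that region at
or below the **highest** blank value is re-coded as `censored_by_blank`
and its value cleared. This is whole-record censoring, not blank
subtraction: the surveys this mirrors report *counts of censored samples*,
not adjusted concentrations, and censoring is idempotent by construction.
Results above the blank maximum, and regions without a blank detection of
that analyte, are untouched.

Non-detect substitution exists **only** to complete the numeric matrix
required by the distance-based statistics. The fixed constants are:

| rule key | substitute (µg/L) |
|---|---|
| pesticides, pharmaceuticals, PFAS (class) | 0.0001 |
| DBPs and cumulative-organic aggregates (class) | 0.01 |
| manganese, nitrate-N, lead (named) | 0.01 |
| arsenic, uranium (named) | 0.1 |

Two deliberate literalisms are worth flagging. First, the nitrate constant
is applied on the µg/L scale exactly as printed even though nitrate is
otherwise reported in mg/L; with ambient nitrate medians near 1.5 mg/L the
substitute sits four orders of magnitude below any detection, so the
choice is inconsequential for rank-based statistics but is logged. Second,
the constants take precedence even if a hypothetical detection fell below
one; under the packaged generator's envelopes this never occurs. An
analyte that has a non-detect but no applicable rule is a hard error —
extending the rule table is a deliberate analyst action, never a silent
default.

Exceedance screening and both mixture statistics operate on **detected
values only**; substituted values never enter an EAR or TQ.

## Individual-constituent screening

Detection frequency is `100 × detections / roster size`, reported to one
decimal; the roster denominator is all samples, which reproduces published
frequencies for DBP-type constituents measured everywhere. Medians and
ranges summarise detected values only. A result strictly above a positive
benchmark exceeds it (a value exactly at the benchmark is compliant — the
standard compliance convention); a benchmark of **zero** (an MCLG with no
identified safe-exposure level) is exceeded *de facto* by every detection.
Total trihalomethanes are the sum of detected chloroform,
bromodichloromethane, dibromochloromethane and bromoform, and are
non-detect — not zero — when all four are absent, so the aggregate keeps
meaningful detection-frequency semantics. The lead entry in the packaged
benchmark table is the non-health-based Action Level, carried as an
MCL-type row with a note. The estrogen-receptor bioassay comparison is a
strict test of measured E2-equivalents against the 3.8 ng/L effects-based
trigger.

## ΣEAR: bioactivity-weighted mixture screen

For each detected organic with a molecular weight and an exact CAS match
in the ACC table, concentrations convert to micromolar (µg/L ÷ g/mol) and
each included assay contributes `EAR = conc_µM / ACC_µM`. Assays flagged
as non-specific endpoints, baseline responses or unreliable curves are
excluded before any arithmetic. Two additive aggregation conventions are
implemented because the field's tooling supports both and survey write-ups
rarely say which was used:

* `sum_of_chemical_max` (default): ΣEAR = Σ over chemicals of the
  chemical's maximum EAR across assays;
* `max_endpoint_sum`: chemicals are summed within each assay endpoint and
  ΣEAR is the largest endpoint sum.

The second can never exceed the first (each endpoint sum is bounded by the
sum of chemical maxima), and both are linear in concentration. They
coincide exactly when every chemical has a single assay on one shared
endpoint. Neither is asserted to be "the" published convention; the choice
is a logged argument. ΣEAR above 1 marks exposure expected to modulate a
molecular target in vitro; above 0.001 is a precautionary screening level
chosen because targeted analyte lists cover only a small fraction of
chemicals in commerce. Chemicals without coverage contribute zero and are
listed in a coverage report rather than dropped silently.

The packaged ACC table (`acc_synthetic.csv`) is **synthetic**: it mirrors
the invitroDB export schema and covers the screen's driver chemicals with
plausible magnitudes and exclusion flags so the pipeline is exercised end
to end, but it is not ToxCast data. Production screening should supply a
real ACC export in the same layout.

## ΣTQ: benchmark-weighted hazard index

Each detected, benchmarked analyte — organic or inorganic — contributes
`TQ = conc / benchmark` against its *most protective* (lowest) available
benchmark. Zero-valued MCLGs are replaced **before** minimisation by
surrogates — 0.1 µg/L generally (DBPs, arsenic, lead, uranium) and
0.0001 µg/L for PFOA and PFOS — so a literal zero never wins and no TQ
divides by zero. ΣTQ ≥ 1 classifies `high_risk`, ΣTQ < 0.1 `negligible`,
between them `intermediate`; drivers are ranked by individual TQ. The
four-PFAS mixture hazard index (PFNA, PFBS, PFHxS, GenX) follows the
mixture rule: flagged only when HI strictly exceeds 1 *and* at least two
components are detected. Its component health-based water concentrations
are deliberately config-only — no authoritative values are packaged, and
the analysis driver uses clearly-labelled synthetic placeholders.

Note that one published ΣTQ summary ("median 18.8; IQR 19.7–209") is
internally inconsistent (the median falls below the lower quartile), so no
distributional ΣTQ value is asserted anywhere in the tests; the structural
property that every sample detecting a zero-MCLG DBP at or above
0.1 µg/L must classify `high_risk` is asserted instead, since
TQ = conc/0.1 ≥ 1 follows arithmetically.

## Group statistics

The testing protocol is two-stage: a one-way PERMANOVA on Euclidean
distances of the complete (substituted) concentration matrix, and — only
when it fires at α = 0.05 — a Kruskal–Wallis test on a per-sample summary
(default: cumulative concentration) with a Dunn post hoc under Bonferroni
correction when three or more groups are compared.

PERMANOVA uses the direct partition of squared interpoint distances:
`SS_T = Σ_{i<j} d²_ij / N`, within-group `SS_W` summed per group, and
`pseudo-F = (SS_A/(a−1)) / (SS_W/(N−a))`. The permutation p-value counts
the observed statistic in both numerator and denominator,
`p = (1 + #{F* ≥ F}) / (1 + n_perm)`, the standard exact-test convention
that keeps p strictly positive with floor `1/(n_perm+1)`. Permutation
comparisons use a small absolute guard (1e−12) so floating-point noise in
algebraically tied statistics cannot flip a count. The test responds to
both centroid and dispersion differences; no separate dispersion test is
provided. Kruskal–Wallis applies the standard tie correction
`1 − Σ(t³−t)/(N³−N)` with a chi-square reference on a−1 degrees of
freedom; an all-tied response returns H = 0, p = 1 rather than 0/0. Dunn
z-statistics use pooled midranks with the matching tie term, two-sided
normal p-values, and Bonferroni inflation by the number of pairs. Compact
letter displays come from an insert-and-absorb pass: groups sharing no
letter differ at α.

These tests are implemented from their defining formulas rather than
delegated, so they can be verified against independent references —
`vegan::adonis2` for the pseudo-F, exhaustive label enumeration for exact
small-instance p-values, and `stats::kruskal.test` for H — which the test
suite does.

## The synthetic study generator

The generator emulates the structure of a five-region synoptic campaign:
60 samples split 12/6/10/10/22 across Gold Country, the Bay Area,
Merced/Fresno, Kern and SELA; five private wells, all in Gold Country,
groundwater-sourced by definition; 19 small (<10,000 served) among 55
public-supply samples; 10 surface-water-only and 18 groundwater-only
sourced homes. The analyte roster is padded to the campaign's analytical
scope (251 organics, 32 inorganics); named constituents carry detection
probabilities and medians set to the published occurrence table (e.g.
bromodichloromethane 0.867, lithium 1.0, arsenic 0.10) with regional
overrides concentrating PFAS in SELA and arsenic in Kern.

Detection is Bernoulli per (sample, analyte); detected concentrations are
lognormal bodies centred on the configured medians, **winsorised** (not
tail-truncated) to the published detected ranges. Winsorising was chosen
deliberately: clipping keeps every draw inside the printed envelope while
preserving the configured median exactly, whereas asymmetric tail
truncation would shift the realised median away from the value it was
calibrated to. DBP concentrations within a sample share a latent
"disinfection intensity" factor (default correlation 0.5) so they
co-occur at correlated levels; private wells receive no DBPs at all,
mirroring the absence of disinfection. Field blanks follow the campaign
layout — two events per region, one in the Bay Area, nine in total (the
source text's count of ten conflicts with its own per-region enumeration;
the per-region statement is followed) — with contamination restricted to
the blank-prone analytes (nitrate, copper, iron, manganese, zinc) at low
magnitudes.

What the generator does *not* emulate: spatial autocorrelation within
regions, seasonality (the emulated design is one-time synoptic),
reporting-limit heterogeneity across methods, and correlated
inorganic/organic co-occurrence beyond the DBP latent factor. Tests that
pass on generated data therefore validate the **pipeline's arithmetic and
invariances**, not distributional claims about any real water system.

## Numerical and interface choices

* Same seed ⇒ byte-identical datasets and permutation p-values; all
  generator and permutation randomness flows through locally scoped RNG
  streams that never disturb the caller's RNG state.
* Archives are delimited text with a JSON manifest; numeric columns are
  written at 17 significant digits on the internal µg/L scale, making
  write-then-read round-trips bit-identical.
* Degenerate inputs are explicit: constant distance matrices and
  singleton groups are errors for PERMANOVA; a study with no detections
  produces all-zero screens and skips statistics with a manifest note;
  an empty included-assay set yields ΣEAR 0 with a warning.
* Problem sizes in the shipped tests and analysis scripts are the study's
  own: the 60-sample campaign layout throughout, 9,999 permutations for
  the reported statistics, 199 permutations per replicate in the 500-run
  null-calibration study, and ~1,000-sample configurations for parameter
  recovery.

## Worked example

```{r example, eval = FALSE}
library(tapscreen)
ds <- generate_study(preset_california(), seed = 1)
ds$measurements <- censor_to_blanks(ds$measurements, ds$blanks, ds$samples)
tq <- study_sum_tq(ds)
table(tq$class)
ear <- study_sum_ear(ds)
summary(ear$sum_ear)
res <- run_pipeline(ds, out_dir = tempfile("run"), n_perm = 999, seed = 1)
```

The numbered scripts under `analysis/` run the same stages as a narrated
workflow and write their tables under `results/`.

## Known limitations

The packaged ACC fixture is synthetic; benchmark coverage is limited to
the constituent set of the emulated campaign; the PFAS-HI component
benchmarks must be user-supplied; PERMANOVA conflates location and
dispersion by design; and no figure-generation layer is provided beyond
the delimited tables (standard plotting tools apply directly to the
per-sample outputs).
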