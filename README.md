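# careseg

Need-based population segmentation for primary-care performance reporting,
as a tested R pipeline over administrative-claims-style data.

Primary care serves everyone from healthy adults to frail people near the
end of life, and performance reports that pool them hide the variation
that matters. `careseg` partitions an adult population into four mutually
exclusive segments defined by expected need for care — **low need**
(≤ 1 chronic condition, no complexity event), **multiple morbidities**
(≥ 2 conditions), **medically complex** (≥ 1 condition plus a linked
complexity event such as dialysis with chronic kidney disease), and
**frail** (65+ with frailty-based care, palliative status, or ≥ 2
Edmonton-scale criteria) — then reports costs, utilisation and
primary-care attributes by segment and SES stratum, attributes patients
to family-physician panels, and models costs within each segment.

Because the data this design targets (linked provincial billing, hospital,
ED and pharmacy records) are access-restricted, the package ships a
**synthetic-claims generator with known ground truth**: planted segments
that the classifier must recover exactly, and planted cost-model
coefficients that the fitting stage must recover statistically. Everything
downstream is exercised against that truth.

## The model

For person *i* in segment *s*, outcome-year total cost is modelled in two
parts:

* **Part one** (any cost): logistic regression,
  `logit P(C_i > 0) = x_i' beta_s`, reported as odds ratios;
* **Part two** (cost among users): Gamma GLM with log link,
  `E[C_i | C_i > 0] = exp(x_i' gamma_s)`, reported as cost ratios;

with covariates age group (ref 65–74), sex (ref male), chronic-condition
count capped at 5 (continuous; categorical as sensitivity analysis), and
SES (neighbourhood-income quintiles 1–2 = low vs 3–5 = high, ref high).
Part two adds three primary-care attributes: the usual-provider-of-care
continuity index `UPC = max_j v_ij / sum_j v_ij` over ambulatory FP visits
in a 3-year window, coordination (saw < 5 distinct FPs in the outcome
year, ref ≥ 5), and out-of-hours access (any flagged FP billing, ref
none). Totals are winsorized beforehand at the 99th percentile within
age–sex groups; persons with no FP visit in the continuity window are
excluded from the models.

## Worked example

The analysis is organised as numbered scripts under `analysis/`
(simulate → cohort/segment → attribute → metrics → models → reports),
each a thin driver over exported functions; `run_pipeline()` does the same
in one call. On the default study conditions at n = 50,000 (seed
20260401) the scripts print:

```
Cohort: 48657 included, 1343 excluded
Segment sizes (cohort): 39840 6367 1456 994
Planted-segment recovery: 100 %

Assigned 45148 of 48657 patients to 250 physician panels
Median panel share in the low-need segment: 80.5 %
Median billing-dollar share from low-need patients: 58.8 %

   segment mean_total_cost mean_fp_visits mean_upc pct_access pct_lt5_fps
1:       1            1476            4.1     0.72        2.4        99.1
2:       2            5729           11.5     0.82        4.2        95.0
3:       3           10406           13.8     0.72        4.7        76.1
4:       4           12131           19.1     0.82       10.8        78.9

Part-two cost ratios for low SES by segment:
  segment 1: CR 1.12 (1.11-1.14)   ... segment 4: CR 1.18 (1.08-1.29)
```

Reading this: segmentation recovers every planted segment; mean total
cost rises monotonically from the low-need to the frail segment while
billing dollars concentrate on high-need patients relative to panel
shares; and the fitted SES cost ratios recover the generator's planted
`log(1.12)` SES effect. In miniature:

```r
library(careseg)
cfg <- generator_config(n_persons = 5000, seed = 42)
dat <- generate_synthetic_data(cfg)
cohort <- apply_eligibility(dat$persons, dat$coverage)
seg <- segment_cohort(dat, dat$persons, cohort_ids = cohort$included)
table(seg$segment)
```

The methods vignette (`vignettes/segmentation-methods.Rmd`) documents the
segment rules and their open corners, the generator's planting and
calibration, and every numerical convention (winsorization definition,
tie-breaks, boundaries).

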