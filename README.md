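# bh3toolkit

Analysis pipeline for **BH3 mimetic drug-response profiling** of hematologic
tumor samples by Annexin V / 7AAD flow cytometry with counting beads — a
functional precision-medicine assay that measures which anti-apoptotic
protein (BCL-2, MCL-1 or BCL-XL) a patient's tumor cells depend on, at
baseline or after an *ex vivo* drug exposure.

It is written for analysts of plate-based cytometry drug screens: it takes
per-well event data (FCS 3.0/3.1 or a documented CSV dialect) plus a plate
layout, and produces gated class counts, Δ Annexin V statistics,
bead-normalized absolute cell counts, CellTiter-Glo viability, dependency
scores, dynamic-profiling shifts, internal-control QC, ANOVA comparisons and
radar/heatmap reports. A synthetic cytometry generator with known ground
truth makes every stage testable without instrument data.

## The statistics at the core

Living cells are treated 4 h with BH3 mimetics (venetoclax → BCL-2,
AZD-5991 → MCL-1, A-1155463 → BCL-XL, navitoclax → pan) at 10 nM, 100 nM and
1 µM. Early apoptosis is the Annexin V single-positive fraction (7AAD⁺
events are excluded as non-specific late death):

```
Δ AnnexinV = %AnnexinV⁺7AAD⁻(treated) − %AnnexinV⁺7AAD⁻(vehicle)        [points]

score_target = 100 × Δ_sample(drug, 1 µM) / Δ_control(drug, 1 µM)
score_MCL-1  = 100 × Δ_sample(AZD-5991, 1 µM) / 30      (weighted default)

cells_per_well = events × beads_added / beads_observed   (counting beads)

shift = Δ(pre-treated arm) − Δ(vehicle arm)              (dynamic mode)
```

Internal controls are OCI-Ly1 (BCL-2), JJN3 (MCL-1) and HEL (BCL-XL), with
reference 1 µM responses 75.4 / 55.4 / 69.1 points and thaw-to-thaw SDs
5.0 / 7.7 / 5.9; a control batch passes QC when its mean response lies in
mean ± 2 SD.

## Worked example

Recover the BCL-2 control's response through the full pipeline — simulate 3
treated/vehicle pairs at 20,000 events, fit gates from the vehicle wells,
classify, difference:

```r
library(bh3toolkit)

truths <- control_line_truths()          # published control responses as truth
run <- recover_delta(truths[["OCI-Ly1:venetoclax"]], dose_nM = 1000,
                     n_pairs = 3, n_events = 20000,
                     variability = variability_model(rng_seed = 1))
run$delta[, c("sample_id", "drug", "dose_nM", "delta_pct", "sem")]
#>   sample_id drug       dose_nM delta_pct   sem
#> 1 OCI-Ly1   venetoclax    1000      75.5 0.197
```

The estimate (75.5 ± 0.2 points) recovers the generator truth of 75.4 — the
pipeline's gating and differencing add no material bias. Score a CLL-like
sample against the three controls:

```r
controls <- data.frame(sample_id = c("OCI-Ly1", "JJN3", "HEL"),
                       drug = c("venetoclax", "AZD-5991", "A-1155463"),
                       dose_nM = 1000, delta_pct = c(75.4, 55.4, 69.1))
sample <- data.frame(sample_id = "CLL-1",
                     drug = c("venetoclax", "AZD-5991", "A-1155463", "navitoclax"),
                     dose_nM = 1000, delta_pct = c(70.0, 10.4, 7.6, 40.0))
profile_sample(sample, controls)
#> Dependency profile for CLL-1
#>  BCL2_score  MCL1_score BCLXL_score
#>        92.8        34.7        11.0
#> MCL-1 formula: weighted (weight 30 )
#> overall priming (navitoclax delta, not scored): 40 points
```

A high BCL-2 score with low MCL-1/BCL-XL scores is the classic CLL pattern —
this sample responds to venetoclax almost as strongly as the BCL-2 control
line itself. Batch QC of control vials:

```r
qc_check(c(73.1, 79.8, 71.2), default_control_references()[1, ],
         batch_ids = c(1, 1, 2))
#> QC OCI-Ly1: mean 74.7 over 3 vials -> PASS (within range; range [65.4, 85.4])
#>   inter-batch SD 0.00, intra-batch SD 4.74
```

`render_radar()` plots profiles as the assay's radar charts (reference
polygon at score 100), `render_heatmap()` draws the Δ Annexin V drug × dose
grid; both emit their numbers as CSV sidecars.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study at desk scale and
write tables to `results/tables/` and figures to `results/figures/`:

| script | what it does |
|---|---|
| `01_simulate_plates.R` | simulate the baseline control plate (36 wells), write event files + truth table |
| `02_gate_quantify.R` | fit thresholds from vehicle wells, classify, Δ Annexin V table + heatmap |
| `03_dependency_scores.R` | score a synthetic CLL/AML/MM-like cohort, radar charts |
| `04_dynamic_profiling.R` | ironomycin and azacytidine pre-treatment shift recovery |
| `05_qc_and_stats.R` | thaw reproducibility + batch QC, bead counting, ANOVA, Δ-vs-CTG correlation |

Run them in order: `for s in analysis/0*.R; do Rscript $s; done`.

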