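---
title: "Methods: quantifying anti-apoptotic dependencies from BH3 mimetic flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying anti-apoptotic dependencies from BH3 mimetic flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bh3toolkit)
```

## The assay and its statistics

Living tumor cells are exposed for 4 h to a small toolkit of BH3 mimetics —
venetoclax (BCL-2), AZD-5991 (MCL-1), A-1155463 (BCL-XL) and the
pan-inhibitor navitoclax — at 10 nM, 100 nM and 1 µM, then stained with
Annexin V and 7AAD. Because cells stay intact (no permeabilization, no
cytochrome-c antibody), the early onset of apoptosis is read as the Annexin V
single-positive fraction: 7AAD-positive events are late-apoptotic or
necrotic, and are deliberately excluded because late death is not specific to
the mimetic. The assay's primary statistic is

$$\Delta\text{AnnexinV} = \%\text{AnnexinV}^{+}\,7\text{AAD}^{-}(\text{treated}) -
  \%\text{AnnexinV}^{+}\,7\text{AAD}^{-}(\text{vehicle}),$$

in percentage points. Dependency on a specific anti-apoptotic protein is then
expressed relative to an internal control cell line measured in the same run
at 1 µM — OCI-Ly1 for BCL-2, JJN3 for MCL-1, HEL for BCL-XL:

$$\text{score}_{\text{BCL-2}} = 100 \times
  \frac{\Delta_{\text{sample}}(\text{venetoclax},\,1\,\mu M)}
       {\Delta_{\text{OCI-Ly1}}(\text{venetoclax},\,1\,\mu M)},$$

and likewise for BCL-XL. Counting beads spiked at a known number per well
convert event counts to absolute cell numbers
(`cells = events × beads_added / beads_observed`), which supports the
4 h → 24 h cell-death read-out (∆ cell death, the viable-percentage
difference between control and treated) and between-plate toxicity
monitoring. In dynamic mode a 20 h pre-treatment with a drug of interest
precedes the toolkit, and the read-out is the shift
$\Delta_{\text{pretreated}} - \Delta_{\text{vehicle-pretreated}}$ per
(mimetic, dose), sign preserved.

### The MCL-1 axis

The MCL-1 control (JJN3) has the weakest 1 µM response of the three lines
(≈55 points vs ≈75 for OCI-Ly1), which would inflate MCL-1 ratios relative to
the other axes. The package therefore weights the MCL-1 score by 30 by
default: `score = 100 × ∆_sample / 30`, i.e. the control denominator is
replaced by a fixed weight. Because the exact published formula for this
weighting is not available in full detail, the unweighted ratio is kept as a
selectable variant (`formula_variant = "ratio"`), and every scored output is
stamped with the variant and weight used. Scores clip negative sample deltas
to 0 — a radar axis cannot be negative — while the delta and dynamic-shift
tables always keep the sign, since a pre-treatment genuinely can *reduce* a
dependency.

## Gating model

Events are classified in a fixed priority order: **bead** (bead channel above
the bead gate — counting beads are extremely bright everywhere, so they must
be removed first), **debris** (outside the forward/side-scatter gate),
**dead** (7AAD-positive, single or double positive), **early-apoptotic**
(Annexin V-positive, 7AAD-negative), **alive** (double negative). Values
exactly at a threshold are negative; this tie rule is deterministic across
platforms. Fluorescence is compared in arcsinh space
(`asinh(x / cofactor)`, cofactor 150, the conventional choice for
non-spectral flow data); scatter is gated on the raw scale.

Fractions are reported over the *intact-cell* denominator
(alive + early + dead) by default. The live-plus-early denominator is
selectable (`denominator = "live_plus_early"`) because gating displays that
show only living cells suggest it as an alternative; the choice is recorded
in every `WellQuant`.

### Automatic thresholds

When vehicle wells are available, the Annexin V and 7AAD cutoffs are placed
in the upper tail of the pooled, scatter-gated, bead-excluded vehicle events.
Two rules are provided:

* `robust_from_vehicle` (default): `median + z_q × MAD`, with `q = 0.995`.
* `quantile_from_vehicle`: the plain `q`-quantile.

The robust rule is the default for a quantitative reason. Vehicle wells are
not pure negatives: baseline apoptosis of a few percent is biologically
expected (the generator default is 4.6 % early + 5.4 % dead). When the
genuinely positive fraction exceeds `1 − q = 0.5 %`, the plain quantile lands
*inside* the positive population — with 8 % positives, the 99.5th overall
percentile is the ~94th percentile of the positives — and the resulting
threshold destroys the ∆ Annexin V recovery. The median/MAD rule estimates
the same `q`-tail of the *negative* component and tolerates up to ~50 %
contamination. It concedes a small known false-positive rate (~`1 − q` of
negatives per channel); because that rate is nearly equal in treated and
vehicle arms it largely cancels in the delta, leaving a residual bias well
under one percentage point at default settings. Valley-seeking was rejected
because it fails outright when a class is absent (e.g. a fully responding
well with no alive population).

The default manual thresholds (2.0 in arcsinh units) sit mid-gap between the
default synthetic populations and are used where no vehicle wells exist.

## The synthetic cytometry generator

No raw data accompanies the assay's published description, so the package
ships a generator that emulates the assay's statistical structure with known
ground truth; every downstream stage is validated against the hidden labels
it carries.

* **Populations.** Five classes (alive, early-apoptotic, dead, debris,
  bead), each Gaussian in arcsinh-transformed fluorescence (≈ log-normal
  raw) and Gaussian in raw scatter. Default locations: negatives at raw
  median ≈ 45, Annexin V positives ≈ 5 000, 7AAD positives ≈ 6 000, beads at
  60 000 in their own channel and bright (20 000) in all others; debris at
  low forward scatter. These defaults make the classes separable by design —
  what the oracle-agreement tests verify is that the *gating logic* finds
  the separation, not that real data is this clean.
* **Mixtures.** A well's class weights come from baseline fractions
  (default alive 0.90 / early 0.046 / dead 0.054), plus dose-dependent
  conversion of alive to early-apoptotic. Dose response is an explicit
  per-dose table on the assay's grid {0, 10, 100, 1000} nM (the published
  results are per-dose values, not curves); a Hill mode exists for users who
  want one. Control-line truths are set to the published 1 µM responses
  (75.4 / 55.4 / 69.1 points); intermediate doses not printed are filled
  with monotone plausible values.
* **Timepoints.** The plate processed 24 h later converts a fraction
  `progression_rate` (default 0.8) of early-apoptotic cells to dead and
  applies a global attrition factor (default 0.16, matching the observed
  thawing decline of control cells from 17 000 to ~14 281) to absolute
  counts.
* **Variability.** Replicate wells perturb the induced fraction with SD
  `replicate_sd` (default 1.0 point — technical well-to-well variation of
  wells plated from one suspension). Thaw-to-thaw biological variability is
  larger and is injected explicitly in the reproducibility simulations
  (5.0 / 7.7 / 5.9 points for the three control lines). Batch shifts and a
  fresh-vs-frozen offset are additional optional effects. Counting beads are
  Poisson around `beads_added × acquisition_fraction` (volumetric pipetting
  noise); event counts from a true cell count are Binomial in the
  acquisition fraction, which is what makes bead normalization an unbiased
  estimator of the true count.
* **Determinism.** Every well is fully determined by the integer seed in its
  `variability_model`; plates derive one seed per well. Identical seeds give
  byte-identical CSV output.

What the generator does **not** emulate: spectral spillover/compensation,
doublets, acquisition-time drift, debris that overlaps the cell scatter
gate, or non-Gaussian population shapes. Passing recovery tests therefore
demonstrates correctness of the *computational* pipeline under the assay's
published statistical conditions, not robustness to instrument artifacts.

## Numerical and design choices

* **Problem sizes.** Recovery runs use 3 replicate pairs × 20 000 events per
  well (the seeding density of the assay; acquisition counts are not
  published). Binomial noise on a fraction at n = 20 000 is ≈ 0.35 points,
  so 3-pair means resolve the published deltas comfortably within ±2 points.
  The reproducibility simulation uses 12 thaws; the sample SD of 12 draws of
  a 5-point effect has a sampling SD of ≈ 1.1 points, which is the dominant
  term in that check's ±1.5 tolerance.
* **Replicate aggregation.** Deltas default to arm means (treated mean −
  vehicle mean); per-replicate pairing is available (`paired = TRUE`) when
  the layout pairs wells, and retains per-pair deltas for SEM.
* **Dose grid.** Fixed to {0, 10, 100, 1000} nM unless
  `allow_custom_doses = TRUE`, preventing silent µM/nM unit errors; dose 0
  if and only if the drug is the vehicle.
* **Timepoint encoding.** Hours after toolkit addition; the plate processed
  24 h after the 4 h read is encoded 28 internally, with aliases `"4h"` and
  `"24h-later"` accepted in layouts.
* **Bead counts.** `beads_added` comes from the bead-lot concentration ×
  5 µL when not given explicitly; there is no default lot concentration —
  it must be supplied, because guessing it would silently scale every
  absolute count.
* **CTG viability.** Treated luminescence as % of the matched dose-0
  control; cytotoxicity is signed (−99.3 means near-complete kill),
  matching the convention of the assay's published figures.
* **Two-way ANOVA.** Fixed effects with interaction over condition × dose;
  per-dose contrasts against the dose-0 cell via estimated marginal means
  with Šídák adjustment by default (`none`/`holm` selectable, stamped in
  the output). The published analysis names only "two-way ANOVA"; the
  post-hoc choice here is a declared default, not a claim about the
  original software. Degenerate all-constant input returns p = 1 rather
  than NaN. A single-condition table degrades to the dose factor alone.
* **QC rule.** A control batch passes when ≥ 2 vials were tested and the
  mean lies in the closed interval mean ± k·SD of the line's reference
  (k = 2 by default; the published account says responses must fall in the
  previously determined range without defining it). Variance decomposition
  into inter- vs intra-batch SD uses one-way random-effects
  method-of-moments, truncating negative between-batch variance to zero.
* **Scores at 4 h.** Dependency scores use the 4 h (profiling plate) deltas;
  whether the published scores ever use the later plate is not stated, and
  4 h is the conservative reading since late events are non-specific.

## Known limitations

* The FCS codec is deliberately minimal: FCS 3.0/3.1, list mode, float
  data, single data set. It round-trips this package's own files and any
  conformant float file, but it is not a general cytometry parser (no
  integer data, no multi-segment files, no spillover keywords).
* Scores depend on the internal-control lines; the package enforces their
  presence on the same run and refuses to score against a non-positive
  control delta rather than silently extrapolating.
* The weighted MCL-1 variant makes that axis independent of the measured
  JJN3 delta; JJN3 still matters for QC and for the ratio variant.
* Synthetic recovery quantifies estimator behaviour under the generator's
  assumptions only; real instrument effects (compensation, drift, doublets)
  are out of scope by design.

## Reproducing the numbers

The `analysis/` scripts run the whole workflow at desk scale (simulate →
gate → quantify → score → dynamic → QC/stats) and write their tables under
`results/`; `scripts/acceptance.R --seed N --out results/acceptance.json`
recomputes the headline recovery quantities from scratch. The testthat suite
asserts every arithmetic identity, tie rule, invariant and recovery
tolerance described above.
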