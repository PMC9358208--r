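---
title: "Methods: neutrophil-subset severity analysis in sICH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neutrophil-subset severity analysis in sICH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichneutro)
```

## The problem

Spontaneous intracerebral hemorrhage (sICH) carries the highest mortality of
the stroke subtypes, driven in large part by neutrophil-mediated secondary
brain injury that manifests radiologically as perihematomal edema (PHE).
This package implements, as tested code, the analysis pipeline of a pilot
cohort study asking whether a "rogue" DEspR+CD11b+ neutrophil subset —
counted by flow cytometry and, in its NET-forming state, by fluorescence
cytology of blood smears — tracks clinical and radiological severity. The
statistical endpoint is a Spearman rank-correlation matrix over a 13-patient
cohort, with Bonferroni correction, power analysis, and composite severity
markers, all recomputable from the packaged per-patient table.

Four computational stages feed the cohort table:

1. **CT volumetry** of the intraparenchymal hemorrhage (IPH) and PHE, by
   rater-style ABC/2 estimation and by a semiautomated dual-clustering
   segmentation.
2. **Smear NET scoring** of NET-forming neutrophils via a nuclear
   circularity index.
3. **Flow gating** of DEspR+CD11b+ neutrophils via scatter gating and
   isotype-anchored quadrant counting.
4. **Severity statistics** on the assembled cohort.

No raw images are published alongside the cohort, so the imaging and flow
stages are validated property-style against seeded synthetic generators
with closed-form ground truth; the statistical stage is validated directly
against the printed per-patient values.

## The cohort

`ich_cohort()` returns the 13-patient table: demographics, ICU course,
admission ICH score, 90-day modified Rankin Scale (mRS), same-day Glasgow
Coma Scale (GCS), IPH/PHE volumes (ml), modified Graeb score (mGS, 0–32),
neutrophil–lymphocyte ratio (NLR), and the DEspR+CD11b+ ("rogue") and
NET-forming neutrophil counts in cells/µl.

```{r}
co <- ich_cohort()
nrow(co)
c(ivh = sum(co$ivh), cmo = sum(co$cmo), survivors = sum(co$survivor))
```

Derived flags are deliberately thin: IVH presence is operationalized as
mGS > 0 because the Graeb score is the only printed IVH indicator; survival
as the absence of a recorded death day. Two printed-table quirks are kept
as-is rather than reconciled: the table footer labels the mean
flow-cytometry day "3.2" while the raw values average 3.23 (the narrative
elsewhere says 3.3), and the narrative's "died on average 1.75 days after
CMO designation" is not derivable from the printed CMO/death days (which
give 1.5). The fixture stores raw days and leaves both narrative numbers
alone.

Counts are stored in cells/µl exactly as printed; the composite analysis
(below) needs them in K/µl, so the conversion is an explicit, exact factor
of 1000 (`counts_to_k()`).

## ABC/2 volumetry

The bedside estimate treats the lesion as an ellipsoid: on the axial slice
with the largest lesion, A is the longest in-slice length and B the
orthogonal width (cm); C is the craniocaudal extent. We implement

$$V = \frac{A \times B \times (n_{\text{slices}} \times t)}{2}\ \text{ml},$$

with slice thickness $t$ configurable (0.5 cm default). The source
formula's "number of slices divided by 2" conflates a count with a length;
since the /2 is explicitly the ellipsoid compensation factor
($ABC/2 \approx \frac{3}{\pi}\cdot\frac{\pi ABC}{6}$), C must be a length,
so the count is multiplied by the thickness.

Slice eligibility follows the stated rule that slices with under 25%
hemorrhage are not counted; the unstated denominator is taken to be the
largest (reference) slice's lesion area, and the threshold is exposed as
`min_fraction`. Two consequences worth knowing:

* On a true ellipsoid the 25% rule truncates C by the factor
  $\sqrt{3}/2 \approx 0.866$ (slice area falls off parabolically), so the
  textbook $3/\pi$ ABC/2-to-truth ratio holds only when C spans the full
  lesion extent. The identity tests therefore measure with
  `min_fraction = 0`; the 25% rule is tested by its own threshold
  arithmetic.
* A slice with no lesion at all is never eligible, regardless of
  `min_fraction`.

PHE by ABC/2 is the edema-outline estimate minus the hematoma volume,
clamped at zero (clamping flagged).

## Dual-clustering segmentation

The semiautomated pipeline retains a voxel when its HU lies in a
compartment window *and* at least a fraction of its neighborhood is also
in-window, then filters connected components by size and mean intensity —
the "dual" in dual-clustering: per-voxel windowing plus neighborhood
consensus, refined by component-level connectivity and intensity checks.

Numerical choices, all exposed in `dual_cluster_params()`:

* Neighborhood: the full 26-neighborhood at radius 1, with
  `neighbor_fraction = 0.5` — chosen for isotropy. Edge voxels are judged
  against the neighbors they actually have.
* Connectivity for components: 26 by default (6 available).
* HU windows are user parameters, not fixed constants; defaults are brain
  soft tissue [0, 80], hemorrhage [45, 90] (acute blood), edema [5, 23]
  (hypodense relative to parenchyma at ~30 HU). The source procedure
  publishes none of its windows, so these defaults are declared choices.
* Brain extraction keeps the single largest soft-tissue component, which
  removes skull and scalp-like structures.
* The edema search region is a ring built by iterated 6-connected binary
  dilation of the hemorrhage (default limit 10 voxels), minus the
  hemorrhage, inside the brain; a final dual-clustering pass with the
  edema window refines it. Edema is disjoint from hemorrhage by
  construction, and all mask invariants (containment in brain,
  disjointness) are asserted on every pipeline output, not assumed.

On noise-free phantoms the segmentation recovers compartment volumes to
within a one-voxel surface shell; at noise sd 3–5 HU, hematoma Dice stays
≥ 0.95 and IPH/PHE volumes within 10% of the analytic truth. These bounds
are what the synthetic phantoms can certify; real CT adds partial-volume
effects, beam hardening and anatomy that no phantom here emulates, so they
say nothing about rater agreement on clinical scans.

## NET scoring by circularity

Nuclei are segmented on the DAPI channel (per-field Otsu threshold by
default, hole filling, 8-connected components, minimum area 20 µm²). The
circularity index is

$$\text{circ} = \frac{4\pi \cdot A_{\text{MEC}}}{P^2},$$

where $A_{\text{MEC}}$ is the area of the minimum circle enclosing the
whole nucleus *including DNA extrusions* and $P$ the traced outline length
of the DNA. A compact nucleus scores 1; extruded DNA lengthens the outline
faster than it grows the enclosing circle and drives the score down.
NET-positive means circ < 0.8; exactly 0.8 is negative.

Implementation details that matter at the 0.8 cutoff:

* The perimeter is a 4-direction Crofton estimator; chain-code perimeters
  overestimate curved outlines by up to ~8%, which would push round nuclei
  below the cutoff.
* The enclosing circle covers the pixel *squares*, not just their centers,
  preserving the invariant that the enclosing-circle area is at least the
  object area. Because of that same invariant, slightly rough disks can
  score just above 1; scores are clamped to 1 and flagged.
* Rasterized disks score 1.0 ± 0.05; a star polygon with closed-form
  perimeter and circumradius reproduces its analytic index within
  rasterization tolerance; the index is scale-invariant to < 0.03 under
  resolution doubling.

The synthetic smear generator draws round nuclei as disks and NET-like
nuclei as disks with sinuous extrusion arms; arm count, radial extent and
tortuosity (arc length relative to extent) control the target circularity.
Four arms of 5 µm extent at tortuosity 1.33 reproduce the "moderate
extrusion" morphology class at a measured index of ≈ 0.6; increasing
tortuosity at fixed extent strictly lowers the index (the enclosing circle
is pinned while the outline grows). Marker positivity is a conjunction:
mean CD11b and mean DEspR over the nucleus pixels must each exceed a
background threshold (mean + 3 sd of a cell-free region by default; the
original assay used isotype controls, which are not quantified in the
source).

Converting a NET+ fraction to cells/µl requires an external anchor
concentration (e.g. the same-day CBC absolute neutrophil count). The
source does not state its conversion, so the anchor is an explicit input
and the conversion is never exercised by the cohort-level statistics.

## Flow quadrant gating

Events carry FSC/SSC scatter and two fluorescence channels. The neutrophil
cloud is gated by a simple polygon in scatter space (boundary inclusive;
self-intersecting polygons rejected). Quadrant thresholds are quantiles
(default 0.999) of the isotype-control distribution, with FMO controls as
the config alternative. Positivity is strictly above threshold — analysis
software conventions differ, so the convention is fixed and documented. Q2
(DEspR+ and CD11b+) identifies the rogue subset; fractions are over gated
events and sum to one by partition. As with the smears, an absolute Q2
concentration requires an explicit anchor.

The synthetic mixture plants three scatter clouds (neutrophils, monocytes,
lymphocytes at 55/10/35%), log-normal fluorescence (background meanlog
log 50, sdlog 0.4; positive meanlog log 500, sdlog 0.3), monocytes
CD11b+ only, and a controlled double-positive fraction among neutrophils.
Under the documented default gate, truth-labeled neutrophil recall exceeds
0.95 and a planted 10% Q2 fraction is recovered within ±0.01 at 50,000
events. Real cytometry adds spillover, drift and doublets that the
generator deliberately omits (channels are generated pre-compensated, as
the original workflow compensated with beads upstream of analysis).

## Severity statistics

**Spearman.** Midranks for ties, then the Pearson correlation of the rank
vectors. This is the convention that reproduces the printed coefficients
on this heavily tied cohort (ICH score, mRS and GCS are small integers);
the $1 - 6\sum d^2/(n^3-n)$ shortcut is equivalent only without ties.

**P-values.** A t approximation on $n-2$ degrees of freedom, or an exact
permutation null (full enumeration to $n = 8$, seeded Monte Carlo above;
the permutation null assumes tie-free ranks).

**Bonferroni.** `min(1, m * p)`. The family size behind each printed
corrected p is not recoverable from the source (different tables imply
different families), so family size is a per-report configuration and
corrected p-values are never treated as reproduction surfaces — only the
correlation coefficients are.

**Power.** The Fisher-z normal approximation
$\Phi(\sqrt{n-3}\,\mathrm{atanh}|\rho| - z_{1-\alpha/2})$, two-sided
$\alpha$, opposite tail ignored. At $\rho = 0.71$, $n = 13$,
$\alpha = 0.05$ this gives 0.801, consistent with the "power > 0.8"
qualifier attached to the reported strong correlations. A strength class
summarizes each pair: *strong* means $|r| > 0.7$, power > 0.8 and
corrected p below alpha; *moderate* means significant but not strong.

**Group comparisons.** Mann–Whitney U from midrank sums; exact two-sided p
by enumeration when $n_1 + n_2 \le 12$ without ties, otherwise the normal
approximation with tie and continuity corrections. Hedge's g uses the
pooled-SD d with either the standard small-sample factor
$J = 1 - 3/(4(n_1+n_2)-9)$ or a fixed-percent factor. The source quotes a
"< 4% correction" for n < 20 while the standard factor at those sizes is
closer to 11%; both modes are provided, `standard_J` is the default, and
neither feeds a reproduction target (the survivor-subgroup membership
behind the published group comparison is not printed).

**Composites.** Per-patient arithmetic sums. Reconciliation against the
printed combinatorial coefficients fixes the scale convention: neutrophil
counts enter in K/µl (cells/µl sums cannot reproduce any of the printed
composite rows; K/µl reproduces all of them to 3 decimals). Columns named
`*_count` are converted automatically; everything else enters raw.

```{r}
severity_table4(co)[, c("x", "r")]
```

**Display rounding** in reports is half-even at the configured precision
(base `round()`).

## Synthetic cohorts

`generate_cohort()` draws from a Gaussian copula: the target matrix is
specified directly on the Spearman scale, converted once to the latent
Pearson scale by the exact relation $\rho_P = 2\sin(\pi\rho_S/6)$, and
pushed through per-column quantile functions. With continuous marginals
the empirical Spearman matrix converges to the target (±0.05 at
n = 2000 in the tests); heavily discretized marginals attenuate rank
correlations through ties, which is exactly the regime the real cohort
lives in — recovery tests therefore use continuous marginals.

All generators are pure functions of their spec, including the seed: they
snapshot and restore the caller's RNG state.

## Problem sizes and scope

Test phantoms are 60×72×72 voxels at 1 mm (≈ 311k voxels), smear fields
240×240 px at 0.5 µm, flow draws up to 50,000 events, copula cohorts up to
n = 2000 — sizes chosen so the full suite certifies every stated tolerance
in well under a minute on a laptop while keeping discretization effects
(voxel shells, rasterization) small relative to those tolerances.

Out of scope by design: DICOM ingestion, registration, learning-based
segmentation, FCS parsing, compensation modeling, plasma-biomarker assay
logic (those values enter only as optional cohort columns), and any
imputation of unprinted measurements (midline shift, the supplementary
correlation matrix).

## Orchestration

`run_report()` is the pipeline entry point for the statistical stage: it
loads a cohort CSV, computes the three published table shapes plus
descriptives, and writes a deterministic JSON bundle with a provenance
block (config hash, seed, package version). Reruns with the same config
are byte-identical. The package's functions are its interface; the JSON
report is the machine-diffable output surface.
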