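---
title: "Modelling calliper measurement error in subcutaneous tumour studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calliper measurement error in subcutaneous tumour studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxcal)
```

# The model

`voxcal` grows tumours as cellular automata on a 3D integer lattice whose
`z = 1` layer rests on the body wall (the subcutaneous base plane). A voxel
is `EMPTY`, belongs to one of two cell populations (`POP_A`, or the
aggressive mutant `POP_B` of the birthday-cake preset), or is `NECROTIC`
(ulcerated tissue: permanently lost, blocking regrowth into its voxel).
One step is one day, and the update applies three rules in a fixed order:

1. **Division.** Every occupied voxel with at least one `EMPTY`
   face-connected (von Neumann) neighbour divides with probability
   `p_divi` per day (`POP_B`: `p_divi * mutant_p_divi_factor`, capped at
   1). The daughter occupies one `EMPTY` face neighbour sampled with
   weight 1 for the four lateral and the downward directions and weight
   `1 + bias` for the upward direction, so `bias = 0` recovers an
   unbiased Eden-type growth and larger values push the tumour up off the
   body wall. Parents are swept in a random permutation; a parent whose
   empty neighbours were taken earlier in the sweep loses its division
   (first-come-wins). This synchronous-sweep order removes spatial
   scan-order artefacts while keeping the trajectory reproducible.
2. **Treatment.** On days `treatment_start <= day <
   treatment_start + lam_len` every tumour cell — including daughters born
   that day — independently dies with probability `lam`. Treatment is a
   death process, not a division brake: whether a cytotoxic parameter
   should act on death, division, or both is not derivable from the
   source material, and death is the simplest mechanism that produces the
   observed volume dip during the window.
3. **Ulceration** (volcano preset only). On `ulceration_day` the
   `floor(crater_fraction * N)` occupied voxels nearest the apex (the top
   of the tallest occupied column, ties resolved towards the footprint
   centroid) become `NECROTIC`, carving a central crater. The crater is a
   single discrete event on an established tumour; re-applying it daily
   would simply erode the tumour away.

Defaults (`sim_params()`): `bias = 1`, `p_divi = 0.1`, `lam = 0.4`,
`lam_len = 10`, `treatment_start = 15`, `total_days = 30`, so treatment
shapes volumes over days 15–25 of a 30-day study — the canonical schedule
of the experiments this package reproduces. The lattice is 100×100×50
voxels at `voxel_edge = 0.2` mm, seeded with radius-3 voxel hemispheres
(~57 cells); a run aborts with a classed boundary error if the tumour
reaches the lateral wall, rather than silently truncating the morphology.
Every simulation owns a private RNG stream seeded from `params$seed`
(restored afterwards), and ensembles use `seed + replicate`, which doubles
as common random numbers: a control (`lam = 0`) and treated arm sharing a
seed are bit-identical until the first treatment day.

The **ground-truth (GT) volume** is the occupied voxel count times the
voxel volume. Necrotic voxels do not count: ulcerated tissue is lost mass.

# The virtual calliper

`simulated_calliper()` projects occupied voxels onto the base plane and
measures the footprint the way an operator applies a calliper: the first
jaw along the tumour's apparent long axis, the second at right angles.
Concretely, length and width are the sides of the **minimum-area bounding
rectangle** of the footprint's voxel corner points, found by a
rotating-calipers style sweep at 1° resolution (finer resolution is
spurious at 0.2 mm voxels); length is the longer side. For an
axis-aligned cuboid footprint this returns the plain x/y extents.

The alternative — taking length as the global maximal Feret diameter —
was rejected deliberately: the maximal Feret of a 10×6 rectangle is its
11.7 diagonal, which no operator would report as "length". Height is the
top face of the highest occupied voxel (`(max z) * voxel_edge`: voxels
are solid cubes); footprint area is the column count times the voxel face
area. No skin-fold thickness is added: the emulation is purely geometric,
the minimal faithful reading of a "simulated calliper".

Three volume conversions are provided:

* spheroid `V = (pi/6) l w^2` — the calliper convention (height assumed
  equal to width);
* cylindrical `V = area * height` — the scanner's footprint extrusion;
* ellipsoid `V = (pi/6) l w h` — the scanner's three-dimension formula,
  chosen as the standard ellipsoid volume because it reduces exactly to
  the spheroid formula at `h = w`.

A geometric fact worth recording: for a half-ellipsoid sitting on the base
plane, `(pi/6) l w h` with the *measured* height `h` equals the
half-ellipsoid volume exactly, so the ellipsoid estimate converges to the
GT voxel volume (ratio 1) as the voxel edge shrinks, while the spheroid
formula overestimates by the factor `w / h`. This is precisely why a
height-aware scan formula tracks excised weight better than callipers,
and the convergence is verified in the test suite at three resolutions.

# Efficacy metrics and the ensemble experiment

`tgi()` implements
`TGI(t) = (1 - V_T(t) V_C(0) / (V_T(0) V_C(t))) * 100%` and
`auc_index()` implements `AUC = (1 - AUC_T / AUC_C) * 100%` with
trapezoidal integration on the shared daily grid from day 0 to the
evaluation day — the trapezoid is the preclinical standard where no rule
is specified. Both are invariant under common rescaling of the two
curves, which the suite checks property-style.

`run_ensemble()` pairs replicate *i*'s control with replicate *i*'s
treated arm under shared seeds (default), isolating measurement error
from biological variability: with `lam = 0` the paired design yields an
exact TGI ≡ 0 null under GT. Because "every pair of control and treated
curves" can also be read literally, a `pairing = "cross"` mode evaluates
all control × treated combinations; the paired mode is the documented
default. Evaluation days default to 18, 24 and 30. Replicates aborting on
the lattice boundary are skipped and counted, with a warning above 5%.

`compare_distributions()` summarises GT-vs-SC index distributions with
means, SDs and a histogram overlap coefficient (50 shared equal-width
bins over the pooled range, sum of bin-wise minimum relative frequencies;
degenerate zero-range input is a shared point mass, overlap 1).
`sensitivity_scan()` varies one parameter at a time and reports the mean
SC−GT volume bias at day 30 and TGI(GT)−TGI(SC) bias at day 24 with
Monte-Carlo standard errors.

# Repeatability statistics

* **CV** is `sd/mean` with the sample (n−1) denominator — with 2–4
  operators per tumour-day the population form would be badly biased —
  returning `NA` ("null") below two values or at non-positive mean.
  Duplicate same-operator readings are averaged first: the unit of
  repeatability is the operator, not the press of the calliper.
* **ICC** is ICC(2,1): two-way random effects, absolute agreement, single
  measurement, with the McGraw–Wong F-based confidence interval. The
  implementation was cross-checked against an independent reference
  implementation and the oracle values frozen into the tests. Groups are
  stratified by the number of distinct operators; since different tumours
  are measured by different people, the rater columns are operator
  *slots* filled in operator-id order within each group. A different ICC
  variant would shift estimates slightly; the variant is therefore an
  explicit function (`icc_a1()`) rather than buried in a pipeline.
* **Bland–Altman** converts excised weight to an equivalent volume at a
  configurable tissue density (default 1 g/cm³ within the soft-tissue
  range 0.90–1.09) and fits difference against mean by OLS; the slope
  measures proportional bias. `relative_error_banding()` reports the
  canonical proportions (volume > weight; |error| < 20%, < 50%; weight at
  least half the volume equivalent).
* **Consistency** pairs each scan with the same-mouse same-day calliper
  mean and counts agreement within ±3 mm (and beyond 8 mm), with 1-mm
  binned histograms by strain.
* **Welch one-sided t-tests** take the direction as a parameter (the
  systematic direction observed in practice is scan < calliper) and
  adjust with Holm — valid without independence assumptions, since the
  adjustment method is otherwise unspecified. Zero-variance ties are
  assigned p = 1 and flagged rather than erroring.

Records flagged `excluded` (misaligned or failed scans) are dropped
before every statistic.

# The synthetic-record generator

`generate_records()` emulates a multi-operator calliper study with fully
known latent structure: per-mouse baseline volumes are log-normal
(default median 500 mm³, sdlog 0.5 — a typical mid-study xenograft
spread), growing exponentially at 0.1/day; length/width derive from the
volume spheroid-consistently with a drawn aspect ratio (median 1.25);
height is 0.7 × width (subcutaneous tumours are flatter than wide). Each
operator applies a multiplicative per-operator bias factor and
multiplicative log-normal noise *per linear dimension* (default CV 0.1) —
noise lives on dimensions, not volumes, because callipers err on lengths
and the volume error structure then follows from the spheroid formula,
which is exactly the propagation under study. Weight is exact
(`true volume × density`), so downstream volume–weight discrepancies are
attributable entirely to the measurement model.

What a green test does and does not establish: the generator reproduces
the *structure* of real studies (operators, days, instruments, missing
and excluded records) but not their biology — no strain effects on
measurement difficulty, no locally invasive models that are genuinely
harder to measure, no operator learning over time, and its noise is
homoscedastic on the log scale. Parameter-recovery tests therefore
validate the estimators, not any claim about real calliper data.

Two analytic facts anchor the recovery tests. First, the delta method on
`V ∝ l w²` with independent dimension noise of CV 0.1 gives a volume CV
of `sqrt(5) × 0.1 ≈ 0.224`. Second, a sample CV from k = 2 readings is
`σ/μ · |Z|` with `Z` standard normal, so the *median* per-tumour CV is
`qnorm(0.75) × sqrt(5) × 0.1 ≈ 0.151`: the finite-sample factor is part
of the oracle, written down before measuring, not a tolerance adjusted
afterwards. The analytic ICC for the generator's log-normal components is
likewise available in closed form and is required to fall inside the
estimate's confidence interval at 500 mice.

# Numerical choices and degenerate inputs

* Probabilities are validated jointly; configuration errors list every
  violated field at once and carry classed conditions
  (`vc_config_error`, `vc_data_error`, `vc_boundary_error`, ...), which
  the CLI maps to exit codes 2/3/4.
* An empty lattice measures as an error from `simulated_calliper()` but
  as volume 0 with an `empty` flag inside growth curves: a fully
  regressed tumour is a data point, not a failure.
* `floor()` semantics make a single-voxel tumour immune to 50%
  ulceration; ties in the crater ordering break on voxel index for
  reproducibility.
* Misordered calliper inputs (`length < width`) are swapped with a
  warning rather than rejected; negative dimensions are errors.
* TGI is undefined (classed error) at `V_T(0) = 0` or `V_C(t) = 0`; the
  AUC index at `AUC_C = 0`.

# Known limitations

The automaton has no nutrient field, angiogenesis, mechanics or local
invasion — morphology comes from seeding and rule presets, not emergent
physiology. Exact update rules and parameter values of the original
supplementary material were unavailable when this package was designed;
the neighbourhood (von Neumann), bias mechanism (upward weight `1+bias`),
conflict resolution and treatment-after-division order are this package's
own documented choices, and the simulation experiments should be read as
reproducing the *qualitative* claims (overestimation, variance inflation,
attenuated and noisier TGI under calliper measurement), which the
acceptance tests check at 100–200 replicates per morphology. Replication
of published numeric dataset statistics requires the original
supplementary CSVs, which cannot be shipped here; the readers and schema
maps are in place for users who obtain them.
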