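---
title: "Quantifying EEC cytoplasmic and mitochondrial calcium dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EEC cytoplasmic and mitochondrial calcium dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eecdynamics)
```

## The measurement problem

Enteroendocrine cells (EECs) are sparse sensory cells of the intestinal
epithelium. In dual-indicator imaging, channel 1 reports cytoplasmic Ca²⁺
(GCaMP6f) and channel 2 mitochondrial-matrix Ca²⁺ (mitoRGECO), recorded as
3D stacks every 10 s in a living, moving animal. The quantities of interest
are per-cell: absolute and t0-normalized intensity traces, the
mito-to-cyto ratio, spontaneous-activity and stimulus-responder calls,
response amplitudes and the sustained mitochondrial elevation, the
intracellular base-to-apex mitochondrial distribution, and cohort summaries
with standard group tests. This vignette explains the models, parameters and
numerical choices behind each stage, and what the synthetic ground truth
does and does not establish.

## The synthetic scene and trace model

`simulation_config()` fixes the study conditions. Cells are axis-aligned
prolate ellipsoids (equatorial radius `cell_radius` = 3.5 µm, long axis
1.5× along y, volume ≈ 270 µm³ — inside the 100–1000 µm³ analysis window),
placed by rejection sampling with pairwise centre distance ≥ 2.5 radii so
cells never touch, in a voxel grid of `shape` (default 32 × 96 × 192 voxels
at 1 × 0.5 × 0.5 µm). The basal pole is the −y end of each cell, so
base–apex orientation is known to ground truth; in the animal this
orientation is anatomical and must be annotated, which is why
`axis_profile()` takes the axis as an input and `estimate_axis()` is only a
labelled heuristic.

Traces are built from a baseline of 1 (arbitrary units):

* **Spontaneous activity.** A cell drawn active (probability
  `active_fraction`, default 0.21 — the colonized-condition scale) receives
  Poisson events (`spontaneous_event_rate` = 0.05/frame) of amplitude
  `spontaneous_amplitude` = 0.4 decaying with τ = 20 s. The ground-truth
  `is_active` flag is set only when at least one event realized: a cell with
  no events has a flat trace, and no classifier could (or should) call it
  active.
* **Stimulus response.** Responders (probability `responder_fraction`) add
  an instant rise of `cyto_peak_amplitude` = 0.8 at `stimulus_frame`,
  returning exponentially with `cyto_decay_tau` = 30 s — after five decay
  constants the trace is back at baseline to within 1%.
* **Mitochondrial coupling.** With `mito_coupling` on, a responder's
  mitochondrial trace rises after `mito_delay` = 10 s, linearly over
  `mito_rise_time` = 30 s, to a plateau of `1 + mito_sustained_level`
  (default 1.4) held to the end of the recording. The piecewise-linear ramp
  was chosen over an exponential so the plateau is reached *exactly*,
  giving closed-form targets for the sustained-elevation metric. With
  coupling off — the germ-free-like phenotype — mitochondrial traces stay
  flat.
* **Heterogeneity.** One lognormal factor per cell (CV `amplitude_cv` = 0.3,
  mean 1) scales both the cytoplasmic peak and the mitochondrial plateau,
  which is what makes the two amplitudes positively correlated across cells
  when coupling is on, and uncorrelated when it is off. Setting
  `amplitude_cv = 0` recovers identical, exactly analytic cells.

Rendering assigns each cell voxel the trace value itself (indicator
fluorescence dominates autofluorescence; `background` = 0.1 applies outside
cells). Channel 2 is spatially weighted: `even` cells are uniform;
`basal_hotspot` cells mix 25% uniform with 75% of mass in a Gaussian
(σ = 0.12 cell lengths) at the basal pole, normalized to mean 1 inside the
cell — so per-cell channel means are mode-independent, and at least half the
channel-2 mass falls in the basal quarter. Noise is Poisson shot noise
(`poisson_scale` = 200 photons per intensity unit) plus Gaussian read noise
(`noise_sd` = 0.05); rigid scene drift is a random-direction walk of
`drift_per_frame` = 0.5 µm; track loss hides a cell (intensity to
background) from a geometric random frame onward
(`track_loss_rate` = 0.01/frame).

What the generator does **not** emulate: optical point-spread blur, spectral
bleed-through, photobleaching, deformable tissue motion, cell–cell contact,
and intensity non-uniformity in the cytoplasmic channel. Passing the
recovery suite therefore shows the algorithms are correct under the stated
noise and geometry, not that they are robust to every property of real
recordings — in particular, real segmentation quality depends on indicator
expression levels the generator idealizes.

## Segmentation

`segment_frame()` applies, in order: Gaussian smoothing with physical sigma
0.85 µm (converted per axis, so anisotropic voxels are handled); an
intensity threshold — Otsu's inter-class-variance maximum on a 256-bin
histogram of the smoothed frame by default, or an absolute value, with an
optional mode that reuses the frame-0 threshold across the recording;
removal of connected components (6-connectivity) whose equivalent spherical
diameter is below 1 µm; marker-based watershed separation; and removal of
components with volume outside 100–1000 µm³. The "< 1 µm" rule is read as
equivalent spherical **diameter** — a volume reading would be subsumed by
the 100 µm³ floor, and the two size rules are evidently distinct.

The watershed separates touching components using peaks of the anisotropic
Euclidean distance transform as seeds, with minimum peak separation
0.22 µm. Two numerical choices matter. First, seeds are located on a
distance map smoothed at half the minimum object diameter: the raw discrete
distance transform of a voxelized blob carries spurious local maxima a
voxel or two apart, and since 0.22 µm is below the voxel size, every such
artefact would otherwise seed a split. Sub-resolution peaks cannot be real
seeds, so suppressing them below the resolvable object scale is principled,
and genuinely touching cells still present two resolvable peaks. Second,
watershed flooding uses a priority queue ordered by distance value with
first-in-first-out tie-breaking, making label assignment deterministic.
Whether the original vendor operation acts on eroded seeds or surface
distance is not recoverable; the separation distance is an exposed
parameter.

The no-touching case reduces exactly to connected components plus the two
size filters, which is verified against a brute-force flood-fill oracle.

## Tracking

`link_objects()` performs per-frame-pair optimal assignment on centroid
distance (an exact Hungarian solver on a padded square matrix), gated at
`max_displacement` (default 10 µm ≈ two cell diameters' worth of movement;
the source analysis names no value). Forbidden links carry a prohibitive
cost, so the solver returns the cheapest assignment among those of maximal
size — verified against exhaustive enumeration on up to 5 × 5 toys.
Unmatched objects open new tracks; unmatched tracks end. Gap closing is off
by default (lost tracks are accepted as a fact of gut motility) and can be
enabled for 1-frame gaps. Tracks never interpolate: frames without an
observation stay absent through `extract_traces()`.

## Trace metrics

Every per-cell series (cyto, mito, ratio = mito/cyto) is normalized to its
frame-0 value; cells without a positive frame-0 observation cannot be
normalized and are excluded with their ids reported. Downstream rules, with
the reasoning where the source leaves the rule open:

* **Active vs quiet** — normalized cyto > 1.2 for ≥ 2 *consecutive* frames.
  The original call is graphical; 0.2 matches the scale of low-amplitude
  spontaneous firing and two consecutive frames (20 s) rejects single-frame
  noise. Both knobs are exposed.
* **Stimulus responders** — maximum post-stimulus normalized cyto − 1 ≥
  0.25 (exposed default).
* **Sustained elevation** — mean normalized mito over the final quartile of
  post-stimulus frames, − 1. The elevation persists to the end of recording
  in the source data without a defined window; the final quartile reads the
  plateau once the ramp (≈ 40 s) has long finished. Undefined (and flagged)
  with fewer than 4 post-stimulus frames.
* **ATP responders** — sensor/reference ratio increase strictly greater
  than 15% between paired t0 and end measurements.
* **Clustering** — correlation distance with average linkage, verified
  against naive agglomeration on 6 traces.
* **Group tests** — two-sided Student's t (pooled variance unpaired, or
  paired), one-way ANOVA + Tukey for > 2 groups; p-values are reported raw,
  with no multiple-testing correction, matching the source reporting.
  Zero-variance comparisons are flagged degenerate (t = 0, p = 1 at equal
  means) instead of erroring.

A caveat stated rather than hidden: a spontaneously firing cell whose event
lands after the stimulus is indistinguishable from a responder by the
amplitude rule; responder-recovery checks therefore use quiescent
non-responders, and real-data responder percentages inherit this confound.

## Mitochondrial distribution

`axis_profile()` projects channel-2 intensity inside a cell mask onto the
base-to-apex axis, bins positions into 20 equal-length bins spanning the
mask's extent, and normalizes to sum 1 (machine-exact up to 1e-9 in the
tests; axis reversal exactly reverses the profile). `classify_distribution()`
calls a profile a hotspot when its maximum bin exceeds 2× the mean bin —
a uniform intensity in an ellipsoid projects to at most 1.5× the mean, so
the factor 2 cleanly separates geometric tapering from genuine
concentration — and a basal hotspot when that peak lies in the basal quarter
of bins. Both knobs are exposed; the original classification was visual, so
concordance with human calls cannot be verified, only the generator-mode
recovery (≥ 0.9 sensitivity and specificity at default noise).

## Transcriptomic quadrant statistics

`quadrant_fractions()` screens genes on the microbial contrast (adjusted
p < 0.05 — the source states "P < 0.05" without specifying adjustment; both
modes are supported and adjusted is the default) and reports, among
significantly CV-upregulated genes, the share with positive EEC-vs-IEC fold
change. EEC enrichment deliberately carries no significance requirement on
its own axis by default (`strict = TRUE` adds one). `generate_de_table()`
constructs tables with *exact* quadrant counts (sign assignment on the
significant stratum) and tunes the overall fold-change correlation by
root-finding the latent correlation of the remaining genes against the
empirical Pearson r — deterministic given the seed, accurate to well within
±0.05.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages from one YAML/list configuration,
echoes every threshold into `summary.json` for provenance, derives each
stage's seed deterministically from the global seed, and reproduces all
tables byte-identically on re-run. Stage failures abort with the stage name.

Simulation sizes used throughout the test suite were chosen to exercise
every code path at comfortable margins: the segmentation benchmark is 60
cells in a 32 × 128 × 256 voxel scene over 12 frames with default noise and
0.5 µm/frame drift; recovery studies use 10–20 cohorts of 60 cells at the
trace level (where the voxel render adds nothing but photometric noise,
which `observe_traces()` models directly); voxel-level checks use 2–40
cells. The trace-level shortcut is itself validated against the full render
by the photometry tests (channel sums against analytic traces, r > 0.999;
extracted normalized traces within 1% noise-free).

## Known limitations

* The active/quiet and responder thresholds are declared defaults, not
  inferred intent; cohort percentages shift with them.
* Mitochondrial and ATP dynamics are phenomenological (ramp to plateau),
  not a biophysical uptake model; only their summary statistics are meant
  to be faithful.
* Segmentation assumes cells are brighter than their surroundings in
  channel 1 everywhere; dim or touching cells in real tissue will need the
  absolute-threshold mode or curated parameters.
* The ratio trace divides two noisy means; at low cytoplasmic intensity it
  inflates, which is why ratio-based metrics are only computed where the
  cytoplasmic mean is positive and cells failing normalization are dropped
  loudly.
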