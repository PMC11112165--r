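# eecdynamics

Quantitative analysis of enteroendocrine cell (EEC) calcium dynamics in 4D
(3D + time) two-channel fluorescence microscopy, built for the larval
zebrafish intestine.

EECs are rare intestinal sensory cells (< 1% of the epithelium) that detect
luminal nutrients and secrete hormones. In vivo they can be imaged with a
cytoplasmic Ca²⁺ indicator (GCaMP6f, channel 1) and a mitochondrially
targeted Ca²⁺ indicator (mitoRGECO, channel 2), giving per-cell readouts of
cytoplasmic activity, mitochondrial activity, and the mito-to-cyto Ca²⁺
ratio. This package implements the full quantification chain for such
recordings, plus a ground-truthed synthetic data generator so every stage is
testable without microscope data:

- **Simulation** — `simulation_config()`, `generate_cell_traces()`,
  `generate_timelapse()`: prolate-ellipsoid cells in an epithelium-like
  volume; cytoplasmic traces with baseline 1, spontaneous transients
  (amplitude *a*, decay τ) and stimulus transients
  *F(t) = 1 + A·exp(−(t−t_s)/τ_c)*; mitochondrial traces that ramp after a
  delay to a sustained plateau *1 + L*; basal-hotspot or even mitochondrial
  spatial modes; Gaussian + Poisson noise, rigid drift, and track loss.
- **Segmentation** — `segment_frame()`: Gaussian smoothing (0.85 µm),
  automatic (Otsu) or absolute thresholding, removal of objects with
  equivalent spherical diameter < 1 µm, watershed separation
  (0.22 µm peak separation), and a 100–1000 µm³ volume window;
  `measure_objects()` reports per-object volume, centroid and dual-channel
  means.
- **Tracking** — `link_objects()`: optimal frame-to-frame assignment
  (Hungarian algorithm) on centroid distance with a displacement gate;
  `filter_tracks()` for length/completeness filtering.
- **Trace metrics** — `extract_traces()`, `normalize_traces()` (everything
  normalized to its t0 value), `classify_spontaneous()` (active vs quiet
  cells), `detect_stimulus_responders()` and `response_metrics()`
  (amplitudes, sustained mitochondrial elevation, post-peak ratio change),
  `classify_atp_responders()` (strict > 15% sensor/reference increase),
  `amplitude_correlation()`, `cluster_traces()` (correlation distance,
  average linkage), `compare_groups()` / `compare_groups_anova()`.
- **Mitochondrial distribution** — `axis_profile()` (base-to-apex binned
  intensity profile), `classify_distribution()` (even vs hotspot vs basal
  hotspot), `cohort_summary()`.
- **Transcriptomics** — `load_gene_table()`, `quadrant_fractions()`,
  `signature_upregulation()`, `de_axis_correlation()` for dual-contrast
  differential-expression tables (microbial status × cell fate), and
  `generate_de_table()` to simulate them with exact quadrant composition.
- **Pipeline** — `run_pipeline()` chains everything from one YAML/list
  config with a seeded, byte-reproducible run directory; a thin CLI lives at
  `inst/exec/eecpipe`.

All user-facing functions take and return tibbles where the data are
tabular, so stages chain with the pipe; result objects have `tidy()` /
`glance()` methods and `plot_*()` / `autoplot()` helpers.

## Worked example

Simulate a colonized-phenotype cohort (60 cells, nutrient stimulus at frame
10, 10 s frame interval), measure traces, and summarize:

```r
library(eecdynamics)

cfg   <- preset_cv(n_cells = 60, seed = 1)       # stimulus @ frame 10
truth <- generate_cell_traces(cfg)
obs   <- observe_traces(truth, cfg)              # photometric noise added

glance(classify_spontaneous(obs, frames = 0:9))  # resting window
#>   n_cells n_active percent_active
#> 1      60        1           1.67

rec <- response_metrics(obs, cfg$stimulus_frame)
glance(rec)
#>   n_cells n_responders percent_responders mean_cyto_amplitude ...
#> 1      60           30                 50               0.771

amplitude_correlation(rec)
#>       r  p_value     n
#> 1 0.871 3.97e-10    30
```

Half the cells respond to the stimulus (the preset's responder fraction),
their mean cytoplasmic amplitude is ~0.77 (relative to baseline 1), and
cytoplasmic and mitochondrial amplitudes are strongly coupled across
responders (r = 0.87) — the signature of intact mitochondrial Ca²⁺ uptake.
With `preset_gf()` (no mitochondrial coupling) the same pipeline yields flat
mitochondrial amplitudes and no correlation.

The voxel-level route is the same shape:

```r
sim    <- generate_timelapse(benchmark_config(seed = 1))
obj    <- segment_timelapse(sim$timelapse)
tracks <- link_objects(obj, max_displacement = 10)
traces <- normalize_traces(extract_traces(tracks, obj))
plot_traces(traces)
```

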