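# livingarray

Single-cell transcriptional dynamics from living-microarray time-lapse
imaging.

Reverse-transfection microarrays print hundreds of plasmid spots on one
slide; cells plated on top take up the construct printed beneath them, and
automated microscopy images every transfected cluster every 20 minutes in
two channels — an inducible, destabilized, nuclear-localized **Venus**
reporter and a constitutive **ECFP** control carried on the same plasmid.
Because both fluorophores share the plasmid, the per-cell ratio
`r(t) = Venus(t) / ECFP(t)` cancels transfection-efficiency differences,
and fold induction is `r(t)` relative to the cell's own pre-induction
baseline. This package implements the full computational pipeline behind
such measurements, for microscopists and computational biologists running
or reanalyzing living-microarray screens:

- **Registration** — printed-spot detection on slide overviews (disk
  convolution + watershed, intensity-weighted sub-pixel centroids),
  single-coefficient pincushion distortion correction `r' = r(1 + k r²)`,
  and affine mapping to stage coordinates from three corner anchors.
- **Focus** — cubic focus-surface interpolation
  `z(x,y) = Σᵢⱼ aᵢⱼ xⁱ yʲ` (i,j = 0..3) fitted to 45 manually focused
  positions with RANSAC outlier rejection; Vollath-F4 autocorrelation
  focus scoring; per-pass global offset as the median of four feature
  drifts.
- **Segmentation** — ideal Fourier low-pass preconditioning (binary disk,
  diameter 69), watershed with an 8-connected neighbourhood, background
  rejection at the first histogram peak + 2000 counts, a 125 px² minimum
  area, and field-level background subtraction (mean of the dimmest 10%
  of cells).
- **Tracking** — strict linking of consecutive frames (centroid distance
  < 10 px and rotation-minimized mean-squared patch difference ≤ 0.0155),
  then flexible gap closing over up to five frames using the stability of
  the constitutive ECFP signal (3-SD pool rule).
- **Analysis** — ECFP-normalized induction profiles, responder calling at
  mean + 3 SD of the initial population, fold-change distributions
  (<3, 3–50, >50), responder CVs, per-spot curves, replicate subsampling,
  and QC error rates.
- **Simulation** — a generator of dual-channel nuclei movies, spot-grid
  overviews and noisy focus samples with complete ground truth (masks,
  correspondences, per-cell induction parameters), which powers the whole
  validation suite.

## Worked example

A small synthetic field, end to end (about half a minute):

```r
library(livingarray)

cfg <- pipeline_config(
  n_fields   = 1L,
  simulation = simulation_config(field_size_px = c(256L, 256L),
                                 n_cells = 20L, n_frames = 36L,
                                 rng_seed = 1L),
  segmentation = segmentation_params(lowpass_diameter_px = 35),
  seed = 1L)
summary <- run_pipeline(cfg)

summary$per_field$mean_cells_per_frame  # 20    -- every nucleus found, every frame
summary$n_tracks                        # 20    -- one track per true cell
summary$qc_error_rate_pct               # 0     -- no segmentation/tracking errors vs truth
summary$responder_fraction              # 0.526 -- half the cells induce (configured 0.5)
summary$median_peak_fold                # 3.14
summary$fold_distribution
#>      bin count fraction_pct
#> 1     <3     9         47.4
#> 2 [3,50]     7         36.8
#> 3    >50     3         15.8
```

Every nucleus is segmented in all 36 frames and linked into exactly one
track; the fold-change bins recover the configured heavy-tailed mixture
(at 20 cells the fractions carry binomial noise; the full-size validation
uses 3 × 85 cells). The filter diameter scales with the frame: 69 for the
default 512-px field, 35 here.

Lower-level entry points (`simulate_field`, `segment_frame`,
`track_field`, `fit_focus_surface`, `detect_spots`, ...) are documented
individually, and `exec/livingarray` exposes the stages as shell
subcommands (`simulate`, `register`, `focusfit`, `segment`, `track`,
`run`).

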