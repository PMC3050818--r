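---
title: "Quantifying single-cell transcriptional induction on living microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell transcriptional induction on living microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livingarray)
```

## The measurement problem

A living microarray couples reverse transfection with automated time-lapse
microscopy: hundreds of printed spots on one slide each transfect a cluster
of adherent cells with a dual-reporter plasmid, and every cluster is imaged
repeatedly (here, every 20 minutes over 24 hours) in two channels. The
inducible promoter drives a fast-maturing, destabilized, nuclear-localized
Venus; a constitutive cassette on the same plasmid drives ECFP. Because
both fluorophores ride on the same plasmid, the ECFP signal is a per-cell
proxy for plasmid copy number, and the ratio

$$ r_c(t) = \frac{\mathrm{Venus}_c(t)}{\mathrm{ECFP}_c(t)} $$

cancels transfection-efficiency differences between cells. Fold induction
for cell $c$ is $r_c(t)$ relative to the mean of $r_c$ over the cell's
first few pre-induction frames. The computational task is everything
between the raw TIFF stacks and those per-cell induction statistics:
locating the printed spots, keeping the slide in focus over hundreds of
positions, segmenting nuclei in every frame, linking them through time,
and summarizing the resulting tracks.

## Geometry: spot registration and the focus surface

Printed spots are found on a slide overview image by convolving with a
unit-sum disk kernel the size of one spot, computing the watershed
transform of the convolved image (each intensity peak floods one basin),
rejecting background basins with the same histogram rule used for nuclei
(below), and reporting the intensity-weighted centroid of each accepted
basin core, which is sub-pixel accurate. Pincushion lens distortion is
modelled as a single-coefficient radial polynomial $r' = r(1 + k r^2)$
about the image center, with $r$ normalized by half the smaller image
dimension; the coefficient is accepted as configuration, never estimated
from imagery. Images are corrected by forward-map resampling with bilinear
interpolation, and point coordinates are undistorted by Newton inversion
of the cubic. Detected centers map to stage coordinates through the unique
affine transform fixed by three anchor spots at the array corners; two
invariant slide-edge features are stored as slide-relative offsets so a
re-mounted slide reuses the mapping.

Best-focus height varies smoothly across a mounted slide, so the platform
interpolates focus for all spots from 45 manually focused positions using
a full third-degree polynomial surface

$$ z(x, y) = \sum_{i=0}^{3}\sum_{j=0}^{3} a_{ij}\, x^i y^j , $$

with $x, y$ rescaled to $[-1, 1]$ over their observed range before fitting
(the degree-3 cross terms are badly conditioned on raw stage microns; the
rescaling is recorded with the fit). Manual focusing occasionally locks
onto debris, so the fit is wrapped in RANSAC: 16-point minimum samples
(16 coefficients), 2000 iterations. Two details matter with 16 parameters
against 45 points. First, the inlier threshold cannot come from a pilot
full fit — the cubic is flexible enough to absorb gross outliers, which
inflates any pilot-based scale until nothing is rejected; the scale is
instead taken from the least-median-of-squares candidate (with the
standard small-sample correction), and candidates are then re-scored by
inlier count at that threshold, which prefers models supported across the
whole design over ones that bend to absorb a high-leverage corner
outlier. Second, the consensus set is refined iteratively (refit,
re-estimate the robust scale with a $\sqrt{n/(n-16)}$ degrees-of-freedom
correction, re-select; the threshold may grow but never shrinks below the
initial estimate) until stable. On 45 points with 5 gross outliers and
0.2 um noise this removes every planted outlier and matches the
least-squares fit on the clean points.

Per acquisition pass, focus drift is measured on four invariant features
with an autocorrelation sharpness score (Vollath's F4,
$\sum I(x,y)I(x+1,y) - \sum I(x,y)I(x+2,y)$ on the mean-subtracted image;
the mean subtraction makes a featureless image score exactly zero), and
the global offset applied to all spots is the median of the four drifts —
the mean of the two middle values, which shrugs off one arbitrarily
corrupted feature.

## Segmentation

Watershed segmentation applied to raw fluorescence images over-segments:
camera noise and intranuclear texture each seed spurious basins. Frames
are therefore preconditioned with an ideal low-pass filter — forward FFT,
multiplication by a centered binary disk of diameter 69 (frequency-index
units, matched to a 512-px frame), inverse FFT. The binary mask makes the
filter exactly idempotent and mean-preserving. After filtering, each
nucleus carries a single regional maximum and the watershed transform
(8-connected, with a small peak-merging tolerance for residual ripple)
yields one basin per nucleus plus background basins.

Basins are screened by two rules. The intensity rule anchors to the image
histogram: the background mode is the first substantial peak of the
smoothed histogram (bin width 16 counts, 5-bin moving average, with a
prominence requirement so that the ringing undershoot of the ideal filter
cannot masquerade as the background mode), and a segment must exceed that
mode by 2000 counts. The area rule discards segments below 125 px^2
(80 um^2 at 0.8 um pixels). The reported segment is the basin's bright
core: pixels above `background + 0.35 * (peak - background)`. The 0.35
fraction is half-maximum contouring restated for this filter: the ideal
disk passes only part of a nucleus-sized object's spectrum, attenuating
its filtered peak by roughly 30% relative to the interior amplitude, so
contouring at 0.35 of the attenuated peak sits near half the interior
amplitude — the level that recovers a step edge under any symmetric blur —
independently of cell brightness. Centroids are intensity-weighted over
the core, which tracks a textured nucleus rigidly at sub-pixel scale.

Fluorescence is quantified on the *raw* images: a cell's total is the sum
of raw pixels inside its segment, per channel. The field background is the
mean total of the dimmest 10% of cells (count `ceiling(0.1 N)`, at least
one; ties broken by label order) and is subtracted from every cell;
negative results are clamped to zero and flagged. In the pipeline,
segmentation runs on the ECFP channel — the constitutive signal is present
in every transfected cell regardless of induction state — and both
channels are quantified over the resulting masks.

## Tracking

Tracking is two-phase. Strict linking joins cells in consecutive frames
that are within 10 px (8 um) and look alike. The appearance score is the
mean squared difference between the two cells' normalized appearance
patches, minimized over relative rotation. Patches are square windows of
side equal to the segment's equivalent diameter plus 4 px, sampled
bilinearly at the exact sub-pixel centroid and resampled to 32x32
(the window side is kept real-valued: an integer side would step
discretely as the measured area fluctuates, mis-scaling patches of the
same cell between frames), min-max normalized to $[0,1]$ over the nucleus
mask, zero outside. Rotation uses a 0-350 degree grid in 10-degree steps
via precomputed bilinear resampling maps (angle 0 is an exact identity;
pixels whose rotated source falls outside the window are excluded from
the average rather than zero-filled), and the difference is averaged over
the union of the two masks so shape mismatch is penalized. Links require
a score at or below 0.0155. A cell whose best and second-best candidates
score within 20% of each other is considered ambiguous and left unlinked;
remaining conflicts are resolved greedily in order of increasing score,
yielding a partial one-to-one matching.

Flexible linking closes gaps. For each frame separation $g = 1..5$ in
turn, candidate joins pair a fragment end with a fragment start exactly
$g$ frames later within $g \times 10$ px. The identity cue is the
constitutive ECFP intensity: the absolute ECFP differences of all
candidates are pooled slide-wide, candidates more than 3 SDs from the
pool mean are discarded, and surviving joins are accepted greedily in
order of increasing difference, each end and start used once. Joined
tracks carry the number of skipped frames ($g-1$) as a gap annotation.
ECFP is the right cue because it is induction-independent; Venus can
change several-fold across a short occlusion.

Fields share no state, so they can be processed in any order — or in
parallel — with identical results.

## Induction statistics

Profiles divide Venus by ECFP per frame (frames with clamped-zero ECFP
are excluded and flagged), and fold change divides by the mean ratio over
the track's first three frames (the first hour at 20-minute passes;
induction delays in the generator start at 60 minutes, so this window is
pre-induction by construction). Responders are called against a threshold
of mean + 3 SD of the signal across cells at the initial frame, exceeded
either at any later frame (maximally sensitive; the default) or at the
final frame only. Under sustained induction the final-frame mode is the
accurate estimator of the responder fraction: with ~70 later frames,
any-frame calling lets per-frame noise cross the threshold eventually and
inflates the called fraction, while final-frame calling misses only the
rare responder whose fold is within noise of 1. Fold-change distributions
are binned below 3, 3-50, and above 50-fold, with percentages reported to
one decimal. Coefficients of variation summarize the peak normalized fold
across responding cells. All spreads use the population-SD convention
(divide by $N$).

The replicate-subsampling analysis asks how many replicate spots suffice:
for each subset size $n$ (1-20), 1000 subsets of the per-spot values are
drawn without replacement, and a size is adequate when the mean absolute
deviation between subset SD and population SD is at most half the
population SD. The subset-mean SD tracks $\sigma/\sqrt{n}$ (times the
finite-population correction, since sampling is without replacement from
75 spots).

## The synthetic-data generator

Every stage is validated against a generator that emulates the platform's
acquisition regime with complete ground truth: per-frame label masks, true
correspondences, and per-cell parameters. Defaults describe one field:
512x512 16-bit frames at 0.8 um/px, 85 nuclei, 72 frames at 20-minute
intervals. The cell model is a mixture: plasmid copy number is lognormal
(log-SD 0.4; the median cell's ECFP interior is ~10,000 counts above a
1000-count camera offset, comfortably clearing the histogram + 2000 rule
while keeping the dim tail realistic); half the cells respond, and
responders draw a lognormal induction fold whose two parameters are
solved in closed form from two tail targets of the overall mixture —
55.7% of cells below 3-fold and 8.3% above 50-fold — giving a median
responder fold of ~14. The calibration is fixed at that reference
mixture regardless of the responder fraction actually simulated.
Induction follows a logistic ramp from baseline to fold x baseline,
with a uniform 60-300 minute delay and a 240-minute rise; the ramp is
parameterized so it covers 2-98% of its span across the rise window.

Nuclei are ellipses (equivalent radius ~7 px, area ~154 px^2, straddling
the 125 px^2 cutoff from above; axis ratio uniform on 1-1.5) with a fixed
per-cell speckle texture — a standardized sum of Gaussian bumps evaluated
analytically in the cell's own frame, so texture persistence under
rotation is exact rather than an interpolation artifact. Edges roll off
smoothly over ~0.7 px (the half-intensity contour is the true ellipse):
real nuclei are diffraction-blurred, and razor-sharp synthetic edges
would alias against the sub-pixel patch sampling in a way real images do
not. Cells move by a reflected random walk (SD 2 px/frame) with small
per-frame rotations (SD 3 degrees), and nuclei exclude each other at 18 px
center distance — they cannot interpenetrate, which also bounds how
closely two textures can blend. Occlusion events (a cell invisible for
1-3 frames) are modelled as transient disappearance and are off by
default; tests enable them to exercise gap closing. The camera adds the
offset, Gaussian read noise (SD 30), optional shot noise, and a smooth
+/-10% illumination gradient. Identical configurations (including the
seed) produce byte-identical output.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: optical point-spread functions and
chromatic effects beyond the soft edge; cell division, apoptosis and
cytoplasmic spillover; reporter maturation and degradation kinetics
(induction plateaus rather than decaying, so final-frame responder
calling is unbiased here in a way it may not be for transient responses);
spatial correlation between neighbouring cells' induction; and
focus-dependent blur coupling the focus module to segmentation.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on a three-field replicate
slide at the default conditions (3 x 85 cells x 72 frames), which gives
~255 tracked cells — enough binomial resolution to check recovery of the
responder fraction within its 95% CI and paired per-cell fold recovery
within 10%, while a single field checks per-frame count accuracy and
strict-link recovery across all 71 transitions. Smaller fixtures
(256-px fields with the filter diameter scaled to 35, keeping the same
cutoff-to-image ratio) exercise unit-level behaviour. Determinism is
enforced end to end: every stochastic stage takes an explicit seed, and
library code restores the caller's RNG state.

Known limitations, stated plainly. Segment footprints are contour-based
reconstructions under heavy ideal-filter blur: overlap with the true
ellipse is typically Jaccard ~0.84 (median) but drops toward ~0.7 for
the most elongated nuclei, whose tips round off; the area rule and all
downstream statistics are insensitive to this, but boundary-sensitive
uses would need a finer edge model. The ambiguity margin in strict
linking ("discrepant scores") is an interpretation — a relative 20%
margin, with ties counting as discrepant — exposed as a parameter. The
flexible-linking candidate radius grows linearly with gap length, a
random-walk assumption. And the 2000-count intensity offset is kept in
camera units: it is meaningful only on a sensor whose background mode
and nuclear signals sit at the multi-thousand-count scale, as here.
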