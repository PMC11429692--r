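---
title: "Models and methods behind larvaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind larvaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaquant)
```

This vignette is the package's own account of the models, parameters and
numerical choices in its quantification pipeline for whole-larva
light-sheet imaging of antimicrobial-peptide (AMP) reporter expression in
the insect fat body. It also states exactly what the synthetic-larva
generator emulates — and what it does not — so that the meaning of a green
test suite is clear.

## Coordinate and data conventions

Images are numeric matrices `[y, x]` or arrays `[y, x, z]`. The x axis is
the anterior-posterior (AP) axis of the larva with the anterior at low x;
y is the short (vertical) axis; z is depth. Pixel centers sit at 0-based
integer coordinates, and all external tables (cell centers, tracks) use
0-based pixel units and 0-based frame indices, matching the conventions of
the interactive annotation tools such data typically comes from. On-disk
images are TIFF (multi-page for stacks and time-lapses; intensities are
min-max scaled into the portable [0, 1] float range with the affine
transform stored in a `.scale.json` sidecar so `read_image()` restores raw
values); tables are CSV and scalar metadata JSON.

## The illumination field

At low magnification the excitation sheet under-fills the detection plane,
so raw images carry a smooth multiplicative artifact. It is modeled as

$$I(x, y) = \frac{I_0}{1 + \left(\frac{x - x_c}{x_R}\right)^2}
\exp\!\left(-\frac{(y - y_c)^2}{2\sigma_y^2}\right),$$

a Lorentzian along the sheet propagation axis (the beam's Rayleigh-range
profile, half-width $x_R$, center $x_c$) times a Gaussian along the
vertical axis (width $\sigma_y$, center $y_c$), peaking at $I_0$. All five
parameters, including the vertical center $y_c$, are fit jointly to a
reference image of a uniform fluorophore solution.

Fitting is bounded Levenberg-Marquardt (`minpack.lm::nlsLM`) over every
pixel. Initialization comes from intensity moments: centers from the
intensity-weighted centroid, widths from marginal half-widths at half
maximum, $I_0$ from the maximum. If a fit does not converge it is retried
from up to five deterministically jittered starts; a final failure is an
error carrying the best residual. On noiseless synthetic references the
round trip recovers parameters to ~1e-15 relative error, and to ~1% at
SNR 20 on a 48×96 grid.

`correct_illumination()` first crops a fraction of rows from each vertical
end (default `crop_fraction = 0.1` per side — the sheet fit is least
reliable at the vertical extremes; the cropped amount is a package default,
exposed as an argument) and then divides by the field scaled to unit
maximum, so corrected intensities stay on the raw scale and dim edges are
boosted. Correction is applied after dual-illumination averaging; the two
operations commute for a shared field, and averaging first halves the
number of corrections.

## Single-cell quantification

Reporter intensity per cell is the sum over the lattice disk
$(i - c_y)^2 + (j - c_x)^2 \le \rho^2$ around the (possibly fractional)
center, with no anti-aliasing; the default $\rho = 6$ px corresponds to
roughly 2 µm at the 20× single-time-point optics and roughly 5.5 µm at the
5× time-lapse optics. Disks are clipped at the image border and
`n_pixels_in_disk` is reported so callers can normalize. For an interior
center the radius-6 disk contains exactly 113 pixels.

Nuclei are segmented in 3D by Gaussian blur, a global threshold (Otsu by
default), full-connectivity connected components and a minimum-size filter
(which also excludes much smaller, dimmer objects such as bacteria visible
in the nuclear channel). Local background for nuclear sums is the mean
signal in a shell formed by dilating each nuclear mask by 2 px and
subtracting the mask; shell voxels belonging to *any* nucleus are excluded
so a bright neighbor cannot contaminate the background estimate. The
corrected sum `raw - shell_mean * voxels` is exactly invariant to adding a
constant to the stack.

Per-larva responses are classified against mock-injected controls: larvae
with median cell intensity at or below `mean(mock) + 3 sd(mock)` are
`none`; the rest split into `partial`/`complete` by 2-cluster k-means on
log10 medians (scale-invariant by construction), with the threshold at the
midpoint of the cluster centers. Real cohorts are strongly bimodal, which
makes the split easy; ties and single-larva cases require an explicit
threshold rather than a silent guess.

## AP expression profiles

Tissue-scale profiles avoid any cell segmentation: two Otsu thresholds are
computed on `log(image + 1)` (the +1 offset handles zeros), giving three
classes — dim background, bright background, strong GFP. The strong-GFP
mask is applied to the *raw* image, masked intensity is summed over y per
x-column, and columns are aggregated into half-open AP bins (default 50
per larva; 20 for cross-larva averages, where profiles are first mapped to
a normalized [0, 1] AP coordinate, linearly interpolated at common bin
centers, and divided by their own maximum). The multi-Otsu search is exact:
over the unique intensity levels when there are ≤256 of them, otherwise
over a 256-bin histogram, maximizing between-class variance by cumulative
moments with ties broken toward the smallest thresholds.

Region statistics use anterior/middle/posterior fractions of the AP axis
(default 0.25/0.50/0.25 — the tissue's outer lobes versus its middle; the
boundaries are configurable and recorded in the output). The headline
quantity is the ratio of the anterior and posterior region means to the
middle mean.

## Bacteria counting

Fluorescent bacteria appear both as point-like planktonic cells and as
large clusters (often internalized by nephrocytes and hemocytes), so
segmentation runs in two phases: a Difference-of-Gaussians band-pass
(default σ 1 and 3 px) thresholded for spots, and a heavier Gaussian blur
(default σ 6 px) thresholded for clusters, with the union labeled at full
connectivity. Automatic thresholds are robust multiples of the filtered
images' spread (MAD-based); they are deliberately configurable because
such constants never transfer between imaging setups.

Each object's cell count is `n = ceiling(S / median(S))`, where `S` is the
object's summed raw intensity and the median runs over all detected
objects (singletons dominate detections; an option restricts the median to
spot-phase objects). Objects with `n < 3` are flagged planktonic — freely
suspended in the hemolymph — and only those enter the AP density histogram
by default. The estimator is scale-invariant, and exact when all
singletons share one intensity. One limitation is intrinsic to the
ceiling: with continuous intensity noise, roughly half the singletons have
`S` above the median and round up to 2, biasing totals upward. On the
package's synthetic scenes (25 singletons, 3 clusters of 5-15 cells,
amplitude cv 0.2) the mean total-count error over 50 scenes is ~8%, partly
because merged nearby singletons cancel some of the ceiling inflation;
per-scene errors can exceed 15%.

## Expression dynamics

Traces are disk sums at manually tracked centers, one per frame, so
tracking a moving cell reproduces the static trace exactly. The activation
rate is an ordinary least-squares slope over the initial phase: onset is
the first time the trace exceeds its first-3-point baseline mean plus 3
baseline sd, and the default window runs from onset to onset + 4 h
(clipped to the trace; the window is a package policy — activation rises
over a few hours and plateau data would dilute the slope — and both policy
and window are recorded in the fit output, with full-trace and fixed-window
alternatives available). Endpoint expression is the trace value at the
frame nearest 6 h. Summaries report per-region rate medians and quartiles,
the anterior/middle and posterior/middle median ratios, and the R² of
endpoint on rate across cells.

## Spatial transcriptomics

The module consumes a cells × genes count matrix with per-cell AP
coordinates. "Transcript frequency" of a gene in a cell is its count
divided by the cell's total counts — a definition chosen here and stated
prominently because reasonable alternatives (normalized or transformed
counts) exist. Genes are first filtered to a minimum detection fraction
(default 5%, inclusive at the boundary). Profiles are per-bin means of
transcript frequency (default 10 AP bins) with error bars from `B = 100`
bootstrap resamples of each bin's cells, seeded for reproducibility; a
bin's bootstrap sd estimates the standard error of its mean, and at
n = 1000 cells per bin the median calibration ratio across bins is within
a few percent of 1. Clustering and differential expression are consumed as
inputs (cluster labels, upregulated gene lists) from the established
implementations users already run; the overlap of an upregulated list with
a known-immunity list is scored by the upper-tail hypergeometric
probability at a user-stated universe size, with case-folded exact
identifier matching and no alias resolution.

## The synthetic-larva generator

Every generator is a pure function of its configuration and seed
(bit-identical reruns). Scenes are rendered as Gaussian blobs — smooth,
bandwidth-controlled, analytically integrable — on a constant background,
with the illumination field applied multiplicatively before noise
(additive Gaussian, optional Poisson; the camera model is a package
choice). Defaults, chosen once as this package's study conditions:

* Regional rate medians anterior : middle : posterior = **2.0 : 1.0 : 1.6**
  — the regional contrast the dynamics pipeline is designed to detect —
  with per-cell rates log-normal (`sdlog = 0.35`, a continuous but clearly
  regionalized spread) and region fractions 0.25/0.50/0.25 of the AP axis.
* Onset `t0 = 0` with optional jitter; per-cell GFP amplitude
  `baseline + rate * max(0, t - t0)`, so disk-summed traces are exactly
  affine in time when noise is off.
* Partial-response single-time-point scenes modulate the *expressing-cell
  fraction*: outer lobes fully expressing, middle scattered
  (`express_prob`, default 1 everywhere). This mirrors what partial
  responders actually look like — scattered middle expression over a broad
  per-cell distribution reaching zero — and it matters for the profile
  stage: under uniform amplitude dimming the hard multi-Otsu mask drops
  middle cells entirely and the measured region ratio grossly overshoots
  the generated contrast, whereas fraction modulation yields ratios that
  track it. Expressing cells default to rate 10 a.u./h against background
  10 a.u., i.e. cells clearly brighter than background at a few hours, as
  in real reporter images.
* Bacteria: point-like singletons (Gaussian σ 1 px, amplitude cv 0.2) and
  tight clumps of 5-15 cells; per-object true counts exported.
* Cell placement is rejection sampling with a minimum separation (default
  3 cell radii), with an explicit packing-limit error when a configuration
  cannot fit.

What the generator does **not** emulate: optical physics (PSF, scattering,
depth attenuation), larval motion and tissue deformation, autofluorescence
texture, lipid-droplet structure inside cells, or segmentation-confusing
debris. Passing tests therefore demonstrate the *algorithms* — threshold
searches equal exhaustive oracles, sums equal lattice enumeration, fits
recover generating parameters, ratios and calibrations are recovered under
the stated noise — not robustness to every artifact of real microscopy;
parameter defaults (blur scales, thresholds, minimum sizes) will need
adjustment on real data.

## Numerical choices and degenerate inputs

* Multi-Otsu ties break toward the smallest threshold pair; images with
  fewer than three distinct (log-)levels yield an all-zero profile flagged
  degenerate rather than an error.
* Tile fusion places tiles at `round(stage_offset / pixel_size)` — no
  sub-pixel interpolation, matching stage-coordinate placement — and
  averages overlaps; uncovered canvas is 0.
* Gaussian blur uses a separable kernel truncated at 4σ with replicate
  padding; connected components use full (8/26) connectivity via a
  foreground-adjacency graph; dilation uses a Euclidean ball.
* An empty nuclear shell (a nucleus filling its whole neighborhood) is an
  error naming the nucleus; an empty bacteria list yields an empty table,
  while a zero median intensity is an error.
* `fit_activation_rate` needs ≥3 points; if the initial-phase window holds
  fewer, it extends forward until it has 3. An undetected onset falls back
  to a full-trace fit flagged `onset_found = FALSE`.
* All simulation-based checks run at desk scale by design: reference
  images 48×96, scenes 80×300 to 120×800 px with 60-200 cells, 13-frame
  time-lapses, 50 bacteria scenes, 40 profile scenes, 10,000-cell count
  matrices — sizes at which every stochastic summary is stable yet the
  whole suite runs in about a minute.

## Known limitations

* The ceiling-based bacteria count estimator is biased upward under
  continuous intensity noise (see above); totals are accurate to ~10% in
  the tested regime, not exact.
* The profile region ratio is a thresholded-mass statistic: it compresses
  or amplifies the underlying expression contrast depending on where the
  strong-GFP threshold lands relative to the dimmer population. It is a
  robust *pattern* detector, not an unbiased contrast estimator.
* `classify_response` presumes clean per-larva bimodality; heavily
  overlapping populations will split somewhere, and the recorded threshold
  should be inspected.
* Axis alignment is assumed (anterior left); there is no larva
  straightening, and OME-Zarr I/O is out of scope for this R
  implementation — TIFF + CSV/JSON sidecars are the on-disk format.
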