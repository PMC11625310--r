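---
title: "Quantifying septin-focal adhesion biology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying septin-focal adhesion biology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faquant)
```

This vignette documents the models, parameter choices and numerical
conventions behind `faquant`, in the spirit of a methods section: what each
stage computes, which knobs matter, what the synthetic validation scenes do
and do not establish about real data, and where the design was genuinely
open and a choice had to be made.

## The measurement problem

Focal adhesions (FAs) are micron-scale, elongated integrin complexes that
couple the extracellular matrix to the actin cytoskeleton. In fibroblasts,
septin-7 forms both thick perinuclear bundles along ventral stress fibres
and fainter punctate signal near peripheral adhesions, and the scientific
questions — does septin sit *in* the adhesion or *next to* it, and does
perturbing it change adhesion size, turnover and matrix sensing? — all
reduce to per-object image measurements:

* per-adhesion **pixel-wise Pearson correlation** between a reference
  adhesion channel (paxillin) and a second marker, split by cell
  compartment (perinuclear "inner" vs peripheral "outer");
* **morphometrics** (area, moment-ellipse axes, roundness) of segmented
  adhesions and septin structures;
* **line-scan profiles** across single adhesions, aligned on the paxillin
  peak, to read out sub-adhesion displacement of a marker;
* **anisotropy** of the filamentous septin texture;
* **lifetimes and formation rates** from time-lapse movies, **migration
  metrics** from nuclei tracks, and **fibronectin clearance per cell**;
* a nonparametric statistical battery over the resulting tidy tables.

## Segmentation pipeline

`segment_fas()` chains four deterministic raster operations:

1. **Background subtraction** (`subtract_background()`): white top-hat, a
   grayscale opening with a disc of radius `bg_radius` (default 50 px)
   subtracted from the image. The opening is a rolling-ball equivalent:
   structures narrower than the disc survive, smooth background does not.
   The default radius is several times the largest adhesion diameter at
   100x TIRF sampling (0.11 µm/px), so adhesions are untouched.
2. **Median filter** (`median_filter()`, default radius 1): exact sample
   medians over square windows with mirror-reflected edges. The windows
   are sorted with a vectorised exchange network rather than a quantised
   histogram, so the output is exactly a value from each window — the
   property the test suite checks against a per-pixel sort oracle.
3. **Otsu threshold** (`otsu_threshold()`): the histogram split maximising
   between-class variance. Float images are binned into 256 equal-width
   bins over `[min, max]`, matching 8-bit behaviour; ties in the criterion
   resolve to the lowest bin. *Foreground is strictly above the
   threshold*, and the returned value is the largest observed
   background-class intensity, so the strictly-above rule reproduces the
   optimal histogram partition exactly. This convention is worth fixing
   explicitly: the alternative (foreground ≥ threshold) moves object
   boundaries by a one-pixel rim and measurably changes areas.
4. **Connected components** (`label_connected()`): default 8-connectivity,
   the particle-analysis default in ImageJ-style tools; 4-connectivity is
   available. Labels are assigned in raster order of each component's
   first pixel so the labelling is reproducible.

The **area filter** keeps components with 0.20 µm² < area < 6 µm²
(exclusive on both sides): smaller components are unresolvable speckle,
larger ones are merged structures. Objects touching the image border are
retained but flagged (`on_border`), so users can exclude them; the
measurement itself is well defined either way.

**Roundness** is `4·area/(π·major_axis²)` with axes from the object's
second-moment ellipse (major axis = 4·sqrt of the larger covariance
eigenvalue), the same definition ImageJ reports; it is 1 for a disc and
tends to 0 for elongated adhesions. Values are clipped into (0, 1] because
pixel discretisation can push a tiny compact object marginally above 1.

## Inner/outer partition and per-object Pearson

Published analyses often split cells into perinuclear and peripheral
regions by hand. `partition_regions()` replaces the manual step with a
reproducible rule: a pixel is *inner* when its Euclidean distance to the
cell edge is at least `fraction` (default 0.5) of the maximum such
distance. The rule is monotone (fraction 0 = whole cell inner, 1 = deepest
pixels only), the two masks are disjoint and exhaustive, and user-supplied
masks can be passed instead to mimic hand-drawn ROIs. Objects are assigned
by their centroid pixel; a centroid outside the cell is an error rather
than a silent guess.

`pearson_per_object()` computes, per labelled object, the plain Pearson
correlation of the two channels over that object's pixels only, via
per-label sufficient sums. An object in which either channel is constant
carries no correlation information; it is returned as `NA` with
`defined = FALSE` and excluded from binning, never coerced to 0.

**Random binning** (`bin_random()`): values are shuffled with a fixed
seed, cut into consecutive groups of `bin_size` (default 10), the
remainder dropped, and group means returned — the "each point is the
average of 10 random FAs" plotting convention. The shuffle restores the
caller's RNG state afterwards, so analysis code never perturbs a
surrounding simulation's random stream.

## Line profiles

`extract_line_profile()` samples bilinearly at unit-pixel spacing along a
segment, averaging an odd number of parallel offset lines.
`normalize_profile()` applies min-max scaling `(i − min)/(max − min)` per
channel — the normalization that maps every scan onto [0, 1]; a constant
channel is a `degenerate_profile_error`, not a division by zero.
`align_and_average()` shifts each profile so the reference (paxillin) peak
sits at position 0, resamples onto a common 1-px grid and returns
pointwise mean and SD; grid points outside a profile's support are simply
not counted for that profile (`n` records coverage). `loess_smooth()` is
standard LOESS (tricube weights, local quadratic, default span 0.75) with
`surface = "direct"` so that polynomial reproduction is exact rather than
interpolation-approximate.

## Anisotropy

No single published algorithm is attached to "septin anisotropy", so the
package uses the standard fibre-alignment score for cytoskeletal images:
structure-tensor **coherency**. Gradients are central differences (the
one-pixel border is excluded), the tensor components are smoothed with a
Gaussian (`sigma`, default 2 px), averaged over the ROI, and the score is
`(λ₁ − λ₂)/(λ₁ + λ₂)` of the mean tensor: 0 for isotropic texture, 1 for
parallel stripes. The dominant angle is the filament direction
(perpendicular to the mean gradient), reported in [−π/2, π/2). A
zero-gradient ROI returns score 0 with a `degenerate` flag. Scores are
comparable within this implementation only — coherency values from other
tools with other smoothing scales are not numerically interchangeable.

## Dynamics

`build_kymograph()` stacks width-averaged line profiles as columns
(rows = space, columns = time). Lifetimes use the **frames-present
convention**: `min_lifetime = (last − first + 1) × dt`. A record touching
the movie's first or last frame is *censored* — the observed span only
bounds the true lifetime from below, which is why the quantity is called a
minimum lifetime. `detect_presence()` derives presence from images with
one fixed threshold taken from the maximum-intensity projection (per-frame
re-thresholding flickers and inflates apparent turnover), and an object is
present in a frame when at least half its reference footprint is above
threshold. Runs interrupted for at most `gap_tolerance` frames (default
1) are bridged for blinking robustness; strict mode is `gap_tolerance =
0`. The formation rate counts objects first appearing after the movie
start, per minute of observation; an events-per-area variant was
considered and rejected because the ROI area is a free parameter that
would silently rescale the number.

`link_tracks()` is deliberately a greedy nearest-neighbour linker with a
hard displacement gate and no gap closing: adequate for sparse,
slowly-moving nuclei imaged every few minutes, and simple enough that its
failure mode (track splitting on a missed detection) is obvious rather
than subtle. It is not an optimal-assignment tracker and is documented as
such. `migration_metrics()` excludes tracks spanning less than 8 h
(continuous-tracking filter), then reports speed (path length/duration),
persistence (net displacement/path length, in [0, 1] by the triangle
inequality) and forward progress (net displacement/duration), in µm/min.

## Function assays

`cell_area()` is Otsu + components + a 50 µm² debris floor at wide-field
sampling (0.325 µm/px). `clearance_per_cell()` segments pixels *below* a
threshold as cleared substrate, removes components under 5 µm² (noise
speckle), sums the remainder and divides by the cell count (supplied, or
counted from a nuclei channel). The threshold is an explicit number — the
reproducible stand-in for a manual threshold — with an `"auto"` option
that takes the dark Otsu class. A threshold below the image minimum
legitimately yields zero clearance.

## Statistics

`mann_whitney_u()` and the omnibus of `kruskal_dunn()` delegate to R's
`wilcox.test`/`kruskal.test` (exact small-sample p values, tie and
continuity corrections); the test suite checks the exact branch against
full enumeration of group assignments. Dunn's post hoc z tests on pooled
ranks, with the tie-corrected variance, are computed in-package (base R
has no implementation); pairwise p values are Bonferroni-adjusted by
default (Holm and none available) — commercial statistics packages
multiplicity-adjust their Dunn output, so the adjusted default matches
what practitioners expect. All tests are two-sided. Star labels use the
strict conventional cutoffs (**** < 0.0001, *** < 0.001, ** < 0.01,
* < 0.05, else ns).

`run_report()` optionally bins within groups before testing. Whether
binned points or raw objects should enter the tests is genuinely ambiguous
in practice, so both modes exist; binned is the default because that is
what the plots show.

## The synthetic-scene generator

`generate_fa_scene()` emulates the statistical structure the analysis
assumes, not the optics:

* **Objects** are plateau ellipses (peak-normalized to 1) with a short
  anti-aliased rim, areas uniform in `area_range` (default 0.5–4 µm²),
  axis ratios 1.5–3.5, placed without overlap (rejection sampling, capped
  at 10,000 attempts per object, then a capacity error) entirely inside
  their assigned compartment of an elliptical cell. The **ground-truth
  footprint is the half-maximum support** of the profile — the standard
  definition of an object's extent for a peak-normalized profile, and the
  contour a threshold-based segmenter should recover.
* **Noise** is additive Gaussian with σ = peak/snr (default snr 10) on a
  constant background (default 0.2), with optional Poisson shot noise.
  Camera modelling, PSF blur, photobleaching and 3D structure are
  explicitly out of scope.
* **Correlation** between channels is constructed per object as
  `B = ρ·z(A) + sqrt(1 − ρ²)·ε` on the *standardized realized* first
  channel (i.e. after its noise), so the expected per-object Pearson r
  equals ρ at any snr. Constructing on the noise-free signal and adding
  independent noise afterwards would attenuate r by the factor
  σ²ₛ/(σ²ₛ + σ²ₙ) per channel and the generator's ρ would not be the
  quantity the measurement estimates. Setting `inner_offset_um > 0`
  instead renders the inner objects' second-channel signal displaced
  toward the cell centre — the "septin next to, not in, the adhesion"
  configuration — and records their true ρ as `NA`.
* **Time-lapses** place Gaussian spots present exactly between their
  appear/disappear frames (1-based, inclusive); **clearance scenes** carve
  holes of exactly specified pixel counts (the N disc pixels nearest each
  hole centre) into a bright fibronectin field; **tracks** follow
  straight, random-walk or biased-walk step models with fixed step length.
* Identical parameters and seed give bit-identical output.

Passing the validation suite on these scenes establishes that the
*measurement chain is correct*: thresholds match the histogram optimum,
per-object r estimates the constructed correlation without bias, recovered
areas and lifetimes match construction, the statistics hold their nominal
type-I error. It does not establish robustness to what the generator does
not model — uneven illumination, PSF-correlated noise between channels,
adhesion splitting/merging, out-of-focus light. On real data those enter
through the configurable steps (background radius, thresholds, gap
tolerance), which is why every such constant is an explicit argument.

## Validation problem sizes

The shipped tests and `scripts/acceptance.R` run at desk scale, chosen so
the whole suite completes in a few minutes on one core while keeping the
Monte Carlo error of every calibrated quantity well inside its decision
band: 512×512 px scenes with 12 objects (10 seeds) for segmentation
recovery; 20 seeds × 6 objects of ≥ 500 px for Pearson calibration at
ρ ∈ {0, 0.3, 0.6, 0.9} (the SE of the mean r is ≈ 0.003, against a ±0.05
band); 60-frame noise-free movies for lifetime exactness; 2000-step random
walks (20 seeds) for persistence decay; 500 null simulations for the
type-I rate (binomial SE ≈ 0.01 at a size of ≈ 0.043 for the exact
10-vs-10 Mann-Whitney test).

## Known limitations

* Segmentation is threshold-based; nascent sub-diffraction adhesions and
  machine-learned segmentation are out of scope.
* The Pearson measure is per-object and linear; it does not detect
  nonlinear co-occurrence, and objects with a constant channel are
  reported as undefined rather than estimated.
* The tracker has no gap closing; a single missed detection splits a
  track. For dense or fast objects use a dedicated tracker and feed its
  tracks into `migration_metrics()`.
* Anisotropy scores depend on the smoothing scale `sigma`; compare only
  within a fixed configuration.
* The inner/outer rule is geometric; it approximates, but is not, a
  nucleus-registered partition. Supply nucleus-derived masks where that
  distinction matters.
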