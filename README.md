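# faquant

Quantitative image analysis of septin–focal adhesion biology in adherent
cells. `faquant` turns multi-channel fluorescence images and time-lapse
stacks of fibroblast-like cells into per-adhesion numbers: where a marker
such as septin-7 sits relative to paxillin-defined focal adhesions (FAs),
how large and how round those adhesions are, how long they live, how
anisotropic the filamentous septin bundles are, and how much fibronectin
each cell clears from its substrate — together with the nonparametric
statistics used to compare conditions. Because raw microscopy data for this
kind of study is rarely shareable, the package ships a seeded
synthetic-scene generator that produces images with complete ground truth
(object labels, true per-object correlations, lifetimes, tracks), so every
stage of the pipeline is verifiable end to end.

It is written for cell biologists and image analysts who want an
ImageJ-style particle workflow as reproducible, scriptable R.

## What it computes

**Segmentation and morphometrics.** Each channel is background-subtracted
(grayscale opening / top-hat), median-filtered, thresholded with Otsu's
method (foreground strictly above the threshold), and labelled into
connected components (8-connectivity by default). Components are kept only
in the exclusive range 0.20 µm² < area < 6 µm². For each adhesion the
moment-ellipse axes give

    roundness = 4 · area / (π · major_axis²)  ∈ (0, 1]

**Object-based Pearson colocalization.** For adhesion *k* with pixels
*i = 1…n* and channels *a*, *b*:

    r_k = Σ (a_i − ā)(b_i − b̄) / sqrt( Σ(a_i − ā)² · Σ(b_i − b̄)² )

computed over the adhesion's pixels only, using the reference (paxillin)
mask to index both channels. Cells are split into an inner (perinuclear)
and outer (peripheral) compartment by an edge-distance rule, and r values
are averaged in seeded random bins of 10 before plotting or testing.

**Profiles, texture, dynamics.** Cross-FA line scans (bilinear, width
averaged) are min-max normalized, peak-aligned and LOESS-smoothed.
Filament anisotropy is the structure-tensor coherency (λ₁−λ₂)/(λ₁+λ₂) of an
ROI. Kymographs, minimum lifetimes (frames present × frame interval, with
censoring flags at the movie ends), formation rates, and migration metrics
(speed, persistence = net displacement / path length, forward progress,
with an 8 h minimum-tracking filter) come from time-lapse stacks and
greedy nearest-neighbour tracks.

**Statistics.** Mann-Whitney U for two groups, Kruskal-Wallis with Dunn's
post hoc (Bonferroni-adjusted by default) for three or more, star labels at
the conventional strict cutoffs, all wrapped in `run_report()`.

## Worked example

```r
library(faquant)

# a seeded two-channel scene: 6 perinuclear FAs at rho = 0.2,
# 6 peripheral FAs at rho = 0.7
sc <- generate_fa_scene(scene_params(rho_inner = 0.2, rho_outer = 0.7, seed = 1))

res <- quantify_adhesions(sc$channels$paxillin, sc$channels$septin,
                          cell_mask = sc$truth_regions$cell)
head(res$objects[, c("label", "area", "roundness", "region", "pearson")], 4)
#>   label   area roundness region   pearson
#> 1     1 1.4641 0.3238832  outer 0.6319109
#> 2     2 3.3275 0.3003634  inner 0.2858122
#> 3     3 2.9887 0.6527325  outer 0.6590550
#> 4     4 2.9282 0.3074819  inner 0.2401275

rep <- run_report(res$objects, group = "region", value = "pearson",
                  bin_size = NULL)   # too few objects here to bin by 10
rep$summary
#>       group n_raw n_tested    median
#> inner inner     6        6 0.2059229
#> outer outer     6        6 0.6793513
rep$test
#> mann_whitney_u: statistic = 0, p = 0.002165 (**), n = 6/6
```

The per-adhesion areas (µm²) fall inside the 0.20–6 size filter, the
recovered Pearson r values sit near the correlations the scene was built
with (0.2 inner, 0.7 outer), and the rank test separates the two
compartments. The same functions run unchanged on real TIFF data loaded
with `read_micro_tiff()`.

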