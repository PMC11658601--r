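---
title: "Methods: from field point clouds to loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from field point clouds to loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofield)
```

phenofield implements a complete plot-scale phenotyping chain for
replicated nitrogen trials of wheat: 3D point clouds of the field are
segmented into ground and canopy, per-plot canopy heights and
nitrogen-related vegetation indices are extracted across the season,
each plot's time course is condensed into six dynamic traits by
Gaussian curve fitting, and the traits feed a genome-wide association
scan. Because real UAV campaigns are not reproducible on demand, every
stage is driven by a synthetic field generator with known ground truth;
this vignette documents the models, the defaults, and the choices made
where the design was genuinely open.

## The synthetic trial

The default `trial_design()` mirrors a season-long replicated nitrogen
trial: 160 varieties under three nitrogen levels (N0/N180/N240, applied
rates 0/180/240 kg N ha^-1^, overridable since labels and rates are
logically independent) with 2 replicates, giving 960 plots of 1.5 x 1 m
holding 5 sown rows at 20 cm spacing, observed at 10 acquisition days
between 20 and 185 days after sowing (DAS). Plots are laid out
row-major on a near-square grid with 0.5 m aisles; the layout, not a
clustering of the data, defines all plot rectangles downstream, because
trial geometry is known in practice.

### Growth trajectories

Canopy height follows a Gaussian bump on a baseline,

$$f(t) = c + a\,e^{-(t-\mu)^2 / 2\sigma^2},$$

which rises through stem elongation, peaks at $\mu$, and declines
slightly during grain filling along the falling limb. The default
treatment parameters are the exact solution of four seasonal
constraints within this family: all treatments peak at 160 DAS, the
fertilized treatments reach a maximum 15 cm above the control, mean
height at 65 DAS is 50 cm (N180/N240) versus 42 cm (N0), and about 5 cm
of height is shed between the peak and the last acquisition at 185 DAS.
Solving gives N0 $(a, \mu, \sigma, c) = (47.54, 160, 53, 32.46)$ and
N180/N240 $\approx (66, 160, 63, 28.75)$ (cm, DAS, days, cm). Variety
random effects (SDs 4 cm on $a$, 3 d on $\mu$, 3 d on $\sigma$, 2 cm on
$c$) and 2 cm of observation noise are field-plausible scales chosen
once; they set the between-plot variance that the height-agreement and
association stages see. A second generator family (logistic rise +
linear decline) is available, off by default, to probe sensitivity to
the fitted family being wrong.

### Point clouds, reflectance, genotypes

`generate_field_cloud()` emits ground returns over the whole field
(soil between rows is visible from above) on a configurable tilted
plane with 1 cm roughness, canopy returns confined to plot rectangles
and concentrated on the sown rows, with elevation = ground + true
height + N(0, 5 cm) truncated below at the ground, and a small
(0.5%) fraction of tall "weed" outliers labeled ground — mirroring
annotation practice in which weeds and signs are folded into the ground
class. Colors are class-specific (soil brown vs leaf green) with 0.04
RGB noise; that chromatic separation, not elevation alone, is what the
learned segmenter mostly exploits.

`generate_multispectral_raster()` maps each plot's nitrogen status (a
unitless score in [0, 1] that scales with both treatment and canopy
development) to five-band reflectance through affine responses that are
monotone by construction: NIR and red-edge rise with status, red falls.
This is a deliberate caricature — no radiative transfer, no shadows, no
view geometry — sufficient to make the vegetation-index chain testable
(the plot-mean CCCI must be strictly increasing in status on noise-free
rasters, and is).

`generate_genotypes()` draws per-SNP allele frequencies uniformly in
[0.05, 0.5], Hardy-Weinberg dosages, independent missingness, and
optionally plants QTLs whose additive effects shift a growth-curve
parameter per variety via `qtl_variety_effects()`; linkage
disequilibrium and deeper population structure are out of scope beyond
a simple two-subpopulation option used to validate the PCA covariates.

## Segmentation

Two segmenters share one contract (labels: 0 = ground, 1 = canopy).

The **geometric baseline** thresholds elevation above a ground model at
0.10 m. The ground model is a per-cell low-percentile grid (default
0.25 m cells, 5th percentile of z, nearest-cell fill): soil returns
dominate the low tail of every cell, so on gently varying terrain this
matches what a cloth-simulation filter produces at a fraction of the
complexity. The percentile is capped at 50 to keep the estimate on the
ground side; cell size trades terrain resolution against per-cell
sample size.

The **learned segmenter** is a miniature hierarchical point-set
network: two set-abstraction levels (farthest point sampling to 512/128
centers, fixed-radius grouping at 0.25/0.75 m with 16 points per
group, shared two-layer feature maps of width 32/64, channel-wise max
pooling) and two feature-propagation levels (inverse-distance-weighted
3-NN interpolation back to the finer level, concatenation with skip
features, per-point feature map), ending in a linear two-class head.
Input features are elevation above the chunk's 5th z-percentile plus
RGB; clouds are chunked into 2 m blocks of at most 4,096 points, and
within-chunk point order is canonicalized by coordinates so predictions
are invariant to input order. Training minimizes class-frequency-
weighted cross-entropy (ground returns usually dominate) with Adam
(lr 0.01, 25 epochs) and is deterministic for a fixed seed. Exact ties
at probability 0.5 go to ground, the conservative choice for height
statistics. The published architecture this miniature follows is
faithful in kind, not in scale: it trains on a CPU in about a minute on
the default fields.

Both segmenters are evaluated with precision, recall, F1 and mean
intersection-over-union on the percent scale, canopy as the positive
class, mIoU averaged over both classes.

## Heights, indices, dynamic traits

Canopy height per plot is the mean of (z − local ground) over
canopy-labeled points inside the plot rectangle (half-open edges, so
adjacent plots never share points), reported in cm; a percentile
aggregator is available for robustness against residual soil points.
Plots without canopy points yield NA, never 0, so downstream fits drop
the timepoint rather than absorb a phantom measurement.

The four indices are computed pixelwise from five-band reflectance:
NDRE = (R~NIR~ − R~red~)/(R~NIR~ + R~red~), CCCI = (NDRE − 0.24)/(0.61
− 0.24), MSAVI = (2R~NIR~ + 1 − sqrt((2R~NIR~+1)² − 8(R~NIR~ −
R~red~)))/2, RVI~1~ = R~NIR~/R~red~, RVI~2~ = R~NIR~/R~green~. Two
deliberate decisions: the NDRE here uses the red band, matching the
CCCI formulation adopted, with a red-edge override available since the
index's name suggests it (`vi_params(ndre_band = "red_edge")`); and
CCCI is not clipped to [0, 1] by default — the affine map exceeds its
endpoints whenever NDRE leaves the [0.24, 0.61] calibration range, and
clipping would flatten exactly the seasonal dynamics the curve fitting
needs. Plot means are taken over edge-buffered masks (default 0.1 m
buffer, a value not dictated by anything sharper than "exclude marginal
pixels"; pixel membership is by pixel center, consistent with the
half-open plot convention).

Per-plot (or replicate-averaged) series are fitted by bounded
Levenberg-Marquardt least squares in the same Gaussian family the
generator uses — deliberately, so that noise-free parameter recovery to
1e-6 relative error is an exact, testable statement. Auto-initialization
(c = min, a = range, mu = argmax, sigma = span/4) converges on every
series the suite generates; five jittered restarts under a fixed seed
are tried before declaring failure. A series with zero variance is
returned as a degenerate flat fit, flagged, and yields NA traits.

The six dynamic traits per signal are the curve maximum $c + a$, its
day $\mu$ (clipped into the observed window when the fit pushes it
outside, and flagged), and a rapid-change window: the field's
literature distinguishes slow and rapid growth stages without an
operational definition in the accessible text, so the package declares
one — the window where the rising-limb rate exceeds $\theta$ times its
maximum $r^\* = (a/\sigma)e^{-1/2}$ (attained at $\mu - \sigma$),
default $\theta = 0.5$. Its endpoints solve $x e^{-x^2/2} = \theta
e^{-1/2}$, found by bisection to 1e-8 days; duration and the secant
growth rate over the window complete the six. The secant rather than
peak rate is the default summary because it is stable under noise; the
peak-rate variant is an option. The convention is isolated in
`extract_dynamic_traits()` so an alternative definition can be swapped
in without touching anything else.

## Association scan

Genotype QC follows the strict reading of the conventional rules: SNPs
with *more than* 10% missing calls are removed, then SNPs with MAF
*below* 5% (both boundaries survive). Population structure enters as
the top 3 principal components of the mean-imputed, centered dosage
matrix. The scan itself is per-SNP ordinary least squares of the trait
on dosage + intercept + PCs with a two-sided t test — a deliberately
transparent stand-in for multi-locus mixed-model methods, sufficient
for planted-signal validation (the end-to-end test demands the causal
SNP be the top hit on its chromosome in at least 80% of 20 seeded
replicates, and the null scan's type-I error be nominal). Missing
dosages are handled per-SNP complete-case in the scan (n varies per
SNP) but mean-imputed for the PCA, as is conventional. Markers reaching
−log10(p) ≥ 3.5 (boundary inclusive) are flagged; Bonferroni or FDR
control can be applied externally to the returned p-values.

## What the tests do and do not show

Every acceptance-style check in the suite runs against synthetic fields
whose truth is known, at sizes chosen to keep the full suite around a
minute: 24-plot fields (4 varieties x 3 treatments x 2 replicates) for
segmentation and height agreement, the full 960-plot design for
trajectory recovery (cheap, since trajectories are curve evaluations),
150-200 varieties and up to 1,000 SNPs for the association properties.
Passing them shows the chain is correct and well-calibrated under the
generator's assumptions — Gaussian growth, clean class-conditional
colors, monotone optics, independent SNPs. It does not show robustness
to occlusion, registration error, mixed pixels, LD structure, or
growth curves outside the fitted family; the logistic generator family
and the percentile height aggregator exist to probe the first steps
beyond those assumptions.

## Known limitations

Multi-class segmentation (weeds as their own class), GPU training,
radiometric calibration, orthomosaic stitching, kinship-aware
association models and LD clumping are out of scope. The rapid-change
window is a declared convention, not a community standard; compare
$\theta$ settings before interpreting `v_srg`/`v_erg` biologically.
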