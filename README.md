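# phenofield

Multiscale plot phenotyping for replicated field trials, from 3D point
clouds and multispectral rasters down to genetic loci — with a synthetic
field generator so every stage is verifiable against known ground truth.

## Who this is for

Breeders and phenomics researchers running UAV campaigns over replicated
trials (the motivating case is wheat under nitrogen gradients) who need
the full chain in one tested toolbox:

1. **Segment** field point clouds into ground and canopy — either a
   deterministic geometric baseline (per-cell low-percentile ground model
   + height threshold) or a miniature hierarchical point-set network
   (set abstraction: farthest point sampling → ball query → shared
   feature map → max-pool; feature propagation: inverse-distance
   interpolation + skip connections), trained on CPU in minutes.
2. **Measure** per-plot 3D canopy height: mean of (z − local ground) over
   canopy points inside each plot rectangle, in cm.
3. **Index** nitrogen status from 5-band reflectance via
   NDRE = (R<sub>NIR</sub> − R<sub>red</sub>)/(R<sub>NIR</sub> + R<sub>red</sub>),
   CCCI = (NDRE − 0.24)/(0.61 − 0.24),
   MSAVI = (2R<sub>NIR</sub> + 1 − √((2R<sub>NIR</sub>+1)² − 8(R<sub>NIR</sub> − R<sub>red</sub>)))/2,
   RVI₁ = R<sub>NIR</sub>/R<sub>red</sub>, RVI₂ = R<sub>NIR</sub>/R<sub>green</sub>,
   aggregated through edge-buffered plot masks.
4. **Summarize** each plot's season by fitting
   f(t) = c + a·exp(−(t−μ)²/2σ²) and extracting six dynamic traits:
   maximum (c + a), day of maximum (μ), start/end/duration of the
   rapid-change window (where f′ exceeds θ·max rising rate, θ = 0.5),
   and the mean rate over that window.
5. **Map** traits to markers: genotype QC (>10% missing or MAF <5%
   removed), top-3 PC covariates, per-SNP OLS scan with a
   −log10(p) ≥ 3.5 significance rule, Manhattan/QQ exports.

Formats: PLY/XYZ/LAS 1.2 point clouds, multi-page float TIFF rasters
with a JSON sidecar, VCF/CSV genotypes, CSV tables everywhere else.

## Worked example

A 24-plot trial (4 varieties × 3 nitrogen levels × 2 replicates),
simulated at 10 timepoints, segmented, measured and summarized:

```r
library(phenofield)

design <- trial_design(n_varieties = 4)       # defaults: N0/N180/N240, 2 reps
layout <- generate_layout(design)
#> Field layout: 24 plots over 8.0 x 9.0 m

truth  <- simulate_trajectories(layout, growth_config(), seed = 1)
day100 <- truth[truth$day == 100, ]
cloud  <- generate_field_cloud(layout, day100, cloud_config(), seed = 2)
#> Point cloud: 20454 points, with colors, labeled (10854 ground / 9600 canopy)

ground <- estimate_ground(cloud)
pred   <- segment_geometric(cloud, ground)
segmentation_metrics(pred, cloud$labels)
#> precision 99.44  recall 100.00  F1 99.72  mIoU 99.47 (percent)

cloud$labels <- pred
heights <- plot_heights(cloud, layout, ground, day = 100)
agree <- height_agreement(heights$height_cm,
                          day100$true_height_cm[match(heights$plot_id, day100$plot_id)])
#> R2 = 0.999, RMSE = 0.80 cm over 24 plots
```

The segmenter labels 99.4%+ of points correctly and the recovered plot
heights track the generator's truth to better than a centimeter. The
same trajectories, averaged per treatment and fitted, give the six
dynamic traits:

```r
series <- transform(truth, value = true_height_cm)
trait_table(series, grouping = "treatment")
#>   treatment v_max  v_md v_srg v_erg v_drg   v_gr
#> 1        N0 79.01 160.5 52.44 142.5  90.1 0.4229
#> 2      N180 94.28 161.0 34.46 140.0 105.5 0.5000
#> 3      N240 94.18 161.7 33.55 140.4 106.9 0.5033
```

Height peaks near 160 DAS in all treatments, the fertilized treatments
top out ~15 cm above the control, and their rapid-growth window opens
earlier and runs longer — the seasonal anatomy the generator encodes,
recovered end to end. `run_pipeline(default_field_config())` chains all
six stages (simulate → segment → heights → vi → dynamics → gwas) and
writes a manifest of artifacts with checksums.

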