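# fundustex

Dual-framework analysis of color retinal fundus photographs in R:

1. **Vascular texture** — the retinal vessel tree is segmented (oriented
   matched filtering + isodata thresholding, after CLAHE and median
   preprocessing) and profiled with eight Haralick features of the 16-level
   gray-level co-occurrence matrix (GLCM), averaged over the four standard
   orientations (0°, 45°, 90°, 135°, distance 1).
2. **Global color distribution** — per-channel 256-bin RGB histograms of
   the full fundus area, group averages, bivariate (joint) channel
   histograms, and Mahalanobis separability of groups in histogram space.

Both layers feed a statistical comparison engine (two-sample
Kolmogorov–Smirnov for texture features, Wilcoxon–Mann–Whitney per color
channel, Lilliefors normality checks, μ±σ group tables). The target use is
the contrast between healthy retinas and retinas with reduced vascular
complexity (diabetic retinopathy, glaucoma): pathology shows up as *higher*
GLCM energy, *lower* correlation/variance/sum average/sum variance/sum
entropy/entropy, and chromatic shifts concentrated in the green and blue
channels.

Because clinical databases cannot ship with a package, `fundustex` includes
a seeded **synthetic fundus cohort generator** (branching random-walk
vessel trees with ground-truth masks on a reddish circular field) whose
presets reproduce exactly those contrasts; every stage of the pipeline is
tested against it offline.

## The core quantities

For a quantized image (levels 1..N), the GLCM `P(i, j)` is the normalized
count of level pairs at offset `(π_x(d, θ), π_y(d, θ))`. The eight
features: energy `ΣP²`, contrast `Σ(i−j)²P`, correlation
`Σ((i−μx)(j−μy)/σxσy)P`, variance `Σ(i−μx)²P`, sum average `Σ k P_{x+y}(k)`,
sum variance `Σ(k−μ_{x+y})² P_{x+y}(k)`, sum entropy, entropy (base-2 logs,
`0·log 0 = 0`). Segmentation quality is scored with the Dice coefficient
`2|A∩B|/(|A|+|B|)`; group separability with
`D = sqrt((μA−μB)ᵀ Σ⁺ (μA−μB))` using an eigenvalue-truncated pseudo-inverse
of the pooled covariance (the clouds live in 256·channels dimensions with
~15 points each).

## Worked example

```r
library(fundustex)
report <- run_synthetic_study(presets = c("healthy", "pathological"),
                              seed = 42, n_images = 6)
print(report)
#> <study_report>
#>   groups: healthy, pathological
#>   images: 12
#>   feature summary rows: 16
#>   mean Dice: 0.721
subset(report$feature_summary, feature %in% c("energy", "entropy", "variance"))
#>   feature        group n  mean      sd ks_statistic   ks_p
#>    energy      healthy 6 0.809 0.01140           NA     NA
#>    energy pathological 6 0.892 0.00545            1 0.0013
#>  variance      healthy 6 1.523 0.17642           NA     NA
#>  variance pathological 6 0.770 0.06488            1 0.0013
#>   entropy      healthy 6 0.887 0.05326           NA     NA
#>   entropy pathological 6 0.507 0.02102            1 0.0013
report$mahalanobis
#>                     pair  channel distance
#>  healthy vs pathological        R     2.01
#>  healthy vs pathological        G    53.19
#>  healthy vs pathological        B    54.90
#>  healthy vs pathological combined    24.09
```

Reading the numbers: the synthetic pathological cohort has sparser/thinner
vessels, so its masked-vessel texture is more uniform — energy is higher
(0.892 vs 0.809) while variance and entropy are lower, each with a
significant two-sample KS p-value (n = 6 per group here). The chromatic
shift injected only into G and B makes the green/blue Mahalanobis
distances (53.2, 54.9) dwarf the red one (2.0). The Dice column scores the
segmentation against the generator's ground-truth masks.

Real images are analyzed the same way from a manifest CSV
(`file,group[,mask_file][,fov_file]`):

```r
report <- run_study("manifest.csv", config = study_config(), out_dir = "report/")
```

A command-line front end is installed as `exec/fundustex`
(`fundustex simulate|run|segment|texture|color ...`); presets live in
`inst/presets/*.yaml`.

## Package layout

- `R/synthetic.R` — cohort specs, presets, vessel-tree growth, rendering
- `R/preprocess.R` — grayscale, CLAHE, median filtering
- `R/segmentation.R` — matched filter, isodata threshold, Dice
- `R/glcm.R` — quantization, co-occurrence matrices, Haralick features
- `R/color.R` — channel/bivariate histograms, Mahalanobis separability
- `R/stats.R` — KS, rank-sum, Lilliefors, group summaries
- `R/pipeline.R`, `R/cli.R` — study orchestration and CLI
- `src/filters.cpp` — convolution, median filter, connected components
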