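# darcspot

Automated labeling and counting of fluorescently labeled apoptosing
retinal cells in DARC images (Detection of Apoptosing Retinal Cells: in
vivo confocal scanning laser ophthalmoscopy of Annexin V–labeled retinal
ganglion cells). Apoptosing cells appear as small bright spots on a
retinal background whose luminance and contrast drift across the field;
counting them manually takes minutes per image and varies between
operators. `darcspot` is for researchers who need reproducible,
operator-independent counts from such images — and a way to validate the
counter without clinical data.

## The method

The pipeline has two stages with five fixed parameters.

**Stage 1 — pre-processing.** Each pixel is converted to a local
z-score using Gaussian-weighted local statistics of scale *s*:

    mu = G_s ⊗ I,  sigma = sqrt(G_s ⊗ I² − mu²),  Z = (I − mu) / sigma

which flattens slowly varying luminance/contrast structure. *Z* is then
convolved with a Laplacian-of-Gaussian band-pass filter of scale *u*
(sign-flipped so bright blobs respond positively). Defaults: *s* = 64 px,
*u* = 1.5 px (for 600-pixel-square images).

**Stage 2 — cell identification.** The response is thresholded at
*T* = mean + *k*·SD over the whole image (*k* = 1.8); connected
components of the surviving pixels are measured (area *A*, centroid,
moment-equivalent-ellipse axes L_maj, L_min) and classified by fixed
rules, in order:

* *A* < *A*_min (9.0 px²) → **noise**
* L_maj / L_min > *Aspect*_min (3.0) → **vessel**
* otherwise → **cell**

The package also provides the pre-analysis geometry (crop, bilinear
resize to 600 px square), a seeded synthetic DARC-like image generator
with ground truth (including the documented failure modes: dim small
spots, aberration-elongated spots, heavy granularity, strong luminance
gradients), overlay rendering, batch CSV output, and the method-agreement
statistics used to compare automated with manual counts (Pearson r/R²,
ICC with 95% CI, Cronbach's alpha, paired t, percent-difference
Bland–Altman limits of agreement).

## Worked example

```r
library(darcspot)

# a 280-px synthetic scene with 25 spots at realistic density
spec <- synthetic_spec(height = 280, width = 280, n_cells = 25, seed = 7)
sim  <- generate_image(spec)

det <- detect_cells(sim$image)
det
#> <darc_detection> 280 x 280 image: 42 blobs (25 cells, 0 vessels, 17 noise)

glance(det)
#> # A tibble: 1 × 6
#>   n_cells n_vessels n_noise n_blobs height width
#> 1      25         0      17      42    280   280

score_detection(det, sim)
#> # A tibble: 1 × 6
#>   precision recall count_error n_matched n_detected n_true
#> 1         1      1           0        25         25     25

head(tidy(det), 3)
#> # A tibble: 3 × 8
#>   label_id  area l_maj l_min aspect centroid_row centroid_col class
#> 1        1     1  1.15  1.15   1            241           6   noise
#> 2        2    47  8.26  7.37   1.12         156.         14.2 cell
#> 3        3    43  7.78  7.15   1.09         265.         28.9 cell
```

All 25 spots are recovered as cells (precision and recall 1, count error
0); the 17 sub-9-px² blobs from background granularity are classified as
noise and excluded from the count. `autoplot(det)` draws the labeled
image; `render_overlay()` + `write_image()` export the green
(cell) / red (non-cell) overlay PNG.

Comparing methods on a count table (one row per image, one column per
method):

```r
rep <- agreement_report(counts, automated = "automated")
rep
#> <agreement_report> 8 images; automated = `automated`, gold = `mean_manual`
#> automated vs mean_manual: r = 1.000 (R2 = 1.000), ICC = 0.999 [0.998, 1.000], alpha = 1.000
#>   paired t p = 0.7732; Bland-Altman bias 0.44%, LoA [-1.59%, 2.47%]
#> inter-operator RM-ANOVA p = 0.7435
```

`tidy(rep)` returns the full pairwise statistics table, `glance(rep)`
the headline row, `autoplot(rep)` the Bland–Altman plot.

## Command line

A thin CLI over the same functions lives at `inst/cli/darc.R`:

```sh
Rscript inst/cli/darc.R run image1.png image2.tif --crop 1,1,560,600 \
    --csv counts.csv --overlay overlays/
Rscript inst/cli/darc.R simulate --n-images 5 --cells 126 --seed 1 --out sims/
Rscript inst/cli/darc.R evaluate counts.csv --report agreement.json
```

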