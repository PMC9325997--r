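# eigenimage

Contrast enhancement for multichannel wide-field fluorescence acquisitions
of composite hard/soft tissue, built around a *spectral PCA* (sPCA): a
principal component analysis in which each emission channel — flattened
row-major into a pixel-length vector — is one observation, and pixels are
the features. The leading principal axes are reshaped back into
**eigen-images** and merged into an RGB false-color composite that
delineates tissue boundaries (tooth root, alveolar bone, periodontal
ligament, gingiva) better than any single raw channel shows them.

## Who this is for

Groups doing macro- or mesoscale fluorescence imaging of mineralized +
soft tissue with a filter-wheel acquisition (a handful of co-registered
emission channels: here blue, green, red, NIR), who want a reproducible,
parameter-explicit rendering step between acquisition and histological
interpretation.

## The method

For a cube of k co-registered channels with p = height × width pixels,
each channel is preprocessed along one of two parallel branches and then
median-filtered (size 4):

* **Std** — each image row is standardized to mean 0 and unit population
  standard deviation along the x-axis;
* **Clahe** — contrast-limited adaptive histogram equalization
  (clip limit 12.0, 10 × 10 tile grid, 256 bins, bilinear interpolation of
  tile mappings).

The k × p matrix **X** of flattened channels is centered per pixel,
**X**ᶜ = **X** − **1**μᵀ, and decomposed exactly via the k × k Gram matrix
**X**ᶜ**X**ᶜᵀ = **U**Λ**U**ᵀ; the pixel-space axes **v**ᵢ =
**X**ᶜᵀ**u**ᵢ/√λᵢ are reshaped into eigen-images, with explained variance
ratios λᵢ/Σλ. Three components are retained (centering k = 4 observations
leaves rank ≤ 3, so they carry all the variance), min–max normalized to
[0, 255], and assigned to red, green, blue.

A synthetic tissue-phantom generator (labeled regions, per-tissue
spectral signatures, dye crosstalk, autofluorescence background, Poisson +
Gaussian noise) and a between/within-class scatter separability score make
every claim testable without real data. See the methods vignette
(`vignettes/spectral-pca-workflow.Rmd`) for the model, conventions and
limitations.

## Worked example

```r
library(eigenimage)

ph  <- generate_phantom(phantom_spec(height = 192, width = 256, seed = 7))
ph$cube
#> <spectral_cube> 4 channels (blue, green, red, nir), 192 x 256

res <- run_pipeline(ph$cube)   # defaults: clip 12.0, grid 10x10, median 4, 3 PCs
res$std$eigen
#> <eigen_image_set> branch 'std', 3 components, 192 x 256
#> explained variance ratio: 0.7912 0.1922 0.0166

glance(res$std$eigen)
#> # A tibble: 1 × 6
#>   branch n_components evr_1 evr_2  evr_3 evr_total
#>   <chr>         <int> <dbl> <dbl>  <dbl>     <dbl>
#> 1 std               3 0.791 0.192 0.0166         1

separability(res$std$composite, ph$labels)
#> <separability_report> 5 classes, 3 plane(s), score 1.3324
```

The three explained-variance ratios sum to 1 because centering four
channel observations leaves at most three dimensions of variance; PC1
(79.1%) carries the dominant tissue contrast. `tidy(res$std$eigen)` gives
the per-channel loadings of each component, `autoplot(res$std$composite)`
renders the false-color image, and `write_composite()` persists it as
8-bit TIFF/PNG. The separability score is the ratio of between-class to
pooled within-class scatter of the composite's planes over the phantom's
ground-truth labels.

A command-line front end wrapping the same functions ships in
`inst/cli/eigenimage.R` with `run`, `phantom` and `score` subcommands.

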