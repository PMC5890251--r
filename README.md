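# emtort

Quantifying the tortuosity of the epithelial–mesenchymal border in
two-phase tissue images — the 2-D surface-area proxy used to show that
feather branching *reduces* the epithelial surface area once the basal
keratinocytes retract their filopodia.

## The problem

Before a feather follicle branches, each basal keratinocyte extends 3–5
filopodia (2–10 µm long) into the mesenchyme, so the epithelial–mesenchymal
(E-M) border in a section is a densely fringed curve. After branching the
border is smooth. The geometric summary is the border's **tortuosity**

    λ / d

where λ is the arc length of the E-M border across the field of view and d
the straight-line distance between its endpoints. Pre-branch borders have
λ/d around 5–16 (mean ≈ 11); post-branch borders around 4–8 (mean ≈ 6) —
so, counter-intuitively, total surface area *drops* by roughly half at
branching. Because the border is rough at the filopodium scale, λ depends
on the measurement scale (the coastline effect), which makes the pixel
calibration part of the measurement.

`emtort` implements the full measurement chain:

1. **`synthetic phantoms`** (`phantom_spec()`, `generate_border()`,
   `rasterize_phantom()`, `make_dataset()`, `ratio_phantom_spec()`) —
   two-phase images whose border geometry (filopodia-fringed pre-branch vs
   smooth lobed post-branch) is known as an exact polyline, with seeded
   noise and optional intensity-inhomogeneity (bias) fields;
2. **segmentation** (`acm_params()`, `acm_segment()`, `acm_evolve()`,
   `acm_energy()`, `acm_gradient()`) — a region-based active contour whose
   energy combines Chan–Vese global fitting, Gaussian-kernel local binary
   fitting (for bias robustness), and contour-length regularization, with
   regularized Heaviside/Dirac factors
   `H_ε(x) = ½(1 + (2/π) arctan(x/ε))`, `δ_ε(x) = (1/π) ε/(ε²+x²)`,
   minimized by fixed-step gradient descent on the level-set field;
3. **measurement** (`extract_border()`, `curve_length()`,
   `linear_distance()`, `tortuosity()`) — subpixel zero-level contour
   extraction, clipped to an ROI, returning λ, d, λ/d in micrometers;
4. **comparison** (`compare_groups()`, `run_full()`) — two-tailed t-test
   between the pre and post groups, percent decrease, and an end-to-end
   pipeline with manifest and CSV/JSON outputs.

The methods vignette (`vignettes/tortuosity-methods.Rmd`) documents the
model, every numerical choice, and the limits of what the synthetic
validation shows.

## Worked example

```r
library(emtort)

# one pre-branch phantom: ground truth, image, segmentation, measurement
sp  <- phantom_spec("pre_branch", seed = 11)
tr  <- generate_border(sp)          # exact border polyline + lambda, d
ras <- rasterize_phantom(tr, sp)    # 200 x 300 px image at 0.2 um/px
seg <- acm_segment(ras$image, acm_params())
rec <- tortuosity(extract_border(seg$phi, sp$pixel_size_um))

c(analytic = tr$ratio, measured = rec$ratio, dice = dice(seg$mask, ras$mask))
#> analytic measured     dice
#> 7.828101 7.265208 1.000000
```

The measured λ/d sits a few percent below the analytic truth — the
subpixel filopodium tips are not representable in the raster — and the
error shrinks as the pixel size does (see the vignette's resolution
discussion).

The full experiment (10 phantoms per group, as in a ten-follicle analysis):

```r
out <- run_full(list(n_pre = 10, n_post = 10, seed = 1))
print(out$comparison)
#> lambda/d pre : mean 8.8 (sem 0.42, range 6.54-10.5, n=10)
#> lambda/d post: mean 5.33 (sem 0.12, range 4.64-5.94, n=10)
#> percent decrease: 39.4%
#> two-sample t (pooled variance, two-tailed): t = 7.89, df = 18, p = 2.98e-07
```

The pre-branch group's fringed borders carry substantially more border
length than the post-branch group's smooth lobed ones — the measured λ/d
drops by about 40% (the analytic drop is slightly larger; the sharpest
filopodia lose a few percent of λ to the raster) — with p ≪ 0.01 at
n = 10 per group, reproducing the direction and strength of the
surface-area decrease at branching.

The same analysis as a scripted workflow:

```sh
Rscript analysis/01_simulate.R         # phantoms + ground truth -> results/phantoms/
Rscript analysis/02_segment_measure.R  # segmentation + lambda/d  -> results/tortuosity_records.csv
Rscript analysis/03_compare_groups.R   # group t-test             -> results/comparison.json
Rscript analysis/04_resolution_study.R # recovery error vs pixel size
```

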