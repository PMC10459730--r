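# leafspec

Chemometric quantification and mapping of leaf photosynthetic pigments —
chlorophyll a (Chla), chlorophyll b (Chlb), total chlorophylls
(Chls = Chla + Chlb) and total carotenoids (Cars), in mg/L — from
visible–near-infrared hyperspectral reflectance (646 bands, 430–900 nm).

The package is aimed at plant-phenotyping and chemometrics researchers
who want a fully scripted, testable version of the standard
imaging-spectroscopy pipeline:

1. **Calibration** — white/dark reflectance correction
   `R = (R0 − Rb)/(Rw − Rb)`; ENVI-style cube I/O (BSQ/BIL/BIP).
2. **ROI harvesting** — elliptical regions
   (`xi²/a² + yi²/b² ≤ 1`) pooled into per-sample mean spectra.
3. **Reference chemistry** — ethanol-extract absorbances to
   concentrations: `Chla = 13.95·A665 − 6.88·A649`,
   `Chlb = 24.96·A649 − 7.32·A665`, `Chls = Chla + Chlb`,
   `Cars = (1000·A470 − 2.05·Chla − 114.8·Chlb)/245`.
4. **Pretreatment** — Savitzky–Golay smoothing, standard normal
   variate, and SG+SNV.
5. **Partitioning** — SPXY (joint X–Y distance Kennard–Stone),
   deterministic, `floor(0.75·N)` calibration samples
   (435 → 326/109).
6. **Modelling** — NIPALS PLSR with seeded k-fold cross-validation;
   metrics R², RMSE and RPD = sd(ref)/RMSE (>2 "good").
7. **Coarse–fine wavelength selection** — CARS (Monte Carlo sampling,
   exponentially decreasing retention `r_j = a·e^(−bj)` with
   `a = (p/2)^{1/(N−1)}`, `b = ln(p/2)/(N−1)`, adaptive reweighted
   sampling, RMSEcv-scored) followed by IRIV (balanced binary
   submodels, Mann–Whitney classification into
   strong/weak/uninformative/interfering, iterated elimination,
   backward elimination).
8. **Visualization** — pixel-wise inversion of the fitted affine model
   onto leaf cubes, enhanced Lee despeckling (3×3, damping 1, CV zones
   0.52/1.73), blue→red pseudo-colour maps (plain-text PPM).

Because no public dataset exists for this workflow, a synthetic
hyperspectral leaf generator (`generate_dataset()`,
`generate_cube()`, `generate_planted_support()`) is a first-class,
tested module; every stage runs end-to-end without downloads. See the
methods vignette (`vignettes/leafspec-methods.Rmd`) for the forward
model, noise calibration and known limitations.

## Worked example

```r
library(leafspec)

ds <- generate_dataset(sim_config(seed = 1))        # 435 x 646
model <- fit_pigment_model(ds$spectra, ds$pigments$Chla, ds$wavelengths,
                           recipe = "sg+snv", selector = "cars-iriv",
                           N = 60, m = 60, seed = 1, pigment = "Chla")
round(unlist(model$metrics$prediction[c("R2", "RMSE", "RPD")]), 3)
#>    R2  RMSE   RPD
#> 0.890 1.268 3.031
format_percent(length(model$band_indices), 646)
#> [1] "1.08% (7/646)"
```

Read: on the synthetic prediction set the coarse–fine model explains
89% of the variance with an RPD of 3.0 ("good" by the >2 rule), using
7 of 646 wavelengths. The synthetic world's pigment signal is rank-one
per pigment, so very few bands suffice; on real data the selected
counts are typically 10–20.

```r
cmap <- matrix(0, 14, 18); cmap[3:12, 2:8] <- 6; cmap[3:12, 10:17] <- 18
cube <- generate_cube(sim_config(seed = 1), cmap)    # raw + white/dark
map  <- invert_pixels(cube$reflectance, model, cube$mask)
map  <- enhanced_lee(map)
render_pseudocolor(map, "chla_map.ppm")$mean_concentration
#> [1] 12.35127
```

The rendered map shows the 6 vs 18 mg/L regions in blue vs red; the
returned mean is the foreground average concentration.

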