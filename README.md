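# tidemark3d

Reconstruction and cross-modality comparison of the three-dimensional
**tidemark** — the interface between noncalcified articular cartilage and the
calcified cartilage zone — from high-frequency ultrasound B-scan stacks and
micro-CT volumes. The package is aimed at quantitative cartilage imaging
work: validating that a 25 MHz B-mode scan of an osteochondral specimen
recovers the same interface geometry as the micro-CT reference, and
quantifying that interface's waviness, roughness, and en face appearance.

Because paired scans of real osteochondral disks are not freely
distributable, the package includes a synthetic phantom generator that
produces paired US/CT volumes from a known analytic ground-truth surface
(plane + low-frequency waviness + band-limited roughness, with speckle,
cracks, perforation channels, a CT tilt and a rigid inter-modality offset).
Every stage of the pipeline is tested against that ground truth.

## The method

1. **US extraction** — noise level from the saline region
   (mean + 3 SD), then per B-scan line the first peak above the noise level
   in a 20-pixel (~0.30 mm) window centred on a coarse manual profile;
   echo-free (crack) lines are interpolated from neighbours.
2. **CT extraction** — small-angle tilt correction, global Otsu
   binarization, first abrupt background-to-bone change per vertical line,
   hole interpolation.
3. **Registration** — coarse lateral alignment, then rigid point-to-point
   ICP (SVD fit, 0.01 µm iteration-difference stopping rule) of the US
   point cloud onto the triangulated CT surface, and the mean surface
   discrepancy

   $$D_\mathrm{diff} = \frac{1}{N}\sum_{i=1}^N d\!\left(p_{\mathrm{US},i},\, s_{\mathrm{CT}}\right),$$

   the average unsigned point-to-mesh distance.
4. **Smoothness** — areal indices
   $S_a = \frac{1}{MN}\sum_{i,j}\lvert s_{ij}-SR_{ij}\rvert$ and
   $S_q = \sqrt{\frac{1}{MN}\sum_{i,j}(s_{ij}-SR_{ij})^2}$ against a
   first-order polynomial reference (waviness SWa/SWq) and a fifth-order
   reference (roughness SRa/SRq), with Pearson correlation reports across a
   cohort.
5. **En face imaging** — the volume flattened relative to the extracted
   tidemark and projected over a configurable slab by maximum or average
   intensity (MIP/AIP).

See `vignettes/tidemark-methods.Rmd` for the full model description,
parameter defaults, and numerical choices.

## Worked example

One synthetic disk, simulated and pushed through the whole pipeline:

```r
library(tidemark3d)

params <- synth_params(field_size_mm = 3, seed = 11,
                       waviness_amplitude = 120, roughness_amplitude = 30)
res <- run_disk_pipeline(params, pipeline_config(icp_trim = 0.9, ct_mad_k = 4))

res$icp
#> <icp_result> 11 iterations, final RMS 13.7828 um, converged: TRUE
c(res$discrepancy$d_diff, res$discrepancy$sd)
#> [1] 6.484575 5.814856
res$panel_us
#>        SWa      SWq      SRa      SRq
#> 1 63.34524 81.67524 24.29026 30.48727
res$panel_ct
#>       SWa      SWq      SRa      SRq
#> 1 62.8142 80.74937 24.85155 32.05243
```

Reading: the US tidemark cloud registers onto the micro-CT reference with a
mean surface discrepancy of 6.5 ± 5.8 µm — a fraction of the coarsest
sampling step (32 µm) — and the two modalities report nearly identical
waviness (~63 µm SWa, driven by the 120 µm undulation of this disk) and
roughness (~24–25 µm SRa, from the 30 µm RMS texture).

The numbered scripts under `analysis/` run the same steps as a narrative
workflow on a full 7 × 7 mm disk (220 B-scans of 15 µm pixels, 21 µm CT) and
on a 15-disk cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # phantom volumes + ground truth
Rscript analysis/02_extract_surfaces.R  # both tidemark surfaces
Rscript analysis/03_register.R          # ICP + D_diff
Rscript analysis/04_smoothness_cohort.R # 15-disk panels + correlations
Rscript analysis/05_enface.R            # MIP/AIP slab images
```

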