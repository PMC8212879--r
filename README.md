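# shgmetrics

Collagen architecture metrics from second-harmonic generation (SHG)
microscopy, for quantitative comparison of fibrotic tissue models (e.g.
3D lung-fibroblast spheroids under collagen-crosslink modulation).

SHG microscopy probes fibrillar collagen label-free, and polarization-
resolved variants read out structure well below the diffraction limit.
This package implements the full metric suite such a study needs, driven
either by measured TIFF stacks or by a built-in synthetic-image generator
with known ground truth:

- **P-SHG pixel fitting** — per-pixel bounded nonlinear least squares of
  the angular response of the cylindrically symmetric χ⁽²⁾ model,

  I(θ) = A·{sin²[2(θ−φ)] + [sin²(θ−φ) + b·cos²(θ−φ)]²} + c,

  giving the tensor ratio b = χ_ZZZ/χ_ZXX and the effective α-helical
  pitch angle θₚ = arctan√(2/b) (45° at b = 2).
- **SHG signal anisotropy** — β(θ) = (I∥ − I⊥)/(I∥ + 2·I⊥) from
  parallel/perpendicular analyzed channels; 1 = perfectly aligned dipole
  moments, 0 = random, −0.5 = analytic lower bound.
- **SHG circular dichroism** — |I_LHCP − I_RHCP| / [(I_LHCP + I_RHCP)/2]
  per pixel over a noise-background threshold mask, in [0, 2].
- **Depth attenuation / relative conversion efficiency** — self-normalized
  intensity-vs-depth profiles of z-series with linear slope and
  exponential coefficient μ; profile ratios at a query depth compare
  conversion efficiency between samples.
- **Fiber morphology** — per-fiber length, width and straightness
  (endpoint chord / arc length) via a ridge/skeleton extractor
  (multiscale Hessian ridge filter → hysteresis → thinning → branch
  decomposition).
- **Group statistics** — one-way ANOVA with post hoc two-tailed Student's
  t-tests implemented from sums of squares, plus crosslink-per-collagen
  normalization from hydroxyproline content (300 Hyp and 300 kDa per
  triple helix).

Images travel as multi-page grayscale TIFFs with a small YAML sidecar
describing the acquisition geometry (`read_stack()`/`write_stack()`);
all tabular outputs are CSV.

## Worked example

```r
library(shgmetrics)

scene <- synthetic_scene(b_true = 2, phi_deg = 30, amplitude = 1000,
                         noise = "poisson", seed = 42, dim = c(32, 32))
stack <- gen_pshg_stack(scene)
fit   <- fit_pshg(stack)
fit
#> P-SHG pixel fit: 18 angles, 1024 of 1024 pixels valid
#>   b: median 2.004  phi: median 30.01 deg  r2: median 0.998
pitch_map(fit)
#> Pitch-angle map: mean 44.958 deg, SEM 0.00471 over 1024 valid pixels

cd_field(gen_chiral_pair(scene))
#> SHG-CD: mean 0.3138, sum 287.4 over 916 masked pixels (threshold 0.9369)

depth_profile(gen_depth_series(scene, n_sections = 9, z_step_um = 10))
#> Attenuation profile: 9 sections, z = 0..80 um
#>   slope = -0.0068917 1/um, mu = 0.010096 1/um (window 0..80 um)
```

The fit recovers the injected tensor ratio (b = 2 → 45° pitch) to a small
fraction of a percent under Poisson noise at 1000 peak counts, and the
attenuation coefficient (0.01/µm injected) to ~1 %. The SHG-CD mean
(0.314) sits above the injected asymmetry (0.2) because |L − R| of two
Poisson variates is positively biased at finite counts — the shot-noise
floor discussed in the methods vignette; it vanishes as counts grow and
is exactly 0.2 in the noise-free case.

A full four-group study (simulate → analyze → ANOVA + post hoc report):

```r
cfg <- study_config(n_per_group = 3, seed = 1)
man <- simulate_study(cfg, "study")
res <- run_pipeline(man, "report")
res$anova
```

A thin command-line wrapper with subcommands (`simulate`, `fit-pshg`,
`anisotropy`, `shg-cd`, `attenuation`, `fibers`, `stats`) is installed at
`inst/cli/shgtool.R`.

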