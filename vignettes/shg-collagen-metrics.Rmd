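---
title: "Models and methods behind shgmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shgmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shgmetrics)
```

shgmetrics quantifies collagen architecture from second-harmonic
generation (SHG) microscopy across three size scales: the effective
peptide helix (polarization-resolved pixel fitting), the fibril
(signal anisotropy, circular dichroism) and the fiber (morphology,
depth attenuation). This vignette explains the models, the tunable
parameters and their defaults, what the synthetic generator does and
does not emulate, and the numerical choices that matter.

## The P-SHG pixel model

Collagen fibrils behave as cylindrically symmetric (C∞v) harmonophore
assemblies. Under Kleinman symmetry the χ⁽²⁾ tensor reduces to two
independent elements, and the SHG intensity as the excitation linear
polarization θ rotates is

$$I(\theta) = A\left\{\sin^2[2(\theta-\varphi)] +
  \left[\sin^2(\theta-\varphi) + b\,\cos^2(\theta-\varphi)\right]^2
  \right\} + c,$$

with $b = \chi_{ZZZ}/\chi_{ZXX}$ the tensor ratio, $\varphi$ the
in-plane fiber orientation, $A$ an amplitude and $c$ an additive
offset. This specific functional form is the single most consequential
modeling choice in the package: the literature's "generic model" family
admits variants (complex tensor elements, non-Kleinman terms, out-of-
plane tilt), and we deliberately adopt the canonical real-valued
in-plane form, which is consistent with a single-ratio readout. The
tensor ratio converts to the effective α-helical pitch angle

$$\theta_p = \arctan\sqrt{2/b},$$

strictly decreasing in $b$, with $b = 2 \mapsto 45°$. Whether a
per-pixel offset was used in comparable published fits is usually
unstated; $c$ is included by default and can be pinned to zero with
`fit_offset = FALSE`.

### Fitting

$A$ and $c$ enter the model linearly, so for any $(b, \varphi)$ they
are profiled out by linear least squares (with the amplitude clamped
nonnegative). The nonlinear search therefore runs over $(b, \varphi)$
only, using bounded Levenberg–Marquardt (`minpack.lm`), $b \in
(0.05, 10]$. Initialization comes from the discrete Fourier
$\cos 2\theta/\sin 2\theta$ phase of the angular response (which pins
$\varphi$ up to the 180°-periodic landscape's symmetries) and the
heuristic $b_0 \approx \sqrt{I_{max}/I_{min}}$; the four phase
candidates $\varphi_0 + \{0°, 45°, 90°, 135°\}$ are ranked by profiled
residual and the best few refined. On noise-free synthetic input the
fit recovers $(b, \varphi, A, c)$ to machine precision, and on 20
random instances it matches an exhaustive coarse-to-fine grid search
(resolution 0.001) within the grid resolution.

One identifiability caveat: at exactly $b = 1$ the bracketed term is
constant and the model becomes 90°-periodic, so $\varphi$ and
$\varphi + 90°$ produce identical curves. The fitter returns one of
the two; tests compare orientations modulo 90° at $b = 1$.

Per-pixel validity requires (i) mean intensity over angles at or above
`min_mean_intensity` (default 0 — every pixel with signal; pass a
background-derived threshold for measured data), (ii) nonzero angular
modulation (an angle-uniform response has no defined $\varphi$ and is
masked rather than assigned an arbitrary one), and (iii) $r^2 \ge$
`r2_min` (default 0.5). Summaries are mean ± standard error over the
valid mask.

## Signal anisotropy

From parallel/perpendicular analyzed channels,
$\beta = (I_\parallel - I_\perp)/(I_\parallel + 2 I_\perp)$: 1 for
perfectly aligned dipole moments, 0 for random, −0.5 the analytic
lower bound. The package aggregates the *per-pixel* β (mask-mean per
excitation angle), not the β of summed intensities — the two differ
under spatial heterogeneity, and the pixel-based convention matches
how such maps are reported. Negative aggregated values are reported,
never clipped: near the orthogonal excitation angle, low-count
subtraction noise genuinely drives pixel β below zero, and that
behavior is part of the readout.

Masking defaults to "denominator > 0". The optional `threshold =
"auto"` rule (darkest-decile mean + 3 SD) exists for measured images
with true background; it is not the default because on synthetic
uniform fields — where every pixel carries signal — a background rule
estimated from the image itself would discard everything.

## Circular dichroism

Per pixel, $\mathrm{CD} = |L - R| / [(L + R)/2] \in [0, 2]$, absolute
values throughout because the sign depends on fiber orientation. The
mask keeps pixels whose average intensity exceeds the background mean
+ `k_sigma`·SD (darkest-decile estimate by default, or an explicit
background region). Both the mask-mean (intensity-independent, the
primary scalar) and the mask-sum are reported, since "integrated" and
"per-pixel" conventions coexist in the literature and silently
choosing one would make results incomparable.

Shot-noise floor: $|L - R|$ of two Poisson variates is positively
biased, so at finite counts the mean CD of an achiral field is
positive and decreases as counts grow (a documented, tested property).
Group comparisons should therefore be made at matched intensities.

## Depth attenuation

Section means are computed over a foreground mask estimated once on
the brightest section (background mean + 3 SD of the darkest decile)
and applied to every section — re-selecting the mask per section
biases the decay estimate under noise. The profile is self-normalized
by a robust peak: the maximum of a 3-point running median of the
section means (endpoints kept). A running median tolerates a single
aberrant bright section yet is exact for monotone decay, which a
3-point moving average is not (it would shrink the peak and shift
every normalized value). Both readouts are fitted from the peak
section to the deepest one: the linear slope of the normalized profile
(the conventional "attenuation slope") and the exponential coefficient
μ from a log-linear fit (primary for simulation recovery; exact on
noise-free input, within 5 % at the tested Poisson noise levels).
`relative_efficiency()` interpolates two normalized profiles at a
query depth and returns their ratio.

## Fiber morphology

The extractor replaces curvelet-based fiber extraction with a fully
specified pipeline: median background subtraction (radius
`bg_radius_px`) → multiscale ridge enhancement (magnitude of the most
negative Hessian eigenvalue of the Gaussian-smoothed image, σ²-
normalized, max over `scales_px`) → hysteresis binarization (growth of
the high-threshold seeds through the low mask, 8-connected) →
Zhang–Suen thinning → branch decomposition at junction pixels. A
junction is a skeleton pixel with crossing number ≥ 3 (0→1 transitions
around its 8-neighborhood); a plain neighbor count would misclassify
diagonal staircase pixels and fragment every oblique fiber. Branches
are not merged across junctions (conservative; crossing fibers
fragment, and the tests on crossing phantoms assert total length, not
count).

Metrics per branch: arc length of the centerline after smoothing with
a 5-point moving average (raw pixel chains inflate diagonal lengths by
~8 % through staircasing); straightness = endpoint chord / arc length,
capped at 1; width = 2 × the distance transform of a per-branch
half-maximum intensity mask, sampled along the middle 80 % of the
centerline (endpoints excluded to avoid cap bias). The half-maximum
mask is used for width — rather than the hysteresis mask — because the
hysteresis thresholds are deliberately permissive fractions of the
ridge response and overestimate physical width by over a pixel,
whereas the FWHM of a blurred bar profile matches its true width.
Branches shorter than `min_length_um` (default 5 µm) are pruned.

On phantoms the extractor recovers straight-fiber length within 5 %,
straightness ≥ 0.99, width within half a pixel, semicircle
straightness within 0.03 of 2/π, and is rotation-invariant within 2 %.

## Group statistics and crosslink normalization

One-way ANOVA ($F = MS_{between}/MS_{within}$, $(k-1, N-k)$ df) and
post hoc two-tailed two-sample Student's t-tests (pooled variance;
Welch behind a flag) are computed from sums of squares and the
distribution CDFs directly, so every intermediate is inspectable; the
test suite cross-checks them against `aov()` and `t.test()`. "Two-way
Student's t-tests" in the source protocol is read as two-*tailed*
two-sample tests. No multiple-testing correction is applied by default
(matching the protocol); Holm is available via `adjust = "holm"`.
Star thresholds are configurable (default * < 0.05, ** < 0.01,
*** < 0.001, **** < 1e-4) because published caption conventions vary.
Degenerate cases are defined, not errors: zero pooled variance with
equal means gives t = 0, p = 1; with unequal means an infinite-t flag.

Crosslink normalization: collagen (nmol) = Hyp (nmol)/300, collagen
(µg) = collagen (nmol) × 300 (300 kDa per triple helix), crosslink
density = (PYD+DPD)/collagen, mol/mol, undefined (flagged) at zero
hydroxyproline.

## The synthetic generator

`synthetic_scene()` fixes ground truth for every acquisition geometry:
P-SHG stacks evaluate the forward model exactly; channel pairs split
the total intensity so the noise-free β equals `beta_true` at every
pixel ($I_\parallel = T(1+2\beta)/(2+\beta)$,
$I_\perp = T(1-\beta)/(2+\beta)$); chiral pairs inject a symmetric
multiplicative asymmetry ($L = \mathrm{base}(1+\varepsilon/2)$,
$R = \mathrm{base}(1-\varepsilon/2)$) so the noise-free CD is exactly
ε; depth series scale a base image by $e^{-\mu z}$; fiber phantoms
render constant-width segments, arcs, and smoothed random walks
(heading-noise amplitude tuned by bisection to a target straightness),
with closed-form truth for the first two. The default base image for
chiral/depth stacks is a smooth blob field over a near-zero
background, so background-threshold rules are well posed.

Defaults follow the emulated acquisition: 18 excitation angles (0–170°
in 10° steps; a 19-frame 0–180° sweep is also accepted on input),
Poisson noise on expected counts (photon-counting detection) with
optional additive Gaussian for read-noise studies, peak ~10³ counts
(a stated convention, not a measured detector property), pixel size
0.332 µm (an 85 µm field over 256 px). Identical seed and parameters
give bit-identical stacks; every consumer of randomness draws from a
sub-stream derived from the scene seed.

What the generator does *not* emulate — and what passing tests
therefore do not show about measured data: focal-volume polarization
mixing at high NA, scattering-induced depolarization (cleared-tissue
acquisition is assumed), optical-system polarization distortion,
out-of-plane fiber tilt, detector gain/afterpulsing, and real fiber
texture (phantoms are constant-width and isolated or simply crossing).
The four-group study simulator (`study_config()`) encodes effect
*directions* consistent with crosslink-modulation biology (control:
largest b/smallest pitch, highest β and CD; promoter: shallowest
attenuation; inhibitor: steepest, ~3-fold intensity ratio at 80 µm
against the promoter) with n = 3 samples per group (12 samples); the
magnitudes are choices for end-to-end testing, not measured values.

## Problem sizes and costs

The default test and acceptance workloads are sized for a single CPU:
per-pixel fitting is exercised at 64×64 px × 18 angles (~30 s), the
study pipeline at 12×12 px stacks with 2–3 samples per group, phantom
extraction at ~160×200 px images. The per-pixel fitter costs roughly
2–5 ms/pixel; a full 256×256 field takes a few minutes.

## Known limitations

The adopted P-SHG form is real-valued, in-plane and Kleinman-
symmetric; data violating those assumptions will fit with degraded r²
rather than fail loudly. The extractor does not disambiguate fiber
bundles from single fibers and splits wavy fibers at apparent
junctions. The attenuation model is single-exponential in the section
mean; layered or strongly scattering samples need more structure. CD
is reported unsigned; signed, orientation-deconvolved CD is out of
scope. Donor nesting (multiple samples per donor) is not modeled in
the statistics.
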