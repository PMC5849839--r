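---
title: "Predicting electron cutout output factors by annular-kernel convolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting electron cutout output factors by annular-kernel convolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(cutoutof)
```

## The problem

Electron beams treat shallow tumors, and each field is shaped by a
patient-specific metal cutout inserted in the applicator cone. The monitor
units delivered depend on the cutout's *output factor* (OF) — dose per MU at
the depth of maximum dose, relative to the reference open applicator. For
irregular cutouts that factor is traditionally measured per patient, a slow
and error-prone QA step. This package computes it instead from a small
commissioning set of circular-cutout measurements, for any aperture shape,
as a full 2D map.

## The model

Two physical assumptions make this possible:

1. **Radial isotropy.** Scatter contributions to the calculation point
   depend only on distance, so a field decomposes into annuli: the output
   contribution of the ring between radii $r$ and $r + \Delta r$ is the
   difference of two circular-field output factors,
   $\mathrm{AOF}(r) = OF(r + \Delta r) - OF(r)$.
2. **Shift invariance.** The contribution pattern does not change as the
   calculation point moves across the aperture. This neglects the angular
   dependence of scatter from off-axis beamlets, which is acceptable while
   the opening stays near the central axis but degrades near ragged edges —
   the motivation for the P2A complexity flag below.

Under these assumptions the prediction is a discrete convolution. A
circularly symmetric *output kernel* $OK[n_1, n_2]$ on a 1 mm grid assigns
every pixel in annulus $k$ the value $\mathrm{AOF}_k / NP_k$, with $NP_k$
the number of pixels in the annulus. For a binary aperture mask $f[x, y]$
(1 = open) the cutout output factor everywhere is

$$COF[x, y] = \sum_{n_1}\sum_{n_2} OK[n_1, n_2]\, f[x - n_1,\, y - n_2].$$

The value at the convolution maximum is the predicted chamber reading at
the recommended measurement point; the whole map doubles as a relative
output distribution.

```{r pipeline}
curve <- preset_curve("9E")          # stands in for measured circular OFs
kernel <- build_kernel(curve)        # 1 mm pixels, 6 cm support
shape <- synth_cutout("irregular", radius_cm = 2.5, amplitude = 0.25,
                      seed = 11)
mask <- rasterize(shape, resolution_mm = 1, padding_cm = 6.2)
cof <- compute_cof_map(kernel, mask)
find_max_point(cof)[c("x_cm", "y_cm", "cof")]
```

## Fitting the measured curves

Circular-cutout OFs are measured at radii 1–6 cm in 1 cm steps (the largest
circle that fits a 15 × 15 cm cone) and must be interpolated to the 1 mm
kernel resolution. Choices made here:

* **Origin anchor $OF(0) = 0$.** A zero-radius field passes no dose. This
  convention is what makes the annular decomposition *telescope*: the kernel
  summed over the binned disk of radius $R$ returns exactly $OF(R)$, which
  the test suite checks to $10^{-12}$ over random curves.
* **Monotone interpolant.** The default is a Fritsch–Carlson monotone
  piecewise cubic Hermite through the anchor and all samples, implemented
  in the package with the $\alpha^2 + \beta^2 \le 9$ derivative restriction.
  (`stats::splinefun(method = "monoH.FC")` was observed to undershoot by up
  to $10^{-3}$ on monotone inputs, which would inject spurious negative
  annuli; `"hyman"` rejects noisy inputs outright.) Linear interpolation is
  available via `interpolation = "linear"`.
* **Plateau extrapolation.** Beyond the largest measured radius the curve
  continues at its last value: measured electron OF curves flatten by about
  4 cm radius, so the annular contributions beyond the data are zero.
* **Negative annuli.** A noisy, non-monotone measurement set produces
  negative AOFs. The default keeps them (clipping would break the
  telescoping identity) and warns; `clip_negative_aof = TRUE` or
  `negative_aof = "error"` change that policy. Roundoff-scale negativity
  (below $10^{-12}$) is ignored.

## Kernel geometry

Pixels are assigned to annuli by their center distance with half-open bins
$[k\Delta r, (k+1)\Delta r)$; $\Delta r$ defaults to the 1 mm pixel pitch.
Center-distance binning makes $NP_k$ unambiguous and the disk sums exact at
any resolution. The kernel support defaults to the largest measured radius
(6 cm, a 121 × 121 grid); beyond it the plateau makes every annulus zero
anyway.

Energy shapes the kernel in a characteristic way, which the three synthetic
presets reproduce: at low energy (6E-like) scatter spreads output toward
the kernel edge, while at high energy (15E-like) the central pixel
dominates.

```{r kernels, fig.height = 3}
library(ggplot2)
profs <- dplyr::bind_rows(lapply(c("6E", "9E", "15E"), function(e) {
  dplyr::mutate(kernel_profile(build_kernel(preset_curve(e))), energy = e)
}))
ggplot(profs, aes(radius_mm, value, colour = energy)) +
  geom_line() +
  scale_y_sqrt() +
  labs(x = "annulus radius (mm)", y = "per-pixel kernel value")
```

## Apertures

Cutout openings are simple polygons in cutout-plane cm coordinates (y up,
origin at the cone center). Rasterization places pixel centers on the
resolution lattice and applies the even-odd rule with the standard half-open
boundary convention (centers on a left/bottom edge are inside, right/top
outside), so translating a polygon by whole pixels translates its mask
bit-for-bit — the discrete counterpart of the shift-invariance assumption.
Masks must be padded by at least the kernel support radius so the
convolution sees the whole neighborhood of every open pixel;
`compute_cof_map()` refuses underpadded masks and names the padding it
needs. Multi-hole apertures are rejected: one simple polygon per cutout.

The aperture is *not* magnified when working at extended SSD: kernels are
built per-SSD from curves measured (or derived) at that SSD with the same
physical cutouts, so beam divergence is absorbed in the curves.

## Extended SSD from limited measurements

Re-measuring all circles at each extended SSD is costly. For radii
$\ge$ 4 cm the effective SSD is stable, and the extended-SSD output factor
follows an inverse-square law:

$$OF_{ext}(r) = \frac{OF_0(r)}{\left(\dfrac{SSD_{eff} + d_{max} + SSD_{ext}
  - SSD_0}{SSD_{eff} + d_{max}}\right)^{2}}$$

`of_extend_inverse_square()` applies this to the large-radius samples and
flags the result partial; `of_merge_samples()` splices in directly measured
small-radius points before kernel construction. The companion
`pct_difference()` (symmetric, mean-normalized) quantifies the effect of
the shortcut on predicted COFs.

## Evaluating distributions: gamma index and P2A

`gamma_index()` compares two registered planar distributions with the
standard $\gamma$ test, defaulting to 3% dose difference and 3 mm
distance-to-agreement, normalized globally at the reference maximum (the
convention that yields the best achievable global passing rate; local
normalization is available). Numerical policy, all configurable:

* search disk of radius 3 × DTA on the evaluated grid upsampled 3× by
  bilinear interpolation (sub-pixel minimum without an unbounded search);
* reference points whose window leaves the evaluated grid are excluded and
  counted, not silently passed;
* the passing-rate denominator drops points below 10% of the normalization
  value; a 0% threshold reproduces the unmasked rate.

One property of sub-pixel gamma worth knowing: with spatially uncorrelated
noise in the evaluated distribution, interpolation between neighboring
pixels almost always crosses the reference value within a fraction of a
pixel, so even 5–8% noise can pass at 100%. Point-sampled comparison
(`upsample = 1`) restores the pointwise Gaussian-tail behavior; the test
suite exercises both regimes.

Prediction quality correlates with aperture complexity, summarized by
$P2A = P^2/A$ (perimeter squared over area): $4\pi$ for a circle, 16 for a
square, large for elongated or ragged shapes. `classify_complexity()` flags
shapes above 30 (inclusive boundary) as needing measurement rather than
convolution-only relative dosimetry.

## What the synthetic generators do and do not show

`synth_of_curve()` draws from a saturating exponential
$OF(r) = p\,(1 - e^{-(r/\lambda)^q})$ — monotone, plateau by ~4 cm — with
presets (plateau, $\lambda$ cm, $q$) of (1.0, 1.8, 2) for 6E, (0.9, 1.3, 2)
for 9E, and (0.8, 0.8, 1.5) for 15E, chosen once to match the published
qualitative behavior of measured curves and kernels. `synth_cutout()`
produces circles (regular 128-gons by default), rectangles, and star-shaped
radial perturbations $r(\theta) = R(1 + a\sum_k c_k \sin(k\theta +
\phi_k))$, simple by construction for $a < 0.5$. `synth_film()` resamples a
computed map with a sub-pixel rigid shift and seeded Gaussian noise. All
generators are deterministic given their seed.

These fixtures validate the machinery — telescoping, recovery of the
generating curve through the full kernel–mask–convolution loop (within
0.5%, in practice ~0.2%), shift invariance, gamma closed forms. They do not
validate the physics: no Monte Carlo transport, no angular scatter, no
film-response model stands behind them, so passing tests say the algorithm
is implemented correctly, not that a particular linac's cutouts will agree
with it. Commissioning against measured circles remains the user's step.

## Numerical choices and problem sizes

* Convolution runs by zero-padded 2D FFT by default; the `"direct"`
  shift-and-add route is the same double sum evaluated independently, and
  the suite pins both to a literal triple-loop oracle (FFT agreement
  $\le 10^{-9}$, observed $\sim 10^{-16}$). FFT results have magnitudes
  below $10^{-12}$ snapped to zero so blocked regions stay exactly empty.
* Point queries default to nearest-pixel (chamber positioning is ~1 mm);
  bilinear is available. Maximum search breaks ties row-major and reports
  every pixel within 0.1% of the maximum as a plateau set, a direct reading
  of how well-determined the measurement point is.
* All file formats are plain CSV with `# key=value` geometry headers,
  written at 17 significant digits so write→read round-trips are bit-exact.
* Default test and validation sizes: 121 × 121 kernels (6 cm support at
  1 mm), masks up to ~250 px square, gamma grids of 30–50 px, 100-curve
  telescoping sweeps, and 1000 random polygons for the isoperimetric
  property — sizes at which the full suite completes in well under a
  minute while exercising every code path.

## Known limitations

* Single simple polygon per cutout; no island blocks.
* No depth dependence (maps live at $d_{max}$) and no absolute dose — COF
  is relative to the 10 × 10 cm open applicator by construction.
* One applicator cone per curve set; cone size enters only as a label.
* The effective SSD is user input, not estimated from data, and the
  inverse-square shortcut is least accurate at low energies, where the
  effective SSD genuinely shifts with field size.
* Shift invariance fails gradually for highly irregular shapes; treat
  P2A > 30 predictions as guidance for where to measure, not as QA results.
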