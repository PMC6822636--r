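---
title: "Modeling and imaging normalized solid stress in tumors"
author: "ssnPoro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and imaging normalized solid stress in tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnPoro)
```

# The model

A growing tumor accumulates solid stress (SSg) from three sources — the
resistance of the surrounding tissue, chemical swelling, and residual
growth stress. SSg compresses vessels, raises interstitial fluid pressure
(IFP), drives hypoxia and limits drug delivery, yet it cannot be measured
non-invasively by direct means. The approach implemented here rests on one
structural result: in a creep-compression poroelastography experiment the
compression-induced solid stress (SSc) that develops inside a spherical
poroelastic tumor has the *same spatial distribution* as the SSg that the
tumor accumulated while growing. A normalized, dimensionless profile —
the normalized solid stress, SSn — is therefore imageable from an
ultrasound experiment even though absolute SSg is not.

For a spherical tumor of radius $a$ with uniform mechanical and transport
properties, the compression-induced interstitial fluid pressure at
normalized radius $r = R/a$ is

$$p(r) = \Psi\left(1 - \frac{\sinh(\alpha r)}{r\,\sinh\alpha}\right),
\qquad \alpha = a\sqrt{\frac{L_p}{k}\frac{S}{V}},$$

where $L_p$ is vascular permeability, $k$ interstitial permeability and
$S/V$ the capillary area-to-volume ratio. $\Psi$ (kPa) sets the scale;
the center pressure is $P_0 = \Psi(1 - \alpha\,\mathrm{cosech}\,\alpha)$.
The radial and circumferential SSc offset the boundary stresses by this
pressure, $\sigma^c_{RR}(r) = \sigma^a_{RR} - p(r)$ and
$\sigma^c_{\theta\theta}(r) = \sigma^a_{\theta\theta} - p(r)$, while the
growth-induced stresses share the same kernel with amplitude pairs
$(\Omega_{bR}, \Omega_{pR})$ and $(\Omega_{bT}, \Omega_{pT})$. Every one of
these profiles, normalized by its own boundary value and amplitude,
collapses onto

$$SS_n(r) = 1 - \frac{\sinh(\alpha r)}{r\,\sinh\alpha}, \qquad
SS_{n,p} = 1 - \alpha\,\mathrm{cosech}\,\alpha,$$

which is the quantity the imaging pipeline reconstructs. $\alpha$ is the
single shape parameter: small $\alpha$ gives a gentle parabolic profile
($SS_n \approx \tfrac{\alpha^2}{6}(1-r^2)$), large $\alpha$ an interior
plateau near 1 with a thin boundary layer of width $\sim 1/\alpha$.

```{r}
peakSSn(c(0.3, 3, 33))
```

## Assumptions

Spherical tumor, perfectly bonded to the background, uniform properties,
remote load (tumor small relative to the sample), biphasic poroelastic
behavior, creep (constant-pressure) compression. The model is evaluated at
a single acquisition time; $\Psi$ absorbs the time scale, which is why the
package carries no time integrator — SSn is time-normalized by
construction.

# Boundary stresses

The scalars $\sigma^a_{RR}$, $\sigma^a_{\theta\theta}$ come from Eshelby's
equivalent-inclusion solution for a spherical inhomogeneity under remote
uniaxial stress: the interior stress is uniform and depends only on the
applied stress and the two pairs of (drained) elastic constants. The
cylindrical components natural to elastography are rotated to spherical
components by the standard tensor transformation and reduced to scalars
over the sphere. The spherically symmetric 1-D model needs
$\theta$-independent scalars, and the surface-area-weighted mean
(`"angle_average"`, $\overline{\cos^2\theta} = 1/3$) is the
least-committal reduction; `"axis"` and `"equator"` are exposed for
sensitivity analyses.

```{r}
boundaryStressScalars(-2, ElasticProperties(20, 0.3),
                      ElasticProperties(10, 0.3))
```

Sign convention: compression negative, so an applied creep pressure of
$P$ kPa enters as $\sigma = -P$. The paper-motivated loading range is
1–4 kPa.

# The synthetic phantom

`generateSscMap()` renders $\sigma^c_{RR}$ on a pixel grid for a spherical
inclusion imaged through its center, with a constant background outside
and additive zero-mean Gaussian noise calibrated so that
$10\log_{10}(\text{mean-square signal in mask}/\sigma_n^2)$ equals
`snrDb`. Defaults (fixed once): a 96×96 grid at 0.25 mm/pixel, radius
8 mm (32 pixels — comparable to a small-animal tumor at elastography
resolution), $\alpha = 5$ (the transport regime considered favorable for
drug delivery, hence a clinically interesting midpoint), $\Psi = 1$ kPa,
boundary stresses $(-1.2, -0.75)$ kPa as produced by the package's own
Eshelby route for a 2:1 stiffness contrast under ~2 kPa loading, and
20 dB SNR — a mid-range choice spanning optimistic (40 dB) to pessimistic
(10 dB) regimes, since output-level noise of strain estimation chains is
near-Gaussian but its magnitude is instrument-dependent.

What the phantom deliberately does *not* emulate: RF speckle and the
strain-estimation chain (the noise enters at the stress-map level), the
exterior Eshelby decay (the background is constant, because the
reconstruction consumes only in-mask pixels), and off-center imaging
planes (a 2-D central slice of the 3-D sphere). Passing recovery tests
therefore demonstrate correctness of the model and estimator under
calibrated Gaussian perturbations, not robustness to correlated
elastographic artifacts.

`generateCohort()` emulates the longitudinal treated/untreated experiment:
both arms start at $\alpha = 3$, untreated tumors grow $\alpha$ by 1.5×
per week (progression concentrates IFP), treated tumors shrink it by
0.7×, and each weekly observation carries multiplicative lognormal noise
(sd 0.1). Six tumors per arm for three weeks mirror the in vivo cohort
size.

# Reconstruction

```{r}
ph <- generateSscMap(PhantomConfig(snrDb = 20, seed = 1L))
prof <- extractRadialProfile(ph$map, nBins = 15)
fit <- fitAlpha(prof, mode = "free_scale")
fit
```

`extractRadialProfile()` bins in-mask pixels into equal-width annuli over
$\rho/a \in [0,1]$ and records per-bin mean value, mean radius and count.
Using the mean radius (not the bin midpoint) as abscissa removes the
first-order discretization bias; the residual second-order bias scales
with the bin width squared and the profile curvature, which is why exact
($10^{-6}$-level) recovery statements apply to profiles sampled from the
model, while map-level recovery is validated statistically.

`fitAlpha()` is a bounded multi-start nonlinear least-squares fit of the
SSn shape, one-dimensional in $\log\alpha$: in `known_scale` mode the
profile is normalized with externally supplied $(\sigma_a, \Psi)$ — the
in vivo route, where both come from Eshelby theory and the pressure
model — and in `free_scale` mode the two scale parameters are profiled
out by weighted linear least squares at each candidate $\alpha$. Nine
fixed log-spaced starts over $\alpha \in [10^{-3}, 10^3]$, ties resolved
to the smallest $\alpha$, make the fit deterministic. Bins are weighted
by pixel count (the correct inverse-variance weights under i.i.d. pixel
noise); empty annuli are dropped, not interpolated. The known-scale fit
is markedly more precise on gently curved profiles (small $\alpha$),
where the three-parameter free fit is noise-limited.

Degenerate inputs are contracts, not crashes: a flat profile returns
`converged = FALSE` with flag `non_identifiable`; a profile whose implied
peak exceeds 0.99 is flagged `saturated`, since beyond $\alpha \approx 30$
the plateau makes $\alpha$ only lower-bound identifiable. The peak-SSn
slot always equals $1 - \hat\alpha\,\mathrm{cosech}\,\hat\alpha$ exactly.

`ssnMap()` then maps each in-mask pixel through
$(\sigma^c - \hat\sigma_a)/(-\hat\Psi)$; out-of-mask pixels become `NaN`
and the fraction of values outside $[-0.2, 1.2]$ is logged, never
clipped. Masks are inputs throughout: the phantom supplies ground truth,
and in vivo delineation is a manual segmentation step outside this
package's scope. Absolute SSg is not recoverable by design — the method
yields the normalized distribution and its peak, not kPa magnitudes of
growth stress.

# Statistics

Weekly treated-vs-untreated comparisons use the Kruskal-Wallis rank test
(midranks, standard tie correction), with stars at p < 0.05/0.01/0.001
and "n.s." otherwise, matching the convention of the longitudinal
analysis being emulated. For two groups the exact permutation null
(available for $N \le 10$) coincides with the exact two-sided Wilcoxon
test, which the test suite uses as an oracle. At $N = 10$ the chi-square
tail is a coarse approximation to the discrete exact null — the two
p-values can differ by up to about 0.09 near $p \approx 1$ — so the exact
option is preferred at cohort sizes like 6 + 6 when decisions ride on a
single week. No multiplicity correction is applied by default (mirroring
the emulated analysis, which reports none); a Holm switch exists.
`weeklySummary(metric = "ssn_peak")` transforms $\alpha$ observations
through the strictly monotone peak-SSn map, so means change but rank-based
p-values do not.

```{r}
co <- generateCohort(CohortSpec(seed = 0L))
weeklySummary(co, metric = "alpha")
```

# Numerical choices

* The sinh ratio is evaluated as
  $e^{(r-1)\alpha}\,\frac{1-e^{-2\alpha r}}{r(1-e^{-2\alpha})}$ —
  identical algebraically, finite up to $\alpha = 10^4$ and beyond
  (naive $\sinh$ overflows near $\alpha = 710$).
* At $r = 0$ the analytic limit $\alpha\,\mathrm{cosech}\,\alpha$ is
  used, with a series below $r < 10^{-8}$ and for
  $\alpha < 10^{-4}$.
* Peak SSn saturates: beyond $\alpha \approx 40$, $1 - SS_{n,p}$ falls
  under double-precision resolution and the value rounds to 1.0;
  monotonicity tests are strict up to $\alpha = 30$ and non-strict
  beyond.
* TIFF maps are written as 32-bit samples after affine normalization to
  [0, 1] with offset/scale in the JSON sidecar (round trip exact to
  ~2×10⁻¹⁰ of the value range); pixel spacing lives only in the sidecar,
  avoiding TIFF resolution-tag dialects.
* Problem sizes used by the validation suites — 96×96 phantoms, 15 bins,
  100 seeds per Monte-Carlo condition, 10,000 null simulations for the
  type-I check — were chosen to make the whole suite run in about a
  minute on a laptop core while keeping Monte-Carlo standard errors well
  under the margins being asserted.

# Known limitations

Non-spherical tumors, spatially varying $\alpha$ or properties, transient
consolidation dynamics, the exterior stress field, and strain-to-stress
inversion from RF data are all out of scope. The constant-peak curve
family (center stress fixed at −0.6 kPa while $\Omega_{bR}$ ranges over
0.2–0.4 kPa at $\alpha = 6$) is the package's own parameterization of the
time-progression scenario: it pins the one feature that scenario requires
— a constant peak with a moving boundary value — while reusing the
amplitude range of the other families.
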