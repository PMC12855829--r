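---
title: "Models and methods behind planktonDVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind planktonDVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

planktonDVM reconstructs, as testable code, the full computational chain of
a high-resolution in situ study of zooplankton diel vertical migration
(DVM): from moonlight and underwater light fields, through shadowgraph
image segmentation and size measurement, to depth-binned density tables and
gamma mixed models with bootstrap confidence intervals. Because raw field
imagery is bulky and instrument-specific, the package ships a synthetic
generator that emulates every input the pipeline consumes, with known
ground truth, so each stage can be validated end to end. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what validation on synthetic data does and does not
establish.

## Sky geometry and the light field

**Ephemeris.** Solar positions use a low-precision analytic series
(Astronomical Almanac style); lunar positions use a truncated Meeus series
(13 longitude terms, 7 latitude terms, 4 distance terms). Accuracy is a
few tenths of a degree in altitude and about one percentage point in the
illuminated disc fraction over 1900-2100 — far better than the light model
needs. The illuminated fraction is tied to the phase angle by
$f = (1 + \cos\alpha)/2$ and this identity is enforced by the `SkyState`
class validity. Outside 1900-2100 the ephemeris refuses to run.

**Surface illuminance.** The study this package emulates used a published
moonlight model; here the same dependencies (lunar phase, elevation,
brightness, atmosphere) are captured by a simplified, fully documented
model:

* solar term: piecewise linear in $\log_{10} E$ through the twilight bands
  — $(-18^\circ, 10^{-3.1}\,\mathrm{lx})$, $(-12^\circ, 10^{-2.1})$,
  $(-6^\circ, 10^{0.48})$, $(0^\circ, 750)$ — joined continuously to
  $E = 750 + 118000 \sin h$ above the horizon. The knots follow standard
  twilight illuminance tables;
* lunar term: a Krisciunas–Schaefer-style phase law
  $m = -12.73 + 0.026|\alpha| + 4\times10^{-9}\alpha^4$ converted to
  illuminance by $E = 10^{(-14.18 - m)/2.5}$, multiplied by
  $\sin(\mathrm{altitude})$ (horizontal projection), an airmass extinction
  factor $10^{-0.4 k X}$ with Rozenberg airmass $X$ and extinction $k$
  (default 0.25 mag/airmass, clear continental air), and inverse-square
  Earth–Moon distance. A full moon at the zenith at mean distance gives
  about 0.21 lx;
* a fixed starlight baseline of 0.001 lx, the conventional moonless
  clear-sky value;
* a multiplicative cloud transmission factor per okta (default vector
  1.00 down to 0.30 for okta 8; the campaign nights this emulates were
  nearly cloud-free, so default analyses run at okta 0).

**Underwater attenuation.** Light decays as
$E(z) = E_0 e^{-K_d z}$, evaluated at the midpoints of half-open 10 cm
bins $[z, z+0.1)$; 16.7 m of water column gives 167 bins. $K_d$ is a
single wavelength-integrated diffuse attenuation coefficient per profile,
default 0.25 m$^{-1}$ (a clear-lake regime). Values below a floor of
0.001 lx — the lowest scotopic sensitivity reported for fish — are set to
exactly zero, so "dark" rows in the statistics are true zeros rather than
tiny positives.

**Radiometric conversions.** Lux converts to W m$^{-2}$ by
$E_e = E_v / (683\,V(\lambda))$ with $V(\lambda)$ the CIE 1931 2°
photopic table (5 nm steps, linear interpolation), and to photon flux by
$\mu mol = W \cdot \lambda_{nm} \cdot 8.359\times10^{-3}$. At 500-520 nm
these reproduce the standard blue-green underwater equivalences (0.06 lx
-> 2.72e-4 W m$^{-2}$ -> 1.14e-3 umol m$^{-2}$ s$^{-1}$). Note that at
480 nm the photopic table gives 1.05e-5 W m$^{-2}$ for 0.001 lx; published
equivalences quoting a larger value at that wavelength evidently used a
different luminosity function, and no attempt is made to match them.

## The synthetic campaign

The generator mirrors a two-lunar-cycle field campaign on a stratified
temperate lake (53.15°N, 13.03°E): four sampling nights, two near new
moon (2022-08-25, 2022-09-29) and two near full moon (2022-09-13,
2022-10-12). `scheduleProfiles()` builds the instrument schedule — one
daytime profile at 16:00 CET, then half-hourly night profiles from 30 min
before sunset, stopping 5 h after sunset (new moon) or when the Moon
passes 50° altitude (full moon, with a 5.5 h fallback and warning).

**Environment fields.** `makeEnvironment()` produces closed-form curves: a
logistic thermocline, chlorophyll-a with a Gaussian deep maximum, a
phycoerythrin peak centred *below* the chlorophyll maximum, and oxygen
comfortably above 3 mg/L. Seeded noise perturbs the curve *parameters*,
not the points, so the structural invariants (monotone temperature, peak
ordering, oxygen floor) hold for every seed by construction. The four
campaign nights carry a seasonal progression — surface temperature 21 to
13.5 °C, thermocline deepening 7 to 10 m, chlorophyll declining — typical
of late August through mid-October. This matters statistically: moonlight
only reaches the epilimnion, where temperature and chlorophyll are nearly
uniform *within* a night, so the light x environment interactions of the
night model are identified mainly by the contrast *across* nights; without
the seasonal trend those coefficients would be near-collinear with the
light main effect.

**Density model.** `simulateBinDensities()` draws per-(profile, bin, size
class) densities from the same generative family the statistics module
fits: $\eta = X\beta + u_{date} + u_{profile}$,
$u \sim N(0, \sigma^2)$, $y \sim \mathrm{Gamma}(k, \mu = e^\eta)$
(variance $\mu^2/k$). Default $\beta$ vectors are the estimated effect
sizes for cladocerans and copepods in the emulated study system; the
recovery test dimensions are 54 night profiles x 167 bins x 3 size
classes with $k = 2$, $\sigma_{date} = 0.2$, $\sigma_{profile} = 0.14$.
Continuous covariates (illuminance, temperature, chlorophyll-a) are
z-scored before entering the night design: the published night-model
coefficient magnitudes are only plausible on a standardized scale, whereas
the day-night design keeps raw lux (its per-lux slopes of order $10^{-6}$
match a 0-50,000 lx range). The night design covers only profiles after
civil twilight (sun below -6°), which restricts underwater illuminance to
the dim twilight-to-moonlight range.

**Two generation modes.** "Density mode" feeds gamma densities directly to
the statistics layer — the exact recovery surface, used for the
simulate-and-refit tests. "Individual mode" converts densities to
organisms (`placeIndividuals()`: Poisson counts with mean density x 0.52 L
bin volume, uniform depths within bins, ESDs uniform within the taxon's
size-class range) and renders them to frames — the end-to-end surface,
which adds Poisson and imaging dispersion on top. A third entry point,
`simulateDepthDistributedIndividuals()`, generates one profile directly
from a truncated-normal depth distribution, used to emulate a reported
daytime depth summary (mean 9.13 m, SD 4.24 m for daytime cladocerans on
new-moon days). Note the truncation to [0, 16.7] m pulls the realized
mean about 0.2 m shallower than the nominal 9.13 m; the recovered value
reflects the truncated distribution, not the untruncated parameter.

**Rendering.** The virtual imager matches the shadowgraph instrument: a
43 mm x 52 mm field over a 100 mm water path, 21 um pixel pitch (2048 x
2476 px), 2.4 frames/s at 5 m/min descent — 34.72 mm per frame, so
consecutive frames overlap by 8.28 mm. A frame's recorded depth is its top
edge; row 0 is the shallowest row. Backgrounds are bright (default grey
230) with a smooth multiplicative illumination field (20% lateral span
plus mild vignetting) and Gaussian sensor noise (default SD 2 counts).
Organisms are dark silhouettes (grey 45) whose prolate-spheroid ESD
equals the ground-truth ESD: for axis ratio $r$, major $= \mathrm{ESD}
\cdot r^{2/3}$ and minor $= \mathrm{ESD}/r^{1/3}$. Cladocerans are compact
ovoids (ratio 1.2-1.8, any orientation); copepods are elongated (ratio
2.2-3.0) with two thin antenna strokes at the head. Copepods are drawn
near-horizontal (within ±20° of the lateral axis) so the one-sided
antennae cannot bias the depth centroid; antennae are rendered at their
physical ~21 um width, which is sub-pixel at coarse scales and handled by
partial darkening. Silhouette edges are anti-aliased with a
signed-distance coverage ramp; this is what lets a 4x-downscaled frame
(pixel pitch 84 um) still carry sub-pixel size information. `scaleFactor`
in {1, 2, 4, 8} divides the pixel grid for desk-scale runs; rendering is
deterministic given (seed, config).

## Imaging

`flatField()` divides by a per-pixel background reference (median over a
frame window, computed with a vectorized sorting network), rescales to
mean 1 and maps back around the frame's mean grey. `binarizeSegment()`
thresholds dark-on-bright at (median − k·MAD) with k = 3 — median/MAD
rather than mean/SD so the sparse silhouettes do not bias the background
estimate (on frames above 0.4 MP the statistics come from a strided
200,000-pixel subsample) — with an Otsu fallback when the spread is
degenerate. Components are labelled 8-connected (4-connected labelling
plus a union-find merge of diagonal contacts). `extractRois()` applies
area thresholds (defaults 50 to 500,000 px at full resolution, scaled by
the squared pitch ratio at other scales; 50 px keeps the smallest
admissible 0.36 mm organism, about 230 px, with ample margin).

`measureRoi()` computes image moments of each ROI. Foreground pixels are
weighted by their darkness contrast against the local background, which
recovers the anti-aliased sub-pixel extent; the equivalent-ellipse axis
diameters are $4\sqrt{\lambda_i}$ of the weighted covariance (binary
masks, which carry no sub-pixel information, get the classic 1/12
unit-pixel variance correction instead). Volume is modelled as a prolate
spheroid, so $\mathrm{ESD} = (\mathrm{major}\cdot\mathrm{minor}^2)^{1/3}$
— chosen because it reduces to the sphere for circular silhouettes and is
the standard plankton-imaging convention. Across a rendered sweep the
measured ESD stays within 5% of truth at full resolution and within 12%
at scaleFactor 4.

The classifier is deliberately a *rule-based stand-in* behind a pluggable
interface (any function from morphometry to (taxon, score) can replace
it): copepod if aspect ratio ≥ 2 or at least two thin protrusions
(connected pixel groups outside the 1.15x fitted ellipse); cladoceran if
aspect < 2 and solidity ≥ 0.9; otherwise "other". On generator
silhouettes the classes are separable by construction and accuracy
exceeds 95%; this says nothing about real imagery, where a trained
classifier would take its place. Detections at or below 0.36 mm ESD are
discarded — the instrument's practical resolution bound.

## Profile assembly

`deoverlapFrames()` removes the 8.28 mm overlap with a keep-first rule:
the first frame keeps its full span, every later frame keeps the strip
not covered by its predecessor's kept strip. Strips are half-open,
pairwise disjoint, and their union is exactly the profiled span — an
invariant tested for arbitrary spacings up to the frame height.
Detections falling outside their own frame's kept strip are duplicates
and are dropped.

`binDensities()` converts counts to ind/L using the *actually sampled*
volume: 52 mm breadth x 100 mm path x the kept-strip length intersecting
each 10 cm bin (0.52 L for a fully covered bin). Bins with no kept
coverage emit no row (no fabricated zeros); covered bins emit one row per
taxon x size class, with zero counts becoming density 0. Size classes use
the closed published ESD ranges per taxon; ESD values in the gaps between
ranges are "unclassified" and excluded from model rows but tallied in an
audit attribute. Density x volume always reproduces the integer count
exactly — the conservation property the suite checks against brute-force
recounts. `profileMeanDepth()` summarises actual individual depths (not
binned densities) per profile and taxon, with SE = SD/sqrt(n) and SE = 0
for singletons.

## Statistics

`buildDesign()` expands a bin table into the two reported model layouts —
day-night: illuminance x size class (6 terms, raw lux); night:
illuminance x size class x temperature + illuminance x size class x
chlorophyll-a (18 terms, z-scored covariates) — with treatment coding,
small as the reference class, and columns in the published term order.
Gamma support excludes zero and the handling of zero-density bins is a
genuine modelling choice: the default drops them (counts are logged); an
alternative offsets them by half the single-organism detection quantum
(0.5/volume). Dropping is the default because an imputed pseudo-density
would manufacture information exactly where the instrument saw nothing.

`fitGammaGlmm()` fits the gamma log-link model with independent normal
random intercepts for date and profile by Laplace-approximated maximum
likelihood (glmmTMB engine). Without random effects it reduces to an IRLS
gamma GLM with the shape profiled out by maximum likelihood — and the
suite verifies the Laplace engine against an independent `stats::glm`
oracle to 1e-4 at $\sigma^2 = 0$. With only four dates the date variance
is weakly identified; when every date holds a single profile the two
factors are aliased outright and the date term is folded into profile.
Bootstrap intervals, not Wald errors, are the authoritative uncertainty
statement.

`parametricBootstrapHpd()` simulates from the fitted generative model
(fresh random intercepts + gamma noise), refits, and reports 95% highest
posterior density intervals: sort the draws, slide a window of
$\lceil 0.95 n \rceil$ order statistics, keep the narrowest (ties broken
toward the point estimate). A term is significant when its interval
excludes zero; variance components, bounded below by zero, carry no flag.
Reported inference uses 10,000 iterations; the test suite uses 40-200
(and 99 for the coverage simulation) to stay fast — coverage at reduced
iterations is checked against its binomial tolerance, not against
exactness. More than 5% failed refits aborts with diagnostics.

## Problem sizes, determinism, limitations

The test suite runs everything at reduced dimensions chosen to exercise
each code path quickly: short water columns (5 m, 50 bins) and 6-12
profiles for the mixed-model unit tests, two full-size simulate-and-refit
sweeps (27,054 rows) only in the acceptance tests, rendering sweeps of a
few dozen silhouettes, and two full rendered profiles at scaleFactor 4
for the end-to-end depth-recovery check. All randomness flows from one
root seed fanned into named substreams (`environment`, `densities`,
`individuals`, `orientation`, `frame-noise`, `bootstrap`, ...), so any
stage can be re-run alone and reproduces byte-identical artifacts.

What passing on synthetic data shows: the pipeline's internal
consistency — geometry, conservation, estimator correctness, interval
calibration — and that the full chain can recover known truth through
rendering and segmentation. What it does not show: performance on real
shadowgraph imagery, whose organisms are not ideal ellipsoids, whose
backgrounds carry marine snow, detritus and schlieren, whose optics
distort off-focus particles, and whose taxa need a learned classifier.
The light model is a smooth idealization (no skyglow, no spectral
attenuation, single $K_d$); the depth-varying attenuation of a real lake
is not modelled. These boundaries are deliberate: the package validates
the computation, not the instrument.
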