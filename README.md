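# planktonDVM

Zooplankton track light: at dusk they rise out of dim deep refuges, and
under bright moonlight they sink back down. Quantifying this diel vertical
migration (DVM) at fine resolution requires an in situ shadowgraph imager
profiling the water column, an image pipeline that turns frames into
sized, classified detections, a model of how much moonlight actually
penetrates the lake, and mixed-effects statistics on the resulting
depth-binned densities. **planktonDVM** implements that entire chain as a
tested R package, together with a synthetic-data generator that renders
ground-truthed shadowgraph frames — so every stage, from ephemeris to
bootstrap interval, can be validated without any field data.

It is aimed at plankton-imaging and freshwater-ecology groups who want a
transparent, reproducible reference implementation of this kind of
analysis, and at anyone needing its parts: a lunar illuminance model, an
underwater light field, silhouette morphometry with equivalent spherical
diameters, or gamma GLMMs with parametric-bootstrap HPD intervals.

## The models at the core

**Light.** A low-precision solar/lunar ephemeris feeds a simplified sky
model: solar twilight curve + lunar term
(phase law *m* = −12.73 + 0.026|α| + 4·10⁻⁹α⁴, airmass extinction,
inverse-square distance, sin-altitude projection) + 0.001 lx starlight,
times a cloud factor. Underwater,
*E(z) = E₀ e^(−K_d z)* evaluated in 10 cm bins (167 bins for 16.7 m),
with values below the 0.001 lx scotopic floor set to zero. Monochromatic
conversions use the CIE photopic curve: *E_e = E_v / (683 V(λ))*.

**Imaging.** Shadowgraph frames (43 × 52 mm field, 21 µm pixels, 2.4
frames/s at 5 m/min, so 34.72 mm descent and 8.28 mm overlap per frame)
are flat-fielded, thresholded at median − 3·MAD, labelled 8-connected,
and measured by darkness-weighted image moments. Volume is a prolate
spheroid on the ellipse axes, so
*ESD = (major · minor²)^(1/3)*; organisms ≤ 0.36 mm ESD are discarded. A
rule-based, pluggable classifier separates cladocerans (compact, solid)
from copepods (elongated, antennae).

**Statistics.** Densities per profile × 10 cm bin × size class are
modelled as Gamma(*k*, μ) with log link,
*log μ = Xβ + u_date + u_profile*, fitted by Laplace maximum likelihood.
Two designs: illuminance × size class (day–night, raw lux) and
illuminance × size class × temperature + illuminance × size class ×
chlorophyll-a (night, z-scored covariates, 18 terms). Uncertainty comes
from a parametric bootstrap: simulate from the fitted model, refit, and
take 95% highest-posterior-density (shortest) intervals; a term is
significant when its interval excludes zero.

## Worked example

```r
library(planktonDVM)

## sky and underwater light on a full-moon sampling night
sky <- lunarState(as.POSIXct("2022-09-13 22:00:00", tz = "UTC"),
                  lat = 53.15, lon = 13.03)
sky
#> SkyState at 2022-09-13 22:00:00 UTC
#>   site: 53.150 deg N, 13.030 deg E
#>   sun: -31.76 deg   moon: +29.23 deg (85.8% lit, phase 44.3 deg)
#>   moon distance: 385866 km   cloud: 0 okta

e0 <- surfaceIlluminance(sky)
round(e0, 4)
#> [1] 0.0282
```

A waning gibbous moon 29° up gives 0.028 lx at the surface. Attenuating
through the water column and converting units per 10 cm bin:

```r
lp <- attenuateProfile(e0, kdPerM = 0.25)
head(lightProfileTable(lp, "fullmoon_22h"), 3)
#>     profile_id bin_index bin_mid_depth_m illuminance_lx irradiance_w_m2 photon_flux_umol
#> 1 fullmoon_22h         0            0.05     0.02784958    0.0001262395     0.0005276401
#> 2 fullmoon_22h         1            0.15     0.02716197    0.0001231227     0.0005146126
#> 3 fullmoon_22h         2            0.25     0.02649134    0.0001200828     0.0005019068
sum(illuminance(lp) > 0)
#> [1] 134
```

Moonlight stays above the scotopic floor down to bin 133 (~13.4 m); the
33 deepest bins are biologically dark. Now simulate densities from the
night model at reduced size (12 profiles, 5 m column) and refit:

```r
tab <- nightDesignTable(nProfiles = 12, lakeDepth = 5, seed = 1)
sim <- simulateBinDensities(tab, nightEffectDefaults("cladoceran"),
                            sigmaDate = 0.2, sigmaProfile = 0.14,
                            gammaShape = 2, seed = 42)
fit <- fitBinTable(sim, design = "night")
fit
#> GlmmFit (night design, glmmTMB): 1800 obs, 18 fixed effects
#>   sigma2 date 0.0150, sigma2 profile 0.0051, gamma shape 2.024
#>   logLik -4508.74, converged: TRUE

ci <- parametricBootstrapHpd(fit, nIter = 200, seed = 42)
head(ci@table[c("term", "estimate", "hpdLow", "hpdHigh", "significant")], 6)
#>          term     estimate      hpdLow    hpdHigh significant
#> 1 (Intercept)  1.640972232  1.50053178 1.77714589        TRUE
#> 2 size_medium -0.006796745 -0.07618396 0.06169827       FALSE
#> 3  size_large -0.034983412 -0.10471023 0.03798650       FALSE
#> 4          lx  0.021340362 -0.05029212 0.10399684       FALSE
#> 5        temp  0.256607852  0.06164574 0.43973086        TRUE
#> 6         chl -0.064275207 -0.29580454 0.11440143       FALSE
```

At this reduced size the fit converges, recovers the gamma shape (2.02
vs the generating 2) and flags the strong terms; at the full study
dimensions (54 profiles × 167 bins × 3 classes) the refits recover the
generating coefficients to a few hundredths — that check lives in the
acceptance suite. `runPipeline(runConfig(...))` chains the remaining
stages (render → segment → assemble → fit → report) and writes every
artifact plus a manifest; see the methods vignette
(`vignettes/plankton-dvm-methods.Rmd`) for the full model documentation.

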