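# Sky geometry, twilight bands, surface illuminance model, underwater
# attenuation and radiometric conversions.

utc <- function(s) as.POSIXct(s, tz = "UTC")

test_that("solar altitude matches an independent solar-position oracle", {
  # reference values computed with the NOAA spreadsheet algorithm
  expect_equal(solarAltitude(utc("2022-09-13 12:00:00"), 53.15, 13.03),
               39.206, tolerance = 0.5 / 39.206)
  expect_equal(solarAltitude(utc("2022-09-13 18:00:00"), 53.15, 13.03),
               -5.467, tolerance = 0.5)
  # near the equinox the sun culminates within a degree of the zenith
  # somewhere over the equator
  alt <- max(solarAltitude(utc("2022-09-23 01:04:00"), 0,
                           seq(-180, 180, by = 0.5)))
  expect_gt(alt, 89)
  # and altitudes at antipodal longitudes are opposite (delta ~ 0)
  h1 <- solarAltitude(utc("2022-09-23 12:00:00"), 53.15, 13.03)
  h2 <- solarAltitude(utc("2022-09-23 12:00:00"), 53.15, 13.03 - 180)
  expect_lt(abs(h1 + h2), 2)
  expect_error(solarAltitude("not-a-time", 0, 0), "invalid timestamp")
  expect_error(solarAltitude(utc("2200-01-01 00:00:00"), 0, 0),
               "1900 and 2100")
})

test_that("twilight bands partition altitude with half-open boundaries", {
  expect_equal(as.character(classifyTwilight(c(5, -4, -10, -15, -30))),
               c("day", "civil", "nautical", "astronomical", "night"))
  # boundary values fall in the band they open
  expect_equal(as.character(classifyTwilight(c(0, -6, -12, -18))),
               c("day", "civil", "nautical", "astronomical"))
  # every altitude maps to exactly one phase
  grid <- seq(-90, 90, by = 0.25)
  ph <- classifyTwilight(grid)
  expect_false(anyNA(ph))
  expect_equal(length(ph), length(grid))
  expect_error(classifyTwilight(95), "-90, 90")
})

test_that("lunar ephemeris reproduces the campaign's moon illumination", {
  s <- lunarState(utc("2022-09-13 00:00:00"), 53.15, 13.03)
  # recorded as 91.5% for that date; the low-precision series must land
  # within 2 percentage points
  expect_lt(abs(s@illuminatedFraction * 100 - 91.5), 2)
  expect_true(validObject(s))
  # illuminated fraction identity holds at every instant on a time grid
  for (d in seq(0, 27, by = 3)) {
    st <- lunarState(utc("2022-08-25 00:00:00") + d * 86400, 53.15, 13.03)
    expect_equal(st@illuminatedFraction,
                 (1 + cos(st@lunarPhaseAngle * pi / 180)) / 2,
                 tolerance = 1e-9)
    expect_true(st@illuminatedFraction >= 0 && st@illuminatedFraction <= 1)
  }
  # new-moon campaign night is indeed dark
  s2 <- lunarState(utc("2022-08-25 00:00:00"), 53.15, 13.03)
  expect_lt(s2@illuminatedFraction, 0.12)
})

test_that("surface illuminance combines sun, moon, stars and cloud", {
  mkSky <- function(sun, moon, phase, okta = 0L, dist = 385000.56) {
    new("SkyState", time = utc("2022-09-13 00:00:00"), lat = 0, lon = 0,
        solarAltitude = sun, lunarAltitude = moon, lunarPhaseAngle = phase,
        illuminatedFraction = (1 + cos(phase * pi / 180)) / 2,
        lunarDistance = dist, cloudOkta = okta)
  }
  # deep night, moon below horizon: only the starlight baseline remains
  expect_equal(surfaceIlluminance(mkSky(-30, -10, 120)), 0.001)
  # full moon at the zenith, clear sky, mean distance
  eFull <- surfaceIlluminance(mkSky(-30, 90, 0))
  expect_gt(eFull, 0.1)
  expect_lt(eFull, 0.4)
  # overcast factor is exactly multiplicative
  p <- lightParams()
  expect_equal(surfaceIlluminance(mkSky(-30, 90, 0, okta = 8L)),
               p$oktaTransmission[9] * eFull)
  # non-negative and monotone non-increasing in okta across random skies
  set.seed(4)
  for (i in 1:25) {
    sun <- runif(1, -90, 90); moon <- runif(1, -90, 90)
    ph <- runif(1, 0, 180)
    e <- vapply(0:8, function(k)
      surfaceIlluminance(mkSky(sun, moon, ph, as.integer(k))), numeric(1))
    expect_true(all(e >= 0))
    expect_true(all(diff(e) <= 1e-12))
  }
  # daylight dwarfs moonlight
  expect_gt(surfaceIlluminance(mkSky(40, -10, 90)), 5e4)
  expect_error(surfaceIlluminance(mkSky(0, 0, 0), params = list()),
               "extinction")
})

test_that("attenuation is exponential at bin midpoints with a hard floor", {
  # closed form: 1 lx through 10 m at Kd 0.3 is e^-3
  lp <- attenuateProfile(1, 0.3, binEdges = c(9.95, 10.05))
  expect_equal(illuminance(lp), exp(-3), tolerance = 1e-12)
  # flooring: everything below 0.001 lx reads exactly zero
  lp2 <- attenuateProfile(0.06, 0.5)
  e <- illuminance(lp2)
  expect_true(all(e == 0 | e >= 0.001))
  expect_true(any(e == 0))
  # pre-floor curve is monotone non-increasing and flooring never raises
  raw <- 0.06 * exp(-0.5 * binMidDepth(lp2))
  expect_true(all(diff(raw) <= 0))
  expect_true(all(e <= raw + 1e-15))
  # Kd 0: no attenuation
  expect_true(all(illuminance(attenuateProfile(2, 0)) == 2))
  # default grid covers the full water column in 10 cm bins
  expect_equal(length(illuminance(lp2)), 167)
  expect_error(attenuateProfile(1, -0.1), "non-negative")
})

test_that("radiometric conversions follow the photopic curve", {
  # blue-green underwater approximation at 500 nm
  expect_equal(luxToIrradiance(0.06, 500), 2.72e-4, tolerance = 0.01)
  expect_equal(irradianceToPhotonFlux(luxToIrradiance(0.06, 500), 500),
               1.14e-3, tolerance = 0.01)
  # the scotopic floor at 520 nm
  expect_equal(luxToIrradiance(0.001, 520), 2.06e-6, tolerance = 0.005)
  expect_equal(luxToIrradiance(0, 500), 0)
  expect_equal(irradianceToPhotonFlux(1, 520), 4.347, tolerance = 1e-3)
  # lux -> W -> lux is the identity
  lx <- c(0.001, 0.06, 13.7)
  for (wl in c(480, 500, 520, 555)) {
    expect_equal(irradianceToLux(luxToIrradiance(lx, wl), wl), lx,
                 tolerance = 1e-12)
  }
  expect_error(luxToIrradiance(1, 900), "photopic table")
  expect_error(luxToIrradiance(-1, 500), "non-negative")
})

test_that("light profile tables carry all three unit systems per bin", {
  lp <- attenuateProfile(0.06, 0.25)
  tab <- lightProfileTable(lp, "p1")
  expect_equal(nrow(tab), 167)
  expect_equal(tab$bin_index, 0:166)
  expect_equal(tab$irradiance_w_m2,
               luxToIrradiance(tab$illuminance_lx, 500), tolerance = 1e-12)
})
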