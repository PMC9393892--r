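test_that("frequency scaling multiplies centers and round-trips", {
  s <- stick_spectrum(c(1700, 1500), c(10, 5), "IR", "x")
  expect_equal(scale_frequencies(s, 1)$frequency, s$frequency)
  expect_equal(scale_frequencies(stick_spectrum(1700, 1, "IR"), 0.980)$frequency,
               1666.0)
  expect_equal(scale_frequencies(scale_frequencies(s, 0.97), 1 / 0.97)$frequency,
               s$frequency, tolerance = 1e-12)
  expect_error(scale_frequencies(s, 0), "invalid scaling factor")
  expect_error(scale_frequencies(s, -1), "invalid scaling factor")
})

test_that("a broadened band has the requested full width at half maximum", {
  s <- stick_spectrum(1650, 100, "IR")
  for (fwhm in c(10, 16)) {
    spec <- lorentzian_broaden(s, fwhm = fwhm,
                               grid_spec = c(1500, 1800, 0.05))
    imax <- which.max(spec$intensity)
    half <- spec$intensity[imax] / 2
    above <- range(which(spec$intensity >= half))
    width <- spec$wavenumber[above[2]] - spec$wavenumber[above[1]]
    expect_equal(width, fwhm, tolerance = 0.1)
    expect_equal(spec$wavenumber[imax], 1650, tolerance = 0.2)
  }
})

test_that("band areas integrate to strength * frequency * conversion", {
  # sticks separated by > 100*fwhm so the +-50*fwhm windows are disjoint
  s <- stick_spectrum(c(700, 1800), c(80, 30), "IR")
  fwhm <- 10
  spec <- lorentzian_broaden(s, fwhm = fwhm, grid_spec = c(100, 2400, 0.1))
  c_ir <- 1e-40 / 2.296e-39  # documented dipole-strength conversion
  for (k in 1:2) {
    nu0 <- s$frequency[k]
    sel <- spec$wavenumber >= nu0 - 50 * fwhm & spec$wavenumber <= nu0 + 50 * fwhm
    area <- sum(diff(spec$wavenumber[sel]) *
                  (spec$intensity[sel][-1] + head(spec$intensity[sel], -1))) / 2
    expect_equal(area, s$strength[k] * nu0 * c_ir, tolerance = 0.03)
  }
  # empty stick list broadens to zero
  empty <- stick_spectrum(numeric(0), numeric(0), "IR")
  expect_true(all(lorentzian_broaden(empty,
                                     grid_spec = c(1000, 1100, 1))$intensity == 0))
})

test_that("broadening is linear in the sticks", {
  set.seed(41)
  f1 <- sort(stats::runif(3, 1500, 1800))
  f2 <- sort(stats::runif(4, 1500, 1800))
  g <- c(1300, 2000, 0.5)
  s1 <- stick_spectrum(f1, stats::runif(3, 1, 10), "VCD")
  s2 <- stick_spectrum(f2, stats::runif(4, -10, 10), "VCD")
  both <- stick_spectrum(c(f1, f2), c(s1$strength, s2$strength), "VCD")
  expect_equal(lorentzian_broaden(both, 10, g)$intensity,
               lorentzian_broaden(s1, 10, g)$intensity +
                 lorentzian_broaden(s2, 10, g)$intensity,
               tolerance = 1e-12)
})

test_that("ensemble averaging is the pointwise weighted sum", {
  set.seed(42)
  g <- c(1400, 1900, 1)
  sticks <- lapply(1:3, function(k) {
    stick_spectrum(sort(stats::runif(4, 1550, 1750)),
                   stats::runif(4, -50, 50), "VCD", label = paste0("c", k))
  })
  w <- tibble::tibble(label = paste0("c", 1:3), delta_e = 0,
                      weight = c(0.5, 0.3, 0.2))
  spec <- ensemble_spectrum(sticks, w, fwhm = 10, grid_spec = g)
  manual <- Reduce(`+`, Map(function(s, wt)
    wt * lorentzian_broaden(s, 10, g)$intensity, sticks, w$weight))
  expect_equal(spec$intensity, manual, tolerance = 1e-12)

  # single conformer with weight 1 equals its broadened sticks
  w1 <- w[1, ]; w1$weight <- 1
  expect_equal(ensemble_spectrum(sticks[1], w1, 10, g)$intensity,
               lorentzian_broaden(sticks[[1]], 10, g)$intensity)

  # identical sticks under any weights collapse to the single spectrum
  same <- lapply(1:3, function(k) {
    s <- sticks[[1]]; attr(s, "label") <- paste0("c", k); s
  })
  expect_equal(ensemble_spectrum(same, w, 10, g)$intensity,
               lorentzian_broaden(sticks[[1]], 10, g)$intensity,
               tolerance = 1e-12)

  # permuting weights together with spectra changes nothing
  perm <- c(3, 1, 2)
  expect_equal(ensemble_spectrum(sticks[perm], w[perm, ], 10, g)$intensity,
               spec$intensity)
  # label mismatch is an error
  wbad <- w; wbad$label <- c("c1", "c2", "zz")
  expect_error(ensemble_spectrum(sticks, wbad, 10, g), "inconsistent ensemble")
})

test_that("intensity matching scales the strongest band to the reference", {
  s <- stick_spectrum(c(1600, 1700), c(10, 30), "IR")
  calc <- lorentzian_broaden(s, 10, c(1400, 1900, 1))
  ref <- calc; ref$intensity <- 2 * ref$intensity
  m <- match_intensity(calc, ref)
  expect_equal(m$factor, 2)
  expect_equal(m$spectrum$intensity, ref$intensity)
  expect_equal(match_intensity(calc, calc)$factor, 1)

  toyc <- continuous_spectrum(seq(1, 10), c(0, 0.4, 0.1, 0, 0, 0, 0, 0, 0, 0))
  toyr <- continuous_spectrum(seq(1, 10), c(0, 0, 0, -1.2, 0, 0, 0, 0, 0, 0))
  expect_equal(match_intensity(toyc, toyr)$factor, 3.0)

  zero <- continuous_spectrum(seq(1, 10), rep(0, 10))
  expect_error(match_intensity(zero, ref), "cannot scale zero spectrum")
})

test_that("sign patterns reproduce signed band sequences", {
  pos <- lorentzian_broaden(stick_spectrum(1650, 5, "VCD"), 10,
                            c(1500, 1800, 1))
  expect_equal(attr(sign_pattern(pos, c(1500, 1800)), "pattern"), "+")

  # four alternating bands at the assigned amide I frequencies of a cyclic
  # tetrapeptide: -/+/+/- reading from high to low wavenumber
  amide <- lorentzian_broaden(
    stick_spectrum(c(1643, 1650, 1668, 1673), c(-1, 1, 1, -1) * 50, "VCD"),
    10, c(1500, 1800, 1))
  pat <- sign_pattern(amide, c(1500, 1800))
  expect_equal(attr(pat, "pattern"), "-/+/+/-")
  expect_equal(pat$sign, c(-1, 1, 1, -1))
  expect_false(is.unsorted(rev(pat$wavenumber)))

  # mirror spectrum flips every sign
  mirror <- amide; mirror$intensity <- -mirror$intensity
  expect_equal(sign_pattern(mirror, c(1500, 1800))$sign, -pat$sign)
  expect_error(sign_pattern(amide, c(2000, 2100)), "empty region")
})

test_that("scaling then broadening equals broadening with scaled centers", {
  set.seed(43)
  s <- stick_spectrum(sort(stats::runif(5, 1500, 1750)),
                      stats::runif(5, -20, 20), "VCD")
  f <- 0.975
  g <- c(1300, 1900, 0.5)
  direct <- lorentzian_broaden(scale_frequencies(s, f), 10, g)
  manual <- lorentzian_broaden(stick_spectrum(s$frequency * f, s$strength,
                                              "VCD"), 10, g)
  expect_equal(direct$intensity, manual$intensity)
})
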