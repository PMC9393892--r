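broadened <- function(freq, strength, modality = "VCD",
                      grid = c(1400, 1900, 1), fwhm = 10) {
  lorentzian_broaden(stick_spectrum(freq, strength, modality), fwhm, grid)
}

test_that("self-overlap is 1 and mirror overlap is -1", {
  set.seed(51)
  spec <- broadened(sort(stats::runif(4, 1500, 1800)),
                    stats::runif(4, -50, 50))
  expect_equal(overlap_estimate(spec, spec, c(1500, 1800)), 1, tolerance = 1e-9)
  neg <- spec; neg$intensity <- -neg$intensity
  expect_equal(overlap_estimate(spec, neg, c(1500, 1800)), -1,
               tolerance = 1e-9)
})

test_that("overlap of two displaced Lorentzians matches the closed form", {
  # int L(x) L(x - d) dx = (G/pi) / (d^2 + G^2)  => S = G^2 / (d^2 + G^2)
  g <- 10; d <- 10
  nu <- seq(1000, 2400, 0.25)
  lor <- function(c0) (g / (2 * pi)) / ((nu - c0)^2 + (g / 2)^2)
  a <- continuous_spectrum(nu, lor(1700))
  b <- continuous_spectrum(nu, lor(1700 - d))
  expect_equal(overlap_estimate(a, b), g^2 / (d^2 + g^2), tolerance = 1e-3)
})

test_that("overlap is symmetric, scale-invariant and bounded", {
  set.seed(52)
  for (rep in 1:20) {
    a <- broadened(sort(stats::runif(3, 1500, 1800)), stats::runif(3, -9, 9))
    b <- broadened(sort(stats::runif(3, 1500, 1800)), stats::runif(3, -9, 9))
    s <- overlap_estimate(a, b, c(1450, 1850))
    expect_true(s >= -1 && s <= 1)
    expect_equal(s, overlap_estimate(b, a, c(1450, 1850)))
    a5 <- a; a5$intensity <- 5 * a5$intensity
    expect_equal(overlap_estimate(a5, b, c(1450, 1850)), s, tolerance = 1e-12)
  }
  zero <- continuous_spectrum(seq(1500, 1800), rep(0, 301))
  a <- broadened(1650, 5)
  expect_error(overlap_estimate(a, zero), "zero norm")
})

test_that("overlap is stable under grid refinement", {
  set.seed(53)
  freq <- sort(stats::runif(4, 1550, 1750))
  str <- stats::runif(4, -40, 40)
  s1 <- broadened(freq, str, grid = c(1400, 1900, 1))
  s2 <- broadened(freq + 4, str, grid = c(1400, 1900, 1))
  coarse <- overlap_estimate(s1, s2)
  f1 <- broadened(freq, str, grid = c(1400, 1900, 0.5))
  f2 <- broadened(freq + 4, str, grid = c(1400, 1900, 0.5))
  fine <- overlap_estimate(f1, f2)
  expect_equal(coarse, fine, tolerance = 1e-4)
})

test_that("single-band overlap degrades monotonically with separation", {
  base <- broadened(1650, 10)
  seps <- c(0, 2, 5, 10, 20, 40)
  vals <- vapply(seps, function(d)
    overlap_estimate(base, broadened(1650 + d, 10)), numeric(1))
  expect_false(is.unsorted(rev(vals)))
  expect_equal(vals[1], 1, tolerance = 1e-9)
})

test_that("restrict_region truncates and normalizes orientation", {
  nu <- seq(1000, 2000)
  spec <- continuous_spectrum(nu, sin(nu / 50))
  full <- restrict_region(spec, c(1000, 2000))
  expect_equal(full$wavenumber, spec$wavenumber)
  cut <- restrict_region(spec, c(1500, 1800))
  expect_equal(nrow(cut), 301)
  rev_cut <- restrict_region(spec, c(1800, 1500))
  expect_equal(rev_cut, cut)
  expect_error(restrict_region(spec, c(3000, 3100)), "empty region")
})

test_that("scaling optimization recovers a planted factor exactly", {
  spec <- fixture_spec(n_conformers = 3, n_duplicate_pairs = 0,
                       planted_scale = 0.975, noise_sd = 0, seed = 7)
  ens <- make_ensemble(spec)$ensemble
  tabs <- make_frequency_tables(spec, ens)
  w <- boltzmann_weights(ens, "gibbs")
  px <- make_pseudo_experiment(tabs, w, spec)
  res <- optimize_scaling(calc_ir = lapply(tabs, freq_sticks, "IR"),
                          calc_vcd = lapply(tabs, freq_sticks, "VCD"),
                          weights = w, exp_ir = px$ir, exp_vcd = px$vcd,
                          region = c(1500, 1800))
  expect_equal(res$scaling_factor, 0.975, tolerance = 1e-9)
  expect_equal(res$s_ir, 1, tolerance = 1e-3)
  expect_equal(res$s_vcd, 1, tolerance = 1e-3)

  # identity distortion recovers f = 1
  spec1 <- fixture_spec(n_conformers = 3, n_duplicate_pairs = 0,
                        planted_scale = 1.0, noise_sd = 0, seed = 8)
  ens1 <- make_ensemble(spec1)$ensemble
  tabs1 <- make_frequency_tables(spec1, ens1)
  w1 <- boltzmann_weights(ens1, "gibbs")
  px1 <- make_pseudo_experiment(tabs1, w1, spec1)
  res1 <- optimize_scaling(calc_ir = lapply(tabs1, freq_sticks, "IR"),
                           calc_vcd = lapply(tabs1, freq_sticks, "VCD"),
                           weights = w1, exp_ir = px1$ir, exp_vcd = px1$vcd)
  expect_equal(res1$scaling_factor, 1.0, tolerance = 1e-9)
})

test_that("negating the experimental VCD lowers the objective by 2*S_VCD", {
  spec <- fixture_spec(n_conformers = 2, n_duplicate_pairs = 0,
                       planted_scale = 0.98, seed = 9)
  ens <- make_ensemble(spec)$ensemble
  tabs <- make_frequency_tables(spec, ens)
  w <- boltzmann_weights(ens, "gibbs")
  px <- make_pseudo_experiment(tabs, w, spec)
  ir <- lapply(tabs, freq_sticks, "IR")
  vcd <- lapply(tabs, freq_sticks, "VCD")
  fr <- c(0.96, 1.0, 0.01)
  res <- optimize_scaling(ir, vcd, w, px$ir, px$vcd, f_range = fr)
  neg_vcd <- px$vcd; neg_vcd$intensity <- -neg_vcd$intensity
  res_neg <- optimize_scaling(ir, vcd, w, px$ir, neg_vcd, f_range = fr)
  expect_equal(res_neg$scan$objective,
               res$scan$objective - 2 * res$scan$s_vcd, tolerance = 1e-9)
})

test_that("tidy and glance summarize a comparison", {
  spec <- fixture_spec(n_conformers = 2, n_duplicate_pairs = 0, seed = 10)
  ens <- make_ensemble(spec)$ensemble
  tabs <- make_frequency_tables(spec, ens)
  w <- boltzmann_weights(ens, "gibbs")
  px <- make_pseudo_experiment(tabs, w, spec)
  res <- optimize_scaling(lapply(tabs, freq_sticks, "IR"),
                          lapply(tabs, freq_sticks, "VCD"),
                          w, px$ir, px$vcd, f_range = c(0.97, 0.98, 0.005))
  td <- tidy(res)
  expect_equal(td$modality, c("IR", "VCD"))
  expect_true(all(abs(td$overlap) <= 1))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$objective, sum(td$overlap))
})
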