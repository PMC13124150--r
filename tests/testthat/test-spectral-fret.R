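test_that("scale_donor_reference matches integrals and recovers quench", {
  ds <- make_fret_dataset(spectra_scenario(true_efficiency = 0))
  # identical spectra -> scale 1
  sc <- scale_donor_reference(ds$f280_notag, ds$f280_notag)
  expect_equal(attr(sc, "scale_factor"), 1)
  expect_equal(sc$intensity, ds$f280_notag$intensity)

  # doubled donor -> scale 2
  dbl <- ds$f280_notag
  dbl$intensity <- 2 * dbl$intensity
  expect_equal(attr(scale_donor_reference(dbl, ds$f280_notag),
                    "scale_factor"), 2)

  # generator with donor quench q -> scale factor (1 - q)
  for (q in c(0.1, 0.45, 0.8)) {
    d <- make_fret_dataset(spectra_scenario(true_efficiency = q))
    got <- attr(scale_donor_reference(d$f280, d$f280_notag),
                "scale_factor")
    expect_equal(got, 1 - q, tolerance = 1e-12)
  }

  zero <- spectrum(300:500, rep(0, 201), kind = "emission",
                   excitation_nm = 280)
  expect_acd_error(scale_donor_reference(ds$f280, zero),
                   "degenerate_spectrum_error")
})

test_that("extract_acceptor_spectrum recovers the acceptor band", {
  # donor-only input: residual ~ 0 over the acceptor window
  ds0 <- make_fret_dataset(spectra_scenario(true_efficiency = 0))
  donor_only <- ds0$f280_notag
  scaled <- scale_donor_reference(donor_only, ds0$f280_notag)
  resid <- extract_acceptor_spectrum(donor_only, scaled)
  idx <- which(resid$abscissa >= 410 & resid$abscissa <= 480)
  expect_lt(max(abs(resid$intensity[idx])), 1e-12)

  # known mixture: recovered band area within 1% of generator's
  sc <- spectra_scenario(true_efficiency = 0.4)
  ds <- make_fret_dataset(sc)
  scaled <- scale_donor_reference(ds$f280, ds$f280_notag)
  ext <- extract_acceptor_spectrum(ds$f280, scaled)
  amp <- sc$ratio_a0_true + sc$proportionality_m * sc$true_efficiency
  expect_equal(sum(ext$intensity), amp * sum(ds$f370$intensity),
               tolerance = 0.01)
})

test_that("ratio_a handles proportional, zero, and generator cases", {
  f370 <- gauss_spectrum(center = 420, width = 35, grid = 300:500)
  prop <- f370
  prop$intensity <- 0.7 * f370$intensity
  r <- ratio_a(prop, f370)
  expect_equal(r$ratio_a, 0.7, tolerance = 1e-12)
  expect_lt(r$flatness, 1e-12)

  zero <- spectrum(300:500, rep(0, 201), kind = "emission",
                   excitation_nm = 280)
  expect_equal(ratio_a(zero, f370)$ratio_a, 0)

  # generator arithmetic: ratio_a0 0.5 + FRET term 0.24 -> 0.74
  ds <- make_fret_dataset(spectra_scenario(true_efficiency = 0.3,
                                           ratio_a0_true = 0.5,
                                           proportionality_m = 0.8))
  scaled <- scale_donor_reference(ds$f280, ds$f280_notag)
  ext <- extract_acceptor_spectrum(ds$f280, scaled)
  expect_equal(ratio_a(ext, ds$f370)$ratio_a, 0.74, tolerance = 1e-9)

  neg <- f370
  neg$intensity[neg$abscissa == 450] <- 0
  expect_acd_error(ratio_a(prop, neg), "division_error")
})

test_that("ratio_a0 is the free-acceptor ratio", {
  f370 <- gauss_spectrum(center = 420, width = 35, grid = 300:500)
  half <- f370
  half$intensity <- 0.5 * f370$intensity
  expect_equal(ratio_a0(half, f370), 0.5, tolerance = 1e-12)

  zero <- spectrum(300:500, rep(0, 201), kind = "emission",
                   excitation_nm = 280)
  expect_equal(ratio_a0(zero, f370), 0)

  ds <- make_fret_dataset(spectra_scenario(ratio_a0_true = 0.45,
                                           noise_sd = 0.005, seed = 7))
  expect_equal(ratio_a0(ds$free_f280, ds$free_f370), 0.45,
               tolerance = 0.02)
})

test_that("relative_fret subtracts and fills ratio_a_result", {
  expect_equal(relative_fret(0.74, 0.50), 0.24)
  expect_equal(relative_fret(0.5, 0.5), 0)
  ds <- make_fret_dataset(spectra_scenario(true_efficiency = 0.3))
  res <- spectral_fret_analysis(ds$f280, ds$f370, ds$f280_notag,
                                ratio_a0 = 0.5)
  expect_equal(res$relative_fret, res$ratio_a - res$ratio_a0)
})

test_that("noise-free pipeline recovers E through the proportionality", {
  m <- 0.8
  for (E in c(0.05, 0.3, 0.7)) {
    ds <- make_fret_dataset(spectra_scenario(true_efficiency = E,
                                             proportionality_m = m))
    a0 <- ratio_a0(ds$free_f280, ds$free_f370)
    res <- spectral_fret_analysis(ds$f280, ds$f370, ds$f280_notag, a0)
    expect_equal(res$relative_fret / m, E, tolerance = 0.03)
  }
})

test_that("ratio_a invariances and monotonicity in true E", {
  ds <- make_fret_dataset(spectra_scenario(true_efficiency = 0.3))
  scaled <- scale_donor_reference(ds$f280, ds$f280_notag)
  ext <- extract_acceptor_spectrum(ds$f280, scaled)
  base <- ratio_a(ext, ds$f370)$ratio_a
  # common positive rescaling leaves the ratio unchanged
  ext2 <- ext; ext2$intensity <- ext$intensity * 3.7
  f370b <- ds$f370; f370b$intensity <- ds$f370$intensity * 3.7
  expect_equal(ratio_a(ext2, f370b)$ratio_a, base, tolerance = 1e-12)

  # relative_fret strictly increasing in E; nonnegative; flatness -> 0
  rf <- sapply(seq(0, 0.8, by = 0.2), function(E) {
    d <- make_fret_dataset(spectra_scenario(true_efficiency = E))
    a0 <- ratio_a0(d$free_f280, d$free_f370)
    r <- spectral_fret_analysis(d$f280, d$f370, d$f280_notag, a0)
    expect_lt(r$flatness, 1e-9)
    r$relative_fret
  })
  expect_true(all(diff(rf) > 0))
  expect_true(all(rf >= -1e-12))
})

test_that("compare_conditions: null case, known shift, reversibility", {
  apo <- c(0.2, 0.21, 0.19, 0.2)
  cmp0 <- compare_conditions(apo, apo)
  expect_equal(cmp0$mean_delta, 0)
  expect_equal(cmp0$p_value, 1)

  # N = 4 replicates, true shift 0.1, noise sd 0.01
  set.seed(99)
  a <- 0.2 + rnorm(4, 0, 0.01)
  b <- 0.3 + rnorm(4, 0, 0.01)
  cmp <- compare_conditions(a, b, construct_id = "K169Acd")
  expect_lt(cmp$p_value, 0.01)
  expect_lt(abs(cmp$mean_delta - 0.1), 0.02)

  # full reversal -> reversibility near 1
  rev <- a + rnorm(4, 0, 0.005)
  cmpr <- compare_conditions(a, b, reversal = rev)
  expect_gt(cmpr$reversibility, 0.9)

  expect_acd_error(compare_conditions(a, b[1:3]), "pairing_error")
  expect_acd_error(compare_conditions(0.1, 0.2), "statistics_error")
})

test_that("condition vocabulary warns on free text", {
  expect_warning(check_condition("znso4"), class = "condition_warning")
  expect_silent(check_condition("zinc_edta"))
})
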