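test_that("read_spectrum parses, validates, and round-trips", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("380,0.1", "381,0.2", "382,0.15"), f)
  s <- read_spectrum(f, "emission", excitation_nm = 280)
  expect_s3_class(s, "spectrum")
  expect_length(s, 3L)
  expect_equal(s$intensity, c(0.1, 0.2, 0.15))

  # header line and tab delimiter are auto-handled
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("wavelength\tintensity", "400\t1", "401\t2", "402\t3"), f2)
  s2 <- read_spectrum(f2, "absorption")
  expect_equal(s2$abscissa, c(400, 401, 402))

  # duplicated abscissa -> monotonicity violation
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("380,0.1", "380,0.2", "382,0.15"), f3)
  expect_acd_error(read_spectrum(f3, "absorption"), "format_error")

  # too few rows
  f4 <- tempfile(fileext = ".csv")
  writeLines(c("380,0.1", "381,0.2"), f4)
  expect_acd_error(read_spectrum(f4, "absorption"), "format_error")

  # write-then-read round trip preserves a generated spectrum
  g <- gauss_spectrum()
  f5 <- tempfile(fileext = ".csv")
  write_spectrum(g, f5)
  g2 <- read_spectrum(f5, "emission", excitation_nm = 370)
  expect_equal(g2$abscissa, g$abscissa, tolerance = 1e-9)
  expect_equal(g2$intensity, g$intensity, tolerance = 1e-9)
})

test_that("spectrum constructor enforces invariants", {
  expect_acd_error(spectrum(1:3, 1:2, kind = "absorption"), "format_error")
  expect_acd_error(spectrum(c(1, 2, 2), 1:3, kind = "absorption"),
                   "format_error")
  expect_acd_error(spectrum(1:3, 1:3, kind = "emission"), "format_error")
  expect_silent(spectrum(1:3, 1:3, kind = "emission", excitation_nm = 280))
})

test_that("subtract_blank handles identity, zero, and generator recovery", {
  s <- gauss_spectrum()
  z <- subtract_blank(s, s)
  expect_equal(z$intensity, rep(0, length(s)))

  blank0 <- spectrum(s$abscissa, rep(0, length(s)), kind = "emission",
                     excitation_nm = 370)
  expect_equal(subtract_blank(s, blank0)$intensity, s$intensity)

  # sample = blank + known band: subtraction recovers the band exactly
  band <- make_band(430, 12, amplitude = 0.7, grid = s$abscissa)
  sample <- spectrum(s$abscissa, s$intensity + band$intensity,
                     kind = "emission", excitation_nm = 370)
  rec <- subtract_blank(sample, s)
  expect_equal(rec$intensity, band$intensity, tolerance = 1e-12)

  mismatched <- gauss_spectrum(grid = 360:500)
  expect_acd_error(subtract_blank(s, mismatched), "grid_error")
  # but works when interpolation is allowed
  expect_s3_class(subtract_blank(s, mismatched, interpolate = TRUE),
                  "spectrum")
})

test_that("interpolate_to_grid is linear, identity on native grid, and
           refuses extrapolation", {
  s <- spectrum(c(400, 402, 404), c(0, 2, 0), kind = "absorption")
  expect_identical(interpolate_to_grid(s, s$abscissa), s)
  fine <- interpolate_to_grid(s, c(400, 401, 402, 403, 404))
  expect_equal(fine$intensity, c(0, 1, 2, 1, 0))
  expect_acd_error(interpolate_to_grid(s, c(399, 401)), "range_error")

  # refine-then-coarsen round trip preserves values on original knots
  set.seed(11)
  r <- spectrum(seq(300, 400, by = 2), runif(51), kind = "absorption")
  refined <- interpolate_to_grid(r, seq(300, 400, by = 0.5))
  back <- interpolate_to_grid(refined, r$abscissa)
  expect_equal(back$intensity, r$intensity, tolerance = 1e-12)
})

test_that("normalize supports max, at_abscissa, region_integral and is
           idempotent", {
  s <- gauss_spectrum(center = 420)
  expect_equal(max(normalize(s, "max")$intensity), 1)

  at <- normalize(s, "at_abscissa", arg = 420)
  expect_equal(at$intensity, normalize(s, "max")$intensity,
               tolerance = 1e-12)

  flat <- spectrum(seq(0, 10, by = 1), rep(5, 11), kind = "absorption")
  ri <- normalize(flat, "region_integral", arg = c(0, 10))
  # constant c with integral c * 10 = 1, i.e. 5 / (5 * 10)
  expect_equal(ri$intensity, rep(0.1, 11))

  for (args in list(list(mode = "max"),
                    list(mode = "at_abscissa", arg = 420),
                    list(mode = "region_integral", arg = c(380, 460)))) {
    once <- do.call(normalize, c(list(s), args))
    twice <- do.call(normalize, c(list(once), args))
    expect_equal(twice$intensity, once$intensity, tolerance = 1e-12)
  }

  zero <- spectrum(1:5, rep(0, 5), kind = "absorption")
  expect_acd_error(normalize(zero, "max"), "degenerate_spectrum_error")
})

test_that("locate_maximum: symmetry, smoothing oracle, scaling invariance,
           interval restriction", {
  s <- gauss_spectrum(center = 420, grid = 350:500)
  expect_equal(locate_maximum(s), 420)

  # smoothing path matches an independently computed moving average
  set.seed(42)
  noisy <- spectrum(350:500,
                    s$intensity + rnorm(151, 0, 0.05),
                    kind = "emission", excitation_nm = 370)
  got <- locate_maximum(noisy, smooth_window = 5)
  sm <- oracle_moving_average(noisy$intensity, 5)
  expect_equal(got, noisy$abscissa[which.max(sm)])

  # invariant to positive rescaling
  scaled <- noisy
  scaled$intensity <- noisy$intensity * 37.5
  expect_equal(locate_maximum(scaled, smooth_window = 5), got)

  # interval restriction and tie-break toward smallest abscissa
  two <- spectrum(1:10, c(0, 5, 0, 0, 0, 0, 5, 0, 0, 0),
                  kind = "absorption")
  expect_equal(locate_maximum(two), 2)
  expect_equal(locate_maximum(two, search_interval = c(5, 10)), 7)
  expect_acd_error(locate_maximum(two, search_interval = c(11, 12)),
                   "range_error")
})
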