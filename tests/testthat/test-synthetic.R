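test_that("make_band: symmetry, zero amplitude, additivity", {
  b <- make_band(420, 30, 1, 300:500)
  expect_equal(locate_maximum(b), 420)
  expect_equal(max(b$intensity), 1)

  z <- make_band(420, 30, 0, 300:500)
  expect_equal(z$intensity, rep(0, 201))

  b2 <- make_band(350, 20, 0.5, 300:500)
  both <- b$intensity + b2$intensity
  grid <- 300:500
  direct <- exp(-((grid - 420)^2) / (2 * 30^2)) +
    0.5 * exp(-((grid - 350)^2) / (2 * 20^2))
  expect_equal(both, direct, tolerance = 1e-12)
})

test_that("make_fret_dataset satisfies its construction identity", {
  # E = 0 -> relative_fret 0
  d0 <- make_fret_dataset(spectra_scenario(true_efficiency = 0))
  a0 <- ratio_a0(d0$free_f280, d0$free_f370)
  r0 <- spectral_fret_analysis(d0$f280, d0$f370, d0$f280_notag, a0)
  expect_equal(r0$relative_fret, 0, tolerance = 1e-12)

  # E = 0.3, m = 0.8, noise 0 -> exactly 0.24
  d <- make_fret_dataset(spectra_scenario(true_efficiency = 0.3,
                                          proportionality_m = 0.8))
  a0 <- ratio_a0(d$free_f280, d$free_f370)
  r <- spectral_fret_analysis(d$f280, d$f370, d$f280_notag, a0)
  expect_equal(r$relative_fret, 0.24, tolerance = 1e-12)

  # sweep E at noise 0: slope m recovered, r = 1
  E <- seq(0.1, 0.9, by = 0.1)
  rf <- sapply(E, function(e) {
    dd <- make_fret_dataset(spectra_scenario(true_efficiency = e,
                                             proportionality_m = 0.8))
    aa <- ratio_a0(dd$free_f280, dd$free_f370)
    spectral_fret_analysis(dd$f280, dd$f370, dd$f280_notag,
                           aa)$relative_fret
  })
  fit <- correlate_and_fit(rf, E)
  expect_equal(fit$slope_m, 0.8, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
})

test_that("generators are seed-deterministic", {
  a <- make_fret_dataset(spectra_scenario(noise_sd = 0.02, seed = 5))
  b <- make_fret_dataset(spectra_scenario(noise_sd = 0.02, seed = 5))
  expect_identical(a$f280$intensity, b$f280$intensity)

  d1 <- make_decay(c(3, 16), c(0.4, 0.6), n_photons = 1e4, seed = 9)
  d2 <- make_decay(c(3, 16), c(0.4, 0.6), n_photons = 1e4, seed = 9)
  expect_identical(d1$counts, d2$counts)

  t1 <- make_flux_trace(seed = 11)
  t2 <- make_flux_trace(seed = 11)
  expect_identical(t1$fluorescence, t2$fluorescence)
})

test_that("make_helix_bundle geometry matches its ground-truth record", {
  # two CA sites placed at a recorded distance: Forster midpoint check
  tb <- make_helix_bundle(toy_structure_scenario(
    n_chains = 2L, n_res = 3L,
    chain_offsets = list(c(0, 0, 0), c(23.5, 0, 0)),
    sites = data.frame(chain = c(1, 2), resid = c(2, 2),
                       resname = c("TRP", "ACD"))))
  d <- tb$distances$distance[tb$distances$site1 == "A2" &
                             tb$distances$site2 == "B2"]
  expect_equal(d, 23.5, tolerance = 1e-9)
  dd <- distance_distribution(
    label_ensemble(as.numeric(tb$sites[1, c("x", "y", "z")])),
    label_ensemble(as.numeric(tb$sites[2, c("x", "y", "z")])))
  expect_equal(pair_efficiency(dd, 23.5), 0.5, tolerance = 1e-9)

  # duplicated chain: intersubunit distances equal the translation
  off <- c(12, 5, -3)
  tb2 <- make_helix_bundle(toy_structure_scenario(
    n_chains = 2L, n_res = 8L,
    chain_offsets = list(c(0, 0, 0), off),
    sites = data.frame(chain = c(1, 2), resid = c(4, 4),
                       resname = c("TRP", "TRP"))))
  expect_equal(tb2$distances$distance[1], sqrt(sum(off^2)),
               tolerance = 1e-9)

  # minimal single-residue scenario parses after writing
  f <- tempfile(fileext = ".pdb")
  make_helix_bundle(toy_structure_scenario(n_chains = 1L, n_res = 1L),
                    path = f)
  m <- load_structure(f)
  expect_equal(nrow(m$atoms), 3L)
})

test_that("make_decay histogram moments match the generator", {
  d <- make_decay(15, 1, irf_sigma = 0.2, n_photons = 1e6, seed = 77,
                  t_max = 200, t0 = 5)
  mean_arrival <- sum(d$time_bins * d$counts) / sum(d$counts)
  expect_equal(mean_arrival, 15 + 5, tolerance = 0.01)

  # degenerate amplitudes (1, 0) reduce to the single component
  da <- make_decay(c(15, 3), c(1, 0), irf_sigma = 0.2, n_photons = 1e5,
                   seed = 78)
  db <- make_decay(15, 1, irf_sigma = 0.2, n_photons = 1e5, seed = 78)
  expect_identical(da$counts, db$counts)
})
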