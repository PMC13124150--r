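test_that("build_label_ensemble: no-clash, total-clash, and oracle cases", {
  # isolated residue: all 9 conformers survive with uniform weights
  lone <- make_helix_bundle(toy_structure_scenario(n_chains = 1L,
                                                   n_res = 1L))
  e <- build_label_ensemble(lone$model, "A", 1, "TRP")
  expect_equal(nrow(e$points), 9L)
  expect_equal(e$weights, rep(1 / 9, 9))
  expect_equal(sum(e$weights), 1, tolerance = 1e-9)

  # cage of obstructing atoms at 2 A around the site: every conformer
  # clashes
  ca <- helix_like_center <- c(2.3, 0, 1.5)
  cage <- expand.grid(x = seq(-8, 12, by = 2), y = seq(-10, 10, by = 2),
                      z = seq(-8, 10, by = 2))
  caged <- make_helix_bundle(toy_structure_scenario(
    n_chains = 1L, n_res = 1L, obstructions = cage))
  expect_acd_error(build_label_ensemble(caged$model, "A", 1, "TRP"),
                   "empty_ensemble_error")

  # single obstructing atom: survivors equal the brute-force oracle
  for (seed in 1:5) {
    set.seed(seed)
    obs <- data.frame(x = rnorm(2, 2, 2), y = rnorm(2, 0, 2),
                      z = rnorm(2, 3, 2))
    tb <- make_helix_bundle(toy_structure_scenario(
      n_chains = 1L, n_res = 6L, obstructions = obs))
    ens <- tryCatch(build_label_ensemble(tb$model, "A", 3, "ACD"),
                    acdfret_error = function(e) NULL)
    cand <- if (is.null(ens)) NULL else attr(ens, "candidates")
    if (is.null(ens)) next
    keep_oracle <- oracle_clash_filter(tb$model, "A", 3, cand, 2.5)
    expect_identical(!attr(ens, "clashed"), unname(keep_oracle))
    expect_equal(nrow(ens$points), sum(keep_oracle))
  }

  expect_acd_error(build_label_ensemble(lone$model, "Z", 1, "TRP"),
                   "site_error")
})

test_that("boltzmann weighting down-weights near-clashing conformers", {
  lone <- make_helix_bundle(toy_structure_scenario(n_chains = 1L,
                                                   n_res = 6L))
  e <- build_label_ensemble(lone$model, "A", 3, "TRP",
                            weighting = "boltzmann")
  expect_equal(nrow(e$points), 9L)  # nothing dropped, only reweighted
  expect_equal(sum(e$weights), 1, tolerance = 1e-9)
  expect_true(all(e$weights >= 0))
})

test_that("distance_distribution: 3-4-5, product weights, brute force", {
  d1 <- distance_distribution(label_ensemble(c(0, 0, 0)),
                              label_ensemble(c(3, 4, 0)))
  expect_equal(d1$distances, 5)
  expect_equal(d1$weights, 1)

  d2 <- distance_distribution(
    label_ensemble(rbind(c(0, 0, 0), c(1, 0, 0))),
    label_ensemble(rbind(c(10, 0, 0), c(0, 10, 0))))
  expect_length(d2$distances, 4L)
  expect_equal(d2$weights, rep(0.25, 4))
  expect_equal(sum(d2$weights), 1, tolerance = 1e-9)

  # seeded random ensembles: weighted mean matches the double loop
  set.seed(31)
  p1 <- matrix(rnorm(15, sd = 4), 5)
  p2 <- matrix(rnorm(12, sd = 4) + 15, 4)
  w1 <- runif(5); w2 <- runif(4)
  dd <- distance_distribution(label_ensemble(p1, w1),
                              label_ensemble(p2, w2))
  expect_equal(sum(dd$weights * dd$distances),
               oracle_mean_distance(p1, w1 / sum(w1), p2, w2 / sum(w2)),
               tolerance = 1e-12)

  expect_acd_error(
    distance_distribution(label_ensemble(c(0, 0, 0)),
                          label_ensemble(c(0, 0, 0))),
    "degenerate_distance_error")
})

test_that("pair_efficiency: Forster midpoint, limits, closed form,
           monotonicity", {
  at <- function(r) distance_distribution(label_ensemble(c(0, 0, 0)),
                                          label_ensemble(c(r, 0, 0)))
  expect_equal(pair_efficiency(at(23.5), 23.5), 0.5)
  expect_equal(pair_efficiency(at(2.35), 23.5), 1 / (1 + 1e-6))

  # two distances {R0, 2 R0}, equal weights
  dd <- distance_distribution(
    label_ensemble(c(0, 0, 0)),
    label_ensemble(rbind(c(20.9, 0, 0), c(41.8, 0, 0))))
  expect_equal(pair_efficiency(dd, 20.9), (0.5 + 1 / 65) / 2,
               tolerance = 1e-12)

  # strictly decreasing in distance, bounded in (0, 1)
  effs <- sapply(seq(5, 60, by = 5),
                 function(r) pair_efficiency(at(r), 23.5))
  expect_true(all(diff(effs) < 0))
  expect_true(all(effs > 0 & effs < 1))

  # <E(r)> vs E(<r>) modes differ for a spread distribution
  expect_false(isTRUE(all.equal(pair_efficiency(dd, 20.9),
                                pair_efficiency(dd, 20.9, "distance"))))
})

test_that("donor_efficiency_multi_acceptor: pair reduction, k-sum, MC vs
           enumeration", {
  don <- label_ensemble(c(0, 0, 0))
  a1 <- label_ensemble(c(23.5, 0, 0))
  expect_equal(as.numeric(donor_efficiency_multi_acceptor(don, a1, 23.5)),
               0.5)

  a2 <- label_ensemble(c(0, 23.5, 0))
  expect_equal(as.numeric(
    donor_efficiency_multi_acceptor(don, list(a1, a2), 23.5)), 2 / 3)

  # single-acceptor enumeration equals pair_efficiency on the distribution
  set.seed(17)
  dens <- label_ensemble(matrix(rnorm(9, sd = 3), 3), runif(3))
  aens <- label_ensemble(matrix(rnorm(9, sd = 3) + 22, 3), runif(3))
  expect_equal(
    as.numeric(donor_efficiency_multi_acceptor(dens, aens, 23.5)),
    pair_efficiency(distance_distribution(dens, aens), 23.5),
    tolerance = 1e-12)

  # adding an acceptor cannot reduce E
  e1 <- as.numeric(donor_efficiency_multi_acceptor(dens, aens, 23.5))
  far <- label_ensemble(matrix(rnorm(9, sd = 3) - 40, 3), runif(3))
  e2 <- as.numeric(donor_efficiency_multi_acceptor(dens, list(aens, far),
                                                   23.5))
  expect_gte(e2, e1)

  # MC agrees with enumeration within 3 standard errors; seeded runs are
  # bit-reproducible
  mc1 <- donor_efficiency_multi_acceptor(dens, list(aens, far), 23.5,
                                         n_samples = 5e4, seed = 8,
                                         enumeration_limit = 1)
  mc2 <- donor_efficiency_multi_acceptor(dens, list(aens, far), 23.5,
                                         n_samples = 5e4, seed = 8,
                                         enumeration_limit = 1)
  expect_identical(as.numeric(mc1), as.numeric(mc2))
  expect_lt(abs(as.numeric(mc1) - e2), 3 * attr(mc1, "std_error"))

  expect_acd_error(
    donor_efficiency_multi_acceptor(dens, aens, 23.5, n_samples = 10,
                                    enumeration_limit = 1),
    "precision_error")
})

test_that("construct_prediction: symmetry, modes, rigid-motion invariance", {
  tb <- toy_dimer()
  m <- tb$model

  p_all <- construct_prediction(m, 15, mode = "all_donors", seed = 3)
  p_intra <- construct_prediction(m, 15, mode = "intrasubunit", seed = 3)

  # symmetric dimer: the two donors see mirror-image geometry
  expect_equal(p_all$per_donor$efficiency[1],
               p_all$per_donor$efficiency[2], tolerance = 1e-6)
  # all_donors >= intrasubunit
  expect_gte(p_all$efficiency, p_intra$efficiency)
  # intrasubunit equals the one-acceptor value for each donor
  expect_equal(p_intra$per_donor$n_acceptors, c(1L, 1L))

  # rigid-body rotation + translation leaves predictions unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(rot)
  m2$atoms$x <- xyz[, 1] + 11
  m2$atoms$y <- xyz[, 2] - 5
  m2$atoms$z <- xyz[, 3] + 2
  p_rot <- construct_prediction(m2, 15, mode = "all_donors", seed = 3)
  expect_equal(p_rot$efficiency, p_all$efficiency, tolerance = 1e-9)

  # acceptor site missing in a chain -> site error
  expect_acd_error(construct_prediction(m, 99), "site_error")

  # the substituted native residue is excluded from the donor list
  tb2 <- make_helix_bundle(toy_structure_scenario(
    n_chains = 2L, n_res = 20L,
    sites = data.frame(chain = c(1, 2, 1, 2), resid = c(5, 5, 15, 15),
                       resname = c("TRP", "TRP", "TYR", "TYR"))))
  p <- construct_prediction(tb2$model, 15, mode = "all_donors", seed = 3)
  expect_equal(nrow(p$per_donor), 2L)  # the two TYR at 15 are replaced
  expect_true(all(p$per_donor$resid != 15))
})

test_that("all_donors >= intrasubunit across sites and seeds", {
  for (seed in 1:3) {
    tb <- toy_dimer(seed = seed, n_res = 18L, offset = 20 + 3 * seed)
    for (site in c(10L, 15L)) {
      ea <- construct_prediction(tb$model, site, mode = "all_donors",
                                 seed = seed)$efficiency
      ei <- construct_prediction(tb$model, site, mode = "intrasubunit",
                                 seed = seed)$efficiency
      expect_gte(ea, ei)
      expect_true(ea >= 0 && ea < 1)
    }
  }
})

test_that("correlate_and_fit: identity, proportionality, closed form", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  f1 <- correlate_and_fit(x, x)
  expect_equal(f1$pearson_r, 1)
  expect_equal(f1$slope_m, 1)

  f2 <- correlate_and_fit(2 * x, x)
  expect_equal(f2$pearson_r, 1)
  expect_equal(f2$slope_m, 2)

  # hand closed form for x = (1,2,3), y = (2,4,7):
  # m = sum(xy)/sum(x^2) = (2 + 8 + 21)/14 = 31/14
  f3 <- correlate_and_fit(c(2, 4, 7), c(1, 2, 3))
  expect_equal(f3$slope_m, 31 / 14)
  expect_equal(f3$pearson_r, stats::cor(c(1, 2, 3), c(2, 4, 7)))

  expect_acd_error(correlate_and_fit(c(1, 2), c(1, 2)),
                   "statistics_error")
  expect_acd_error(correlate_and_fit(c(1, 1, 1), c(1, 2, 3)),
                   "statistics_error")
})

test_that("ensembles export as multi-model PDB", {
  lone <- make_helix_bundle(toy_structure_scenario(n_chains = 1L,
                                                   n_res = 1L))
  e <- build_label_ensemble(lone$model, "A", 1, "ACD")
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(list(e), f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^MODEL", lines)), nrow(e$points))
  expect_equal(sum(grepl("^HETATM", lines)), nrow(e$points))
})
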