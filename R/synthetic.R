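#' Synthetic data with recorded ground truth
#'
#' Every pipeline stage has a matching generator that emits the same file
#' formats and containers the stage consumes, together with the exact
#' parameters used to build the data (`$truth`), so recovery tests compare
#' against a known answer. All generators are deterministic given their
#' seed.
#'
#' @name synthetic_data
NULL

#' Gaussian spectral band
#'
#' @param center,width Band center and Gaussian width (sd), both in the
#'   grid's units.
#' @param amplitude Peak amplitude.
#' @param grid Abscissa grid (default 300:500 nm).
#' @param support Optional interval outside which the band is exactly zero.
#'   Used by [make_fret_dataset()] to keep donor and acceptor bands out of
#'   each other's analysis windows so noise-free identities hold exactly.
#' @param kind,excitation_nm,sample_id Spectrum metadata.
#' @return A [spectrum()].
#' @export
make_band <- function(center, width, amplitude = 1, grid = 300:500,
                      support = NULL, kind = "emission",
                      excitation_nm = 370, sample_id = "band") {
  y <- amplitude * exp(-((grid - center)^2) / (2 * width^2))
  if (!is.null(support)) {
    y[grid < support[1] | grid > support[2]] <- 0
  }
  spectrum(grid, y, kind = kind, excitation_nm = excitation_nm,
           sample_id = sample_id)
}

#' Spectral FRET scenario
#'
#' Bundles the ground-truth parameters of a synthetic Ratio A dataset. The
#' construction guarantees ratio_a - ratio_a0 = proportionality_m *
#' true_efficiency before noise.
#'
#' @param true_efficiency True FRET efficiency E in `[0, 1)`.
#' @param ratio_a0_true Direct-excitation ratio (> 0), default 0.5.
#' @param proportionality_m Proportionality between relative FRET and E,
#'   default 0.8.
#' @param donor_quench Fraction of donor emission lost to transfer;
#'   `NULL` (default) couples it to `true_efficiency`, so donor loss and
#'   acceptor gain move together.
#' @param donor_center,donor_width Donor band (nm), default 335 / 25.
#' @param acceptor_center,acceptor_width Acceptor band (nm),
#'   default 420 / 35 (broad enough that the directly excited acceptor is
#'   well above zero across the whole 410-480 nm averaging window, as a
#'   real acridone emission spectrum is).
#' @param noise_sd Gaussian noise sd as a fraction of each spectrum's peak.
#' @param seed Integer seed.
#' @param grid Wavelength grid, default 300:500 at 1 nm.
#' @return A list of class `spectra_scenario`.
#' @export
spectra_scenario <- function(true_efficiency = 0.3, ratio_a0_true = 0.5,
                             proportionality_m = 0.8, donor_quench = NULL,
                             donor_center = 335, donor_width = 25,
                             acceptor_center = 420, acceptor_width = 35,
                             noise_sd = 0, seed = 1L, grid = 300:500) {
  if (true_efficiency < 0 || true_efficiency >= 1) {
    acd_error("true_efficiency must be in [0, 1)", "range_error")
  }
  if (ratio_a0_true <= 0 || proportionality_m <= 0) {
    acd_error("ratio_a0_true and proportionality_m must be > 0",
              "range_error")
  }
  if (is.null(donor_quench)) donor_quench <- true_efficiency
  structure(list(true_efficiency = true_efficiency,
                 ratio_a0_true = ratio_a0_true,
                 proportionality_m = proportionality_m,
                 donor_quench = donor_quench,
                 donor_center = donor_center, donor_width = donor_width,
                 acceptor_center = acceptor_center,
                 acceptor_width = acceptor_width,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 grid = grid),
            class = "spectra_scenario")
}

#' Generate a synthetic spectral FRET dataset
#'
#' Builds the five spectra of one Ratio A measurement from a
#' [spectra_scenario()]:
#' * `f370` = acceptor band (direct excitation);
#' * `f280` = (1 - donor_quench) x donor band +
#'   (ratio_a0_true + m x E) x acceptor band;
#' * `f280_notag` = donor band (donor-only control);
#' * `free_f370` = acceptor band, `free_f280` = ratio_a0_true x acceptor
#'   band (free acceptor, no donor).
#'
#' The donor band is zeroed above 405 nm and the acceptor band below
#' 365 nm: without this truncation, Gaussian tails leak ~1e-6 of intensity
#' into the 300-360 nm scaling window and the 410-480 nm averaging window,
#' breaking the exact identity relative_fret = m x E that noise-free data
#' must satisfy. Seeded Gaussian noise (sd = `noise_sd` x peak, per
#' spectrum) is added last.
#'
#' @param scenario A [spectra_scenario()].
#' @return A list of class `spectral_fret_input`: the five spectra plus
#'   `truth` (the scenario).
#' @export
make_fret_dataset <- function(scenario = spectra_scenario()) {
  stopifnot(inherits(scenario, "spectra_scenario"))
  sc <- scenario
  donor <- make_band(sc$donor_center, sc$donor_width, 1, sc$grid,
                     support = c(-Inf, 405), excitation_nm = 280,
                     sample_id = "donor_band")
  acceptor <- make_band(sc$acceptor_center, sc$acceptor_width, 1, sc$grid,
                        support = c(365, Inf), excitation_nm = 370,
                        sample_id = "acceptor_band")
  mix <- function(dw, aw, ex, id) {
    spectrum(sc$grid, dw * donor$intensity + aw * acceptor$intensity,
             kind = "emission", excitation_nm = ex, sample_id = id)
  }
  acc280 <- sc$ratio_a0_true + sc$proportionality_m * sc$true_efficiency
  out <- list(
    f280 = mix(1 - sc$donor_quench, acc280, 280, "sample_f280"),
    f370 = mix(0, 1, 370, "sample_f370"),
    f280_notag = mix(1, 0, 280, "notag_f280"),
    free_f280 = mix(0, sc$ratio_a0_true, 280, "free_acd_f280"),
    free_f370 = mix(0, 1, 370, "free_acd_f370")
  )
  if (sc$noise_sd > 0) {
    out <- with_seed(sc$seed, lapply(out, function(s) {
      s$intensity <- s$intensity +
        stats::rnorm(length(s$intensity), 0,
                     sc$noise_sd * max(abs(s$intensity)))
      s
    }))
  }
  out$truth <- sc
  class(out) <- "spectral_fret_input"
  out
}

#' Write a synthetic FRET dataset as CSV files plus a manifest
#'
#' Emits one CSV per spectrum and a tab-separated manifest with columns
#' `construct_id`, `condition`, `replicate`, `role`, `path` in the layout
#' [run_spectral_fret()] consumes.
#'
#' @param dataset A `spectral_fret_input`.
#' @param dir Output directory (created if needed).
#' @param construct_id,condition,replicate Manifest fields.
#' @return The manifest path, invisibly.
#' @export
write_fret_dataset <- function(dataset, dir, construct_id = "synthetic",
                               condition = "apo", replicate = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roles <- c(f280 = "f280", f370 = "f370", f280_notag = "f280_notag",
             free_f280 = "free_acd_280", free_f370 = "free_acd_370")
  rows <- lapply(names(roles), function(nm) {
    fn <- file.path(dir, sprintf("%s_%s_r%d_%s.csv", construct_id,
                                 condition, replicate, nm))
    write_spectrum(dataset[[nm]], fn)
    cid <- if (startsWith(roles[[nm]], "free_acd")) "free_acd"
           else construct_id
    data.frame(construct_id = cid, condition = condition,
               replicate = replicate, role = roles[[nm]], path = fn,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, sprintf("manifest_%s_%s_r%d.tsv", construct_id,
                                  condition, replicate))
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mpath)
}

#' Toy structure scenario
#'
#' @param n_chains Number of chains (identical helices related by the
#'   translations in `chain_offsets`).
#' @param n_res Residues per chain.
#' @param chain_offsets List of length-3 translation vectors, one per
#'   chain. Default stacks chains along x at 25 A spacing.
#' @param chain_rotations Optional list of 3x3 rotation matrices applied
#'   to each chain before its translation; `NULL` means identity for all.
#'   A 180-degree rotation on the second chain gives a C2-symmetric
#'   dimer, the geometry of a physiological homodimer.
#' @param sites data.frame with columns `chain` (index into chains),
#'   `resid`, `resname` assigning TRP/TYR/ACD identities to positions;
#'   remaining residues are ALA.
#' @param obstructions Optional data.frame of extra heteroatoms
#'   (columns x, y, z) used to exercise clash filtering.
#' @param seed Integer seed (recorded; generation is deterministic).
#' @return A list of class `toy_structure_scenario`.
#' @export
toy_structure_scenario <- function(n_chains = 2L, n_res = 20L,
                                   chain_offsets = NULL,
                                   chain_rotations = NULL, sites = NULL,
                                   obstructions = NULL, seed = 1L) {
  if (is.null(chain_offsets)) {
    chain_offsets <- lapply(seq_len(n_chains) - 1L,
                            function(i) c(25 * i, 0, 0))
  }
  if (length(chain_offsets) != n_chains) {
    acd_error("one offset per chain required", "format_error")
  }
  if (is.null(chain_rotations)) {
    chain_rotations <- rep(list(diag(3)), n_chains)
  }
  if (length(chain_rotations) != n_chains) {
    acd_error("one rotation per chain required", "format_error")
  }
  structure(list(n_chains = n_chains, n_res = n_res,
                 chain_offsets = chain_offsets,
                 chain_rotations = chain_rotations, sites = sites,
                 obstructions = obstructions, seed = as.integer(seed)),
            class = "toy_structure_scenario")
}

# Ideal alpha-helix backbone point at (possibly fractional) residue index:
# 2.3 A radius, 1.5 A rise and 100 degrees twist per residue.
helix_point <- function(i, radius = 2.3, rise = 1.5, twist = 100) {
  th <- deg2rad(twist) * i
  c(radius * cos(th), radius * sin(th), rise * i)
}

#' Build a toy helix-bundle structure
#'
#' Writes ideal poly-alanine helices (1.5 A rise, 100 degree twist per
#' residue) with N/CA/C backbone atoms, assigns TRP/TYR/ACD residue names
#' at the requested sites, adds any obstructing pseudo-atoms, and records
#' ground-truth CA coordinates for every special site. The model is valid
#' input for [load_structure()] (when written) and
#' [build_label_ensemble()].
#'
#' @param scenario A [toy_structure_scenario()].
#' @param path Optional output PDB path; when given the file is written.
#' @return A list: `model` (a `structure_model`), `path` (or NULL),
#'   `sites` (data.frame of special sites with their CA coordinates), and
#'   `distances` (data.frame of pairwise CA-CA distances between special
#'   sites).
#' @export
make_helix_bundle <- function(scenario = toy_structure_scenario(),
                              path = NULL) {
  stopifnot(inherits(scenario, "toy_structure_scenario"))
  sc <- scenario
  chain_ids <- LETTERS[seq_len(sc$n_chains)]
  rows <- list()
  for (ci in seq_len(sc$n_chains)) {
    off <- sc$chain_offsets[[ci]]
    rot <- sc$chain_rotations[[ci]]
    for (ri in seq_len(sc$n_res)) {
      resname <- "ALA"
      if (!is.null(sc$sites)) {
        hit <- sc$sites$chain == ci & sc$sites$resid == ri
        if (any(hit)) resname <- sc$sites$resname[which(hit)[1]]
      }
      for (at in c("N", "CA", "C")) {
        frac <- switch(at, N = ri - 1 / 3, CA = ri, C = ri + 1 / 3)
        p <- as.vector(rot %*% helix_point(frac)) + off
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain_ids[ci], resid = ri, resname = resname, atom = at,
          element = substr(at, 1, 1), x = p[1], y = p[2], z = p[3],
          het = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(sc$obstructions)) {
    for (oi in seq_len(nrow(sc$obstructions))) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "X", resid = oi, resname = "OBS", atom = "O",
        element = "O", x = sc$obstructions$x[oi],
        y = sc$obstructions$y[oi], z = sc$obstructions$z[oi],
        het = TRUE, stringsAsFactors = FALSE)
    }
  }
  model <- new_structure_model(do.call(rbind, rows))

  sites <- NULL
  dists <- NULL
  if (!is.null(sc$sites)) {
    a <- model$atoms
    sites <- do.call(rbind, lapply(seq_len(nrow(sc$sites)), function(i) {
      ch <- chain_ids[sc$sites$chain[i]]
      ca <- a[a$chain == ch & a$resid == sc$sites$resid[i] &
              a$atom == "CA", ]
      data.frame(chain = ch, resid = sc$sites$resid[i],
                 resname = sc$sites$resname[i],
                 x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
    }))
    if (nrow(sites) > 1L) {
      pairs <- utils::combn(nrow(sites), 2)
      dists <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        i1 <- pairs[1, j]; i2 <- pairs[2, j]
        data.frame(
          site1 = paste0(sites$chain[i1], sites$resid[i1]),
          site2 = paste0(sites$chain[i2], sites$resid[i2]),
          distance = sqrt(sum((as.numeric(sites[i1, c("x", "y", "z")]) -
                               as.numeric(sites[i2, c("x", "y", "z")]))^2)),
          stringsAsFactors = FALSE)
      }))
    }
  }
  if (!is.null(path)) write_structure_pdb(model, path)
  list(model = model, path = path, sites = sites, distances = dists)
}

#' Simulate a TCSPC decay histogram
#'
#' Photon arrival times are drawn from the amplitude-weighted mixture of
#' exponentials (amplitudes are photon fractions), jittered by a Gaussian
#' IRF centered at `t0`, and histogrammed on uniform bins. The IRF
#' histogram is emitted as the analytic Gaussian profile (a measured IRF
#' is acquired at high counts; a noiseless reference keeps the fit's
#' reduced chi-square interpretable). `irf_sigma = 0` gives a delta IRF.
#'
#' @param lifetimes Component lifetimes (ns).
#' @param amplitudes Photon fractions per component (normalized to 1).
#' @param irf_sigma Gaussian IRF width (ns).
#' @param n_photons Total photons to draw.
#' @param seed Integer seed.
#' @param t_max,dt Histogram range `[0, t_max]` ns and bin width (ns).
#' @param t0 IRF center (ns).
#' @param background Uniform background counts per bin (Poisson-sampled
#'   when > 0).
#' @return A `decay_histogram` with attribute `truth` (list of the
#'   generator parameters, including `mean_lifetime`).
#' @export
make_decay <- function(lifetimes, amplitudes = NULL, irf_sigma = 0.2,
                       n_photons = 1e6, seed = 1L, t_max = 80, dt = 0.04,
                       t0 = 5, background = 0) {
  lifetimes <- as.numeric(lifetimes)
  if (any(lifetimes <= 0)) acd_error("lifetimes must be > 0",
                                     "range_error")
  k <- length(lifetimes)
  if (is.null(amplitudes)) amplitudes <- rep(1 / k, k)
  if (length(amplitudes) != k || any(amplitudes < 0) ||
      sum(amplitudes) <= 0) {
    acd_error("amplitudes must be nonnegative, one per lifetime",
              "range_error")
  }
  amplitudes <- amplitudes / sum(amplitudes)
  breaks <- seq(0, t_max, by = dt)
  centers <- breaks[-1] - dt / 2
  with_seed(seed, {
    comp <- sample.int(k, n_photons, replace = TRUE, prob = amplitudes)
    arrival <- t0 + stats::rexp(n_photons, rate = 1 / lifetimes[comp])
    if (irf_sigma > 0) {
      arrival <- arrival + stats::rnorm(n_photons, 0, irf_sigma)
    }
    arrival <- arrival[arrival >= 0 & arrival <= t_max]
    counts <- as.numeric(table(cut(arrival, breaks = breaks,
                                   include.lowest = TRUE,
                                   labels = FALSE))[
      as.character(seq_along(centers))])
    counts[is.na(counts)] <- 0
    if (background > 0) {
      counts <- counts + stats::rpois(length(counts), background)
    }
    irf <- if (irf_sigma > 0) {
      stats::dnorm(centers, t0, irf_sigma) * dt * 1e6
    } else {
      v <- numeric(length(centers))
      v[which.min(abs(centers - t0))] <- 1e6
      v
    }
    d <- decay_histogram(centers, counts, irf)
    attr(d, "truth") <- list(lifetimes = lifetimes,
                             amplitudes = amplitudes,
                             mean_lifetime = sum(amplitudes * lifetimes),
                             irf_sigma = irf_sigma, t0 = t0,
                             n_photons = n_photons, background = background,
                             seed = seed)
    d
  })
}

#' Simulate an ACMA proton-flux trace
#'
#' Three phases on a 5 s sampling grid: a flat baseline, an exponential
#' quench of the given extent and rate after valinomycin, and a fast
#' collapse to the floor after CCCP. The raw trace is an affine transform
#' (gain and offset) of the ideal normalized trace plus Gaussian noise, so
#' normalization must undo gain and offset exactly.
#'
#' @param extent Quench extent in `[0, 1]`.
#' @param rate Quench rate (1/s).
#' @param noise_sd Noise sd on the normalized scale.
#' @param seed Integer seed.
#' @param baseline_s Baseline duration before valinomycin (default 180 s,
#'   a 3 min baseline).
#' @param quench_s Valinomycin-to-CCCP duration (default 340 s).
#' @param post_s Post-CCCP duration (default 100 s).
#' @param dt Sampling interval (default 5 s).
#' @param gain,offset Instrument affine transform applied to the ideal
#'   trace.
#' @param cccp_rate Rate of the post-CCCP collapse (default 0.1 1/s).
#' @param step_quench If TRUE the valinomycin quench is an instantaneous
#'   step instead of an exponential.
#' @return A `flux_trace` with events `valinomycin` and `cccp` and
#'   attribute `truth`.
#' @export
make_flux_trace <- function(extent = 0.6, rate = 0.01, noise_sd = 0.01,
                            seed = 1L, baseline_s = 180, quench_s = 340,
                            post_s = 100, dt = 5, gain = 1000,
                            offset = 200, cccp_rate = 0.1,
                            step_quench = FALSE) {
  if (extent < 0 || extent > 1) acd_error("extent must be in [0, 1]",
                                          "range_error")
  t <- seq(0, baseline_s + quench_s + post_s, by = dt)
  t_val <- baseline_s
  t_cccp <- baseline_s + quench_s
  ideal <- numeric(length(t))
  pre <- t <= t_val
  mid <- t > t_val & t <= t_cccp
  post <- t > t_cccp
  ideal[pre] <- 1
  ideal[mid] <- if (step_quench) 1 - extent
                else 1 - extent * (1 - exp(-rate * (t[mid] - t_val)))
  v_c <- if (step_quench) 1 - extent
         else 1 - extent * (1 - exp(-rate * quench_s))
  ideal[post] <- v_c * exp(-cccp_rate * (t[post] - t_cccp))
  raw <- with_seed(seed, offset + gain * ideal +
                   gain * stats::rnorm(length(t), 0, noise_sd))
  tr <- flux_trace(t, raw,
                   events = data.frame(label = c("valinomycin", "cccp"),
                                       time = c(t_val, t_cccp)))
  attr(tr, "truth") <- list(extent = extent, rate = rate,
                            noise_sd = noise_sd, gain = gain,
                            offset = offset, t_val = t_val,
                            t_cccp = t_cccp, seed = seed,
                            step_quench = step_quench)
  tr
}
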