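# Shared fixtures and independent oracles used across test files.

# A clean Gaussian emission band on an integer grid.
gauss_spectrum <- function(center = 420, width = 30, grid = 350:500,
                           amplitude = 1, ex = 370) {
  spectrum(grid, amplitude * exp(-((grid - center)^2) / (2 * width^2)),
           kind = "emission", excitation_nm = ex)
}

# Brute-force centered moving average (independent of the package's).
oracle_moving_average <- function(y, w) {
  h <- (w - 1) %/% 2
  sapply(seq_along(y), function(i) {
    mean(y[max(1, i - h):min(length(y), i + h)])
  })
}

# Brute-force weighted mean distance between two point clouds.
oracle_mean_distance <- function(p1, w1, p2, w2) {
  tot <- 0; wsum <- 0
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
    d <- sqrt(sum((p1[i, ] - p2[j, ])^2))
    tot <- tot + w1[i] * w2[j] * d
    wsum <- wsum + w1[i] * w2[j]
  }
  tot / wsum
}

# Brute-force clash filter: which candidate points survive against the
# environment atoms of `model`, excluding the site's own residue.
oracle_clash_filter <- function(model, chain, resid, candidates, cutoff) {
  env <- model$atoms
  env <- env[!(env$chain == chain & env$resid == resid), , drop = FALSE]
  env <- env[toupper(env$element) != "H", , drop = FALSE]
  apply(candidates, 1, function(p) {
    if (nrow(env) == 0) return(TRUE)
    ok <- TRUE
    for (j in seq_len(nrow(env))) {
      d <- sqrt(sum((p - c(env$x[j], env$y[j], env$z[j]))^2))
      if (d < cutoff) { ok <- FALSE; break }
    }
    ok
  })
}

# C2-symmetric toy dimer with one Trp per chain: chain B is chain A
# rotated 180 degrees about z and translated along x, so the two-fold
# axis maps each chain onto the other exactly.
toy_dimer <- function(seed = 1L, n_res = 20L, offset = 25) {
  make_helix_bundle(toy_structure_scenario(
    n_chains = 2L, n_res = n_res,
    chain_offsets = list(c(0, 0, 0), c(offset, 0, 0)),
    chain_rotations = list(diag(3), diag(c(-1, -1, 1))),
    sites = data.frame(chain = c(1, 2), resid = c(5, 5),
                       resname = c("TRP", "TRP")),
    seed = seed))
}

expect_acd_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
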