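#' Label rotamer ensembles and structure-based FRET prediction
#'
#' Fluorophore positions are represented as weighted point clouds
#' ("label ensembles"): one reference point (the ring-system centroid) per
#' sampled side-chain conformer. Conformers are generated by a simplified
#' kinematic chain grown off the site's backbone, with chi dihedrals drawn
#' from a small built-in set, and filtered by a hard-sphere clash test
#' against the environment. Donor-acceptor distance distributions between
#' two ensembles then feed the Forster relation E = 1/(1 + (r/R0)^6),
#' averaged over the distribution.
#'
#' @name structure_fret
NULL

# Forster radii in Angstrom for the native aromatic donors transferring to
# acridonylalanine; kappa^2 = 2/3 is absorbed into these scalars.
default_r0 <- c(TRP = 23.5, TYR = 20.9)

# Simplified label geometry: bond length (A) from CB to CG, distance (A)
# from CG to the ring-system centroid, and the CB-CG-centroid angle (deg).
# The centroid stands in for the transition-dipole position: indole for
# TRP, phenol for TYR, the tricyclic acridone for ACD.
label_geometry <- list(
  TRP = list(cb_cg = 1.53, cg_ref = 2.40, angle = 125),
  TYR = list(cb_cg = 1.53, cg_ref = 2.10, angle = 125),
  ACD = list(cb_cg = 1.53, cg_ref = 3.80, angle = 120)
)

# Chi-angle branches sampled per rotatable bond (deg).
default_chi_set <- c(-60, 60, 180)

deg2rad <- function(d) d * pi / 180

# Natural-extension-reference-frame placement: position a new atom at the
# given bond length from c, with bond angle b-c-new and torsion a-b-c-new.
nerf_place <- function(a, b, c, length, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) {
    # collinear frame: pick any perpendicular
    n <- pracma_cross(bc, c(1, 0, 0))
    if (sqrt(sum(n^2)) < 1e-9) n <- pracma_cross(bc, c(0, 1, 0))
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- pracma_cross(n, bc)
  d <- c(-length * cos(ang),
         length * sin(ang) * cos(tor),
         length * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Place CB from backbone N, CA, C using ideal L-amino-acid geometry.
place_cb <- function(n, ca, c) {
  nerf_place(c, n, ca, length = 1.53, angle = 110.5, torsion = -122.0)
}

#' Build a fluorophore label ensemble at a site
#'
#' Generates candidate conformers of the label's reference point by
#' sampling chi1/chi2 dihedrals from `chi_set` on an idealized side-chain
#' scaffold grown from the site's backbone (N, CA, C), then rejects
#' candidates whose reference point lies within `clash_cutoff` of any heavy
#' atom outside the site's own residue. Survivors get uniform weights;
#' `weighting = "boltzmann"` instead down-weights candidates smoothly by
#' their worst overlap, with softness `softness` (A).
#'
#' @param model A `structure_model`.
#' @param chain,resid Site identifier (author numbering).
#' @param label_type `"TRP"`, `"TYR"` or `"ACD"`.
#' @param chi_set Dihedral branches (deg) sampled for each of the two
#'   rotatable bonds. Default `c(-60, 60, 180)`.
#' @param clash_cutoff Hard-sphere cutoff in Angstrom (default 2.5).
#' @param weighting `"uniform"` (hard filter, default) or `"boltzmann"`.
#' @param softness Softness (A) of the Boltzmann down-weighting.
#' @return A `label_ensemble`: `site`, `label_type`, `points` (K x 3
#'   matrix), `weights` (sum 1). Attributes `candidates` (all sampled
#'   points) and `clashed` (logical per candidate) support auditing the
#'   filter.
#' @export
build_label_ensemble <- function(model, chain, resid,
                                 label_type = c("TRP", "TYR", "ACD"),
                                 chi_set = default_chi_set,
                                 clash_cutoff = 2.5,
                                 weighting = c("uniform", "boltzmann"),
                                 softness = 0.5) {
  label_type <- match.arg(label_type)
  weighting <- match.arg(weighting)
  res <- site_atoms(model, chain, resid)
  bb <- lapply(c("N", "CA", "C"), function(nm) {
    row <- res[res$atom == nm, , drop = FALSE]
    if (nrow(row) == 0L) {
      acd_error(sprintf("site %s/%d lacks backbone atom %s", chain, resid,
                        nm), "site_error")
    }
    as.numeric(row[1, c("x", "y", "z")])
  })
  names(bb) <- c("N", "CA", "C")
  geom <- label_geometry[[label_type]]
  cb <- place_cb(bb$N, bb$CA, bb$C)

  grid <- expand.grid(chi1 = chi_set, chi2 = chi_set)
  pts <- t(apply(grid, 1, function(chis) {
    cg <- nerf_place(bb$N, bb$CA, cb, length = geom$cb_cg, angle = 114,
                     torsion = chis[1])
    nerf_place(bb$CA, cb, cg, length = geom$cg_ref, angle = geom$angle,
               torsion = chis[2])
  }))
  colnames(pts) <- c("x", "y", "z")

  env <- model$atoms
  env <- env[!(env$chain == chain & env$resid == resid), , drop = FALSE]
  env <- env[toupper(env$element) != "H", , drop = FALSE]
  if (nrow(env)) {
    exyz <- as.matrix(env[, c("x", "y", "z")])
    mind <- apply(pts, 1, function(p) {
      sqrt(min(colSums((t(exyz) - p)^2)))
    })
  } else {
    mind <- rep(Inf, nrow(pts))
  }
  clashed <- mind < clash_cutoff

  if (weighting == "uniform") {
    keep <- !clashed
    if (!any(keep)) {
      acd_error(sprintf(
        "all %d conformers at %s/%d clash (cutoff %.2f A); loosen clash_cutoff or chi_set",
        nrow(pts), chain, resid, clash_cutoff), "empty_ensemble_error")
    }
    points <- pts[keep, , drop = FALSE]
    weights <- rep(1 / sum(keep), sum(keep))
  } else {
    overlap <- pmax(0, clash_cutoff - mind)
    w <- exp(-(overlap / softness)^2)
    if (sum(w) < 1e-12) {
      acd_error(sprintf("all conformers at %s/%d fully clash", chain, resid),
                "empty_ensemble_error")
    }
    points <- pts
    weights <- w / sum(w)
  }

  structure(
    list(site = list(chain = chain, resid = resid),
         label_type = label_type,
         points = points, weights = weights),
    class = "label_ensemble",
    candidates = pts, clashed = clashed
  )
}

#' Construct a label ensemble from explicit points
#'
#' Mostly for tests and synthetic scenarios where reference points are
#' known exactly.
#'
#' @param points Numeric K x 3 matrix (or length-3 vector) of coordinates.
#' @param weights Nonnegative weights; default uniform. Renormalized to 1.
#' @param chain,resid,label_type Site metadata.
#' @return A `label_ensemble`.
#' @export
label_ensemble <- function(points, weights = NULL, chain = "A", resid = 1L,
                           label_type = "ACD") {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  if (ncol(points) != 3L) acd_error("points must be K x 3", "format_error")
  k <- nrow(points)
  if (k < 1L) acd_error("empty ensemble", "empty_ensemble_error")
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) <= 0) {
    acd_error("weights must be nonnegative, same length as points",
              "format_error")
  }
  structure(
    list(site = list(chain = chain, resid = resid),
         label_type = label_type, points = points,
         weights = weights / sum(weights)),
    class = "label_ensemble"
  )
}

#' @export
print.label_ensemble <- function(x, ...) {
  cat(sprintf("<label_ensemble> %s at %s/%d: %d rotamers\n", x$label_type,
              x$site$chain, x$site$resid, nrow(x$points)))
  invisible(x)
}

#' Donor-acceptor distance distribution between two ensembles
#'
#' All pairwise Euclidean distances between donor and acceptor reference
#' points; each pair's weight is the product of rotamer weights,
#' renormalized to 1.
#'
#' @param donor,acceptor `label_ensemble` objects.
#' @return A `distance_distribution`: `distances` (A), `weights`,
#'   `donor_site`, `acceptor_site`.
#' @export
distance_distribution <- function(donor, acceptor) {
  stopifnot(inherits(donor, "label_ensemble"),
            inherits(acceptor, "label_ensemble"))
  dp <- donor$points
  ap <- acceptor$points
  d2 <- outer(rowSums(dp^2), rowSums(ap^2), "+") - 2 * dp %*% t(ap)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-6)) {
    acd_error("coincident donor and acceptor points (zero distance)",
              "degenerate_distance_error")
  }
  w <- outer(donor$weights, acceptor$weights)
  structure(
    list(distances = as.vector(d), weights = as.vector(w) / sum(w),
         donor_site = donor$site, acceptor_site = acceptor$site),
    class = "distance_distribution"
  )
}

#' Distribution-averaged pairwise FRET efficiency
#'
#' The Forster relation for a single donor-acceptor pair at distance r is
#' E(r) = 1 / (1 + (r/R0)^6). The default averages E over the distance
#' distribution (the physically correct expectation for a static ensemble);
#' `average = "distance"` instead evaluates E at the mean distance, the
#' common shortcut, exposed for comparison.
#'
#' @param dist A `distance_distribution`.
#' @param r0 Forster radius in Angstrom (> 0).
#' @param average `"efficiency"` (default, <E(r)>) or `"distance"`
#'   (E(<r>)).
#' @return Efficiency in (0, 1).
#' @export
pair_efficiency <- function(dist, r0, average = c("efficiency", "distance")) {
  average <- match.arg(average)
  stopifnot(inherits(dist, "distance_distribution"))
  if (!is.finite(r0) || r0 <= 0) acd_error("r0 must be > 0", "range_error")
  if (average == "efficiency") {
    sum(dist$weights / (1 + (dist$distances / r0)^6))
  } else {
    r <- sum(dist$weights * dist$distances)
    1 / (1 + (r / r0)^6)
  }
}

# Run code with a temporary RNG state seeded at `seed` (NULL = leave RNG
# alone). Restores the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Efficiency of one donor transferring to several acceptors
#'
#' With one donor and multiple independent acceptors, rate additivity gives
#' E = sum_a k_a / (1 + sum_a k_a) with k_a = (R0 / r_a)^6 for a fixed joint
#' conformer state. The returned value is the expectation of E over joint
#' rotamer states (the donor's rotamer and one rotamer per acceptor, drawn
#' independently by their weights). When the joint state count is at most
#' `enumeration_limit` the expectation is computed by exhaustive
#' enumeration; otherwise by Monte Carlo with `n_samples` draws.
#'
#' @param donor A `label_ensemble`.
#' @param acceptors A single `label_ensemble` or a list of them.
#' @param r0 Forster radius (A).
#' @param n_samples Monte Carlo sample count (>= 100).
#' @param seed Integer seed for the Monte Carlo path; enumeration ignores
#'   it.
#' @param enumeration_limit Joint-state threshold below which exhaustive
#'   enumeration replaces sampling (default 1e4).
#' @return Efficiency in (0, 1). Attribute `"method"` records
#'   `"enumeration"` or `"mc"`; for MC, `"std_error"` carries the standard
#'   error of the estimate.
#' @export
donor_efficiency_multi_acceptor <- function(donor, acceptors, r0,
                                            n_samples = 1e5, seed = NULL,
                                            enumeration_limit = 1e4) {
  if (inherits(acceptors, "label_ensemble")) acceptors <- list(acceptors)
  if (length(acceptors) < 1L) {
    acd_error("need at least one acceptor ensemble", "site_error")
  }
  if (!is.finite(r0) || r0 <= 0) acd_error("r0 must be > 0", "range_error")
  sizes <- c(nrow(donor$points),
             vapply(acceptors, function(a) nrow(a$points), integer(1)))
  n_states <- prod(sizes)

  k_of <- function(dpt, apt) {
    r <- sqrt(sum((dpt - apt)^2))
    if (r < 1e-6) {
      acd_error("coincident donor and acceptor points",
                "degenerate_distance_error")
    }
    (r0 / r)^6
  }

  if (n_states <= enumeration_limit) {
    idx <- expand.grid(lapply(sizes, seq_len))
    e <- 0
    for (row in seq_len(nrow(idx))) {
      di <- idx[row, 1]
      w <- donor$weights[di]
      ksum <- 0
      for (j in seq_along(acceptors)) {
        ai <- idx[row, j + 1]
        w <- w * acceptors[[j]]$weights[ai]
        ksum <- ksum + k_of(donor$points[di, ], acceptors[[j]]$points[ai, ])
      }
      e <- e + w * ksum / (1 + ksum)
    }
    return(structure(e, method = "enumeration"))
  }

  if (n_samples < 100) {
    acd_error("n_samples < 100 with a non-enumerable state space",
              "precision_error")
  }
  with_seed(seed, {
    di <- sample.int(sizes[1], n_samples, replace = TRUE,
                     prob = donor$weights)
    ksum <- numeric(n_samples)
    for (j in seq_along(acceptors)) {
      aj <- acceptors[[j]]
      ai <- sample.int(nrow(aj$points), n_samples, replace = TRUE,
                       prob = aj$weights)
      dvec <- donor$points[di, , drop = FALSE] -
              aj$points[ai, , drop = FALSE]
      r <- sqrt(rowSums(dvec^2))
      if (any(r < 1e-6)) {
        acd_error("coincident donor and acceptor points",
                  "degenerate_distance_error")
      }
      ksum <- ksum + (r0 / r)^6
    }
    ei <- ksum / (1 + ksum)
    structure(mean(ei), method = "mc",
              std_error = stats::sd(ei) / sqrt(n_samples))
  })
}

#' Predict the FRET efficiency of one Acd construct
#'
#' Places acceptor (Acd) ensembles at the given residue in every chain of
#' the model, enumerates the native Trp/Tyr donors (excluding any native
#' residue at the substituted position, which the acceptor replaces), and
#' computes each donor's multi-acceptor efficiency with the donor-type
#' Forster radius. `mode = "intrasubunit"` restricts each donor to the
#' acceptor copy in its own chain; `"all_donors"` lets every donor see both
#' acceptor copies of the dimer. The construct-level efficiency is the
#' donor-weight-weighted mean of per-donor efficiencies.
#'
#' @param model A `structure_model` (a dimer for `all_donors` mode).
#' @param acd_site Residue number of the acceptor site (must exist in every
#'   chain).
#' @param mode `"all_donors"` (default) or `"intrasubunit"`.
#' @param donor_weights Named weights for donor types,
#'   default `c(TRP = 1, TYR = 1)` (equal weighting).
#' @param r0 Named Forster radii (A), default `c(TRP = 23.5, TYR = 20.9)`.
#' @param chi_set,clash_cutoff Passed to [build_label_ensemble()].
#' @param n_samples,seed,enumeration_limit Passed to
#'   [donor_efficiency_multi_acceptor()]; per-donor seeds are derived from
#'   `seed`.
#' @param average `"efficiency"` or `"distance"`; with `"distance"`, each
#'   donor's efficiency is E at the mean donor-acceptor distance (single
#'   acceptor treatment applied per acceptor, then rate-summed at mean
#'   distances).
#' @param construct_id Label for the output; default `"<site>Acd"`.
#' @return A `fret_prediction`: `construct_id`, `mode`, `efficiency`,
#'   `per_donor` (data.frame: chain, resid, type, r0, efficiency,
#'   n_acceptors).
#' @export
construct_prediction <- function(model, acd_site,
                                 mode = c("all_donors", "intrasubunit"),
                                 donor_weights = c(TRP = 1, TYR = 1),
                                 r0 = default_r0,
                                 chi_set = default_chi_set,
                                 clash_cutoff = 2.5,
                                 n_samples = 1e5, seed = NULL,
                                 enumeration_limit = 1e4,
                                 average = c("efficiency", "distance"),
                                 construct_id = NULL) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  stopifnot(inherits(model, "structure_model"))
  if (is.null(construct_id)) construct_id <- paste0(acd_site, "Acd")
  chains <- sort(unique(model$atoms$chain[!model$atoms$het]))
  if (mode == "all_donors" && length(chains) < 2L) {
    acd_error("all_donors mode needs a multi-chain (dimer) model",
              "site_error")
  }
  acceptor_by_chain <- lapply(chains, function(ch) {
    has <- any(model$atoms$chain == ch & model$atoms$resid == acd_site &
               !model$atoms$het)
    if (!has) {
      acd_error(sprintf("Acd site %d missing in chain %s", acd_site, ch),
                "site_error")
    }
    build_label_ensemble(model, ch, acd_site, "ACD", chi_set = chi_set,
                         clash_cutoff = clash_cutoff)
  })
  names(acceptor_by_chain) <- chains

  donors <- find_native_donors(model)
  donors <- donors[donors$resid != acd_site, , drop = FALSE]
  if (nrow(donors) == 0L) {
    acd_error("model has no native Trp/Tyr donors", "site_error")
  }

  per <- lapply(seq_len(nrow(donors)), function(i) {
    d <- donors[i, ]
    dens <- build_label_ensemble(model, d$chain, d$resid, d$resname,
                                 chi_set = chi_set,
                                 clash_cutoff = clash_cutoff)
    acc <- if (mode == "intrasubunit") acceptor_by_chain[d$chain]
           else acceptor_by_chain
    acc <- acc[!vapply(acc, is.null, logical(1))]
    eff <- if (average == "efficiency") {
      donor_efficiency_multi_acceptor(
        dens, unname(acc), r0[[d$resname]], n_samples = n_samples,
        seed = if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max,
        enumeration_limit = enumeration_limit)
    } else {
      # E at mean distances, rates summed across acceptors
      ksum <- sum(vapply(acc, function(a) {
        dd <- distance_distribution(dens, a)
        rbar <- sum(dd$weights * dd$distances)
        (r0[[d$resname]] / rbar)^6
      }, numeric(1)))
      ksum / (1 + ksum)
    }
    data.frame(chain = d$chain, resid = d$resid, type = d$resname,
               r0 = r0[[d$resname]], efficiency = as.numeric(eff),
               n_acceptors = length(acc), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  w <- donor_weights[per$type]
  eff <- sum(w * per$efficiency) / sum(w)

  structure(
    list(construct_id = construct_id, mode = mode,
         efficiency = eff, per_donor = per),
    class = "fret_prediction"
  )
}

#' @export
print.fret_prediction <- function(x, ...) {
  cat(sprintf("<fret_prediction> %s (%s): E = %.4f over %d donors\n",
              x$construct_id, x$mode, x$efficiency, nrow(x$per_donor)))
  invisible(x)
}

#' Correlate measured relative FRET with predicted efficiency
#'
#' The comparison the whole pipeline builds toward: a Pearson correlation
#' between per-construct measured relative FRET and predicted efficiency,
#' plus the least-squares slope of the through-origin line
#' measured = m * predicted (m = sum(xy) / sum(x^2)), since relative FRET
#' is proportional, not equal, to efficiency.
#'
#' @param measured,predicted Matched numeric vectors (n >= 3).
#' @return An `origin_fit`: `slope_m`, `pearson_r`, `n`.
#' @export
correlate_and_fit <- function(measured, predicted) {
  measured <- as.numeric(measured)
  predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted)) {
    acd_error("measured and predicted lengths differ", "pairing_error")
  }
  n <- length(measured)
  if (n < 3L) acd_error("need n >= 3 constructs", "statistics_error")
  if (stats::sd(measured) == 0 || stats::sd(predicted) == 0) {
    acd_error("zero variance in measured or predicted values",
              "statistics_error")
  }
  structure(
    list(slope_m = sum(measured * predicted) / sum(predicted^2),
         pearson_r = stats::cor(measured, predicted), n = n),
    class = "origin_fit"
  )
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("<origin_fit> m = %.4f, Pearson r = %.3f (n = %d)\n",
              x$slope_m, x$pearson_r, x$n))
  invisible(x)
}
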