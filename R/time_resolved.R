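#' TCSPC decay histograms and reconvolution fitting
#'
#' Time-correlated single photon counting records a histogram of photon
#' arrival times. The measured histogram is the true multiexponential decay
#' convolved with the instrument response function (IRF), so lifetimes are
#' recovered by reconvolution fitting: the model is a background plus the
#' discrete convolution of the (optionally time-shifted) IRF with
#' sum_k alpha_k exp(-t / tau_k), and parameters are estimated by weighted
#' least squares with Poisson weights (variance approximated by
#' max(counts, 1)). A Poisson maximum-likelihood objective is available as
#' an option.
#'
#' @name time_resolved
NULL

#' TCSPC decay histogram container
#'
#' @param time_bins Uniformly spaced bin centers (ns).
#' @param counts Nonnegative counts per bin.
#' @param irf_counts Optional IRF histogram on the same bins. Absent IRF is
#'   treated as a delta function at the first bin by [fit_decay()].
#' @return A `decay_histogram`.
#' @export
decay_histogram <- function(time_bins, counts, irf_counts = NULL) {
  time_bins <- as.numeric(time_bins)
  counts <- as.numeric(counts)
  if (length(time_bins) != length(counts)) {
    acd_error("time_bins and counts lengths differ", "format_error")
  }
  if (length(time_bins) < 3L) acd_error("need >= 3 bins", "format_error")
  dt <- diff(time_bins)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    acd_error("time bins must be uniform and increasing", "format_error")
  }
  if (any(counts < 0)) acd_error("negative counts", "format_error")
  if (!is.null(irf_counts)) {
    irf_counts <- as.numeric(irf_counts)
    if (length(irf_counts) != length(counts) || any(irf_counts < 0)) {
      acd_error("irf_counts must be nonnegative, same length as counts",
                "format_error")
    }
  }
  structure(list(time_bins = time_bins, counts = counts,
                 irf_counts = irf_counts),
            class = "decay_histogram")
}

#' Read a decay (or IRF) histogram from two-column text
#'
#' @param path Path to a time (ns) / counts delimited text file.
#' @param irf_path Optional path to the IRF histogram on the same bins.
#' @return A `decay_histogram`.
#' @export
read_decay <- function(path, irf_path = NULL) {
  s <- read_spectrum(path, kind = "chromatogram")  # reuse the 2-col reader
  irf <- NULL
  if (!is.null(irf_path)) {
    si <- read_spectrum(irf_path, kind = "chromatogram")
    if (!isTRUE(all.equal(si$abscissa, s$abscissa))) {
      acd_error("IRF bins differ from decay bins", "grid_error")
    }
    irf <- si$intensity
  }
  decay_histogram(s$abscissa, s$intensity, irf)
}

# Discrete convolution of normalized IRF p with kernel d (both length n),
# returning the first n lags.
reconvolve <- function(p, d) {
  n <- length(d)
  stats::convolve(p, rev(d), type = "open")[seq_len(n)]
}

# Shift the IRF by s ns via linear interpolation on its own grid
# (positive s delays the IRF).
shift_irf <- function(irf, t, s) {
  if (s == 0) return(irf)
  stats::approx(t + s, irf, xout = t, method = "linear", yleft = 0,
                yright = 0, ties = "ordered")$y
}

# Per-component convolved basis curves for given lifetimes; columns are
# unit-amplitude decays convolved with the normalized IRF.
decay_basis <- function(t, irf_norm, lifetimes) {
  trel <- t - t[1]
  vapply(lifetimes, function(tau) reconvolve(irf_norm, exp(-trel / tau)),
         numeric(length(t)))
}

#' Fit a multiexponential decay with IRF reconvolution
#'
#' Variable-projection fit: lifetimes (and optionally an IRF shift) are
#' optimized by [stats::optim()]; at each step the per-component
#' amplitudes and (when free) a constant background are solved by weighted
#' linear least squares with nonnegativity enforced by an active-set
#' clamp. When the histogram carries pre-pulse bins (IRF mass below 1e-9 of
#' its peak) the background is fixed to their mean instead of fitted.
#'
#' Reported amplitudes are fractional photon contributions
#' a_k = alpha_k tau_k / sum_j alpha_j tau_j (summing to 1), so
#' [mean_lifetime()] is the intensity-weighted mean.
#'
#' @param decay A `decay_histogram`.
#' @param n_components Number of exponential components (>= 1).
#' @param init Optional list with `lifetimes` (ns) to start from.
#' @param objective `"wls"` (default) or `"mle"` (Poisson deviance).
#' @param fit_shift Fit an IRF time shift (default FALSE).
#' @return A `decay_fit`: `lifetimes` (ascending, ns), `amplitudes`,
#'   `shift`, `background` (counts/bin), `goodness` (reduced chi-square of
#'   the weighted residuals), `mean_lifetime`, `fitted` (model curve),
#'   `degenerate` (TRUE when components collapse), `convergence`.
#' @export
fit_decay <- function(decay, n_components = 1L, init = NULL,
                      objective = c("wls", "mle"), fit_shift = FALSE) {
  objective <- match.arg(objective)
  stopifnot(inherits(decay, "decay_histogram"))
  k <- as.integer(n_components)
  if (k < 1L) acd_error("n_components must be >= 1", "argument_error")
  t <- decay$time_bins
  y <- decay$counts
  n <- length(y)
  if (sum(y > 0) < 10L * k * 3L) {
    acd_error("too few populated bins for this many components",
              "fit_error")
  }
  irf <- decay$irf_counts
  if (is.null(irf)) {
    irf <- numeric(n)
    irf[1] <- 1
  }
  if (sum(irf) <= 0) acd_error("IRF has no counts", "format_error")

  # fixed background from pre-pulse bins when the IRF leaves room for them
  irf_start <- which(irf > 1e-9 * max(irf))[1]
  bg_fixed <- NA_real_
  if (!is.null(decay$irf_counts) && !is.na(irf_start) && irf_start > 5L) {
    bg_fixed <- mean(y[seq_len(irf_start - 1L)])
  }
  fit_bg <- is.na(bg_fixed)

  w <- 1 / pmax(y, 1)

  # initial lifetimes: spread around the background-corrected mean arrival
  if (is.null(init) || is.null(init$lifetimes)) {
    ybg <- pmax(y - ifelse(fit_bg, 0, bg_fixed), 0)
    t_irf <- sum(t * irf) / sum(irf)
    tau_m <- max(sum(ybg * (t - t_irf)) / sum(ybg), diff(t[1:2]))
    tau0 <- tau_m * 2^seq(-(k - 1) / 2, (k - 1) / 2, length.out = k)
  } else {
    tau0 <- sort(as.numeric(init$lifetimes))
    if (length(tau0) != k || any(tau0 <= 0)) {
      acd_error("init$lifetimes must be n_components positive values",
                "argument_error")
    }
  }

  irf_norm0 <- irf / sum(irf)

  # weighted nonnegative LS solve of y ~ basis (+ background column)
  solve_amplitudes <- function(basis, bg_col) {
    m <- if (bg_col) cbind(basis, 1) else basis
    cols <- seq_len(ncol(m))
    coef <- rep(0, ncol(m))
    active <- cols
    repeat {
      sw <- sqrt(w)
      fit <- tryCatch(
        stats::lm.fit(m[, active, drop = FALSE] * sw, y * sw)$coefficients,
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      fit[is.na(fit)] <- 0
      if (all(fit >= 0) || length(active) == 1L) {
        coef[active] <- pmax(fit, 0)
        break
      }
      active <- active[fit >= 0]
      if (length(active) == 0L) break
    }
    coef
  }

  obj <- function(par) {
    taus <- exp(par[seq_len(k)])
    s <- if (fit_shift) par[k + 1L] else 0
    irf_norm <- if (s == 0) irf_norm0 else {
      v <- shift_irf(irf_norm0, t, s)
      if (sum(v) <= 0) return(1e12)
      v / sum(v)
    }
    basis <- decay_basis(t, irf_norm, taus)
    coef <- solve_amplitudes(basis, fit_bg)
    if (is.null(coef)) return(1e12)
    alph <- coef[seq_len(k)]
    bg <- if (fit_bg) coef[k + 1L] else bg_fixed
    mu <- as.vector(basis %*% alph) + bg
    if (objective == "wls") {
      sum(w * (y - mu)^2)
    } else {
      mu <- pmax(mu, 1e-12)
      2 * sum(mu - y * log(mu))
    }
  }

  par0 <- c(log(tau0), if (fit_shift) 0)
  if (length(par0) > 1L) {
    opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    par0 <- opt$par
  }
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12,
                                     ndeps = rep(1e-6, length(par0))))
  if (!is.finite(opt$value) || opt$value >= 1e12) {
    acd_error(sprintf(
      "decay fit failed to converge (objective %.3g, code %d)",
      opt$value, opt$convergence), "fit_error")
  }

  taus <- exp(opt$par[seq_len(k)])
  s <- if (fit_shift) opt$par[k + 1L] else 0
  irf_norm <- if (s == 0) irf_norm0 else {
    v <- shift_irf(irf_norm0, t, s); v / sum(v)
  }
  basis <- decay_basis(t, irf_norm, taus)
  coef <- solve_amplitudes(basis, fit_bg)
  alph <- coef[seq_len(k)]
  bg <- if (fit_bg) coef[k + 1L] else bg_fixed
  mu <- as.vector(basis %*% alph) + bg

  ord <- order(taus)
  taus <- taus[ord]
  alph <- alph[ord]
  photon_share <- alph * taus
  amp <- if (sum(photon_share) > 0) photon_share / sum(photon_share)
         else rep(1 / k, k)

  npar <- k + sum(alph > 0) + as.integer(fit_bg) + as.integer(fit_shift)
  chi2 <- sum(w * (y - mu)^2) / (n - npar)
  degenerate <- k > 1L &&
    (min(amp) < 1e-3 || min(taus[-1] / taus[-k]) < 1.05)

  structure(
    list(lifetimes = taus, amplitudes = amp, shift = s, background = bg,
         goodness = chi2, mean_lifetime = sum(amp * taus),
         fitted = mu, degenerate = degenerate,
         convergence = opt$convergence, objective = objective),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  comp <- paste(sprintf("%.3g ns (%.1f%%)", x$lifetimes,
                        100 * x$amplitudes), collapse = ", ")
  cat(sprintf("<decay_fit> %s; mean %.3g ns; chi2_red %.3f%s\n", comp,
              x$mean_lifetime, x$goodness,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Amplitude-weighted mean lifetime
#'
#' @param fit A `decay_fit`.
#' @return sum(a_k * tau_k) in ns.
#' @export
mean_lifetime <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  sum(fit$amplitudes * fit$lifetimes)
}
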