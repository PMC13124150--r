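#' Spectral FRET (Ratio A) analysis
#'
#' The Ratio A method quantifies donor-to-acceptor energy transfer from
#' steady-state emission spectra without absolute intensity calibration.
#' Three spectra are required per sample: the emission under donor
#' excitation at 280 nm (`F280`, containing Trp/Tyr emission plus Acd
#' emission from both FRET and direct excitation), a donor-only control
#' under the same excitation (`F280_notag`, protein without the acceptor),
#' and the acceptor emission under direct excitation at 370 nm (`F370`).
#' The donor control is scaled onto the sample's donor band, subtracted to
#' leave the pure acceptor emission, and that extracted spectrum is divided
#' by `F370`. The mean of this per-wavelength ratio over the acceptor band
#' (410-480 nm) is Ratio A; subtracting the free-acceptor value Ratio A0
#' (direct excitation only) leaves a quantity directly proportional to the
#' FRET efficiency.
#'
#' @name spectral_fret
NULL

default_donor_window <- c(300, 360)
default_acceptor_window <- c(410, 480)

#' Scale the donor-only reference onto a sample spectrum
#'
#' Multiplies the no-acceptor control by the scalar that matches its
#' trapezoidal integral over the donor emission window to that of the
#' sample. Integral matching over 300-360 nm is the default because it is
#' less noise-sensitive than matching a single peak; both the rule's window
#' and the alternative `"peak"` rule are exposed.
#'
#' @param f280 Sample emission spectrum, excitation 280 nm.
#' @param f280_notag Donor-only control spectrum, excitation 280 nm.
#' @param donor_window Interval over which to match (default 300-360 nm).
#' @param rule `"integral"` (default) or `"peak"` (match maxima within the
#'   window).
#' @return The scaled control [spectrum()] on `f280`'s grid, with the scale
#'   factor in attribute `"scale_factor"`.
#' @export
scale_donor_reference <- function(f280, f280_notag,
                                  donor_window = default_donor_window,
                                  rule = c("integral", "peak")) {
  rule <- match.arg(rule)
  check_interval(donor_window, "donor_window")
  f280_notag <- align_to(f280_notag, f280)
  idx <- in_window(f280$abscissa, donor_window)
  if (length(idx) < 2L) {
    acd_error("donor_window holds < 2 samples", "range_error")
  }
  x <- f280$abscissa[idx]
  if (rule == "integral") {
    num <- trapz(x, f280$intensity[idx])
    den <- trapz(x, f280_notag$intensity[idx])
  } else {
    num <- max(f280$intensity[idx])
    den <- max(f280_notag$intensity[idx])
  }
  if (!is.finite(den) || den <= 0) {
    acd_error("donor reference has no signal in the donor window",
              "degenerate_spectrum_error")
  }
  k <- num / den
  out <- f280_notag
  out$intensity <- f280_notag$intensity * k
  attr(out, "scale_factor") <- k
  out
}

# Interpolate b onto a's grid; error when impossible.
align_to <- function(b, a) {
  if (isTRUE(all.equal(a$abscissa, b$abscissa))) return(b)
  if (min(a$abscissa) < min(b$abscissa) || max(a$abscissa) > max(b$abscissa)) {
    acd_error("spectra do not share a common grid and cannot be aligned",
              "grid_error")
  }
  interpolate_to_grid(b, a$abscissa)
}

#' Extract the acceptor emission spectrum
#'
#' Pointwise difference between the sample spectrum under donor excitation
#' and the scaled donor-only control. The residual holds the acceptor
#' emission from direct excitation plus the FRET-sensitized component.
#'
#' @param f280 Sample emission spectrum, excitation 280 nm.
#' @param scaled_notag The output of [scale_donor_reference()].
#' @return A [spectrum()] on `f280`'s grid.
#' @export
extract_acceptor_spectrum <- function(f280, scaled_notag) {
  if (!isTRUE(all.equal(f280$abscissa, scaled_notag$abscissa))) {
    acd_error("extract_acceptor_spectrum needs a common grid", "grid_error")
  }
  out <- f280
  out$intensity <- f280$intensity - scaled_notag$intensity
  out
}

#' Per-wavelength acceptor ratio and its window mean (Ratio A)
#'
#' Divides the extracted acceptor spectrum by the directly excited acceptor
#' spectrum, pointwise over the averaging window, and averages. A flat ratio
#' trace (low coefficient of variation, reported as `flatness`) indicates
#' clean unmixing and detector linearity.
#'
#' @param extracted Extracted acceptor [spectrum()]
#'   (see [extract_acceptor_spectrum()]).
#' @param f370 Acceptor emission under direct excitation.
#' @param window Averaging window, default 410-480 nm, endpoints inclusive.
#' @return A list of class `ratio_a_result`: `ratio_trace` (data.frame of
#'   wavelength and ratio), `ratio_a`, `averaging_window`, `flatness`, and
#'   placeholders `ratio_a0`/`relative_fret` (filled by [relative_fret()]).
#' @export
ratio_a <- function(extracted, f370, window = default_acceptor_window) {
  check_interval(window, "window")
  f370 <- align_to(f370, extracted)
  idx <- in_window(extracted$abscissa, window)
  if (length(idx) < 2L) acd_error("window holds < 2 samples", "range_error")
  den <- f370$intensity[idx]
  if (any(den <= 0)) {
    acd_error("F370 must be strictly positive over the averaging window",
              "division_error")
  }
  tr <- extracted$intensity[idx] / den
  ra <- mean(tr)
  flat <- if (abs(ra) > 0) stats::sd(tr) / abs(ra) else NA_real_
  structure(
    list(ratio_trace = data.frame(wavelength = extracted$abscissa[idx],
                                  ratio = tr),
         ratio_a = ra, ratio_a0 = NA_real_, relative_fret = NA_real_,
         averaging_window = window, flatness = flat),
    class = "ratio_a_result"
  )
}

#' @export
print.ratio_a_result <- function(x, ...) {
  cat(sprintf("<ratio_a_result> Ratio A = %.4f over %g-%g nm (flatness %.3g)",
              x$ratio_a, x$averaging_window[1], x$averaging_window[2],
              x$flatness))
  if (is.finite(x$relative_fret)) {
    cat(sprintf("; Ratio A0 = %.4f; Ratio A - Ratio A0 = %.4f",
                x$ratio_a0, x$relative_fret))
  }
  cat("\n")
  invisible(x)
}

#' Direct-excitation ratio from free acceptor (Ratio A0)
#'
#' The same ratio computed on spectra of the free acceptor amino acid, which
#' carries no donor and hence no FRET: its ratio isolates the
#' direct-excitation component.
#'
#' @param free_acd_f280 Free-acceptor emission, excitation 280 nm.
#' @param free_acd_f370 Free-acceptor emission, excitation 370 nm.
#' @param window Averaging window, default 410-480 nm.
#' @return The scalar Ratio A0.
#' @export
ratio_a0 <- function(free_acd_f280, free_acd_f370,
                     window = default_acceptor_window) {
  ratio_a(free_acd_f280, free_acd_f370, window = window)$ratio_a
}

#' Relative FRET: Ratio A minus Ratio A0
#'
#' The difference removes the direct-excitation component, leaving the
#' FRET-sensitized fraction of acceptor emission, which is directly
#' proportional to the FRET efficiency.
#'
#' @param ratio_a A scalar Ratio A or a `ratio_a_result`.
#' @param ratio_a0 Scalar Ratio A0.
#' @return If given a `ratio_a_result`, that object with `ratio_a0` and
#'   `relative_fret` filled; otherwise the scalar difference.
#' @export
relative_fret <- function(ratio_a, ratio_a0) {
  if (inherits(ratio_a, "ratio_a_result")) {
    ratio_a$ratio_a0 <- ratio_a0
    ratio_a$relative_fret <- ratio_a$ratio_a - ratio_a0
    return(ratio_a)
  }
  ratio_a - ratio_a0
}

#' Full Ratio A analysis of one sample
#'
#' Convenience wrapper chaining [scale_donor_reference()],
#' [extract_acceptor_spectrum()], [ratio_a()] and [relative_fret()].
#'
#' @param f280,f370,f280_notag The three sample spectra.
#' @param ratio_a0 Scalar Ratio A0 from [ratio_a0()]. `NA` leaves
#'   `relative_fret` unset.
#' @param donor_window,window,rule Passed through to the stages.
#' @return A `ratio_a_result`.
#' @export
spectral_fret_analysis <- function(f280, f370, f280_notag, ratio_a0 = NA,
                                   donor_window = default_donor_window,
                                   window = default_acceptor_window,
                                   rule = "integral") {
  scaled <- scale_donor_reference(f280, f280_notag,
                                  donor_window = donor_window, rule = rule)
  extracted <- extract_acceptor_spectrum(f280, scaled)
  res <- ratio_a(extracted, f370, window = window)
  if (is.finite(ratio_a0)) res <- relative_fret(res, ratio_a0)
  res
}

known_conditions <- c("apo", "zinc", "zinc_edta")

#' Compare relative FRET between paired conditions
#'
#' Paired per-replicate comparison of relative FRET (e.g. apo vs 1 mM Zn2+),
#' with an optional reversal arm (Zn2+ then EDTA) from which a
#' reversibility fraction is computed: 1 means the chelator fully undoes the
#' treatment-induced change.
#'
#' @param apo,treated Numeric vectors of per-replicate relative FRET values
#'   (or lists of `ratio_a_result`), paired and in matching order.
#' @param reversal Optional paired replicates after reversal.
#' @param construct_id Label carried into the result.
#' @param test `"paired"` (default, two-sided paired t-test) or
#'   `"unpaired"` (Welch).
#' @param p_adjust Multiple-testing correction method passed to
#'   [stats::p.adjust()] by callers that test many constructs; stored here
#'   for bookkeeping only. Default `"none"`.
#' @return A list of class `condition_comparison`: `construct_id`, `deltas`,
#'   `mean_delta`, `p_value`, `reversibility` (NA without a reversal arm).
#' @export
compare_conditions <- function(apo, treated, reversal = NULL,
                               construct_id = "",
                               test = c("paired", "unpaired"),
                               p_adjust = "none") {
  test <- match.arg(test)
  apo <- as_fret_values(apo)
  treated <- as_fret_values(treated)
  if (length(apo) != length(treated)) {
    acd_error("apo and treated replicate counts differ", "pairing_error")
  }
  if (length(apo) < 2L) {
    acd_error("need at least 2 replicates", "statistics_error")
  }
  deltas <- treated - apo
  p <- tryCatch(
    if (test == "paired") stats::t.test(treated, apo, paired = TRUE)$p.value
    else stats::t.test(treated, apo)$p.value,
    error = function(e) 1  # zero variance (identical pairs): no evidence
  )
  if (is.na(p)) p <- 1
  rev_frac <- NA_real_
  if (!is.null(reversal)) {
    reversal <- as_fret_values(reversal)
    if (length(reversal) != length(apo)) {
      acd_error("reversal replicate count differs", "pairing_error")
    }
    shift <- mean(treated) - mean(apo)
    if (abs(shift) > 0) {
      rev_frac <- 1 - abs(mean(reversal) - mean(apo)) / abs(shift)
    }
  }
  structure(
    list(construct_id = construct_id, deltas = deltas,
         mean_delta = mean(deltas), p_value = p, reversibility = rev_frac,
         test = test, p_adjust = p_adjust),
    class = "condition_comparison"
  )
}

as_fret_values <- function(x) {
  if (is.list(x) && all(vapply(x, inherits, logical(1), "ratio_a_result"))) {
    x <- vapply(x, function(r) {
      if (is.finite(r$relative_fret)) r$relative_fret else r$ratio_a
    }, numeric(1))
  }
  as.numeric(x)
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s: mean delta %.4f (n=%d), p=%.3g",
              x$construct_id, x$mean_delta, length(x$deltas), x$p_value))
  if (is.finite(x$reversibility)) {
    cat(sprintf(", reversibility %.2f", x$reversibility))
  }
  cat("\n")
  invisible(x)
}

#' Check a condition label against the fixed vocabulary
#'
#' `apo`, `zinc` and `zinc_edta` are the recognized labels; anything else is
#' allowed but triggers a warning, catching typos in manifests.
#'
#' @param condition Character label.
#' @return The label, invisibly.
#' @export
check_condition <- function(condition) {
  if (!is.null(condition) && !condition %in% known_conditions) {
    acd_warn(sprintf("condition '%s' is not one of {%s}", condition,
                     paste(known_conditions, collapse = ", ")),
             "condition_warning")
  }
  invisible(condition)
}
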