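#' Sampled optical trace
#'
#' A `spectrum` is the package's container for any sampled optical trace: a
#' fluorescence emission spectrum, an absorption spectrum, or a
#' size-exclusion chromatogram. It couples a strictly increasing abscissa
#' (wavelength in nm, or elution volume in mL for chromatograms) with an
#' intensity vector in arbitrary units, plus acquisition metadata.
#'
#' @param abscissa Strictly increasing numeric vector (nm or mL), length >= 3.
#' @param intensity Numeric vector, same length as `abscissa`.
#' @param kind One of `"emission"`, `"absorption"`, `"chromatogram"`.
#' @param excitation_nm Excitation wavelength in nm. Required when
#'   `kind = "emission"`.
#' @param sample_id Free-text sample identifier.
#' @param condition Optional condition label (e.g. `"apo"`, `"zinc"`,
#'   `"zinc_edta"`, or a solvent name).
#'
#' @return An object of class `spectrum`: a list with elements `abscissa`,
#'   `intensity`, `kind`, `excitation_nm`, `sample_id`, `condition`.
#' @examples
#' s <- spectrum(380:480, exp(-((380:480) - 420)^2 / 800),
#'               kind = "emission", excitation_nm = 370)
#' locate_maximum(s)
#' @export
spectrum <- function(abscissa, intensity,
                     kind = c("emission", "absorption", "chromatogram"),
                     excitation_nm = NULL, sample_id = "",
                     condition = NULL) {
  kind <- match.arg(kind)
  abscissa <- as.numeric(abscissa)
  intensity <- as.numeric(intensity)
  if (length(abscissa) < 3L) {
    acd_error("a spectrum needs at least 3 points", "format_error")
  }
  if (length(intensity) != length(abscissa)) {
    acd_error("abscissa and intensity lengths differ", "format_error")
  }
  if (any(!is.finite(abscissa)) || any(!is.finite(intensity))) {
    acd_error("non-finite values in spectrum", "format_error")
  }
  if (any(diff(abscissa) <= 0)) {
    acd_error("abscissa must be strictly increasing", "format_error")
  }
  if (kind == "emission" && is.null(excitation_nm)) {
    acd_error("emission spectra require excitation_nm", "format_error")
  }
  structure(
    list(abscissa = abscissa, intensity = intensity, kind = kind,
         excitation_nm = if (is.null(excitation_nm)) NULL
                         else as.numeric(excitation_nm),
         sample_id = as.character(sample_id), condition = condition),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$kind == "chromatogram") "mL" else "nm"
  cat(sprintf("<spectrum: %s> %d points, %.6g-%.6g %s",
              x$kind, length(x$abscissa), min(x$abscissa), max(x$abscissa),
              unit))
  if (!is.null(x$excitation_nm)) cat(sprintf(", ex %g nm", x$excitation_nm))
  if (nzchar(x$sample_id)) cat(sprintf(", sample '%s'", x$sample_id))
  if (!is.null(x$condition)) cat(sprintf(" [%s]", x$condition))
  cat("\n")
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$abscissa)

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(abscissa = x$abscissa, intensity = x$intensity)
}

# Detect the delimiter of a two-column text trace: comma if the first
# data-looking line contains one, else whitespace/tab.
detect_sep <- function(lines) {
  for (ln in lines) {
    if (grepl(",", ln, fixed = TRUE)) return(",")
    if (grepl("\t", ln, fixed = TRUE)) return("\t")
  }
  ""
}

#' Read a two-column delimited trace
#'
#' Parses a CSV/TSV file with abscissa in column 1 and intensity in column 2.
#' A single header line whose first token is non-numeric is skipped; rows with
#' non-numeric entries in either column are dropped. The delimiter (comma or
#' tab/whitespace) is auto-detected; decimal separator is the point.
#'
#' @param path Path to the file.
#' @inheritParams spectrum
#' @param ... Further metadata passed to [spectrum()] (`excitation_nm`,
#'   `sample_id`, `condition`).
#' @return A validated [spectrum()].
#' @export
read_spectrum <- function(path, kind = c("emission", "absorption",
                                         "chromatogram"), ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    acd_error(sprintf("file not found: %s", path), "format_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) acd_error("empty file", "format_error")
  sep <- detect_sep(lines[seq_len(min(5L, length(lines)))])
  tab <- tryCatch(
    utils::read.table(text = lines, sep = sep, header = FALSE,
                      colClasses = "character", fill = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) acd_error(sprintf("cannot parse %s: %s", path,
                                          conditionMessage(e)),
                                  "format_error")
  )
  if (ncol(tab) < 2L) acd_error("need two columns", "format_error")
  x <- suppressWarnings(as.numeric(tab[[1L]]))
  y <- suppressWarnings(as.numeric(tab[[2L]]))
  keep <- is.finite(x) & is.finite(y)
  if (sum(!keep) > 1L) {
    acd_warn(sprintf("%d non-numeric rows dropped from %s",
                     sum(!keep) - 1L, basename(path)), "parse_warning")
  }
  if (sum(keep) < 3L) {
    acd_error(sprintf("fewer than 3 numeric rows in %s", path),
              "format_error")
  }
  if (any(diff(x[keep]) <= 0)) {
    acd_error(sprintf("abscissa not strictly increasing in %s", path),
              "format_error")
  }
  spectrum(x[keep], y[keep], kind = kind, ...)
}

#' Write a spectrum as two-column CSV
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @param header Write a `abscissa,intensity` header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, header = TRUE) {
  stopifnot(inherits(s, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("abscissa,intensity", con)
  writeLines(sprintf("%.10g,%.10g", s$abscissa, s$intensity), con)
  invisible(path)
}

#' Subtract a blank trace
#'
#' Pointwise `sample - blank`, the standard blank correction for cuvette
#' measurements. Grids must match; if they do not, both traces are first
#' resampled onto the coarser grid's overlap (see [interpolate_to_grid()])
#' when `interpolate = TRUE`. Negative intensities are kept, preserving the
#' noise statistics for downstream ratios.
#'
#' @param sample,blank [spectrum()] objects of the same kind.
#' @param interpolate Resample onto a common (coarser) grid when the grids
#'   differ. Default FALSE: differing grids are an error.
#' @return A [spectrum()] with `sample`'s metadata.
#' @export
subtract_blank <- function(sample, blank, interpolate = FALSE) {
  stopifnot(inherits(sample, "spectrum"), inherits(blank, "spectrum"))
  if (!isTRUE(all.equal(sample$abscissa, blank$abscissa))) {
    if (!interpolate) {
      acd_error("sample and blank grids differ (set interpolate = TRUE)",
                "grid_error")
    }
    common <- common_grid(sample, blank)
    sample <- interpolate_to_grid(sample, common)
    blank <- interpolate_to_grid(blank, common)
  }
  out <- sample
  out$intensity <- sample$intensity - blank$intensity
  out
}

# Coarser of two grids, restricted to the overlap of their ranges.
common_grid <- function(a, b) {
  lo <- max(min(a$abscissa), min(b$abscissa))
  hi <- min(max(a$abscissa), max(b$abscissa))
  if (lo >= hi) acd_error("grids do not overlap", "grid_error")
  # coarser = larger median step
  ga <- a$abscissa[a$abscissa >= lo & a$abscissa <= hi]
  gb <- b$abscissa[b$abscissa >= lo & b$abscissa <= hi]
  if (stats::median(diff(ga)) >= stats::median(diff(gb))) ga else gb
}

#' Linearly interpolate a spectrum onto a new grid
#'
#' Extrapolation is forbidden: every grid point must lie within the
#' spectrum's abscissa range.
#'
#' @param s A [spectrum()].
#' @param grid Strictly increasing numeric vector within `range(s$abscissa)`.
#' @return A [spectrum()] on `grid`.
#' @export
interpolate_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  if (any(grid < min(s$abscissa)) || any(grid > max(s$abscissa))) {
    acd_error("grid exceeds the spectrum's abscissa range (no extrapolation)",
              "range_error")
  }
  if (isTRUE(all.equal(grid, s$abscissa))) return(s)
  y <- stats::approx(s$abscissa, s$intensity, xout = grid,
                     method = "linear", ties = "ordered")$y
  out <- s
  out$abscissa <- grid
  out$intensity <- y
  out
}

#' Normalize a spectrum
#'
#' Three conventions used when presenting spectra:
#' * `max`: peak intensity scaled to 1.
#' * `at_abscissa`: intensity at abscissa `arg` scaled to 1 (linear
#'   interpolation between samples).
#' * `region_integral`: trapezoidal integral over the interval `arg`
#'   scaled to 1.
#'
#' @param s A [spectrum()].
#' @param mode One of `"max"`, `"at_abscissa"`, `"region_integral"`.
#' @param arg An abscissa value (`at_abscissa`) or interval `c(lo, hi)`
#'   (`region_integral`). Ignored for `max`.
#' @return The rescaled [spectrum()].
#' @export
normalize <- function(s, mode = c("max", "at_abscissa", "region_integral"),
                      arg = NULL) {
  stopifnot(inherits(s, "spectrum"))
  mode <- match.arg(mode)
  denom <- switch(mode,
    max = max(s$intensity),
    at_abscissa = {
      if (is.null(arg) || length(arg) != 1L) {
        acd_error("at_abscissa mode needs a single abscissa value",
                  "range_error")
      }
      if (arg < min(s$abscissa) || arg > max(s$abscissa)) {
        acd_error("abscissa value outside range", "range_error")
      }
      stats::approx(s$abscissa, s$intensity, xout = arg,
                    ties = "ordered")$y
    },
    region_integral = {
      check_interval(arg, "region_integral interval")
      idx <- in_window(s$abscissa, arg)
      if (length(idx) < 2L) acd_error("interval holds < 2 samples",
                                      "range_error")
      trapz(s$abscissa[idx], s$intensity[idx])
    }
  )
  if (!is.finite(denom) || denom <= 0) {
    acd_error("normalizer is zero or negative (degenerate spectrum)",
              "degenerate_spectrum_error")
  }
  out <- s
  out$intensity <- s$intensity / denom
  out
}

#' Locate the abscissa of maximum intensity
#'
#' Returns the abscissa (wavelength or elution volume) of the maximum,
#' optionally restricted to a search interval and optionally after a
#' centered moving-average smoothing. The default is the raw argmax, the
#' convention behind tabulated emission maxima and elution volumes; ties are
#' broken toward the smallest abscissa.
#'
#' @param s A [spectrum()].
#' @param search_interval Optional interval `c(lo, hi)` restricting the
#'   search.
#' @param smooth_window Optional odd integer width (in samples) of a centered
#'   moving average applied before the argmax. Even widths are bumped up by
#'   one. Edges use the available (shorter) window.
#' @return The abscissa value at the maximum.
#' @export
locate_maximum <- function(s, search_interval = NULL, smooth_window = NULL) {
  stopifnot(inherits(s, "spectrum"))
  y <- s$intensity
  if (!is.null(smooth_window)) {
    w <- as.integer(smooth_window)
    if (w < 1L) acd_error("smooth_window must be >= 1", "range_error")
    if (w %% 2L == 0L) w <- w + 1L
    y <- moving_average(y, w)
  }
  idx <- seq_along(y)
  if (!is.null(search_interval)) {
    check_interval(search_interval, "search_interval")
    idx <- in_window(s$abscissa, search_interval)
    if (length(idx) == 0L) {
      acd_error("search_interval contains no samples", "range_error")
    }
  }
  ysub <- y[idx]
  s$abscissa[idx[which.max(ysub)]]  # which.max takes the first tie
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(y, w) {
  h <- (w - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    mean(y[j])
  }, numeric(1))
}
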