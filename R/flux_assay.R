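#' ACMA liposome proton-flux traces
#'
#' In the flux assay, proteoliposomes are loaded with the pH-sensitive dye
#' ACMA; adding valinomycin sets a K+ diffusion potential that drives
#' protons through the reconstituted channel, quenching the dye, and the
#' protonophore CCCP added at the end collapses the gradient to give the
#' full-quench floor. Traces are normalized to
#' (F(t) - Fmin) / (Fmax - Fmin), with Fmax the mean over the pre-reagent
#' baseline and Fmin the mean over a window after CCCP.
#'
#' @name flux_assay
NULL

#' Flux trace container
#'
#' @param time Strictly increasing times (s).
#' @param fluorescence Raw fluorescence values (arbitrary units).
#' @param events data.frame with columns `label` (e.g. `"valinomycin"`,
#'   `"cccp"`, or custom) and `time` (s), all within the trace's time
#'   range.
#' @return A `flux_trace` (fields `f_max`, `f_min`, `normalized` filled by
#'   [normalize_flux()]).
#' @export
flux_trace <- function(time, fluorescence, events = NULL) {
  time <- as.numeric(time)
  fluorescence <- as.numeric(fluorescence)
  if (length(time) != length(fluorescence) || length(time) < 3L) {
    acd_error("time and fluorescence must match, length >= 3",
              "format_error")
  }
  if (any(diff(time) <= 0)) {
    acd_error("time must be strictly increasing", "format_error")
  }
  if (!is.null(events)) {
    if (!is.data.frame(events) ||
        !all(c("label", "time") %in% names(events))) {
      acd_error("events needs columns label, time", "annotation_error")
    }
    if (any(events$time < min(time) | events$time > max(time))) {
      acd_error("event outside trace time range", "annotation_error")
    }
  } else {
    events <- data.frame(label = character(), time = numeric())
  }
  structure(list(time = time, fluorescence = fluorescence, events = events,
                 f_max = NA_real_, f_min = NA_real_, normalized = NULL),
            class = "flux_trace")
}

#' Read a flux trace and its events sidecar
#'
#' @param path Two-column time/fluorescence delimited text.
#' @param events_path Optional delimited text with columns label,time.
#' @return A `flux_trace`.
#' @export
read_flux_trace <- function(path, events_path = NULL) {
  s <- read_spectrum(path, kind = "chromatogram")
  events <- NULL
  if (!is.null(events_path)) {
    tab <- utils::read.table(events_path, header = FALSE,
                             sep = detect_sep(readLines(events_path, n = 3L,
                                                        warn = FALSE)),
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) acd_error("events file needs label,time columns",
                                  "annotation_error")
    hdr <- suppressWarnings(is.na(as.numeric(tab[1, 2])))
    if (hdr) tab <- tab[-1, , drop = FALSE]
    events <- data.frame(label = as.character(tab[[1]]),
                         time = as.numeric(tab[[2]]))
  }
  flux_trace(s$abscissa, s$intensity, events)
}

event_time <- function(trace, label) {
  idx <- which(trace$events$label == label)
  if (length(idx) == 0L) return(NA_real_)
  trace$events$time[idx[1]]
}

#' Normalize a flux trace to its baseline and floor
#'
#' Fmax is the mean fluorescence over `baseline_window` (default: from the
#' start of the trace to the valinomycin addition, i.e. the recorded
#' baseline) and Fmin the mean over `floor_window` (default: a 30 s window
#' ending at the last sample, after CCCP). The trace is rescaled as
#' (F(t) - Fmin) / (Fmax - Fmin), which is invariant to instrument gain
#' and offset.
#'
#' @param trace A `flux_trace`.
#' @param baseline_window,floor_window Intervals `c(lo, hi)` in seconds;
#'   `NULL` picks the defaults above. Must not overlap.
#' @return The trace with `f_max`, `f_min` and `normalized` filled.
#' @export
normalize_flux <- function(trace, baseline_window = NULL,
                           floor_window = NULL) {
  stopifnot(inherits(trace, "flux_trace"))
  tmax <- max(trace$time)
  if (is.null(baseline_window)) {
    val <- event_time(trace, "valinomycin")
    baseline_window <- c(min(trace$time), if (is.na(val)) tmax else val)
  }
  if (is.null(floor_window)) {
    floor_window <- c(max(min(trace$time), tmax - 30), tmax)
  }
  check_interval(baseline_window, "baseline_window")
  check_interval(floor_window, "floor_window")
  if (baseline_window[2] > floor_window[1] &&
      floor_window[2] > baseline_window[1]) {
    acd_error("baseline and floor windows overlap", "range_error")
  }
  bi <- in_window(trace$time, baseline_window)
  fi <- in_window(trace$time, floor_window)
  if (length(bi) == 0L || length(fi) == 0L) {
    acd_error("a window contains no samples", "range_error")
  }
  f_max <- mean(trace$fluorescence[bi])
  f_min <- mean(trace$fluorescence[fi])
  if (f_max <= f_min) {
    acd_error("Fmax <= Fmin: degenerate (non-quenching) trace",
              "degenerate_trace_error")
  }
  trace$f_max <- f_max
  trace$f_min <- f_min
  trace$normalized <- (trace$fluorescence - f_min) / (f_max - f_min)
  trace
}

#' @export
print.flux_trace <- function(x, ...) {
  cat(sprintf("<flux_trace> %d samples over %.0f s, %d events",
              length(x$time), diff(range(x$time)), nrow(x$events)))
  if (is.finite(x$f_max)) {
    cat(sprintf("; Fmax %.4g, Fmin %.4g (normalized)", x$f_max, x$f_min))
  }
  cat("\n")
  invisible(x)
}

#' Quench extent and rate of a normalized flux trace
#'
#' `extent` is 1 minus the mean normalized fluorescence over the pre-CCCP
#' plateau (the last `plateau_width` seconds before the CCCP addition);
#' `rate` (1/s) comes from a single-exponential fit
#' N(t) = plateau + (1 - plateau) exp(-k (t - t_val)) to the
#' post-valinomycin, pre-CCCP segment. Step-like quenches faster than the
#' sampling interval are reported at the fit's resolution bound
#' (`rate_bound`, 2 / sampling interval) with `rate_censored = TRUE`.
#'
#' @param trace A normalized `flux_trace` (see [normalize_flux()]) with
#'   `valinomycin` and `cccp` events.
#' @param plateau_width Width (s) of the pre-CCCP plateau window
#'   (default 30).
#' @return A list: `extent`, `rate`, `rate_censored`, `rate_bound`.
#' @export
quench_metrics <- function(trace, plateau_width = 30) {
  stopifnot(inherits(trace, "flux_trace"))
  if (is.null(trace$normalized)) {
    acd_error("normalize the trace first (normalize_flux)",
              "annotation_error")
  }
  t_val <- event_time(trace, "valinomycin")
  t_cccp <- event_time(trace, "cccp")
  if (is.na(t_val) || is.na(t_cccp)) {
    acd_error("valinomycin and cccp events are required",
              "annotation_error")
  }
  pi <- in_window(trace$time, c(t_cccp - plateau_width, t_cccp))
  if (length(pi) == 0L) acd_error("no samples in the plateau window",
                                  "range_error")
  extent <- 1 - mean(trace$normalized[pi])

  si <- which(trace$time >= t_val & trace$time <= t_cccp)
  tt <- trace$time[si] - t_val
  yy <- trace$normalized[si]
  dt_samp <- stats::median(diff(trace$time))
  rate_bound <- 2 / dt_samp
  plateau <- 1 - extent

  if (extent <= .Machine$double.eps^0.5) {
    return(list(extent = extent, rate = 0, rate_censored = FALSE,
                rate_bound = rate_bound))
  }
  fit <- tryCatch(
    suppressWarnings(stats::nls(yy ~ p + (1 - p) * exp(-k * tt),
               start = list(p = plateau,
                            k = max(1 / max(tt), 5 / max(tt))),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = TRUE))),
    error = function(e) NULL
  )
  rate <- if (!is.null(fit)) unname(stats::coef(fit)["k"]) else {
    # fall back to log-linear regression on the decaying part
    g <- (yy - plateau) / (1 - plateau)
    ok <- g > 0.02 & g < 0.98
    if (sum(ok) >= 2) {
      as.numeric(-stats::coef(stats::lm(log(g[ok]) ~ tt[ok]))[2])
    } else NA_real_
  }
  censored <- is.na(rate) || rate > rate_bound
  if (censored) rate <- rate_bound
  list(extent = extent, rate = rate, rate_censored = censored,
       rate_bound = rate_bound)
}
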