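# Internal helpers shared across modules.

#' @keywords internal
acd_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "acdfret_error"),
                      call = call))
}

#' @keywords internal
acd_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "acdfret_warning")))
}

# Trapezoidal integral of y over x. x must be sorted; length >= 2.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Validate a length-2 numeric interval c(lo, hi), lo < hi.
#' @keywords internal
check_interval <- function(interval, what = "interval") {
  if (!is.numeric(interval) || length(interval) != 2L ||
      any(!is.finite(interval)) || interval[1] >= interval[2]) {
    acd_error(sprintf("%s must be a finite numeric c(lo, hi) with lo < hi",
                      what), "range_error")
  }
  invisible(interval)
}

# Indices of x falling in [lo, hi] (inclusive both ends).
#' @keywords internal
in_window <- function(x, interval) {
  which(x >= interval[1] & x <= interval[2])
}
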