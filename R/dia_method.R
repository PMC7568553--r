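#' Build a DIA isolation-window scheme
#'
#' Tiles the precursor m/z range with contiguous, non-overlapping
#' isolation windows and groups them into subcycles: blocks of
#' `scans_per_subcycle` MS2 scans interleaved between successive MS1
#' scans. The default HRMS1-DIA geometry covers m/z 400-1210 with 15 Da
#' windows, 18 MS2 scans per subcycle, i.e. 54 windows in 3 subcycles,
#' an MS1-to-MS1 period of ~1.7 s and an overall MS2 cycle of ~5.2 s.
#'
#' @param mz_start,mz_end Precursor range limits (Th); `mz_end > mz_start`.
#' @param window_width Isolation window width (Da).
#' @param scans_per_subcycle Number of MS2 scans between consecutive MS1
#'   scans.
#' @param ms1_cycle_time,ms2_cycle_time MS1-to-MS1 and MS2-to-MS2 cycle
#'   periods in seconds; used by [points_per_peak()] via
#'   [compute_qc_metrics()].
#' @param allow_padding If the range is not an integer number of full
#'   subcycles, pad the final subcycle with windows beyond `mz_end`
#'   (`TRUE`) or fail with a scheme-mismatch error (`FALSE`, default).
#'
#' @return An object of class `dia_method`: a list with the scheme
#'   parameters and a `windows` data.table (`index`, `low`, `high`,
#'   `center`, `subcycle`). Window intervals are half-open `[low, high)`
#'   so each m/z value belongs to exactly one window.
#'
#' @examples
#' m <- build_window_scheme(400, 1210, 15, 18)
#' nrow(m$windows)     # 54
#' m$n_subcycles       # 3
#' m$windows$center[1] # 407.5
#' @export
build_window_scheme <- function(mz_start, mz_end, window_width,
                                scans_per_subcycle,
                                ms1_cycle_time = 1.7,
                                ms2_cycle_time = 5.2,
                                allow_padding = FALSE) {
  if (!is.numeric(mz_start) || !is.numeric(mz_end) || mz_end <= mz_start)
    dh_stop("mz_end must exceed mz_start", "invalid_parameter")
  if (!is.numeric(window_width) || window_width <= 0)
    dh_stop("window_width must be positive", "invalid_parameter")
  if (scans_per_subcycle < 1 || scans_per_subcycle != round(scans_per_subcycle))
    dh_stop("scans_per_subcycle must be a positive integer", "invalid_parameter")
  if (ms2_cycle_time < ms1_cycle_time)
    dh_stop("ms2_cycle_time must be >= ms1_cycle_time", "invalid_parameter")

  span <- mz_end - mz_start
  n_cover <- ceiling(span / window_width - 1e-9)
  n_subcycles <- ceiling(n_cover / scans_per_subcycle)
  n_windows <- if (allow_padding) n_subcycles * scans_per_subcycle else n_cover
  exact <- isTRUE(all.equal(n_cover * window_width, span)) &&
    n_cover %% scans_per_subcycle == 0
  if (!allow_padding && !exact)
    dh_stop(sprintf(
      "range %g-%g not coverable by %d full subcycles of %d x %g Da windows",
      mz_start, mz_end, n_subcycles, scans_per_subcycle, window_width),
      "scheme_mismatch")

  idx <- seq_len(n_windows)
  low <- mz_start + (idx - 1L) * window_width
  windows <- data.table::data.table(
    index = idx,
    low = low,
    high = low + window_width,
    center = low + window_width / 2,
    subcycle = ((idx - 1L) %/% scans_per_subcycle) + 1L
  )
  structure(list(
    mz_start = mz_start, mz_end = mz_end,
    window_width = window_width,
    scans_per_subcycle = as.integer(scans_per_subcycle),
    n_subcycles = as.integer(n_subcycles),
    ms1_cycle_time = ms1_cycle_time,
    ms2_cycle_time = ms2_cycle_time,
    windows = windows
  ), class = "dia_method")
}

#' Default HRMS1-DIA acquisition method
#'
#' The published geometry: m/z 400-1210, 15 Da windows, 18 MS2 scans per
#' subcycle (54 windows, 3 subcycles), MS1 cycle ~1.7 s, MS2 cycle
#' ~5.2 s.
#'
#' @return A `dia_method` object.
#' @export
default_dia_method <- function() {
  build_window_scheme(400, 1210, 15, 18,
                      ms1_cycle_time = 1.7, ms2_cycle_time = 5.2)
}

#' @export
print.dia_method <- function(x, ...) {
  cat(sprintf(
    "<dia_method> m/z %g-%g, %g Da windows: %d windows in %d subcycles of %d\n",
    x$mz_start, x$mz_end, x$window_width, nrow(x$windows),
    x$n_subcycles, x$scans_per_subcycle))
  cat(sprintf("  MS1 cycle %.2f s, MS2 cycle %.2f s\n",
              x$ms1_cycle_time, x$ms2_cycle_time))
  invisible(x)
}

#' Guaranteed data points across a chromatographic peak
#'
#' Number of complete scan cycles guaranteed to fall within an elution
#' peak of the given width, i.e. `floor(peak_width / cycle_time)` -- the
#' worst case over arbitrary phase between peak apex and scan clock.
#' With the default method, the 14-20 s peak-width acceptance band maps
#' to 8-11 MS1 points (1.7 s cycle) and 2-3 complete MS2 points (5.2 s
#' cycle; each precursor is sampled about three times).
#'
#' @param peak_width Chromatographic peak width at base, seconds.
#' @param cycle_time Scan cycle period, seconds.
#' @return Integer count of guaranteed complete cycles.
#' @seealso [expected_points()] for the real-valued average.
#' @examples
#' points_per_peak(17, 1.7) # 10
#' points_per_peak(17, 5.2) # 3
#' @export
points_per_peak <- function(peak_width, cycle_time) {
  if (any(!is.finite(peak_width)) || any(peak_width <= 0))
    dh_stop("peak_width must be positive", "invalid_parameter")
  if (any(!is.finite(cycle_time)) || any(cycle_time <= 0))
    dh_stop("cycle_time must be positive", "invalid_parameter")
  ## 1e-9 relative guard: 17/1.7 must count as 10, not 9.9999...
  as.integer(floor(peak_width / cycle_time * (1 + 1e-9)))
}

#' Expected (real-valued) data points across a peak
#'
#' `peak_width / cycle_time` without flooring: the phase-averaged
#' sampling density. The printed 8-11 MS1 band corresponds to the floor
#' of this quantity over the 14-20 s peak-width band at 1.7 s.
#'
#' @inheritParams points_per_peak
#' @return Numeric ratio.
#' @export
expected_points <- function(peak_width, cycle_time) {
  if (any(!is.finite(peak_width)) || any(peak_width <= 0))
    dh_stop("peak_width must be positive", "invalid_parameter")
  if (any(!is.finite(cycle_time)) || any(cycle_time <= 0))
    dh_stop("cycle_time must be positive", "invalid_parameter")
  peak_width / cycle_time
}

#' Locate the isolation window containing an m/z value
#'
#' Windows are half-open `[low, high)`, so every m/z in
#' `[mz_start, max(high))` maps to exactly one window.
#'
#' @param method A `dia_method`.
#' @param mz Mass-to-charge value (Th), scalar.
#' @return One-row data.table: the matching window.
#' @export
window_for_mz <- function(method, mz) {
  stopifnot(inherits(method, "dia_method"))
  w <- method$windows
  top <- w$high[nrow(w)]
  if (!is.finite(mz) || mz < method$mz_start || mz >= top)
    dh_stop(sprintf("m/z %g outside scheme range [%g, %g)",
                    mz, method$mz_start, top), "range_error")
  idx <- as.integer(floor((mz - method$mz_start) / method$window_width)) + 1L
  idx <- min(max(idx, 1L), nrow(w))
  ## float-edge correction: trust the interval test, not the division
  if (mz < w$low[idx]) idx <- idx - 1L else if (mz >= w$high[idx]) idx <- idx + 1L
  w[idx]
}

#' Window table of a DIA method, for export
#'
#' @param method A `dia_method`.
#' @return data.table with columns index, low, high, center, subcycle.
#' @export
describe_windows <- function(method) {
  stopifnot(inherits(method, "dia_method"))
  data.table::copy(method$windows)
}
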