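## Population statistics and growth-curve analyses.

#' Concentration statistics over a population
#'
#' Maximum, arithmetic mean and minimum of one species' concentration over
#' all cells.
#'
#' @param pop A `cell_population`.
#' @param species Species index: 1 cytoplasmic YAP/TAZ, 2 nuclear YAP/TAZ,
#'   3 phospho-YAP/TAZ.
#' @return Named numeric vector `c(max, mean, min)` (uM).
#' @export
concentration_stats <- function(pop, species = 2L) {
  if (n_cells(pop) < 1L) stop("population is empty")
  x <- pop$X[, species]
  c(max = max(x), mean = mean(x), min = min(x))
}

#' First threshold crossing of a time series
#'
#' Earliest time at which the series lies strictly below (or above) a
#' threshold.
#'
#' @param t Sample times, sorted increasing.
#' @param value Series values at `t`.
#' @param threshold Threshold level.
#' @param direction `"below"` or `"above"`.
#' @return The earliest crossing time, or `NA_real_` if the series never
#'   crosses.
#' @export
first_crossing_time <- function(t, value, threshold,
                                direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (length(t) == 0L) stop("empty series")
  if (is.unsorted(t)) stop("series must be sorted by time")
  hit <- if (direction == "below") value < threshold else value > threshold
  if (!any(hit)) return(NA_real_)
  t[which(hit)[1]]
}

#' Cancer-to-normal nuclear YAP/TAZ ratio over time
#'
#' Ratio of mean nuclear YAP/TAZ between a cancer and a normal run. If the
#' two records do not share a time grid, the cancer series is linearly
#' interpolated onto the normal one (restricted to the overlapping time
#' range). Points with a zero denominator are dropped with a warning.
#'
#' @param normal,cancer Timeseries data frames from [run_simulation()]
#'   (columns `t` and `X2_mean`).
#' @return A data frame with columns `t` and `ratio`.
#' @export
cn_ratio <- function(normal, cancer) {
  if (nrow(normal) == 0L || nrow(cancer) == 0L) stop("empty timeseries")
  same_grid <- nrow(normal) == nrow(cancer) &&
    isTRUE(all.equal(normal$t, cancer$t))
  if (same_grid) {
    t <- normal$t
    num <- cancer$X2_mean
    den <- normal$X2_mean
  } else {
    t <- normal$t[normal$t >= min(cancer$t) & normal$t <= max(cancer$t)]
    num <- stats::approx(cancer$t, cancer$X2_mean, xout = t)$y
    den <- stats::approx(normal$t, normal$X2_mean, xout = t)$y
  }
  bad <- den == 0
  if (any(bad)) {
    warning(sum(bad), " time point(s) with zero normal-tissue mean excluded")
    t <- t[!bad]; num <- num[!bad]; den <- den[!bad]
  }
  data.frame(t = t, ratio = num / den)
}

#' Growth curve of a run
#'
#' @param records Timeseries data frame from [run_simulation()].
#' @return A data frame with columns `t` (s) and `N`.
#' @export
growth_curve <- function(records) records[, c("t", "N")]

#' Uncoupled doubling-law reference curve
#'
#' Cell count of an unconstrained tissue in which every cell divides each
#' full cycle: `N(t) = 2^(1 + floor(t / T_CC))` from the two-cell start.
#'
#' @param t Times (s); vectorized.
#' @param T_CC Cell-cycle duration (s), default 20 h.
#' @return Reference counts.
#' @export
reference_curve <- function(t, T_CC = 20 * 3600) 2^(1 + floor(t / T_CC))
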