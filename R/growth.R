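# Growth-rate computation from OD600 time courses.

#' Construct a growth curve
#'
#' @param time_h Measurement times in hours (strictly increasing).
#' @param od OD600 readings (non-negative).
#' @param replicate Replicate label.
#' @return Object of class `growth_curve`.
#' @export
growth_curve <- function(time_h, od, replicate = "rep1") {
  time_h <- as.numeric(time_h); od <- as.numeric(od)
  stopifnot(length(time_h) == length(od))
  if (is.unsorted(time_h, strictly = TRUE))
    stop("time points must be strictly increasing")
  if (any(od < 0)) stop("OD600 readings must be non-negative")
  structure(list(time_h = time_h, od = od,
                 replicate = as.character(replicate)[1]),
            class = "growth_curve")
}

#' Log-ratio growth rate from an OD600 time course
#'
#' `rate = ln(OD600(t1) / OD600(t0)) / (t1 - t0)`, in inverse hours; the
#' default interval 4 h to 16 h gives the divisor 12. Both time points must
#' be present in the curve (no interpolation) with positive OD.
#'
#' @param curve A [growth_curve()], or `data.frame(time_h, od)`.
#' @param t0,t1 Interval endpoints in hours (defaults 4 and 16).
#' @return Growth rate in h^-1.
#' @examples
#' growth_rate(growth_curve(c(4, 16), c(0.1, 0.8)))  # log(8)/12
#' @export
growth_rate <- function(curve, t0 = 4, t1 = 16) {
  if (is.data.frame(curve))
    curve <- growth_curve(curve$time_h, curve$od)
  stopifnot(inherits(curve, "growth_curve"), t1 > t0)
  pick <- function(t) {
    i <- which(abs(curve$time_h - t) < 1e-9)
    if (length(i) != 1L)
      stop("no OD measurement at t = ", t, " h; interpolation is refused")
    curve$od[i]
  }
  od0 <- pick(t0); od1 <- pick(t1)
  if (od0 <= 0 || od1 <= 0)
    stop("OD must be positive at both interval endpoints")
  log(od1 / od0) / (t1 - t0)
}

#' Per-replicate growth rates with summary statistics
#'
#' Computes the log-ratio rate for each replicate of an OD table and the
#' mean/SD across replicates (rates are computed per replicate first, then
#' summarised).
#'
#' @param od `data.frame(time_h, od, replicate)` (see [read_od_table()]).
#' @inheritParams growth_rate
#' @return List: `per_replicate` (`data.frame(replicate, rate)`), `mean`,
#'   `sd`, `n`.
#' @export
growth_rates <- function(od, t0 = 4, t1 = 16) {
  reps <- split(od, od$replicate)
  rates <- vapply(reps, function(d) {
    d <- d[order(d$time_h), ]
    growth_rate(growth_curve(d$time_h, d$od, d$replicate[1]), t0, t1)
  }, numeric(1))
  list(per_replicate = data.frame(replicate = names(rates), rate = rates,
                                  row.names = NULL),
       mean = mean(rates), sd = if (length(rates) > 1) sd(rates) else NA_real_,
       n = length(rates))
}

#' Welch two-sample comparison of OD readings
#'
#' Thin convenience wrapper around `stats::t.test` for comparing two
#' variants' OD600 readings at one time point.
#'
#' @param x,y Numeric vectors of OD readings.
#' @return The `htest` object.
#' @export
compare_od <- function(x, y) t.test(x, y)
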