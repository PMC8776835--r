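# The N2O emission index I_N2O and its recovery-time anchors.
#
# I_N2O measures the molar amount of N2O relative to N2 + N2O in the
# headspace over a period [0, T], as the ratio of the time-integrals of the
# two amount curves. T is anchored at the time when a given fraction of the
# initial NO3--N has been recovered as gaseous N (N2 + N2O + NO): T_40 for
# 40% and T_100 for 100%. Low values mean efficient N2O reduction.

#' Time at which a recovery fraction is first reached
#'
#' First crossing of `fraction` by a non-decreasing recovery series, with
#' linear interpolation between the bracketing points. If the first point
#' already exceeds the fraction, its time is returned; if the fraction is
#' never reached, `NA` with attribute `reason = "not reached"`.
#'
#' @param recovery A `recovery_series` from [nitrogen_recovery()] (or any
#'   data.frame `time_h, fraction`).
#' @param fraction Target fraction, `0 < fraction <= 1`.
#' @param tol Crossing tolerance: the fraction counts as reached at
#'   `fraction - tol`. Kinetic tails approach complete recovery
#'   asymptotically, so an exact test against 1.0 would never fire.
#' @return Time in h, or `NA_real_` with a `reason` attribute.
#' @examples
#' r <- data.frame(time_h = c(10, 20), fraction = c(0.3, 0.5))
#' recovery_time(r, 0.4)  # 15
#' @export
recovery_time <- function(recovery, fraction, tol = 1e-9) {
  stopifnot(fraction > 0, fraction <= 1)
  fraction <- fraction - tol
  f <- recovery$fraction; t <- recovery$time_h
  if (any(diff(f) < -1e-6))
    warning("recovery series is not non-decreasing; using first crossing")
  if (f[1] >= fraction) return(t[1])
  i <- which(f >= fraction)[1]
  if (is.na(i))
    return(structure(NA_real_, reason = "not reached"))
  if (f[i] == f[i - 1]) return(t[i])
  t[i - 1] + (fraction - f[i - 1]) / (f[i] - f[i - 1]) * (t[i] - t[i - 1])
}

trapz_to <- function(t, y, t_end) {
  keep <- t <= t_end + 1e-12
  tt <- t[keep]; yy <- y[keep]
  if (max(tt) < t_end - 1e-12) {
    yend <- stats::approx(t, y, xout = t_end)$y
    tt <- c(tt, t_end); yy <- c(yy, yend)
  }
  pracma::trapz(tt, yy)
}

#' The N2O index over a period
#'
#' `I_N2O = 100 * integral(N2O) / integral(N2O + N2)` over `[t0, T]`,
#' trapezoidal on the molar amount curves. Counting both gases in umol N
#' (factor 2 each) cancels in the ratio, so plain molar amounts are used.
#' By default headspace amounts are expected (the quantity the index is
#' defined on); pass total amounts for a sensitivity check. An
#' instantaneous-ratio-at-T variant is available behind `method`.
#'
#' @param times Measurement times, h, covering `[t0, t_end]`.
#' @param n2o,n2 Molar amount curves, umol (same length as `times`).
#' @param t_end Upper end T of the integration period, h.
#' @param method `"integral"` (area ratio, default) or `"instantaneous"`
#'   (point ratio at T).
#' @return Index in percent, clipped to `[0, 100]`; `NA` with attribute
#'   `reason = "no gas produced"` when the denominator is zero.
#' @examples
#' t <- 0:10
#' n2o_index(t, n2o = t, n2 = t, t_end = 10)  # 50
#' @export
n2o_index <- function(times, n2o, n2, t_end,
                      method = c("integral", "instantaneous")) {
  method <- match.arg(method)
  stopifnot(length(times) == length(n2o), length(times) == length(n2))
  if (t_end > max(times) + 1e-9 || t_end <= min(times))
    stop("t_end outside the covered period")
  if (method == "instantaneous") {
    a <- stats::approx(times, n2o, xout = t_end)$y
    b <- stats::approx(times, n2, xout = t_end)$y
    if (a + b <= 0) return(structure(NA_real_, reason = "no gas produced"))
    return(min(100, max(0, 100 * a / (a + b))))
  }
  num <- trapz_to(times, n2o, t_end)
  den <- num + trapz_to(times, n2, t_end)
  if (den <= 0) return(structure(NA_real_, reason = "no gas produced"))
  min(100, max(0, 100 * num / den))
}

#' Per-vial and per-treatment N2O-index report
#'
#' Computes T_40/T_100 recovery anchors and the corresponding I_N2O values
#' for a set of vials, plus per-treatment mean and standard deviation.
#' Unreached anchors propagate as status `"not reached"` with `NA` index.
#'
#' @param vials Named list; each element is a list with `times` (h),
#'   `n2o`, `n2` (headspace molar amount curves, umol) and `recovery`
#'   (a `recovery_series`).
#' @param treatments Optional character vector (recycled names) assigning
#'   each vial to a treatment; defaults to one treatment per vial.
#' @param fractions Recovery anchors, default `c(0.4, 1)`.
#' @param method Integration method passed to [n2o_index()].
#' @return Data.frame with one row per vial (`vial_id, treatment, T40_h,
#'   T100_h, I40_pct, I100_pct, status`), with a per-treatment summary
#'   (mean, sd, n) in `attr(, "summary")`.
#' @export
index_report <- function(vials, treatments = NULL, fractions = c(0.4, 1),
                         method = "integral") {
  stopifnot(length(vials) >= 1)
  ids <- names(vials)
  if (is.null(ids)) ids <- sprintf("vial%02d", seq_along(vials))
  if (is.null(treatments)) treatments <- ids
  rows <- lapply(seq_along(vials), function(i) {
    v <- vials[[i]]
    tA <- recovery_time(v$recovery, fractions[1])
    tB <- recovery_time(v$recovery, fractions[2])
    iA <- if (is.na(tA)) NA_real_ else
      n2o_index(v$times, v$n2o, v$n2, tA, method = method)
    iB <- if (is.na(tB)) NA_real_ else
      n2o_index(v$times, v$n2o, v$n2, tB, method = method)
    status <- if (is.na(tA) || is.na(tB)) "not reached" else "ok"
    data.frame(vial_id = ids[i], treatment = treatments[i],
               T40_h = as.numeric(tA), T100_h = as.numeric(tB),
               I40_pct = as.numeric(iA), I100_pct = as.numeric(iB),
               status = status)
  })
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$treatment), function(d) {
    data.frame(treatment = d$treatment[1], n = nrow(d),
               I40_mean = mean(d$I40_pct), I40_sd = stats::sd(d$I40_pct),
               I100_mean = mean(d$I100_pct), I100_sd = stats::sd(d$I100_pct))
  }))
  rownames(agg) <- NULL
  attr(out, "summary") <- agg
  out
}
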