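# Electron-flow budgets, carbon mineralization, nitrogen recovery.
#
# Respiratory electron flow to each terminal acceptor is deduced from the
# measured gas rates: O2 accepts 4 e- per mole, N2O -> N2 transfers 2 e-
# per N2 produced, and full denitrification NO3- -> 1/2 N2 accepts 5 e- per
# N (2 + 1 + 1 + 1 along the chain). Electrons diverted to cell synthesis
# are not part of these budgets.

#' Respiratory electron flow per terminal acceptor
#'
#' Translates species rates into electron flows (umol e- mL^-1 liquid
#' h^-1). Under N2O respiration each N2 produced carries 2 e-; O2
#' consumption carries 4 e- per mole; the full denitrification of NO3- to
#' N2 carries 5 e- per N (so 10 per N2). Nitrate is not a gas: requesting
#' the `"NO3"` acceptor requires an explicit nitrate consumption series
#' (liquid-phase bookkeeping), otherwise the call is rejected.
#'
#' @param rates A `rate_series` from [interval_rates()].
#' @param acceptors Character subset of `c("N2O", "O2", "NO3")`.
#' @param no3_rates Optional data.frame `time_h, rate_umol_ml_h` of NO3-
#'   consumption (umol N mL^-1 h^-1), required for the `"NO3"` acceptor.
#' @param table Species table.
#' @return Data.frame of class `eflow_series`: `t_start, t_end, time_h`,
#'   one column per requested acceptor (lower case), and `total`
#'   (umol e- mL^-1 h^-1). Consumption/production rates with the wrong sign
#'   contribute zero (flows are non-negative).
#' @examples
#' # V_N2 = 0.4 umol N2 mL^-1 h^-1 under N2O respiration -> 0.8 umol e-
#' @export
electron_flow <- function(rates, acceptors = c("N2O", "O2"),
                          no3_rates = NULL,
                          table = default_species_table()) {
  acceptors <- match.arg(acceptors, c("N2O", "O2", "NO3"), several.ok = TRUE)
  grid <- NULL
  out <- list()
  if ("N2O" %in% acceptors) {
    d <- rate_of(rates, "N2")
    grid <- d[, c("t_start", "t_end", "time_h")]
    out$n2o <- 2 * pmax(d$rate_umol_ml_h, 0)
  }
  if ("O2" %in% acceptors) {
    d <- rate_of(rates, "O2")
    if (is.null(grid)) grid <- d[, c("t_start", "t_end", "time_h")]
    out$o2 <- 4 * pmax(-d$rate_umol_ml_h, 0)
  }
  if ("NO3" %in% acceptors) {
    if (is.null(no3_rates))
      stop("acceptor NO3 requested without nitrate bookkeeping; ",
           "supply no3_rates (liquid-phase NO3- consumption)")
    if (is.null(grid)) grid <- data.frame(t_start = NA_real_, t_end = NA_real_,
                                          time_h = no3_rates$time_h)
    if (nrow(no3_rates) != nrow(grid))
      stop("no3_rates does not match the rate grid")
    out$no3 <- 5 * pmax(no3_rates$rate_umol_ml_h, 0)
  }
  res <- cbind(grid, as.data.frame(out))
  res$total <- rowSums(res[, names(out), drop = FALSE])
  class(res) <- c("eflow_series", "data.frame")
  res
}

#' Carbon mineralization rate and cumulative C
#'
#' C mineralized to gas is the sum of the CO2 and CH4 production rates
#' (1 C atom each). The cumulative curve integrates the per-interval rates
#' over their exact interval widths (equivalent to trapezoidal integration
#' of the underlying cumulative amounts). Only physically dissolved CO2 is
#' accounted for: carbonate speciation in the alkaline digestate is not
#' modelled, so dissolved inorganic carbon is underestimated.
#'
#' @param rates A `rate_series` containing CO2 and CH4.
#' @return Data.frame of class `cmin_series`: `t_start, t_end, time_h`,
#'   `c_rate_umol_ml_h`, and `c_cumulative_umol_ml` (evaluated at `t_end`).
#' @export
carbon_mineralization <- function(rates) {
  co2 <- rate_of(rates, "CO2")
  ch4 <- rate_of(rates, "CH4")
  if (nrow(co2) != nrow(ch4) || any(abs(co2$time_h - ch4$time_h) > 1e-9))
    stop("CO2 and CH4 rates are on different time grids")
  r <- co2$rate_umol_ml_h + ch4$rate_umol_ml_h
  out <- data.frame(t_start = co2$t_start, t_end = co2$t_end,
                    time_h = co2$time_h,
                    c_rate_umol_ml_h = r,
                    c_cumulative_umol_ml = cumsum(r * (co2$t_end - co2$t_start)))
  class(out) <- c("cmin_series", "data.frame")
  out
}

#' Fraction of nitrate-N recovered as gaseous N
#'
#' Computes the running fraction of the initial NO3--N pool recovered as
#' N2 + N2O + NO, on an N-atom basis:
#' `fraction(t) = (2 N2 + 2 N2O + NO) / no3_initial`
#' with cumulative production in umol of each gas. Used to anchor the
#' T_40/T_100 recovery times of the N2O index.
#'
#' @param cum A `cumulative_series` containing N2 and N2O (NO optional;
#'   treated as zero with a warning when absent).
#' @param no3_initial Initial nitrate, umol N, > 0.
#' @return Data.frame of class `recovery_series`: `time_h, fraction`.
#'   Fractions above 1.02 trigger an over-recovery warning.
#' @export
nitrogen_recovery <- function(cum, no3_initial) {
  stopifnot(no3_initial > 0)
  cm <- cum_matrix(cum)
  need <- c("N2", "N2O")
  if (!all(need %in% colnames(cm$mat)))
    stop("cumulative N2 and N2O required")
  no <- if ("NO" %in% colnames(cm$mat)) cm$mat[, "NO"] else {
    warning("no cumulative NO series; assuming 0")
    0
  }
  frac <- (2 * cm$mat[, "N2"] + 2 * cm$mat[, "N2O"] + no) / no3_initial
  if (any(frac > 1.02))
    warning(sprintf("over-recovery: fraction reaches %.3f (> 1)", max(frac)))
  out <- data.frame(time_h = cm$times, fraction = as.numeric(frac))
  class(out) <- c("recovery_series", "data.frame")
  out
}
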