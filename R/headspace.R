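# Gas-liquid equilibrium, sampling-dilution correction, rate estimation.
#
# All vials are stirred, so instantaneous equilibrium between headspace and
# liquid is assumed: for a dimensionless Henry constant K (= C_liq/C_gas),
# a total amount n distributes as C_gas = n / (V_g + K V_l).

#' Partition a total gas amount between headspace and liquid
#'
#' Equilibrium split of `total_amount` umol of a species between the
#' headspace and the stirred liquid: `C_gas = n / (V_g + K V_l)`,
#' `C_liq = K C_gas`. With umol and mL, `C_liq` is directly in mM.
#'
#' @param total_amount Total amount in the vial, umol (scalar, >= 0).
#' @param species Species name (row of `table`).
#' @param config A [vial_config()].
#' @param table Species table, see [default_species_table()].
#' @return A list of class `phase_split`: `species`, `total_amount`,
#'   `headspace_amount`, `dissolved_amount` (umol), `gas_conc`
#'   (umol mL^-1 gas), `liquid_conc` (mM).
#' @examples
#' # ~831 umol N2O in a 120 mL vial with 50 mL digestate gives ~5 mM liquid
#' v <- vial_config()
#' n <- injection_to_moles(list(kind = "injection", species = "N2O",
#'                              volume_ml = 20), v)
#' equilibrium_partition(n, "N2O", v)$liquid_conc
#' @export
equilibrium_partition <- function(total_amount, species, config,
                                  table = default_species_table()) {
  stopifnot(length(total_amount) == 1L, total_amount >= 0)
  K <- unname(henry_of(species, table))
  vg <- config$headspace_volume; vl <- config$liquid_volume
  gas_conc <- total_amount / (vg + K * vl)
  hs <- gas_conc * vg
  structure(list(species = species,
                 total_amount = total_amount,
                 headspace_amount = hs,
                 dissolved_amount = total_amount - hs,
                 gas_conc = gas_conc,
                 liquid_conc = K * gas_conc),
            class = "phase_split")
}

#' @export
print.phase_split <- function(x, ...) {
  cat(sprintf("<phase_split> %s: %.4g umol total = %.4g headspace + %.4g dissolved; liquid %.4g mM\n",
              x$species, x$total_amount, x$headspace_amount,
              x$dissolved_amount, x$liquid_conc))
  invisible(x)
}

#' Apply one robotic sampling dilution
#'
#' The sampler withdraws a fraction `f` of the headspace and returns an
#' equal volume of He, so `f * headspace_amount` of every non-He species is
#' removed; the remaining total then re-equilibrates between the phases.
#' `f = 0` is the identity.
#'
#' @param totals Named numeric vector of total amounts per species, umol.
#' @param config A [vial_config()].
#' @param table Species table.
#' @param fraction Sampling fraction; defaults to the config's.
#' @return A list with `totals` (updated named vector) and `removed`
#'   (umol removed per species).
#' @export
apply_sampling <- function(totals, config, table = default_species_table(),
                           fraction = config$sampling_fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  K <- henry_of(names(totals), table)
  vg <- config$headspace_volume; vl <- config$liquid_volume
  hs <- totals * vg / (vg + K * vl)
  removed <- fraction * hs
  removed[names(totals) == "He"] <- 0
  list(totals = totals - removed, removed = removed)
}

match_time <- function(t, times, tol = 1e-7) {
  abs(times - t) < tol
}

#' Reconstruct true cumulative production from measured headspace series
#'
#' Converts a measured headspace series into sampling-corrected cumulative
#' production (consumption negative) per species. Each measurement is
#' assumed taken immediately before the dilution of the same robot visit
#' (and before any injection logged at that time). For interval j the
#' production is
#' `dP_j = A_{j+1} - A'_j - I_j`,
#' where `A` is the equilibrated total amount implied by the measured
#' headspace amount, `A'` is `A` after the sampling dilution, and `I_j` is
#' the amount injected during the interval. Liquid withdrawals remove
#' dissolved gas proportionally and shrink the liquid volume.
#'
#' @param series A [gas_series()] with an event log (or `events = NULL` for
#'   no robot actions).
#' @param config A [vial_config()]; supplies f, volumes, T and P.
#' @param table Species table.
#' @return A long data.frame of class `cumulative_series` with columns
#'   `time_h, species, cumulative_umol, loss_umol` (per-visit sampling
#'   loss), and attributes `liquid_volume` (initial, mL) and `vial_id`.
#'   Negative reconstructed amounts (inconsistent f) are clamped to zero
#'   with a warning and counted in attribute `n_clamped`.
#' @export
reconstruct_cumulative <- function(series, config,
                                   table = default_species_table()) {
  tt <- series$times; sp <- series$species; m <- length(tt)
  if (m < 2) stop("need at least two time points")
  ev <- series$events
  if (!is.null(ev) && nrow(ev)) {
    if (any(ev$time_h < tt[1] - 1e-9 | ev$time_h > tt[m] + 1e-9))
      stop("event outside the measurement time range")
  } else {
    ev <- data.frame(time_h = numeric(), kind = character(),
                     species = character(), volume_ml = numeric())
  }
  K <- henry_of(sp, table)
  vl <- config$liquid_volume
  vg <- config$headspace_volume
  f <- config$sampling_fraction
  cum <- matrix(0, m, length(sp), dimnames = list(NULL, sp))
  loss <- matrix(0, m, length(sp), dimnames = list(NULL, sp))
  n_clamped <- 0L
  for (j in seq_len(m - 1)) {
    A <- series$amounts[j, ] * (1 + K * vl / vg)
    samp <- ev$kind == "sampling" & match_time(tt[j], ev$time_h)
    if (any(samp)) {
      l <- f * series$amounts[j, ]
      loss[j, ] <- l
      A <- A - l
    }
    if (any(A < 0)) {
      n_clamped <- n_clamped + sum(A < 0)
      A[A < 0] <- 0
    }
    in_iv <- ev$time_h >= tt[j] - 1e-9 & ev$time_h < tt[j + 1] - 1e-9
    inj <- stats::setNames(numeric(length(sp)), sp)
    for (k in which(in_iv)) {
      e <- ev[k, ]
      if (e$kind == "injection") {
        if (!e$species %in% sp)
          stop("injected species ", e$species, " not in the series")
        inj[e$species] <- inj[e$species] + injection_to_moles(e, config)
      } else if (e$kind == "liquid_withdrawal") {
        liq_conc <- K * A / (vg + K * vl)
        A <- A - liq_conc * e$volume_ml
        vl <- vl - e$volume_ml
        vg <- vg + e$volume_ml
        if (vl <= 0) stop("liquid withdrawals exhausted the liquid volume")
      }
    }
    A1 <- series$amounts[j + 1, ] * (1 + K * vl / vg)
    cum[j + 1, ] <- cum[j, ] + (A1 - A - inj)
  }
  samp_last <- ev$kind == "sampling" & match_time(tt[m], ev$time_h)
  if (any(samp_last)) loss[m, ] <- f * series$amounts[m, ]
  if (n_clamped > 0)
    warning(sprintf("reconstruct_cumulative: %d negative reconstructed amount(s) clamped to 0 (check sampling_fraction)",
                    n_clamped))
  out <- data.frame(
    time_h = rep(tt, times = length(sp)),
    species = rep(sp, each = m),
    cumulative_umol = as.vector(cum),
    loss_umol = as.vector(loss)
  )
  attr(out, "liquid_volume") <- config$liquid_volume
  attr(out, "vial_id") <- series$vial_id
  attr(out, "n_clamped") <- n_clamped
  class(out) <- c("cumulative_series", "data.frame")
  out
}

cum_matrix <- function(cum) {
  sp <- unique(cum$species)
  tt <- unique(cum$time_h)
  m <- matrix(cum$cumulative_umol, nrow = length(tt), ncol = length(sp),
              dimnames = list(NULL, sp))
  list(times = tt, mat = m)
}

#' Per-interval production rates from a cumulative series
#'
#' Finite-difference rates `dP_j / dt_j` assigned to interval midpoints,
#' both per vial (umol h^-1) and per mL of liquid (umol mL^-1 h^-1; with
#' umol and mL the latter equals mM h^-1). By construction
#' `rate * interval length` reproduces the cumulative increments exactly.
#'
#' @param cum A `cumulative_series` from [reconstruct_cumulative()] (or any
#'   long data.frame with `time_h, species, cumulative_umol`).
#' @param liquid_volume Liquid volume, mL; defaults to the series attribute.
#' @param smooth_window Odd integer width of an optional centered running
#'   mean over intervals; 0 or 1 disables smoothing (default).
#' @return Data.frame of class `rate_series` with columns
#'   `t_start, t_end, time_h` (midpoint), `species`, `rate_umol_h`,
#'   `rate_umol_ml_h`.
#' @export
interval_rates <- function(cum, liquid_volume = attr(cum, "liquid_volume"),
                           smooth_window = 0) {
  if (is.null(liquid_volume))
    stop("liquid_volume required (not found as attribute)")
  cm <- cum_matrix(cum)
  tt <- cm$times
  if (length(tt) < 2) stop("need at least two time points")
  dt <- diff(tt)
  if (any(dt <= 0)) stop("zero-length or negative interval")
  rows <- lapply(colnames(cm$mat), function(s) {
    r <- diff(cm$mat[, s]) / dt
    if (smooth_window > 1) {
      k <- as.integer(smooth_window)
      if (k %% 2 == 0) stop("smooth_window must be odd")
      sm <- stats::filter(r, rep(1 / k, k), sides = 2)
      r <- ifelse(is.na(sm), r, as.numeric(sm))
    }
    data.frame(t_start = tt[-length(tt)], t_end = tt[-1],
               time_h = (tt[-length(tt)] + tt[-1]) / 2,
               species = s, rate_umol_h = r,
               rate_umol_ml_h = r / liquid_volume)
  })
  out <- do.call(rbind, rows)
  attr(out, "liquid_volume") <- liquid_volume
  class(out) <- c("rate_series", "data.frame")
  out
}

rate_of <- function(rates, species) {
  d <- rates[rates$species == species, , drop = FALSE]
  if (nrow(d) == 0) stop("species ", species, " not present in the rate series")
  d[order(d$time_h), , drop = FALSE]
}

#' Subtract a linear N2 leak baseline
#'
#' Blank vials with a He atmosphere show a slow linear ingress of N2 through
#' the septum. Given an externally estimated constant leak rate, this
#' subtracts `rate * (t - t0)` from the species' headspace amounts before
#' reconstruction. Amounts driven negative are clamped at zero with a
#' warning.
#'
#' @param series A [gas_series()].
#' @param control_rate Leak rate, umol h^-1, >= 0 (0 is the identity).
#' @param species Species to correct, default `"N2"`.
#' @return The corrected [gas_series()].
#' @export
leak_baseline_correct <- function(series, control_rate, species = "N2") {
  stopifnot(control_rate >= 0)
  if (control_rate == 0) return(series)
  if (!species %in% series$species)
    stop("species ", species, " not in series")
  corr <- series$amounts[, species] -
    control_rate * (series$times - series$times[1])
  if (any(corr < 0)) {
    warning("leak correction drove ", sum(corr < 0),
            " amount(s) negative; clamped at 0")
    corr[corr < 0] <- 0
  }
  series$amounts[, species] <- corr
  series
}
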