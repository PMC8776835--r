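# Physical configuration, species constants, unit conversion and tabular io.

#' Universal gas constant (J mol^-1 K^-1)
#' @keywords internal
GAS_CONSTANT <- 8.314462618

#' Describe one incubation vessel
#'
#' A `vial_config` holds the physical description of a single crimp-sealed
#' serum vial in a robotized incubation system: volumes, temperature,
#' headspace pressure, and the fraction of headspace gas removed (and
#' replaced by He) at every robotic sampling.
#'
#' @param vial_id Character label for the vial.
#' @param total_volume Total vial volume, mL. Default 120 mL (standard serum
#'   vial).
#' @param liquid_volume Liquid (digestate/soil slurry) volume, mL. Must be
#'   strictly between 0 and `total_volume`.
#' @param temperature Incubation temperature, K. Default 293.15 K (20 degC).
#' @param headspace_pressure Headspace pressure, Pa. Default 101325 Pa.
#' @param sampling_fraction Dimensionless fraction of headspace moles removed
#'   per sampling event, `0 <= f < 1`. The exact dilution factor is an
#'   instrument property and must be supplied; default 0.01.
#' @param stirred Logical; stirred vials are assumed at instantaneous
#'   gas-liquid equilibrium.
#'
#' @return An object of class `vial_config` with the fields above plus the
#'   derived `headspace_volume` (mL).
#' @examples
#' vial_config("D1")
#' @export
vial_config <- function(vial_id = "vial", total_volume = 120,
                        liquid_volume = 50, temperature = 293.15,
                        headspace_pressure = 101325,
                        sampling_fraction = 0.01, stirred = TRUE) {
  stopifnot(is.character(vial_id), length(vial_id) == 1L)
  if (!(liquid_volume > 0 && liquid_volume < total_volume))
    stop("liquid_volume must satisfy 0 < liquid_volume < total_volume")
  if (temperature <= 0) stop("temperature must be positive (K)")
  if (headspace_pressure <= 0) stop("headspace_pressure must be positive (Pa)")
  if (!(sampling_fraction >= 0 && sampling_fraction < 1))
    stop("sampling_fraction must satisfy 0 <= f < 1")
  structure(list(
    vial_id = vial_id,
    total_volume = total_volume,
    liquid_volume = liquid_volume,
    headspace_volume = total_volume - liquid_volume,
    temperature = temperature,
    headspace_pressure = headspace_pressure,
    sampling_fraction = sampling_fraction,
    stirred = isTRUE(stirred)
  ), class = "vial_config")
}

#' @export
print.vial_config <- function(x, ...) {
  cat(sprintf("<vial_config> %s: %.0f mL total, %.0f mL liquid, %.0f mL headspace\n",
              x$vial_id, x$total_volume, x$liquid_volume, x$headspace_volume))
  cat(sprintf("  T = %.2f K, P = %.0f Pa, sampling fraction f = %g, %s\n",
              x$temperature, x$headspace_pressure, x$sampling_fraction,
              if (x$stirred) "stirred" else "static"))
  invisible(x)
}

#' Gas species constants
#'
#' Per-species constants used throughout: the dimensionless Henry solubility
#' (liquid/gas molar concentration ratio, K_cc, at 20 degC), electrons
#' accepted per mole when the species acts as terminal electron acceptor
#' (reduction to the product relevant here: O2 -> H2O is 4 e-, N2O -> N2 is
#' 2 e-, NO -> 1/2 N2O is 1 e-), and C/N atom counts. CO2 solubility is
#' physical only (no carbonate speciation). All values are user-overridable
#' literature defaults.
#'
#' Half-reaction electron constants for the denitrification chain are stored
#' in `attr(, "denitrification_steps")`: NO3- -> NO2- (2 e-), NO2- -> NO
#' (1 e-), NO -> 1/2 N2O (1 e-), 1/2 N2O -> 1/2 N2 (1 e-), all per N.
#'
#' @param overrides Optional named list; each element is itself a named list
#'   of columns to replace for that species, e.g.
#'   `list(N2O = list(henry = 0.60))`.
#' @return A data.frame with rownames O2, N2, N2O, NO, CO2, CH4, He and
#'   columns `henry`, `electrons`, `c_atoms`, `n_atoms`.
#' @examples
#' default_species_table()["N2O", "henry"]
#' @export
default_species_table <- function(overrides = NULL) {
  tab <- data.frame(
    henry     = c(O2 = 0.033, N2 = 0.016, N2O = 0.63, NO = 0.047,
                  CO2 = 0.94, CH4 = 0.034, He = 0.0094),
    electrons = c(O2 = 4, N2 = 0, N2O = 2, NO = 1, CO2 = 0, CH4 = 0, He = 0),
    c_atoms   = c(O2 = 0, N2 = 0, N2O = 0, NO = 0, CO2 = 1, CH4 = 1, He = 0),
    n_atoms   = c(O2 = 0, N2 = 2, N2O = 2, NO = 1, CO2 = 0, CH4 = 0, He = 0)
  )
  if (!is.null(overrides)) {
    for (sp in names(overrides)) {
      if (!sp %in% rownames(tab)) stop("unknown species in overrides: ", sp)
      for (col in names(overrides[[sp]])) tab[sp, col] <- overrides[[sp]][[col]]
    }
  }
  if (any(tab$henry < 0) || any(tab$electrons < 0))
    stop("species coefficients must be non-negative")
  attr(tab, "denitrification_steps") <-
    c(no3_to_no2 = 2, no2_to_no = 1, no_to_half_n2o = 1, half_n2o_to_half_n2 = 1)
  tab
}

henry_of <- function(species, table) {
  miss <- setdiff(species, rownames(table))
  if (length(miss))
    stop("unknown species: ", paste(miss, collapse = ", "),
         " (known: ", paste(rownames(table), collapse = ", "), ")")
  stats::setNames(table[species, "henry"], species)
}

#' Convert a headspace mixing ratio to an amount of gas
#'
#' Ideal-gas conversion of a measured headspace mixing ratio (ppmv) to the
#' molar amount in the headspace of a vial:
#' `n = x * 1e-6 * P * V_g / (R * T)`.
#'
#' @param x Mixing ratio(s), ppmv.
#' @param config A [vial_config()].
#' @return Amount(s) in umol per vial. `umol_to_ppmv()` is the exact inverse.
#' @examples
#' v <- vial_config()
#' ppmv_to_umol(10000, v)  # ~29.1 umol in a 70 mL headspace at 20 degC
#' @export
ppmv_to_umol <- function(x, config) {
  x * config$headspace_pressure * config$headspace_volume * 1e-6 /
    (GAS_CONSTANT * config$temperature)
}

#' @rdname ppmv_to_umol
#' @param n Amount(s), umol per vial.
#' @export
umol_to_ppmv <- function(n, config) {
  n * (GAS_CONSTANT * config$temperature) /
    (config$headspace_pressure * config$headspace_volume * 1e-6)
}

#' Headspace gas time series for one vial
#'
#' Container for per-vial headspace measurements: strictly increasing times
#' (hours, zero at the first measurement), a matrix of headspace amounts
#' (umol per vial) with one column per gas species, and an event log of
#' robot actions (sampling, injection, liquid withdrawal).
#'
#' @param vial_id Vial label.
#' @param times Numeric vector, hours, strictly increasing.
#' @param amounts Numeric matrix, `length(times)` rows, one column per
#'   species, headspace amounts in umol per vial. Non-negative.
#' @param species Character vector of species names (defaults to
#'   `colnames(amounts)`).
#' @param events An event log data.frame as returned by [read_events()],
#'   or `NULL`.
#' @return Object of class `gas_series`.
#' @export
gas_series <- function(vial_id, times, amounts, species = colnames(amounts),
                       events = NULL) {
  amounts <- as.matrix(amounts)
  if (is.null(species)) stop("species names required")
  colnames(amounts) <- species
  if (length(times) != nrow(amounts))
    stop("times and amounts rows differ")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing without duplicates")
  if (any(amounts < 0)) stop("negative headspace amounts")
  if (!is.null(events)) {
    check_event_log(events)
    bad <- events$time_h < min(times) - 1e-9 | events$time_h > max(times) + 1e-9
    if (any(bad))
      stop("event times outside the measurement range: ",
           paste(events$time_h[bad], collapse = ", "))
  }
  structure(list(vial_id = vial_id, times = as.numeric(times),
                 species = species, amounts = amounts,
                 unit = "umol_per_vial", events = events),
            class = "gas_series")
}

#' @export
print.gas_series <- function(x, ...) {
  cat(sprintf("<gas_series> vial %s: %d time points over %.1f h, species: %s\n",
              x$vial_id, length(x$times), diff(range(x$times)),
              paste(x$species, collapse = ", ")))
  if (!is.null(x$events))
    cat(sprintf("  %d events (%s)\n", nrow(x$events),
                paste(names(table(x$events$kind)), collapse = ", ")))
  invisible(x)
}

#' Read headspace gas measurements from CSV
#'
#' Expects a long-format CSV with columns `vial_id, time_h, species, value,
#' unit` where `unit` is `ppmv` or `umol_per_vial`. Values are normalized to
#' umol per vial (ideal-gas conversion for ppmv). Malformed rows are
#' rejected with an error, never silently coerced; the number of accepted
#' rows is reported as a message.
#'
#' @param path CSV file path.
#' @param config A [vial_config()] used for the ppmv conversion (one
#'   configuration for all vials in the file).
#' @param table Species table, see [default_species_table()].
#' @param events Optional event log attached to every returned series.
#' @return A named list of [gas_series()], one per vial.
#' @export
read_gas_series <- function(path, config, table = default_species_table(),
                            events = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vial_id", "time_h", "species", "value", "unit")
  if (!all(need %in% names(df)))
    stop("gas CSV must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(unique(df$species), rownames(table))
  if (length(miss))
    stop("unknown species name(s): ", paste(miss, collapse = ", "),
         "; known species: ", paste(rownames(table), collapse = ", "))
  if (!all(df$unit %in% c("ppmv", "umol_per_vial")))
    stop("unit must be ppmv or umol_per_vial")
  if (any(!is.finite(df$value)) || any(df$value < 0))
    stop("values must be finite and non-negative")
  out <- lapply(split(df, df$vial_id), function(d) {
    units_by_sp <- tapply(d$unit, d$species, function(u) length(unique(u)))
    if (any(units_by_sp > 1))
      stop("mixed units within one vial/species in vial ", d$vial_id[1])
    d$umol <- ifelse(d$unit == "ppmv", ppmv_to_umol(d$value, config), d$value)
    tt <- sort(unique(d$time_h))
    sp <- unique(d$species)
    m <- matrix(NA_real_, length(tt), length(sp), dimnames = list(NULL, sp))
    for (k in seq_len(nrow(d))) {
      i <- match(d$time_h[k], tt); j <- match(d$species[k], sp)
      if (!is.na(m[i, j]))
        stop("duplicate time ", d$time_h[k], " for species ", d$species[k],
             " in vial ", d$vial_id[1])
      m[i, j] <- d$umol[k]
    }
    if (anyNA(m))
      stop("incomplete species-by-time grid in vial ", d$vial_id[1])
    gas_series(d$vial_id[1], tt, m, events = events)
  })
  message(sprintf("read_gas_series: accepted %d rows (%d vial(s))",
                  nrow(df), length(out)))
  out
}

#' Write a gas series to CSV (long format)
#'
#' Inverse of [read_gas_series()]; a write -> read round trip reproduces the
#' numeric matrix exactly.
#'
#' @param series A [gas_series()].
#' @param path Output CSV path.
#' @export
write_gas_series <- function(series, path) {
  df <- data.frame(
    vial_id = series$vial_id,
    time_h = rep(series$times, times = length(series$species)),
    species = rep(series$species, each = length(series$times)),
    value = as.vector(series$amounts),
    unit = "umol_per_vial"
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

EVENT_KINDS <- c("sampling", "injection", "liquid_withdrawal")

check_event_log <- function(ev) {
  need <- c("time_h", "kind", "species", "volume_ml")
  if (!all(need %in% names(ev)))
    stop("event log must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(ev$kind), EVENT_KINDS)
  if (length(bad))
    stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  inj <- ev$kind == "injection"
  if (any(inj & (is.na(ev$volume_ml) | ev$volume_ml <= 0)))
    stop("injection events need volume_ml > 0")
  if (any(!is.na(ev$volume_ml) & ev$volume_ml < 0))
    stop("negative event volume")
  invisible(ev)
}

#' Read an event log from CSV
#'
#' Expects columns `time_h, kind, species, volume_mL` (case of the volume
#' column is tolerated). Kinds are restricted to `sampling`, `injection`,
#' `liquid_withdrawal`. Rows are returned sorted ascending by time.
#'
#' @param path CSV file path.
#' @return A data.frame of class `event_log`.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(ev)[names(ev) == "volume_mL"] <- "volume_ml"
  if (nrow(ev) == 0) {
    ev <- data.frame(time_h = numeric(), kind = character(),
                     species = character(), volume_ml = numeric())
  }
  check_event_log(ev)
  ev <- ev[order(ev$time_h), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_log", "data.frame")
  ev
}

#' Moles added by a gas injection
#'
#' Ideal-gas amount of an injected volume, `n = P V / (R T)`, evaluated at
#' the event's own pressure/temperature when present (`pressure_pa`,
#' `temperature_k` fields), otherwise at the vial configuration's.
#'
#' @param event A single event-log row (data.frame or list) of kind
#'   `injection` with `species` and `volume_ml`.
#' @param config A [vial_config()].
#' @return Amount injected, umol.
#' @examples
#' v <- vial_config()
#' ev <- list(kind = "injection", species = "N2O", volume_ml = 20)
#' injection_to_moles(ev, v)  # ~831 umol
#' @export
injection_to_moles <- function(event, config) {
  if (!identical(as.character(event$kind), "injection"))
    stop("event is not an injection")
  if (is.null(event$species) || is.na(event$species) ||
      !nzchar(event$species))
    stop("injection event lacks a species")
  p <- if (!is.null(event$pressure_pa) && !is.na(event$pressure_pa))
    event$pressure_pa else config$headspace_pressure
  tk <- if (!is.null(event$temperature_k) && !is.na(event$temperature_k))
    event$temperature_k else config$temperature
  p * event$volume_ml * 1e-6 / (GAS_CONSTANT * tk) * 1e6
}

#' Read a vial configuration from a flat key-value CSV
#'
#' The file has columns `key,value` with keys matching the arguments of
#' [vial_config()] (plus `vial_id`). A documented template ships in
#' `inst/extdata/vial_config_template.csv`.
#'
#' @param path CSV file path.
#' @return A [vial_config()].
#' @export
read_vial_config <- function(path) {
  kv <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(kv)))
    stop("config CSV must have columns key,value")
  args <- stats::setNames(as.list(kv$value), kv$key)
  num <- setdiff(names(args), c("vial_id", "stirred"))
  args[num] <- lapply(args[num], as.numeric)
  if ("stirred" %in% names(args)) args$stirred <- as.logical(args$stirred)
  do.call(vial_config, args)
}
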