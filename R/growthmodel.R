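# Two-population model of N2O-respiring bacteria (NRB).
#
# The N2-production rate of an enrichment is modelled as the sum of two
# activities:
#   V_N2(t) = v0 * exp(mu * t) + w0 * exp(-k * t)
# one population growing exponentially from a very low initial abundance
# (specific growth rate mu) and one whose N2O-reduction activity is present
# initially but dies out at first-order rate k. Fitting is done in log-rate
# space (multiplicative error; the rates span several orders of magnitude),
# with positivity enforced by optimizing log-parameters. Assuming a constant
# cell yield Y per mole of electrons, the fit translates into a cell-density
# trajectory N(t) and a cell-specific electron flow V_e = e-flow / N, which
# is constant (= mu / Y) during balanced exponential growth.

twopop_model <- function(p, t) {
  p[["v0"]] * exp(p[["mu"]] * t) + p[["w0"]] * exp(-p[["k"]] * t)
}

num_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

extract_vn2 <- function(rates, times, species) {
  if (inherits(rates, "rate_series") || (is.data.frame(rates) &&
      all(c("time_h", "species", "rate_umol_ml_h") %in% names(rates)))) {
    d <- rate_of(rates, species)
    list(t = d$time_h, v = d$rate_umol_ml_h)
  } else {
    if (is.null(times)) stop("times required when rates is a numeric vector")
    list(t = as.numeric(times), v = as.numeric(rates))
  }
}

#' Fit the two-population model to N2-production rates
#'
#' Least-squares fit of `log V_N2` to
#' `log(v0 exp(mu t) + w0 exp(-k t))` by Levenberg-Marquardt on
#' log-parameters. Initial guesses come from log-linear regressions on the
#' last third (mu, v0) and first third (k, w0) of the points. When the
#' first third shows no decline the model reduces to a pure exponential and
#' mu is the exact closed-form slope of the log-linear regression; when the
#' last third shows no growth only the declining activity is fitted and mu
#' is flagged unidentifiable.
#'
#' @param rates A `rate_series` from [interval_rates()] (the N2 species is
#'   used) or a numeric vector of rates (umol N2 mL^-1 h^-1).
#' @param times Midpoint times, h; only needed when `rates` is a vector.
#' @param window Optional `c(t_a, t_b)` restricting the fit, e.g. to the
#'   phase before substrate limitation sets in.
#' @param init Optional named list `v0, mu, w0, k` of starting values.
#' @param species Species column used when `rates` is a `rate_series`.
#' @return Object of class `twopop_fit`: parameters `v0, mu, w0, k_decline`,
#'   `model` (`"two_pop"`, `"growth_only"` or `"decline_only"`),
#'   `converged`, `mu_identifiable` (covariance-based: relative standard
#'   error of mu below 50%), `cov_log` (covariance of the log-parameters),
#'   `se` (delta-method standard errors), residuals (log scale), `window`,
#'   and the data used.
#' @examples
#' t <- seq(0, 215, by = 3)
#' v <- 0.001 * exp(0.1 * t) + 0.5 * exp(-0.03 * t)
#' fit_two_population(v, times = t)
#' @export
fit_two_population <- function(rates, times = NULL, window = NULL,
                               init = NULL, species = "N2") {
  d <- extract_vn2(rates, times, species)
  t <- d$t; v <- d$v
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; v <- v[keep]
  }
  pos <- is.finite(v) & v > 0
  if (any(!pos)) {
    warning(sum(!pos), " non-positive rate point(s) dropped before the log-space fit")
    t <- t[pos]; v <- v[pos]
  }
  n <- length(v)
  if (n < 6) stop("need at least 6 strictly positive rate points")
  o <- order(t); t <- t[o]; v <- v[o]
  lv <- log(v)
  # dispatch on the position of the rate minimum: a two-population record
  # declines to a valley and grows out of it
  jmin <- which.min(lv)
  i1 <- 1:max(3L, jmin)
  c1 <- stats::coef(stats::lm(lv[i1] ~ t[i1]))
  i2 <- min(n - 2L, jmin):n
  c2 <- stats::coef(stats::lm(lv[i2] ~ t[i2]))
  s1 <- unname(c1[2]); s2 <- unname(c2[2])

  finish <- function(fit) {
    fit$window <- range(t)
    fit$times <- t
    fit$rates <- v
    class(fit) <- "twopop_fit"
    fit
  }

  if ((jmin >= n - 1L || s2 <= 0) && is.null(init)) {
    # no growth signal at the end of the record: declining activity only
    cc <- stats::coef(stats::lm(lv ~ t))
    w0 <- exp(unname(cc[1])); k <- max(0, -unname(cc[2]))
    res <- lv - log(w0 * exp(-k * t))
    return(finish(list(
      v0 = NA_real_, mu = NA_real_, w0 = w0, k_decline = k,
      model = "decline_only", converged = TRUE, mu_identifiable = FALSE,
      cov_log = NULL, se = c(v0 = NA, mu = NA, w0 = NA, k = NA),
      residuals = res, rss = sum(res^2), sigma = sqrt(sum(res^2) / (n - 2)),
      message = "all-decline data: mu unidentifiable")))
  }
  if (jmin <= 2L && is.null(init)) {
    # no decline signal: pure exponential, closed-form log-linear slope
    fitlm <- stats::lm(lv ~ t)
    cc <- stats::coef(fitlm)
    v0 <- exp(unname(cc[1])); mu <- unname(cc[2])
    sm <- suppressWarnings(stats::coef(summary(fitlm)))
    se_mu <- sm[2, 2]
    res <- stats::residuals(fitlm)
    return(finish(list(
      v0 = v0, mu = mu, w0 = 0, k_decline = 0,
      model = "growth_only", converged = TRUE,
      mu_identifiable = is.finite(se_mu) && se_mu < 0.5 * abs(mu),
      cov_log = suppressWarnings(stats::vcov(fitlm)),
      se = c(v0 = v0 * sm[1, 2], mu = se_mu, w0 = NA, k = NA),
      residuals = as.numeric(res), rss = sum(res^2),
      sigma = sqrt(sum(res^2) / (n - 2)),
      message = "no decline signal: reduced to log-linear fit")))
  }

  if (is.null(init)) {
    init <- list(v0 = exp(unname(c2[1])), mu = max(s2, 1e-4),
                 w0 = exp(unname(c1[1])), k = max(-s1, 1e-4))
  }
  th0 <- log(unlist(init)[c("v0", "mu", "w0", "k")])
  resfun <- function(th) {
    p <- exp(th); names(p) <- c("v0", "mu", "w0", "k")
    lv - log(twopop_model(p, t))
  }
  lmfit <- minpack.lm::nls.lm(
    par = th0, fn = resfun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  converged <- lmfit$info %in% 1:4
  if (!converged)
    warning("two-population fit did not converge (info = ", lmfit$info,
            "); returning the best iterate")
  th <- lmfit$par
  p <- exp(th); names(p) <- c("v0", "mu", "w0", "k")
  res <- resfun(th)
  dof <- max(1L, n - 4L)
  sig2 <- sum(res^2) / dof
  J <- num_jacobian(resfun, th)
  cov_log <- tryCatch(sig2 * solve(crossprod(J)),
                      error = function(e) NULL)
  se_log <- if (!is.null(cov_log)) sqrt(pmax(diag(cov_log), 0)) else
    rep(NA_real_, 4)
  names(se_log) <- c("v0", "mu", "w0", "k")
  # delta method: se(p) = p * se(log p)
  se <- p * se_log
  mu_ok <- converged && is.finite(se_log[["mu"]]) && se_log[["mu"]] < 0.5
  finish(list(
    v0 = unname(p["v0"]), mu = unname(p["mu"]), w0 = unname(p["w0"]),
    k_decline = unname(p["k"]), model = "two_pop", converged = converged,
    mu_identifiable = mu_ok, cov_log = cov_log, se = se,
    residuals = as.numeric(res), rss = sum(res^2), sigma = sqrt(sig2),
    niter = lmfit$niter, message = lmfit$message))
}

#' @export
print.twopop_fit <- function(x, ...) {
  cat(sprintf("<twopop_fit> model = %s, converged = %s\n", x$model, x$converged))
  cat(sprintf("  V_N2(t) = v0 exp(mu t) + w0 exp(-k t)\n"))
  cat(sprintf("  v0 = %.4g umol N2/mL/h, mu = %.4g /h%s\n", x$v0, x$mu,
              if (!x$mu_identifiable) " (poorly constrained)" else ""))
  cat(sprintf("  w0 = %.4g umol N2/mL/h, k  = %.4g /h\n", x$w0, x$k_decline))
  cat(sprintf("  log-residual sd = %.3g over window [%.1f, %.1f] h\n",
              x$sigma, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
predict.twopop_fit <- function(object, times = object$times, ...) {
  p <- c(v0 = ifelse(is.na(object$v0), 0, object$v0),
         mu = ifelse(is.na(object$mu), 0, object$mu),
         w0 = object$w0, k = object$k_decline)
  twopop_model(p, times)
}

#' End of the balanced exponential-growth window
#'
#' The exponential window closes at the first time where (a) the modelled
#' growing population carries at least `share` (default 90%) of the total
#' modelled rate, and (b) the observed rate curve has flattened: the local
#' slope of log V_N2 falls below `mu / 2`. If the condition is never met
#' the window extends to the last observation.
#'
#' @param fit A converged [fit_two_population()] result.
#' @param share Growing-population share threshold.
#' @return Time (h) at which the window ends.
#' @export
exponential_window_end <- function(fit, share = 0.9) {
  t <- fit$times; v <- fit$rates
  if (fit$model == "decline_only") stop("no growth phase in this fit")
  g <- fit$v0 * exp(fit$mu * t)
  gshare <- g / predict(fit, t)
  lv <- log(v)
  nn <- length(t)
  slope <- rep(fit$mu, nn)
  if (nn >= 5) {
    for (i in 3:(nn - 2))
      slope[i] <- (lv[i + 2] - lv[i - 2]) / (t[i + 2] - t[i - 2])
    slope[nn - 1] <- slope[nn] <- slope[nn - 2]
  }
  hit <- which(gshare >= share & slope < fit$mu / 2)
  if (length(hit) == 0) max(t) else t[hit[1]]
}

#' Configuration for cell-density reconstruction
#'
#' The gas kinetics fix `mu` and `v0` but not the absolute cell scale, so
#' one anchor is required: either the constant cell yield `Y` (cells per
#' fmol e-), the exponential-phase cell-specific electron flow `V_e_exp`
#' (fmol e- cell^-1 h^-1), or an anchor density (e.g. a ddPCR count) at a
#' known time inside the exponential window. The three are linked by
#' `V_e_exp = mu / Y`.
#'
#' @param yield_per_electron Y, cells per fmol e-.
#' @param v_e_exp Exponential-phase V_e, fmol e- cell^-1 h^-1.
#' @param anchor_time,anchor_density Time (h) and density (cells mL^-1) of
#'   an independent cell count inside the exponential window.
#' @param electrons_per_n2 Electrons per N2 produced from N2O; fixed at 2.
#' @param window_share Passed to [exponential_window_end()].
#' @return Object of class `growth_config`.
#' @export
growth_config <- function(yield_per_electron = NULL, v_e_exp = NULL,
                          anchor_time = NULL, anchor_density = NULL,
                          electrons_per_n2 = 2, window_share = 0.9) {
  if (electrons_per_n2 != 2)
    stop("electrons_per_n2 is fixed at 2 for N2O respiration")
  if (is.null(yield_per_electron) && is.null(v_e_exp) &&
      (is.null(anchor_time) || is.null(anchor_density)))
    stop("cell scale unidentifiable: supply yield_per_electron, v_e_exp, ",
         "or an anchor density (anchor_time + anchor_density)")
  structure(list(yield_per_electron = yield_per_electron, v_e_exp = v_e_exp,
                 anchor_time = anchor_time, anchor_density = anchor_density,
                 electrons_per_n2 = electrons_per_n2,
                 window_share = window_share),
            class = "growth_config")
}

resolve_scale <- function(fit, cfg) {
  if (is.na(fit$mu) || fit$mu <= 0)
    stop("mu must be positive to reconstruct the growing population")
  if (!is.null(cfg$v_e_exp)) {
    ve <- cfg$v_e_exp
  } else if (!is.null(cfg$yield_per_electron)) {
    ve <- fit$mu / cfg$yield_per_electron
  } else {
    n0 <- cfg$anchor_density * exp(-fit$mu * cfg$anchor_time)
    ve <- cfg$electrons_per_n2 * fit$v0 * 1e9 / n0
  }
  list(v_e_exp = ve, yield = fit$mu / ve,
       n0 = cfg$electrons_per_n2 * fit$v0 * 1e9 / ve)
}

#' Back-extrapolate the growing population to time zero
#'
#' The dotted-line construction: the growing population's activity at t = 0
#' is `v0`, and with exponential-phase cell-specific electron flow
#' `V_e_exp` its initial density is `N0 = 2 v0 1e9 / V_e_exp` cells mL^-1
#' (the 1e9 converts umol to fmol).
#'
#' @param fit A converged [fit_two_population()] with `mu > 0`.
#' @param cfg A [growth_config()].
#' @return List with `n0` (cells mL^-1), `initial_activity` (= v0,
#'   umol N2 mL^-1 h^-1), `v_e_exp` and `yield` (cells per fmol e-).
#' @export
backextrapolate_initial <- function(fit, cfg) {
  sc <- resolve_scale(fit, cfg)
  list(n0 = sc$n0, initial_activity = fit$v0,
       v_e_exp = sc$v_e_exp, yield = sc$yield)
}

#' Reconstruct the NRB cell-density trajectory
#'
#' Within the exponential window `N(t) = N0 exp(mu t)`; once substrate
#' limitation ends balanced growth, density is continued by integrating
#' `dN/dt = Y * (growing population's electron flow)` trapezoidally, where
#' the growing population's flow is the measured total minus the modelled
#' declining activity. The cell-specific flow is
#' `V_e(t) = e-flow_growing * 1e9 / N(t)` (fmol e- cell^-1 h^-1).
#'
#' @param fit A converged [fit_two_population()] with `mu > 0`.
#' @param eflow An `eflow_series` from [electron_flow()] (its `total`
#'   column is used, umol e- mL^-1 h^-1).
#' @param cfg A [growth_config()] fixing the cell scale.
#' @return Data.frame of class `cell_density_series` with `time_h`,
#'   `n_cells_ml`, `v_e_fmol`; attributes `n0`, `yield`, `v_e_exp`,
#'   `window_end`.
#' @export
reconstruct_density <- function(fit, eflow, cfg) {
  if (!fit$converged) stop("fit did not converge")
  sc <- resolve_scale(fit, cfg)
  t1 <- exponential_window_end(fit, share = cfg$window_share)
  tt <- eflow$time_h
  w <- if (fit$model == "two_pop")
    2 * fit$w0 * exp(-fit$k_decline * tt) else rep(0, length(tt))
  eg <- pmax(eflow$total - w, 0)
  n <- numeric(length(tt))
  inwin <- tt <= t1 + 1e-9
  n[inwin] <- sc$n0 * exp(fit$mu * tt[inwin])
  i1 <- max(which(inwin), 1L)
  if (!any(inwin)) {
    n[1] <- sc$n0 * exp(fit$mu * tt[1])
    i1 <- 1L
  }
  if (i1 < length(tt)) {
    for (i in (i1 + 1):length(tt)) {
      dt <- tt[i] - tt[i - 1]
      n[i] <- n[i - 1] + sc$yield * 1e9 * (eg[i] + eg[i - 1]) / 2 * dt
    }
  }
  out <- data.frame(time_h = tt, n_cells_ml = n,
                    v_e_fmol = eg * 1e9 / n)
  attr(out, "n0") <- sc$n0
  attr(out, "yield") <- sc$yield
  attr(out, "v_e_exp") <- sc$v_e_exp
  attr(out, "window_end") <- t1
  class(out) <- c("cell_density_series", "data.frame")
  out
}

#' Cell-specific electron flow
#'
#' `V_e(t) = e-flow(t) * 1e9 / N(t)` in fmol e- cell^-1 h^-1, for an
#' electron flow in umol e- mL^-1 h^-1 and a density in cells mL^-1.
#' Accepts either plain numeric vectors or an `eflow_series` plus a
#' `cell_density_series` on the same time grid.
#'
#' @param eflow Electron flow (numeric, umol e- mL^-1 h^-1) or an
#'   `eflow_series` (its `total` column is used).
#' @param density Cell density (numeric, cells mL^-1, all > 0) or a
#'   `cell_density_series`.
#' @return Numeric V_e, or a data.frame `time_h, v_e_fmol` for series
#'   input.
#' @examples
#' cell_specific_eflow(0.8, 1.6e8)  # 5 fmol e- cell^-1 h^-1
#' @export
cell_specific_eflow <- function(eflow, density) {
  if (is.numeric(eflow) && is.numeric(density)) {
    if (any(density <= 0)) stop("density must be positive")
    return(eflow * 1e9 / density)
  }
  tt <- eflow$time_h
  if (nrow(density) != length(tt) ||
      any(abs(density$time_h - tt) > 1e-6))
    stop("eflow and density are on different time grids")
  if (any(density$n_cells_ml <= 0)) stop("density must be positive")
  data.frame(time_h = tt,
             v_e_fmol = eflow$total * 1e9 / density$n_cells_ml)
}

#' Growth rate between two density endpoints
#'
#' Closed-form specific growth rate of exponential growth between two
#' observed densities: `mu = log(n1 / n0) / dt`.
#'
#' @param n0,n1 Densities (same units) at the start and end.
#' @param dt Elapsed time, h.
#' @return mu, h^-1.
#' @examples
#' mu_from_endpoints(2.5e3, 1.6e8, 110)  # ~0.1 /h
#' @export
mu_from_endpoints <- function(n0, n1, dt) {
  stopifnot(n0 > 0, n1 > 0, dt > 0)
  log(n1 / n0) / dt
}

#' Write a JSON fit report
#'
#' Parameters, standard errors, log-parameter covariance, fit window and
#' convergence status of a two-population fit, as a JSON file.
#'
#' @param fit A [fit_two_population()] result.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(
    model = fit$model,
    parameters = list(v0 = fit$v0, mu = fit$mu, w0 = fit$w0,
                      k_decline = fit$k_decline),
    se = as.list(fit$se),
    converged = fit$converged,
    mu_identifiable = fit$mu_identifiable,
    window_h = fit$window,
    residual_log_sd = fit$sigma,
    cov_log = if (!is.null(fit$cov_log)) unclass(fit$cov_log) else NULL
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
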