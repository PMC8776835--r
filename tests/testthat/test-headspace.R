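# Gas-liquid partitioning, sampling correction, rate estimation.

test_that("equilibrium partition reproduces the closed-form mass balance", {
  v <- vial_config()  # V_g = 70, V_l = 50
  n <- injection_to_moles(list(kind = "injection", species = "N2O",
                               volume_ml = 20), v)
  ps <- equilibrium_partition(n, "N2O", v)
  # independent closed form: C_g = n / (V_g + K V_l), K = 0.63
  cg <- n / (70 + 0.63 * 50)
  expect_equal(ps$gas_conc, cg, tolerance = 1e-12)
  expect_equal(ps$liquid_conc, 0.63 * cg, tolerance = 1e-12)
  expect_equal(ps$headspace_amount + ps$dissolved_amount, ps$total_amount,
               tolerance = 1e-15)
  expect_equal(ps$headspace_amount, cg * 70, tolerance = 1e-12)
  # the 20 mL supplement yields ~5 mM in the liquid
  expect_gt(ps$liquid_conc, 4.5); expect_lt(ps$liquid_conc, 5.5)
})

test_that("an insoluble gas stays entirely in the headspace", {
  v <- vial_config()
  tab <- default_species_table(overrides = list(N2 = list(henry = 0)))
  ps <- equilibrium_partition(100, "N2", v, tab)
  expect_equal(ps$dissolved_amount, 0)
  expect_equal(ps$headspace_amount, 100)
})

test_that("partition monotonicity: higher solubility moves gas into the liquid", {
  v <- vial_config()
  ks <- c(0.01, 0.1, 0.5, 1, 2)
  res <- sapply(ks, function(k) {
    tab <- default_species_table(overrides = list(N2O = list(henry = k)))
    ps <- equilibrium_partition(500, "N2O", v, tab)
    c(ps$gas_conc, ps$dissolved_amount / ps$total_amount)
  })
  expect_true(all(diff(res[1, ]) < 0))  # gas concentration strictly falls
  expect_true(all(diff(res[2, ]) > 0))  # dissolved share strictly rises
})

test_that("sampling dilution removes the headspace share and re-equilibrates", {
  v <- vial_config(sampling_fraction = 0.05)
  # gas_conc 10 umol/mL: total = 10 * (70 + 0.63*50) = 1015
  tot <- c(N2O = 10 * (70 + 0.63 * 50))
  out <- apply_sampling(tot, v)
  expect_equal(unname(out$removed["N2O"]), 0.05 * 700)
  expect_equal(unname(out$totals["N2O"]) / (70 + 0.63 * 50), 980 / 101.5,
               tolerance = 1e-12)
  # f = 0 is the identity
  id <- apply_sampling(tot, v, fraction = 0)
  expect_identical(unname(id$totals), unname(tot))
  # insoluble gas: concentration drops by exactly f
  tab <- default_species_table(overrides = list(N2 = list(henry = 0)))
  out2 <- apply_sampling(c(N2 = 100), v, tab)
  expect_equal(unname(out2$totals["N2"]), 95)
  # He backfill itself is never removed
  out3 <- apply_sampling(c(He = 50, N2O = 100), v)
  expect_equal(unname(out3$removed["He"]), 0)
})

test_that("constant concentrations with no robot actions give zero production", {
  v <- vial_config()
  tt <- seq(0, 30, by = 3)
  gs <- gas_series("v", tt, cbind(N2O = rep(500, length(tt))))
  cum <- reconstruct_cumulative(gs, v)
  expect_equal(cum$cumulative_umol, rep(0, length(tt)))
})

test_that("pure sampling decay reconstructs to zero production", {
  # with zero true production and dilution f per visit, the measured
  # headspace follows C_k = C0 (1 - f V_g/(V_g + K V_l))^k
  f <- 0.05
  v <- vial_config(sampling_fraction = f)
  K <- 0.63; vg <- 70; vl <- 50
  k <- 0:12
  hs <- 700 * (1 - f * vg / (vg + K * vl))^k
  tt <- 3 * k
  ev <- data.frame(time_h = tt, kind = "sampling", species = "",
                   volume_ml = f * vg)
  gs <- gas_series("v", tt, cbind(N2O = hs), events = ev)
  cum <- reconstruct_cumulative(gs, v)
  expect_lt(max(abs(cum$cumulative_umol)) / 700, 1e-12)
  # and the per-visit losses ledger holds f * headspace
  expect_equal(cum$loss_umol, f * hs, tolerance = 1e-12)
})

test_that("injections are credited against apparent production", {
  v <- vial_config(sampling_fraction = 0)
  inj <- injection_to_moles(list(kind = "injection", species = "N2O",
                                 volume_ml = 20), v)
  fac <- (70 + 0.63 * 50) / 70
  # amounts: constant total before, total + injection after the event
  hs0 <- 500 / fac
  hs1 <- (500 + inj) / fac
  ev <- data.frame(time_h = 5, kind = "injection", species = "N2O",
                   volume_ml = 20)
  gs <- gas_series("v", c(0, 10), rbind(hs0, hs1), species = "N2O",
                   events = ev)
  cum <- reconstruct_cumulative(gs, v)
  expect_equal(cum$cumulative_umol[2], 0, tolerance = 1e-9)
})

test_that("liquid withdrawal removes dissolved gas and shrinks the liquid", {
  v <- vial_config(sampling_fraction = 0)
  K <- 0.63
  # start: gas_conc 10, total 1015; withdraw 5 mL at t = 0.5
  hs0 <- 700
  removed <- K * 10 * 5                      # liquid_conc * volume
  total1 <- 1015 - removed
  vl1 <- 45; vg1 <- 75
  cg1 <- total1 / (vg1 + K * vl1)
  hs1 <- cg1 * vg1
  ev <- data.frame(time_h = 0.5, kind = "liquid_withdrawal", species = "",
                   volume_ml = 5)
  gs <- gas_series("v", c(0, 1), rbind(hs0, hs1), species = "N2O",
                   events = ev)
  cum <- reconstruct_cumulative(gs, v)
  expect_equal(cum$cumulative_umol[2], 0, tolerance = 1e-9)
})

test_that("conservation: phases + removals - injections - production is constant", {
  sim <- default_enrichment_sim()
  v <- sim$scenario$vial
  tab <- default_species_table()
  gs <- sim$observed_clean
  tr <- sim$truth
  fac <- 1 + tab[gs$species, "henry"] * v$liquid_volume / v$headspace_volume
  totals <- sweep(gs$amounts, 2, fac, "*")
  ev <- sim$events
  inj_cum <- sapply(tr$times, function(t0) {
    sel <- ev$kind == "injection" & ev$time_h < t0 - 1e-9
    sum(vapply(which(sel), function(i)
      injection_to_moles(ev[i, ], v), numeric(1)))
  })
  init <- matrix(rep(tr$initial, each = length(tr$times)),
                 ncol = 4, dimnames = list(NULL, names(tr$initial)))
  balance <- totals + tr$removed - tr$cumulative - init
  balance[, "N2O"] <- balance[, "N2O"] - inj_cum
  expect_lt(max(abs(balance)) / max(totals), 1e-9)
})

test_that("interval rates reproduce cumulative increments exactly", {
  tt <- seq(0, 10, by = 1)
  cum <- data.frame(time_h = tt, species = "N2", cumulative_umol = tt)
  r <- interval_rates(cum, liquid_volume = 50)
  expect_equal(r$rate_umol_h, rep(1, 10))
  expect_equal(r$rate_umol_ml_h, rep(1 / 50, 10))
  # quadratic cumulative: midpoint rates are exact (finite-difference identity)
  tt2 <- c(0, 1, 2.5, 4, 7, 10)
  cum2 <- data.frame(time_h = tt2, species = "N2", cumulative_umol = tt2^2)
  r2 <- interval_rates(cum2, liquid_volume = 50)
  expect_equal(r2$rate_umol_h, 2 * r2$time_h, tolerance = 1e-12)
  expect_error(interval_rates(
    data.frame(time_h = c(5, 0), species = "N2",
               cumulative_umol = c(0, 1)), liquid_volume = 50),
    "zero-length")
})

test_that("the N2 leak baseline subtracts linearly and clamps at zero", {
  v <- vial_config()
  tt <- seq(0, 100, by = 10)
  gs <- gas_series("v", tt, cbind(N2 = 5 + 0.1 * tt))
  expect_identical(leak_baseline_correct(gs, 0), gs)
  corr <- leak_baseline_correct(gs, 0.1)
  expect_equal(corr$amounts[, "N2"], rep(5, length(tt)))
  expect_equal(unname(gs$amounts[length(tt), "N2"] -
                        corr$amounts[length(tt), "N2"]), 10)
  expect_warning(leak_baseline_correct(gs, 1), "clamped")
})

test_that("leak correction recovers leak-free truth on simulated output", {
  scn <- enrichment_scenario(noise_sd = 0, t_end = 60,
                             vial = vial_config(sampling_fraction = 0))
  sim <- simulate_enrichment(scn)
  gs <- sim$observed_clean
  leaky <- gs
  leaky$amounts[, "N2"] <- leaky$amounts[, "N2"] + 0.05 * leaky$times
  fixed <- leak_baseline_correct(leaky, 0.05)
  expect_equal(fixed$amounts[, "N2"], gs$amounts[, "N2"], tolerance = 1e-9)
  cum <- reconstruct_cumulative(fixed, scn$vial)
  truth_n2 <- sim$truth$cumulative[, "N2"]
  got <- cum$cumulative_umol[cum$species == "N2"]
  expect_lt(rel_max(got, truth_n2), 1e-6)
})

test_that("events outside the measured time range are rejected", {
  v <- vial_config()
  gs <- gas_series("v", c(0, 3), cbind(N2 = c(1, 2)))
  gs$events <- data.frame(time_h = 10, kind = "injection", species = "N2",
                          volume_ml = 1)
  expect_error(reconstruct_cumulative(gs, v), "outside")
})
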