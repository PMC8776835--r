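# Mechanistic simulator: determinism, conservation, limiting cases.

test_that("scenario construction enforces yield consistency and bounds", {
  expect_error(enrichment_scenario(yield = 1), "yield")
  expect_error(enrichment_scenario(mu_max = -0.1), "non-negative|>= 0")
  expect_error(enrichment_scenario(dt = 0.5), "0.1")
  scn <- enrichment_scenario()
  expect_equal(scn$yield * scn$v_e_max, scn$mu_max)
})

test_that("same seed gives bit-identical observations, different seed not", {
  scn <- enrichment_scenario(t_end = 30, noise_sd = 0.05, seed = 7)
  s1 <- simulate_enrichment(scn)
  s2 <- simulate_enrichment(scn)
  expect_identical(s1$observed$amounts, s2$observed$amounts)
  s3 <- observe(s1, noise_sd = 0.05, seed = 8)
  expect_false(identical(s1$observed$amounts, s3$amounts))
  # the noise model is multiplicative: clean zero stays zero
  expect_equal(s3$amounts[s1$observed_clean$amounts == 0],
               rep(0, sum(s1$observed_clean$amounts == 0)))
})

test_that("noise-free, dilution-free observations equal equilibrated truth", {
  v <- vial_config("nodil", sampling_fraction = 0)
  scn <- enrichment_scenario(vial = v, noise_sd = 0, t_end = 30)
  sim <- simulate_enrichment(scn)
  tab <- default_species_table()
  # headspace share of the true totals, reconstructed from cumulative truth
  init <- sim$truth$initial
  totals <- sweep(sim$truth$cumulative, 2, init[colnames(sim$truth$cumulative)], "+")
  K <- tab[colnames(totals), "henry"]
  hs <- sweep(totals, 2, 70 / (70 + K * 50), "*")
  expect_equal(sim$observed_clean$amounts, hs, tolerance = 1e-9)
})

test_that("without NRB and N2O there is no N2, and CH4 is suppressed by N2O", {
  scn <- enrichment_scenario(n0 = 0, w0 = 0, noise_sd = 0, t_end = 60)
  sim <- simulate_enrichment(scn)
  expect_equal(max(sim$truth$cumulative[, "N2"]), 0)
  # N2O stays ~5 mM throughout, methane production is nearly shut down
  ch4_rate <- diff(sim$truth$cumulative[, "CH4"]) /
    diff(sim$truth$times) / scn$vial$liquid_volume
  expect_lt(max(ch4_rate), 0.05 * 0.2)
})

test_that("the no-N2O control sustains methane production near 0.2 umol/mL/h", {
  sim <- control_enrichment_sim()
  cum <- reconstruct_cumulative(sim$observed_clean, sim$scenario$vial)
  rts <- interval_rates(cum)
  ch4 <- rts$rate_umol_ml_h[rts$species == "CH4"]
  expect_true(all(abs(ch4 - 0.2) / 0.2 < 0.02))
})

test_that("sampling decay of an inert vial matches the geometric closed form", {
  v <- vial_config("decay", sampling_fraction = 0.05)
  scn <- enrichment_scenario(vial = v, n0 = 0, w0 = 0, n2o_injection_ml = 0,
                             noise_sd = 0, t_end = 30)
  sim <- simulate_enrichment(scn)
  k <- seq_along(sim$truth$times) - 1
  c0 <- sim$observed_clean$amounts[1, "N2O"]
  expected <- c0 * (1 - 0.05 * 70 / (70 + 0.63 * 50))^k
  expect_equal(sim$observed_clean$amounts[, "N2O"], expected,
               tolerance = 1e-9)
})

test_that("electron bookkeeping balances substrate against products", {
  sim <- default_enrichment_sim()
  tr <- sim$truth
  lhs <- tr$e_consumed
  rhs <- 8 * tr$cumulative[, "CH4"] + 2 * tr$cumulative[, "N2"]
  expect_lt(rel_max(lhs, rhs), 1e-9)
  # CO2 follows the same stoichiometry: 1 C per CH4 + 1 C per 4 e- respired
  co2 <- tr$cumulative[, "CH4"] + 2 * tr$cumulative[, "N2"] / 4
  expect_lt(rel_max(tr$cumulative[, "CO2"], co2), 1e-9)
})

test_that("methane inhibition is reversible once N2O is depleted", {
  scn <- enrichment_scenario(n0 = 0, w0 = 0.2, n2o_init_ml = 2,
                             n2o_injection_ml = 0, noise_sd = 0, t_end = 60)
  sim <- simulate_enrichment(scn)
  tr <- sim$truth
  ki <- scn$k_i_n2o
  low <- tr$n2o_liq_mM < 0.1 * ki
  # uninhibited Monod rate at the prevailing substrate level
  uninhib <- scn$v_max_ch4 * tr$substrate / (scn$k_s_ch4 + tr$substrate)
  rate <- c(NA, diff(tr$cumulative[, "CH4"]) / diff(tr$times) /
              scn$vial$liquid_volume)
  idx <- which(low & c(FALSE, low[-length(low)]))  # interval fully below
  expect_gt(length(idx), 3)
  for (i in idx)
    expect_gte(rate[i], 0.9 * min(uninhib[i - 1], uninhib[i]) * 0.999)
})

test_that("halving the RK4 step leaves cumulative outputs unchanged to 1e-6", {
  s1 <- default_enrichment_sim()
  s2 <- simulate_enrichment(enrichment_scenario(noise_sd = 0,
                                                dt = 0.0025))
  expect_lt(rel_max(s1$truth$cumulative, s2$truth$cumulative), 1e-6)
  expect_lt(rel_max(s1$truth$n_cells_ml, s2$truth$n_cells_ml,
                    floor = 1e3), 1e-6)
  q1 <- soil_sim(1)
  q2 <- simulate_soil(soil_scenario(noise_sd = 0, dt = 0.01))
  expect_lt(rel_max(q1$truth$cumulative, q2$truth$cumulative), 1e-6)
})

test_that("unsustainable N2O consumption is rejected with a diagnostic", {
  expect_error(
    simulate_enrichment(enrichment_scenario(
      w0 = 10, n2o_init_ml = 2, n2o_injection_ml = 0, noise_sd = 0,
      t_end = 30, dt = 0.1)),
    "instability")
})

test_that("soil nitrogen mass balance closes at every sampling", {
  sim <- soil_sim(1)
  tr <- sim$truth
  n_in_vial <- rowSums(tr$pools[, c("no3", "no2", "no_n", "n2o_n", "n2_n")])
  n_removed <- tr$removed[, "NO"] + 2 * tr$removed[, "N2O"] +
    2 * tr$removed[, "N2"]
  expect_lt(max(abs(n_in_vial + n_removed - tr$no3_initial)) /
              tr$no3_initial, 1e-9)
  # electrons accepted match the per-step stoichiometry 4/2/1/1/1
  e <- 4 * tr$o2_consumed + 2 * tr$reductions[, "c1"] +
    tr$reductions[, "c2"] + tr$reductions[, "c3"] + tr$reductions[, "c4"]
  expect_lt(rel_max(tr$e_accepted, e), 1e-9)
})

test_that("soil limiting cases: no Nos means pure N2O, strong Nos almost none", {
  g0 <- soil_sim(0)
  expect_equal(max(g0$truth$cumulative[, "N2"]), 0)
  cum <- reconstruct_cumulative(g0$observed_clean, g0$scenario$vial)
  rec <- nitrogen_recovery(cum[cum$species != "O2", ], 50)
  t100 <- recovery_time(rec, 1)
  g <- g0$observed_clean
  expect_equal(n2o_index(g$times, g$amounts[, "N2O"], g$amounts[, "N2"],
                         t100), 100)
  gbig <- simulate_soil(soil_scenario(nos_capacity = 100, noise_sd = 0))
  gg <- gbig$observed_clean
  cum2 <- reconstruct_cumulative(gg, gbig$scenario$vial)
  rec2 <- nitrogen_recovery(cum2[cum2$species != "O2", ], 50)
  i100 <- n2o_index(gg$times, gg$amounts[, "N2O"], gg$amounts[, "N2"],
                    recovery_time(rec2, 1))
  expect_lt(i100, 1)
})

test_that("denitrification waits for oxygen depletion", {
  sim <- soil_sim(1)
  tr <- sim$truth
  early <- tr$times <= 4   # O2 still high
  expect_lt(max(tr$reductions[early, "c1"]), 0.01 * tr$no3_initial)
  expect_gt(tr$pools[1, "no3"] - tail(tr$pools[, "no3"], 1),
            0.99 * tr$no3_initial)
})
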