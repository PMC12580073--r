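small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_units = 2, n_plots = 6,
             treatments = c("Control", "Fire"), ...)
}

test_that("stand generation is reproducible and seed-sensitive", {
  cfg <- small_cfg(seed = 7)
  set.seed(unit_seed_for_test(cfg, 1))
  a <- generate_stand(cfg, "u01")
  set.seed(unit_seed_for_test(cfg, 1))
  b <- generate_stand(cfg, "u01")
  expect_identical(a, b)

  set.seed(unit_seed_for_test(sim_config(seed = 8), 1))
  c <- generate_stand(sim_config(seed = 8), "u01")
  expect_false(identical(a$trees$dbh, c$trees$dbh))
})

test_that("generated stands carry the six-species mix and plausible BA", {
  cfg <- sim_config(seed = 3)
  set.seed(unit_seed_for_test(cfg, 1))
  st <- generate_stand(cfg, "u01")
  expect_true(all(st$trees$species %in%
                    c("ABCO", "CADE", "PSME", "PIPO", "PILA", "QUKE")))
  ba <- vapply(split(st$trees, st$trees$plot_id),
               function(d) sum(pi / 4 * (d$dbh[d$status == "live"] / 100)^2) /
                 0.04, 1)
  expect_gt(mean(ba), 30)
  expect_lt(mean(ba), 90)
})

test_that("a frozen stand does not change except its year", {
  cfg <- small_cfg(
    growth_dbh_mean = 0, growth_dbh_sd = 0, background_mortality = 0,
    snag_fall_rate = 0, litterfall_cm = 0, litter_to_duff = 0,
    duff_decay = 0, fwd_input = c(fwd_1h = 0, fwd_10h = 0, fwd_100h = 0),
    fwd_decay = 0, cwd_decay = 0, soil_c_drift = 0)
  set.seed(1)
  st <- generate_stand(cfg, "u01")
  st2 <- advance(st, 3, cfg)
  expect_equal(st2$year, st$year + 3)
  st2$year <- st$year
  expect_equal(st2, st)
})

test_that("survivor counts are binomially consistent with the mortality
           rate and live carbon never shrinks without mortality", {
  cfg <- small_cfg(background_mortality = 0.05, snag_fall_rate = 0)
  set.seed(2)
  st <- generate_stand(cfg, "u01")
  n0 <- sum(st$trees$status == "live")
  st1 <- advance(st, 1, cfg)
  n1 <- sum(st1$trees$status == "live")
  # one-year survivors within 5 sd of Binomial(n0, 0.95)
  expect_lt(abs(n1 - n0 * 0.95), 5 * sqrt(n0 * 0.05 * 0.95) + 1)

  cfg0 <- small_cfg(background_mortality = 0)
  set.seed(3)
  st <- generate_stand(cfg0, "u01")
  c0 <- latent_live_carbon(st)
  st1 <- advance(st, 5, cfg0)
  expect_gte(latent_live_carbon(st1), c0)
})

test_that("thinning hits the residual basal-area band and spares plots
           already below it", {
  cfg <- sim_config(seed = 5)
  set.seed(11)
  st <- generate_stand(cfg, "u01", "Mech")
  res <- apply_thin(st, cfg)
  ba <- vapply(split(res$stand$trees, res$stand$trees$plot_id),
               function(d) sum(pi / 4 * (d$dbh[d$status == "live"] / 100)^2) /
                 0.04, 1)
  expect_true(all(ba <= 34 + 1e-9))
  expect_gt(nrow(res$harvested), 0)

  # a sparse stand is untouched
  sparse <- st
  keep <- unlist(lapply(split(seq_len(nrow(st$trees)), st$trees$plot_id),
                        head, 3))
  sparse$trees <- st$trees[keep, ]
  res2 <- apply_thin(sparse, cfg)
  expect_equal(nrow(res2$harvested), 0)
  expect_equal(res2$stand$trees, sparse$trees)
})

test_that("thinning from below cannot lower the large-tree carbon share", {
  cfg <- sim_config(seed = 6, crown_thin_share = 0)
  set.seed(12)
  st <- generate_stand(cfg, "u01", "Mech")
  before <- resistant_fractions(
    st$trees |> dplyr::mutate(sample_frame = "main_plot"),
    large_dbh = 40)$pct_large
  res <- apply_thin(st, cfg)
  after <- resistant_fractions(
    res$stand$trees |> dplyr::mutate(sample_frame = "main_plot"),
    large_dbh = 40)$pct_large
  expect_gte(after, before)
})

test_that("mastication conserves carbon and spares large stems", {
  cfg <- sim_config(seed = 4)
  set.seed(21)
  st <- generate_stand(cfg, "u01", "Mech")
  live0 <- latent_live_carbon(st)
  fuel0 <- latent_fuel_carbon(st)
  st2 <- apply_mastication(st, cfg)
  live1 <- latent_live_carbon(st2)
  fuel1 <- latent_fuel_carbon(st2)
  expect_equal(fuel1 - fuel0, live0 - live1, tolerance = 1e-9)
  expect_gt(live0, live1)
  # stems at or above the ceiling are untouched
  big0 <- sum(st$trees$dbh >= 25 & st$trees$status == "live")
  big1 <- sum(st2$trees$dbh >= 25 & st2$trees$status == "live")
  expect_equal(big0, big1)

  # with no eligible stems the tree list is unchanged
  big_only <- st
  big_only$trees <- st$trees[st$trees$dbh >= 25, ]
  st3 <- apply_mastication(big_only, cfg)
  expect_equal(st3$trees, big_only$trees)
})

test_that("prescribed fire emits exactly what it consumes", {
  # no understory burn, no mortality: emission is the deterministic
  # surface-fuel dot product
  cfg <- sim_config(seed = 9, rx_consumption = c(
    litter = 0.85, duff = 0.8, fwd_1h = 0.9, fwd_10h = 0.8, fwd_100h = 0.6,
    cwd = 0.25, understory = 0), rx_mortality_d50 = -500)
  set.seed(31)
  st <- generate_stand(cfg, "u01", "Fire")
  fuel0 <- latent_fuel_carbon(st)
  res <- apply_rx_fire(st, cfg)
  fuel1 <- latent_fuel_carbon(res$stand)
  expect_lt(res$emission, 0)
  expect_equal(-res$emission, fuel0 - fuel1, tolerance = 1e-9)

  # zero consumption and mortality is a no-op with zero emission
  cfg0 <- sim_config(seed = 9, rx_consumption = c(
    litter = 0, duff = 0, fwd_1h = 0, fwd_10h = 0, fwd_100h = 0, cwd = 0,
    understory = 0), rx_mortality_d50 = -500)
  res0 <- apply_rx_fire(st, cfg0)
  expect_equal(res0$emission, 0)
  expect_equal(res0$stand$fuels, st$fuels)
  expect_equal(res0$stand$trees, st$trees)
})

test_that("fire survival probability rises with dbh", {
  cfg <- sim_config(seed = 2)
  p <- plogis(-cfg$rx_mortality_slope *
                (c(5, 15, 30, 60) - cfg$rx_mortality_d50))
  expect_true(all(diff(p) < 0))
})

test_that("2016 small-tree bins assign midpoints by default and in-bin
           uniform draws when requested", {
  cfg <- sim_config(seed = 17)
  set.seed(1)
  st <- generate_stand(cfg, "u01")
  st$year <- 2016L
  set.seed(2)
  snap <- firecarbon:::measure_stand(st, cfg, 2016L)
  sub <- snap$trees[snap$trees$sample_frame == "subplot", ]
  expect_gt(nrow(sub), 0)
  expect_true(all(sub$dbh < 11.4))
  mids <- pmin(1 + 2.54 * (0:4) + 1.27, 11.3)
  expect_true(all(vapply(sub$dbh, function(d) any(abs(d - mids) < 1e-9),
                         logical(1))))

  cfgu <- sim_config(seed = 17, bin_assignment = "uniform")
  set.seed(2)
  snapu <- firecarbon:::measure_stand(st, cfgu, 2016L)
  subu <- snapu$trees[snapu$trees$sample_frame == "subplot", ]
  expect_true(all(subu$dbh >= 1 & subu$dbh < 11.4))
  expect_false(all(vapply(subu$dbh, function(d) any(abs(d - mids) < 1e-9),
                          logical(1))))
})

test_that("experiment generation is reproducible and calendars are right", {
  cfg <- small_cfg(seed = 42)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$inventory$trees, e2$inventory$trees)
  expect_identical(e1$entries, e2$entries)

  ev <- e1$inventory$events
  expect_equal(nrow(ev[ev$unit_id == "u01", ]), 0)          # Control
  fire_ev <- ev[ev$unit_id == "u02" & ev$kind == "rx_fire", ]
  expect_equal(sort(fire_ev$year), c(2002L, 2009L, 2017L))  # three entries
  expect_equal(sort(unique(e1$inventory$plots$year)),
               c(2001L, 2003L, 2009L, 2010L, 2016L, 2017L, 2020L))

  # adding a unit never perturbs the existing ones
  cfg3 <- sim_config(seed = 42, n_units = 3, n_plots = 6,
                     treatments = c("Control", "Fire", "Mech"))
  e3 <- generate_experiment(cfg3)
  expect_identical(
    e3$inventory$trees[e3$inventory$trees$plot_id %in%
                         e1$inventory$trees$plot_id, ],
    e1$inventory$trees)
})

test_that("treatment calendars match the study design", {
  expect_equal(nrow(treatment_events("Control")), 0)
  expect_equal(treatment_events("Fire")$year, c(2002L, 2009L, 2017L))
  m <- treatment_events("Mech")
  expect_setequal(m$year[m$kind == "thin"], c(2001L, 2019L))
  mf <- treatment_events("MechFire")
  expect_setequal(mf$year[mf$kind == "rx_fire"], c(2002L, 2018L))
  expect_true("salvage" %in% mf$kind)
  expect_error(treatment_events("Burn"), "unknown treatment")
})

test_that("treatment orderings are concordant across seeds", {
  # scaled-down experiments (4 units x 3 plots); the orderings mirror the
  # full design: controls out-accumulate the heaviest treatment, and fire
  # NEP exceeds mechanical NEP
  res <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_units = 4, n_plots = 3,
                      treatments = c("Control", "Fire", "Mech", "MechFire"))
    sm <- run_experiment_analysis(cfg)$summary
    v <- function(tr, col) sm[[col]][sm$treatment == tr]
    c(v("Control", "necb") > v("MechFire", "necb"),
      v("Fire", "nep") > v("Mech", "nep"))
  }, logical(2))
  expect_gte(mean(res[1, ]), 0.8)
  expect_gte(mean(res[2, ]), 0.8)
})

test_that("the pipeline runs end-to-end on a small experiment with the
           ledger identity holding exactly", {
  cfg <- sim_config(seed = 13, n_units = 4, n_plots = 5,
                    treatments = c("Control", "Fire", "Mech", "MechFire"))
  out <- run_experiment_analysis(cfg)
  led <- out$ledger
  expect_equal(led$nep, led$necb - led$fire_emission - led$wood_removals,
               tolerance = 0)
  expect_true(all(led$fire_emission <= 0))
  expect_true(all(led$wood_removals <= 0))
  expect_equal(nrow(out$summary), 4)
  expect_named(out$costs, c("Fire", "Mech", "MechFire"), ignore.order = TRUE)
  for (cost in out$costs) {
    expect_equal(nrow(cost), 19)  # 2002..2020
    expect_equal(glance(cost)$undiscounted_cost, sum(cost$delta))
  }
  expect_s3_class(plot_pools(out$pools), "ggplot")
})
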