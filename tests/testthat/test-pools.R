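test_that("tree biomass matches a hand evaluation of the power law", {
  tab <- default_allometry()
  # independent arithmetic: W = a * (d^2 h)^b / 1000, foliage via ratio
  a <- 0.052; b <- 0.948; fr <- 0.070  # shipped PIPO coefficients
  wood <- a * (50^2 * 30)^b / 1000
  expect_equal(tree_wood_biomass("PIPO", 50, 30, tab), wood)
  expect_equal(tree_biomass("PIPO", 50, 30, tab), wood * (1 + fr))
})

test_that("tree biomass is strictly monotone in dbh and height and -> 0", {
  tab <- default_allometry()
  for (sp in c("ABCO", "QUKE", "OTHER")) {
    expect_gt(tree_biomass(sp, 50, 30, tab), tree_biomass(sp, 40, 30, tab))
    expect_gt(tree_biomass(sp, 40, 32, tab), tree_biomass(sp, 40, 30, tab))
    expect_lt(tree_biomass(sp, 1e-6, 1e-6, tab), 1e-6)
  }
})

test_that("carbon conversions use the pool-specific ratios", {
  expect_equal(tree_carbon(100), 48)
  expect_equal(tree_carbon(0), 0)
  expect_equal(tree_carbon(1), 0.48)
  # snag factor: 0.88 x 0.51 applied to wood biomass, and less than live 0.48
  wood <- tree_wood_biomass("ABCO", 40, 25)
  expect_equal(snag_carbon("ABCO", 40, 25), wood * 0.88 * 0.51)
  expect_equal(100 * 0.88 * 0.51, 44.88)
  expect_lt(0.88 * 0.51, 0.48)
})

test_that("shrub carbon follows cover midpoint, crown packing and 0.49", {
  tab <- default_allometry()
  rec <- tibble::tibble(species = "CEIN", cover_class = "lt5",
                        growth_form = "shrub")
  # independent arithmetic: 2.5% of a hectare, 0.9 m2 crowns, 1.8 kg each
  expected <- (0.025 * 1e4 / 0.9) * 1.8 / 1000 * 0.49
  expect_equal(shrub_carbon(rec, tab), expected)
  expect_equal(shrub_carbon(rec[0, ], tab), 0)
  # doubling per-individual biomass doubles the pool
  tab2 <- tab
  tab2$shrub$indiv_biomass_kg <- 2 * tab$shrub$indiv_biomass_kg
  expect_equal(shrub_carbon(rec, tab2), 2 * expected)
})

test_that("herb carbon is additive and linear in cover", {
  tab <- default_allometry()
  k <- tab$herb_coefficient
  one <- tibble::tibble(species = "H1", cover_class = "5to25",
                        growth_form = "herb")
  two <- tibble::tibble(species = c("H1", "H2"),
                        cover_class = c("lt5", "5to25"),
                        growth_form = "herb")
  expect_equal(herb_carbon(one, tab), 0.15 * k)
  expect_equal(herb_carbon(two, tab), 0.175 * k)
  expect_equal(herb_carbon(one[0, ], tab), 0)
})

test_that("composite fuel coefficients are basal-area weighted means", {
  tab <- default_allometry()
  one <- tibble::tibble(species = "PIPO", dbh = 40, height = 25,
                        status = "live", sample_frame = "main_plot")
  comp1 <- composite_fuel_coefficients(one, tab)
  expect_equal(comp1$qmd_10h, tab$fuel$qmd_10h[tab$fuel$species == "PIPO"])

  # equal basal area -> arithmetic mean
  two <- tibble::tibble(species = c("PIPO", "ABCO"), dbh = 40, height = 25,
                        status = "live", sample_frame = "main_plot")
  comp2 <- composite_fuel_coefficients(two, tab)
  f <- tab$fuel
  expect_equal(comp2$sg_1h,
               mean(f$sg_1h[f$species %in% c("PIPO", "ABCO")]))

  # 3-species mix equals the brute-force weighted sum
  mix <- tibble::tibble(species = c("PIPO", "ABCO", "CADE"),
                        dbh = c(50, 30, 20), height = 25, status = "live",
                        sample_frame = "main_plot")
  ba <- pi / 4 * (mix$dbh / 100)^2
  w <- ba / sum(ba)
  comp3 <- composite_fuel_coefficients(mix, tab)
  for (cl in c("qmd_1h", "qmd_100h", "sg_1000h", "sec_10h")) {
    manual <- sum(w * vapply(mix$species,
                             function(s) f[[cl]][f$species == s], 1))
    expect_equal(comp3[[cl]], manual, info = cl)
  }
})

test_that("planar-intercept loads match independent brute-force arithmetic", {
  tab <- default_allometry()
  comp <- composite_fuel_coefficients(
    tibble::tibble(species = "PSME", dbh = 35, height = 24, status = "live",
                   sample_frame = "main_plot"), tab)
  # fixed 10-h case, hand formula
  manual <- pi^2 / 8 * 12 * comp$qmd_10h * comp$sec_10h * comp$sg_10h / 2
  expect_equal(fwd_load(12, comp, "10h"), manual)
  expect_equal(fwd_load(0, comp, "1h"), 0)
  expect_equal(fwd_load(24, comp, "10h"), 2 * manual)

  # cwd: d^2 scaling and additivity
  expect_equal(cwd_load(20, comp), 4 * cwd_load(10, comp))
  d <- c(9.1, 12.4, 30.2)
  expect_equal(cwd_load(d, comp), sum(vapply(d, cwd_load, 1, comp = comp)))
  expect_equal(cwd_load(numeric(0), comp), 0)

  # 1,000 seeded random transects against an independently coded evaluator
  set.seed(421)
  for (i in seq_len(1000)) {
    n <- rpois(1, 8)
    cls <- sample(c("1h", "10h", "100h"), 1)
    L <- c(`1h` = 2, `10h` = 2, `100h` = 3)[[cls]]
    brute <- 1.2337005501 * n * comp[[paste0("qmd_", cls)]] *
      comp[[paste0("sec_", cls)]] * comp[[paste0("sg_", cls)]] / L
    expect_equal(fwd_load(n, comp, cls), brute, tolerance = 1e-9)
    dd <- 7.62 + rexp(rpois(1, 3), 1 / 6)
    brute_c <- 1.2337005501 * sum(dd^2) * comp$sec_1000h * comp$sg_1000h /
      11.3
    expect_equal(cwd_load(dd, comp), brute_c, tolerance = 1e-9)
  }
})

test_that("litter, duff and soil conversions are exact closed forms", {
  comp <- composite_fuel_coefficients(mini_trees("p1", 2001L))
  tx <- mini_transects("p1", 2001L, counts = c(0L, 0L, 0L), litter = 2,
                       duff = 0)
  cc <- carbon_constants()
  got <- plot_fuel_carbon(tx, tibble::tibble(plot_id = character(),
                                             year = integer(),
                                             transect = integer(),
                                             diameter = double()),
                          comp, cc)
  # 2 cm everywhere at 5 Mg/ha/cm -> 10 Mg/ha biomass -> x0.463
  expect_equal(got$litter, 10 * 0.463)
  expect_equal(got$duff, 0)

  expect_equal(soil_carbon(tibble::tibble(bulk_density = 1, carbon_pct = 1,
                                          depth_top = 0, depth_bottom = 15)),
               15)
  expect_equal(soil_carbon(tibble::tibble(bulk_density = c(1, 0.5),
                                          carbon_pct = c(2, 4),
                                          depth_top = 0, depth_bottom = 15)),
               mean(c(30, 30)))
  expect_equal(soil_carbon(tibble::tibble(bulk_density = 1,
                                          carbon_pct = numeric(0),
                                          depth_top = numeric(0),
                                          depth_bottom = numeric(0))[0, ]), 0)
})

test_that("plot pools total conserves and responds locally", {
  inv <- mini_inventory()
  pools <- estimate_pools(inv)
  expect_equal(pools$total,
               rowSums(as.matrix(pools[, c("live_tree", "snag", "understory",
                                           "fwd_1h", "fwd_10h", "fwd_100h",
                                           "cwd", "litter", "duff",
                                           "soil_0_15")])),
               tolerance = 1e-12)
  expect_true(all(as.matrix(pools[, c("live_tree", "snag", "understory",
                                      "fwd_1h", "fwd_10h", "fwd_100h", "cwd",
                                      "litter", "duff", "soil_0_15")]) >= 0))

  # adding a snag changes exactly the snag pool
  inv2 <- mini_inventory()
  snag <- mini_trees("p1", 2001L)[1, ] |>
    dplyr::mutate(tag = "s1", status = "snag")
  inv2$trees <- dplyr::bind_rows(inv2$trees, snag)
  p1 <- pools[pools$plot_id == "p1" & pools$year == 2001, ]
  p2 <- estimate_pools(inv2)
  p2 <- p2[p2$plot_id == "p1" & p2$year == 2001, ]
  expect_gt(p2$snag, p1$snag)
  expect_equal(p2$live_tree, p1$live_tree)
  expect_equal(p2$litter, p1$litter)
})

test_that("pool estimators are homogeneous degree 1 in record counts", {
  inv <- mini_inventory()
  doubled <- mini_inventory()
  doubled$trees <- dplyr::bind_rows(
    doubled$trees,
    doubled$trees |> dplyr::mutate(tag = paste0(tag, "b")))
  p1 <- estimate_pools(inv)
  p2 <- estimate_pools(doubled)
  expect_equal(p2$live_tree, 2 * p1$live_tree, tolerance = 1e-12)
})

test_that("an empty plot yields all-zero pools", {
  inv <- suppressWarnings(as_inventory(mini_plots("p9", 2001L)))
  pools <- estimate_pools(inv)
  expect_equal(pools$total, 0)
  expect_equal(pools$live_tree, 0)
})
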