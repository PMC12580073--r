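test_that("the NEP ledger identity reproduces the published cells", {
  pub <- published_summary()
  got <- nep(pub$necb, pub$fire_emission, pub$wood_removals)
  expect_equal(got, c(110.2, 106.7, 39.7, 38.8))
  expect_equal(round(annualize(got, 19), 1), c(5.8, 5.6, 2.1, 2.0))
})

test_that("nep is the exact identity and warns on sign slips", {
  expect_equal(nep(0, 0, 0), 0)
  expect_equal(nep(19.6, -87.1, 0), 106.7)
  expect_equal(nep(-2.1, 0, -41.8), 39.7)
  expect_warning(nep(10, 5, 0), "negative ledger entries")
})

test_that("necb is sign-symmetric and reads pool tibbles", {
  expect_equal(necb(100, 100), 0)
  expect_equal(necb(100, 210.2), -necb(210.2, 100))
  a <- tibble::tibble(total = 140.3)
  b <- tibble::tibble(total = 250.5)
  expect_equal(necb(a, b), 110.2)
})

test_that("flux_ledger assembles the identity exactly for synthetic units", {
  set.seed(11)
  n <- 25
  led <- flux_ledger(sprintf("u%02d", 1:n),
                     necb = rnorm(n, 20, 50),
                     fire_emission = -rexp(n, 1 / 40),
                     wood_removals = -rexp(n, 1 / 20))
  expect_equal(led$nep, led$necb - led$fire_emission - led$wood_removals,
               tolerance = 0)
  expect_equal(led$annual_nep, led$nep / 19)
})

test_that("fire emission entries are dot products over combustible pools", {
  expect_equal(fire_emission_entry(c(litter = 10), c(litter = 1)), -10)
  expect_equal(fire_emission_entry(c(litter = 10, duff = 5),
                                   c(litter = 0, duff = 0)), 0)
  pools <- c(litter = 8.2, duff = 14.1, fwd_1h = 0.3, fwd_10h = 1.1,
             fwd_100h = 2.2, cwd = 9.7, understory = 0.8)
  frac <- c(litter = 0.85, duff = 0.7, fwd_1h = 0.9, fwd_10h = 0.75,
            fwd_100h = 0.5, cwd = 0.2, understory = 0.6)
  expect_equal(fire_emission_entry(pools, frac), -sum(pools * frac))
  expect_error(fire_emission_entry(c(litter = 1), c(duff = 0.5)),
               "not in pools")
  expect_error(fire_emission_entry(c(litter = 1), c(litter = 1.2)))
})

test_that("annual interpolation spreads evenly and telescopes exactly", {
  # +60 MgC/ha over 2003-2009 -> 10/yr for 6 years
  flux <- interpolate_annual_flux(tibble::tibble(year = c(2003, 2009),
                                                 total = c(100, 160)))
  expect_equal(flux$year, 2004:2009)
  expect_equal(flux$flux, rep(10, 6))

  flat <- interpolate_annual_flux(tibble::tibble(year = c(2001, 2005),
                                                 total = c(50, 50)))
  expect_equal(flat$flux, rep(0, 4))

  set.seed(33)
  series <- tibble::tibble(year = c(2001, 2003, 2009, 2016, 2020),
                           total = cumsum(rnorm(5, 10, 20)) + 100)
  f <- interpolate_annual_flux(series)
  expect_equal(sum(f$flux), series$total[5] - series$total[1],
               tolerance = 1e-12)
})

test_that("wood product chain obeys the mill-efficiency invariants", {
  harvested <- tibble::tibble(
    species = c("PIPO", "ABCO", "PSME", "QUKE", "CADE"),
    dbh = c(55, 35, 24, 40, 12),
    height = c(32, 25, 18, 20, 10),
    sample_frame = "main_plot"
  )
  acc <- wood_product_chain(harvested)
  expect_gt(acc$sawlog_carbon, 0)
  expect_equal(acc$llp, acc$sawlog_carbon * 0.676 * 0.95)
  expect_equal(acc$kerf_emission, acc$sawlog_carbon * 0.224)
  expect_equal(acc$llp + acc$kerf_emission + acc$residue_other,
               acc$sawlog_carbon, tolerance = 1e-12)
  expect_gt(acc$fuelwood_emission, 0)  # the 40-cm oak
  expect_gt(acc$residue_field, 0)      # the 12-cm and 24-cm stems + tops

  # worked constants: 10 MgC/ha of sawlog carbon
  expect_equal(10 * 0.676 * 0.95, 6.422)
  expect_equal(10 * 0.224, 2.24)

  # nothing merchantable -> all-zero account except field residue
  small <- tibble::tibble(species = "ABCO", dbh = 15, height = 12,
                          sample_frame = "main_plot")
  acc0 <- wood_product_chain(small)
  expect_equal(acc0$sawlog_carbon, 0)
  expect_equal(acc0$llp, 0)
  expect_equal(wood_product_chain(small[0, ])$residue_field, 0)
})

test_that("sawlog and fuelwood thresholds gate eligibility", {
  at <- function(sp, dbh) wood_product_chain(
    tibble::tibble(species = sp, dbh = dbh, height = 20,
                   sample_frame = "main_plot"))
  expect_equal(at("PIPO", 22.9)$sawlog_carbon, 0)
  expect_gt(at("PIPO", 23.0)$sawlog_carbon, 0)
  expect_equal(at("QUKE", 27.9)$fuelwood_emission, 0)
  expect_gt(at("QUKE", 28.0)$fuelwood_emission, 0)
  expect_equal(at("QUKE", 40)$sawlog_carbon, 0)  # hardwoods never sawlogs
})

test_that("discounting follows the start-year-equivalent closed forms", {
  ctl <- tibble::tibble(year = 2002:2005, flux = c(1, 0, 0, 0))
  trt <- tibble::tibble(year = 2002:2005, flux = 0)
  cost <- carbon_cost(ctl, trt, rate = 0.04, base_year = 2001)
  g <- glance(cost)
  expect_equal(g$discounted_cost, 1 / 1.04, tolerance = 1e-12)
  expect_equal(g$undiscounted_cost, 1)

  # r = 0 makes discounted and undiscounted equal
  set.seed(5)
  ctl2 <- tibble::tibble(year = 2002:2020, flux = rnorm(19))
  trt2 <- tibble::tibble(year = 2002:2020, flux = rnorm(19))
  g0 <- glance(carbon_cost(ctl2, trt2, rate = 0))
  expect_equal(g0$discounted_cost, g0$undiscounted_cost)

  # identical fluxes -> zero cost
  gz <- glance(carbon_cost(ctl2, ctl2))
  expect_equal(gz$discounted_cost, 0)
  expect_equal(gz$undiscounted_cost, 0)
})

test_that("carbon cost is antisymmetric without LLP and strictly reduced by
           discounting when all deltas are positive", {
  set.seed(9)
  a <- tibble::tibble(year = 2002:2010, flux = rnorm(9, 2))
  b <- tibble::tibble(year = 2002:2010, flux = rnorm(9, 1))
  ab <- glance(carbon_cost(a, b))
  ba <- glance(carbon_cost(b, a))
  expect_equal(ab$discounted_cost, -ba$discounted_cost)
  expect_equal(ab$undiscounted_cost, -ba$undiscounted_cost)

  pos <- tibble::tibble(year = 2002:2010, flux = rep(3, 9))
  zero <- tibble::tibble(year = 2002:2010, flux = 0)
  g <- glance(carbon_cost(pos, zero, rate = 0.04))
  expect_lt(g$discounted_cost, g$undiscounted_cost)
})

test_that("LLP credits lower the cost in the year of harvest", {
  ctl <- tibble::tibble(year = 2002:2004, flux = c(2, 2, 2))
  trt <- tibble::tibble(year = 2002:2004, flux = c(0, 0, 0))
  llp <- tibble::tibble(year = 2002L, llp = 5)
  with_llp <- carbon_cost(ctl, trt, llp_by_year = llp)
  without <- carbon_cost(ctl, trt)
  expect_equal(with_llp$delta[1], without$delta[1] - 5)
  expect_equal(with_llp$delta[-1], without$delta[-1])
  expect_error(carbon_cost(ctl, trt,
                           llp_by_year = tibble::tibble(year = 1999L,
                                                        llp = 1)),
               "outside")
  expect_error(carbon_cost(ctl, trt[1:2, ]), "different years")
})

test_that("tidy/glance/autoplot methods behave", {
  cost <- carbon_cost(tibble::tibble(year = 2002:2003, flux = 1:2),
                      tibble::tibble(year = 2002:2003, flux = 0))
  td <- tidy(cost)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_s3_class(autoplot(cost), "ggplot")
})
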