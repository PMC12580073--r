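#' Configuration for the synthetic BACI experiment
#'
#' Defines the study conditions the generator emulates: 12 experimental
#' units of 20 permanent 0.04-ha plots, three replicates of four
#' treatments (Control, Fire, Mech, Mech+Fire), inventories in
#' 2001/2003/2009/2010/2016/2017/2020, a six-species mixed-conifer
#' composition, thinning to a 28-34 m2/ha residual basal area, mastication
#' of 90% of stems up to 25 cm dbh, and prescribed-fire consumption and
#' size-dependent mortality. One root seed drives everything; each unit
#' draws from its own deterministic substream so adding a unit never
#' perturbs the others.
#'
#' @param seed Integer root seed.
#' @param ... Named overrides for any default listed below.
#' @return A named list (class `sim_config`).
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_units = 12,
    n_plots = 20,
    treatments = rep(c("Control", "Fire", "Mech", "MechFire"), times = 3),
    inventory_years = c(2001L, 2003L, 2009L, 2010L, 2016L, 2017L, 2020L),
    comprehensive_years = c(2001L, 2003L, 2009L, 2016L, 2020L),
    update_years = c(2010L, 2017L),
    species_mix = c(ABCO = 0.30, CADE = 0.20, PSME = 0.15, PIPO = 0.15,
                    PILA = 0.10, QUKE = 0.10),
    # stand structure at establishment (per-ha basis)
    overstory_density = 420,         # stems/ha with dbh >= 11.4 cm
    dbh_weibull = c(shape = 1.4, scale = 24),  # + 11.4 cm offset
    sapling_density = 1200,          # stems/ha, 1.0-11.4 cm
    snag_density = 35,               # snags/ha
    height_curve = c(hmax = 33, k = 0.042, p = 1.1),
    # annual dynamics
    growth_dbh_mean = 0.42, growth_dbh_sd = 0.12,   # cm/yr
    growth_ba_ref = 40, growth_ba_exp = 0.5,        # competition release
    background_mortality = 0.008,    # /yr, live -> snag
    snag_fall_rate = 0.06,           # /yr; 70% of fallen carbon to CWD
    snag_fall_to_cwd = 0.7,
    litterfall_cm = 0.35,            # cm litter depth gain /yr
    litter_to_duff = 0.08,           # /yr depth transfer
    duff_decay = 0.035,              # /yr
    fwd_input = c(fwd_1h = 0.05, fwd_10h = 0.09, fwd_100h = 0.10), # Mg/ha/yr
    fwd_decay = 0.05, cwd_decay = 0.03,  # /yr
    soil_c_drift = 0.02,             # %C per yr
    # initial fuel/soil state
    init_litter_cm = c(3.0, 0.5), init_duff_cm = c(5.5, 1.0),
    init_fwd = c(fwd_1h = 0.4, fwd_10h = 1.6, fwd_100h = 3.0),  # Mg/ha
    init_cwd = c(22, 6),
    init_soil_bd = c(0.78, 0.06), init_soil_pct = c(5.1, 0.5),
    # treatments
    thin_target_ba = 31,             # m2/ha, within the 28-34 prescription
    crown_thin_share = 0.1,
    mastication_dbh_max = 25, mastication_fraction = 0.9,
    rx_consumption = c(litter = 0.85, duff = 0.80, fwd_1h = 0.90,
                       fwd_10h = 0.80, fwd_100h = 0.60, cwd = 0.25,
                       understory = 0.70),
    rx_mortality_d50 = 18, rx_mortality_slope = 0.13,
    foliage_burn_frac = 0.6,
    salvage_fraction = 0.7,
    # measurement model
    depth_cv = 0.12, soil_samples = 2,
    bin_assignment = "midpoint",     # 2016 small-tree bins: or "uniform"
    drought_pulse = FALSE,           # optional 2012-2015 mortality pulse
    drought_mortality = 0.02
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown sim_config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$thin_target_ba >= 28, cfg$thin_target_ba <= 34,
            all(cfg$rx_consumption >= 0), all(cfg$rx_consumption <= 1),
            cfg$mastication_fraction >= 0, cfg$mastication_fraction <= 1)
  structure(cfg, class = "sim_config")
}

unit_seed <- function(cfg, i) {
  (cfg$seed %% 100000L) * 20011L + i * 7919L
}

sim_height <- function(dbh, cfg) {
  hc <- cfg$height_curve
  1.37 + hc[["hmax"]] * (1 - exp(-hc[["k"]] * dbh))^hc[["p"]]
}

draw_species <- function(n, cfg) {
  sample(names(cfg$species_mix), n, replace = TRUE, prob = cfg$species_mix)
}

#' Generate the year-2001 state of one experimental unit
#'
#' Draws the latent stand: every stem >= 1 cm on each full 0.04-ha plot
#' (the measurement protocol later subsamples small trees onto subplots),
#' standing snags, understory cover records, continuous surface-fuel
#' state (litter/duff depth, timelag-class loads) and soil properties.
#' Reproducible under a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param unit_id Unit identifier, e.g. `"u01"`.
#' @param treatment Treatment label.
#' @return A `sim_stand` list: `unit_id`, `treatment`, `year`, `trees`,
#'   `understory`, `fuels`, `soil`.
#' @export
generate_stand <- function(cfg, unit_id, treatment = "Control") {
  plots <- sprintf("%s_p%02d", unit_id, seq_len(cfg$n_plots))
  area <- plot_geometry()$plot_area_ha
  trees <- purrr::map_dfr(plots, function(pid) {
    n_over <- rpois(1, cfg$overstory_density * area)
    n_sap <- rpois(1, cfg$sapling_density * area)
    n_snag <- rpois(1, cfg$snag_density * area)
    dbh_over <- 11.4 + rweibull(n_over, cfg$dbh_weibull[["shape"]],
                                cfg$dbh_weibull[["scale"]])
    dbh_sap <- runif(n_sap, 1, 11.3)
    dbh_snag <- 11.4 + rweibull(n_snag, cfg$dbh_weibull[["shape"]],
                                cfg$dbh_weibull[["scale"]] * 0.8)
    dbh <- c(dbh_over, dbh_sap, dbh_snag)
    n <- length(dbh)
    tibble::tibble(
      plot_id = pid,
      tag = sprintf("%s_t%04d", pid, seq_len(n)),
      species = draw_species(n, cfg),
      dbh = dbh,
      height = pmax(1.4, sim_height(dbh, cfg) * exp(rnorm(n, 0, 0.06))),
      status = rep(c("live", "snag"), c(n_over + n_sap, n_snag)),
      decay_class = NA_integer_
    )
  })
  qs <- quantile(trees$dbh[trees$status == "live"], c(0.5, 0.75, 0.9),
                 names = FALSE)
  trees$crown_class <- ifelse(
    trees$dbh >= qs[3], "dominant",
    ifelse(trees$dbh >= qs[2], "codominant",
           ifelse(trees$dbh >= qs[1], "intermediate", "suppressed")))

  understory <- purrr::map_dfr(plots, function(pid) {
    tibble::tibble(
      plot_id = pid,
      species = c(sample(c("CEIN", "ARVI", "CHFO"), 2), "HERB1", "HERB2"),
      cover_class = sample(c("lt5", "5to25", "25to100"), 4, replace = TRUE,
                           prob = c(0.55, 0.35, 0.10)),
      mean_height = c(runif(2, 0.3, 1.5), NA, NA),
      growth_form = c("shrub", "shrub", "herb", "herb")
    )
  })

  fuels <- tibble::tibble(
    plot_id = plots,
    litter_depth = pmax(0.2, rnorm(cfg$n_plots, cfg$init_litter_cm[1],
                                   cfg$init_litter_cm[2])),
    duff_depth = pmax(0.2, rnorm(cfg$n_plots, cfg$init_duff_cm[1],
                                 cfg$init_duff_cm[2])),
    fwd_1h = pmax(0.02, rnorm(cfg$n_plots, cfg$init_fwd[["fwd_1h"]], 0.1)),
    fwd_10h = pmax(0.05, rnorm(cfg$n_plots, cfg$init_fwd[["fwd_10h"]], 0.4)),
    fwd_100h = pmax(0.1, rnorm(cfg$n_plots, cfg$init_fwd[["fwd_100h"]], 0.8)),
    cwd = pmax(0, rnorm(cfg$n_plots, cfg$init_cwd[1], cfg$init_cwd[2]))
  )
  soil <- tibble::tibble(
    plot_id = plots,
    bulk_density = pmax(0.4, rnorm(cfg$n_plots, cfg$init_soil_bd[1],
                                   cfg$init_soil_bd[2])),
    carbon_pct = pmax(0.5, rnorm(cfg$n_plots, cfg$init_soil_pct[1],
                                 cfg$init_soil_pct[2]))
  )
  structure(list(unit_id = unit_id, treatment = treatment, year = 2001L,
                 trees = trees, understory = understory, fuels = fuels,
                 soil = soil),
            class = "sim_stand")
}

# per-ha live-tree basal area of one plot's tree rows (full-plot basis)
plot_ba <- function(trees) {
  live <- trees[trees$status == "live", , drop = FALSE]
  sum(pi / 4 * (live$dbh / 100)^2) / plot_geometry()$plot_area_ha
}

# whole-tree carbon (MgC/ha, full-plot basis) of tree rows
rows_carbon <- function(trees, table, constants) {
  if (!nrow(trees)) return(0)
  sum(tree_carbon(tree_biomass(trees$species, trees$dbh, trees$height,
                               table), constants)) /
    plot_geometry()$plot_area_ha
}

#' Advance a simulated stand through time
#'
#' Year by year: live stems grow in dbh (non-negative increments) with
#' heights following the height curve; background mortality converts live
#' stems to snags; snags fall, routing part of their carbon to the CWD
#' pool; litterfall deepens the litter layer, litter transfers to duff,
#' duff and woody fuels decay while fine classes receive branch-shed
#' inputs; soil carbon content drifts slowly. With growth, mortality,
#' litterfall and decay all zeroed the stand is unchanged except the year.
#'
#' @param stand A `sim_stand`.
#' @param years Number of years to advance.
#' @param cfg A [sim_config()].
#' @return The advanced `sim_stand`.
#' @export
advance <- function(stand, years, cfg) {
  for (i in seq_len(years)) {
    tr <- stand$trees
    live <- tr$status == "live"
    # diameter growth responds to stand density: release after thinning,
    # suppression in crowded stands (multiplier on the base increment)
    ba_plot <- vapply(split(tr[live, c("dbh", "status")], tr$plot_id[live]),
                      plot_ba, numeric(1))
    mult <- setNames(
      pmin(1.6, pmax(0.7, (cfg$growth_ba_ref /
                             pmax(ba_plot, 1))^cfg$growth_ba_exp)),
      names(ba_plot))
    inc <- pmax(0, rnorm(sum(live), cfg$growth_dbh_mean, cfg$growth_dbh_sd)) *
      mult[tr$plot_id[live]]
    h_inc <- sim_height(tr$dbh[live] + inc, cfg) - sim_height(tr$dbh[live], cfg)
    tr$dbh[live] <- tr$dbh[live] + inc
    tr$height[live] <- tr$height[live] + h_inc
    yr <- stand$year + i
    mort <- cfg$background_mortality +
      if (isTRUE(cfg$drought_pulse) && yr >= 2012 && yr <= 2015)
        cfg$drought_mortality else 0
    died <- live & (rbinom(nrow(tr), 1, mort) == 1)
    tr$status[died] <- "snag"

    fell <- tr$status == "snag" & !died &
      (rbinom(nrow(tr), 1, cfg$snag_fall_rate) == 1)
    if (any(fell)) {
      fall_c <- tibble::tibble(
        plot_id = tr$plot_id[fell],
        c = tree_carbon(tree_biomass(tr$species[fell], tr$dbh[fell],
                                     tr$height[fell]), carbon_constants())
      ) |>
        dplyr::summarise(c = sum(.data$c), .by = "plot_id")
      idx <- match(stand$fuels$plot_id, fall_c$plot_id)
      add <- ifelse(is.na(idx), 0, fall_c$c[idx]) /
        plot_geometry()$plot_area_ha
      # carbon-equivalent biomass addition to the CWD load
      stand$fuels$cwd <- stand$fuels$cwd +
        cfg$snag_fall_to_cwd * add / carbon_constants()$c_wd
      tr <- tr[!fell, , drop = FALSE]
    }
    stand$trees <- tr

    f <- stand$fuels
    transfer <- cfg$litter_to_duff * f$litter_depth
    f$litter_depth <- f$litter_depth + cfg$litterfall_cm - transfer
    cc <- carbon_constants()
    f$duff_depth <- f$duff_depth * (1 - cfg$duff_decay) +
      transfer * cc$litter_depth_to_biomass / cc$duff_depth_to_biomass
    for (cl in names(cfg$fwd_input)) {
      f[[cl]] <- f[[cl]] * (1 - cfg$fwd_decay) + cfg$fwd_input[[cl]]
    }
    f$cwd <- f$cwd * (1 - cfg$cwd_decay)
    stand$fuels <- f
    stand$soil$carbon_pct <- stand$soil$carbon_pct + cfg$soil_c_drift
  }
  stand$year <- stand$year + years
  stand
}

#' Thin a simulated stand to the residual basal-area target
#'
#' Two-stage prescription applied plot by plot: a configurable share of
#' the basal area to be removed comes from mid-canopy stems (crown thin,
#' skipping the largest decile so large trees are retained), the rest
#' from below (smallest stems first) until the plot's live basal area is
#' at or below the target. Plots already at or below the target are
#' untouched.
#'
#' @param stand A `sim_stand`.
#' @param cfg A [sim_config()]; `thin_target_ba` and `crown_thin_share`
#'   control the prescription.
#' @return List: `stand` (thinned), `harvested` (removed tree rows with
#'   `sample_frame = "main_plot"`, ready for [wood_product_chain()]).
#' @export
apply_thin <- function(stand, cfg) {
  removed <- list()
  area <- plot_geometry()$plot_area_ha
  target_plot_ba <- cfg$thin_target_ba * area  # m2 per plot
  for (pid in unique(stand$trees$plot_id)) {
    sel <- stand$trees$plot_id == pid & stand$trees$status == "live"
    tr <- stand$trees[sel, , drop = FALSE]
    ba_i <- pi / 4 * (tr$dbh / 100)^2
    excess <- sum(ba_i) - target_plot_ba
    if (excess <= 0) next
    take <- rep(FALSE, nrow(tr))
    # crown thin: mid-canopy stems, largest decile protected
    big <- tr$dbh >= quantile(tr$dbh, 0.9, names = FALSE)
    ord_mid <- order(-tr$dbh)
    crown_budget <- cfg$crown_thin_share * excess
    for (j in ord_mid) {
      if (crown_budget <= 0) break
      if (big[j] || take[j]) next
      take[j] <- TRUE
      crown_budget <- crown_budget - ba_i[j]
    }
    # thin from below
    ord_low <- order(tr$dbh)
    for (j in ord_low) {
      if (sum(ba_i[!take]) <= target_plot_ba) break
      take[j] <- TRUE
    }
    removed[[pid]] <- tr[take, , drop = FALSE]
    keep_tags <- tr$tag[!take]
    stand$trees <- stand$trees[!(stand$trees$plot_id == pid &
                                   stand$trees$status == "live" &
                                   !(stand$trees$tag %in% keep_tags)), ,
                               drop = FALSE]
  }
  harvested <- dplyr::bind_rows(removed)
  if (nrow(harvested)) harvested$sample_frame <- "main_plot"
  list(stand = stand, harvested = harvested)
}

#' Masticate understory stems of a simulated stand
#'
#' Removes the configured fraction (default 90%) of live stems below the
#' dbh ceiling (default 25 cm) and shreds them in place: their carbon is
#' added to the downed-fuel loads (30% to 10-h, 40% to 100-h, 30% to CWD,
#' as carbon-equivalent biomass), so live-tree carbon lost equals fuel
#' carbon gained exactly. Shrub cover is knocked back one class.
#'
#' @param stand A `sim_stand`.
#' @param cfg A [sim_config()].
#' @return The treated `sim_stand`.
#' @export
apply_mastication <- function(stand, cfg) {
  cc <- carbon_constants()
  eligible <- stand$trees$status == "live" &
    stand$trees$dbh < cfg$mastication_dbh_max
  take <- eligible & (runif(nrow(stand$trees)) < cfg$mastication_fraction)
  if (any(take)) {
    gone <- stand$trees[take, , drop = FALSE]
    per_plot <- tibble::tibble(
      plot_id = gone$plot_id,
      c = tree_carbon(tree_biomass(gone$species, gone$dbh, gone$height), cc)
    ) |>
      dplyr::summarise(c = sum(.data$c), .by = "plot_id")
    idx <- match(stand$fuels$plot_id, per_plot$plot_id)
    add_c <- ifelse(is.na(idx), 0, per_plot$c[idx]) /
      plot_geometry()$plot_area_ha
    add_b <- add_c / cc$c_wd
    stand$fuels$fwd_10h <- stand$fuels$fwd_10h + 0.3 * add_b
    stand$fuels$fwd_100h <- stand$fuels$fwd_100h + 0.4 * add_b
    stand$fuels$cwd <- stand$fuels$cwd + 0.3 * add_b
    stand$trees <- stand$trees[!take, , drop = FALSE]
  }
  down <- c(lt5 = "lt5", `5to25` = "lt5", `25to100` = "5to25")
  shrubs <- stand$understory$growth_form == "shrub"
  stand$understory$cover_class[shrubs] <-
    unname(down[stand$understory$cover_class[shrubs]])
  stand
}

#' Burn a simulated stand with a prescribed fire
#'
#' Consumes the configured fractions of litter, duff, fine and coarse
#' woody debris and understory (each consumed understory record is
#' dropped), kills live stems with logistic size-dependent mortality
#' (survival increases with dbh; killed stems become snags) and emits the
#' consumed surface carbon plus the burned share of killed-tree foliage.
#' With zero consumption and mortality the stand is unchanged.
#'
#' @param stand A `sim_stand`.
#' @param cfg A [sim_config()].
#' @return List: `stand`, `emission` (MgC/ha, <= 0, mean over plots).
#' @export
apply_rx_fire <- function(stand, cfg) {
  cc <- carbon_constants()
  con <- cfg$rx_consumption
  f <- stand$fuels
  n <- nrow(f)
  consumed_c <-
    con[["litter"]] * f$litter_depth * cc$litter_depth_to_biomass *
      cc$c_litter +
    con[["duff"]] * f$duff_depth * cc$duff_depth_to_biomass * cc$c_duff +
    con[["fwd_1h"]] * f$fwd_1h * cc$c_wd +
    con[["fwd_10h"]] * f$fwd_10h * cc$c_wd +
    con[["fwd_100h"]] * f$fwd_100h * cc$c_wd +
    con[["cwd"]] * f$cwd * cc$c_wd
  f$litter_depth <- f$litter_depth * (1 - con[["litter"]])
  f$duff_depth <- f$duff_depth * (1 - con[["duff"]])
  f$fwd_1h <- f$fwd_1h * (1 - con[["fwd_1h"]])
  f$fwd_10h <- f$fwd_10h * (1 - con[["fwd_10h"]])
  f$fwd_100h <- f$fwd_100h * (1 - con[["fwd_100h"]])
  f$cwd <- f$cwd * (1 - con[["cwd"]])
  stand$fuels <- f

  # understory consumption: each record burns with the configured probability
  us <- stand$understory
  burn_us <- runif(nrow(us)) < con[["understory"]]
  us_c_burned <- 0
  if (any(burn_us)) {
    us_c_burned <- sum(purrr::map_dbl(unique(us$plot_id[burn_us]), function(p) {
      rec <- us[burn_us & us$plot_id == p, , drop = FALSE]
      shrub_carbon(rec) + herb_carbon(rec)
    }))
    stand$understory <- us[!burn_us, , drop = FALSE]
  }

  tr <- stand$trees
  live <- tr$status == "live"
  p_kill <- plogis(-cfg$rx_mortality_slope *
                     (tr$dbh - cfg$rx_mortality_d50))
  killed <- live & (runif(nrow(tr)) < p_kill)
  foliage_c <- 0
  if (any(killed)) {
    tab <- default_allometry()
    wood <- tree_wood_biomass(tr$species[killed], tr$dbh[killed],
                              tr$height[killed], tab)
    fol <- wood * species_coef(tr$species[killed], tab$foliage_ratio, "ratio")
    foliage_c <- sum(tree_carbon(fol, cc)) / plot_geometry()$plot_area_ha *
      cfg$foliage_burn_frac
    tr$status[killed] <- "snag"
    stand$trees <- tr
  }

  emission <- -(mean(consumed_c) + (us_c_burned + foliage_c) / n)
  list(stand = stand, emission = emission)
}

salvage_snags <- function(stand, cfg) {
  snag <- stand$trees$status == "snag"
  take <- snag & (runif(nrow(stand$trees)) < cfg$salvage_fraction)
  removal <- 0
  if (any(take)) {
    s <- stand$trees[take, , drop = FALSE]
    cc <- carbon_constants()
    removal <- -sum(snag_carbon(s$species, s$dbh, s$height)) /
      plot_geometry()$plot_area_ha / length(unique(stand$fuels$plot_id))
    stand$trees <- stand$trees[!take, , drop = FALSE]
  }
  list(stand = stand, removal = removal)
}
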