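# Small in-code fixtures shared across test files.

mini_plots <- function(plot_ids = c("p1", "p2"), years = c(2001L, 2020L),
                       unit_id = "u01", treatment = "Control") {
  tidyr::expand_grid(plot_id = plot_ids, year = years) |>
    dplyr::mutate(unit_id = unit_id, treatment = treatment)
}

mini_trees <- function(plot_id = "p1", year = 2001L) {
  tibble::tibble(
    plot_id = plot_id, year = year,
    tag = c("t1", "t2", "t3", "t4"),
    species = c("PIPO", "ABCO", "QUKE", "PILA"),
    dbh = c(52, 30, 28, 8),
    height = c(31, 22, 15, 6),
    status = c("live", "live", "live", "live"),
    crown_class = c("dominant", "codominant", "intermediate", "suppressed"),
    decay_class = NA_integer_,
    sample_frame = c("main_plot", "main_plot", "main_plot", "subplot")
  )
}

mini_transects <- function(plot_id = "p1", year = 2001L,
                           counts = c(6L, 4L, 2L), litter = 2, duff = 3) {
  tibble::tibble(
    plot_id = plot_id, year = year, transect = 1:2, azimuth = c(10, 200),
    counts_1h = counts[1], counts_10h = counts[2], counts_100h = counts[3],
    litter_depth_1 = litter, litter_depth_2 = litter,
    duff_depth_1 = duff, duff_depth_2 = duff
  )
}

mini_inventory <- function() {
  plots <- mini_plots()
  trees <- dplyr::bind_rows(
    mini_trees("p1", 2001L), mini_trees("p1", 2020L),
    mini_trees("p2", 2001L), mini_trees("p2", 2020L)
  )
  understory <- tibble::tibble(
    plot_id = "p1", year = 2001L, species = c("CEIN", "HERB1"),
    cover_class = c("5to25", "lt5"), mean_height = c(0.8, NA),
    growth_form = c("shrub", "herb")
  )
  transects <- dplyr::bind_rows(
    mini_transects("p1", 2001L), mini_transects("p1", 2020L),
    mini_transects("p2", 2001L), mini_transects("p2", 2020L)
  )
  cwd <- tibble::tibble(plot_id = "p1", year = 2001L, transect = 1L,
                        diameter = c(10, 14))
  soil <- tibble::tibble(plot_id = c("p1", "p2"), year = 2001L, sample = 1L,
                         bulk_density = 0.8, carbon_pct = 5,
                         depth_top = 0, depth_bottom = 15)
  suppressWarnings(
    as_inventory(plots, trees, understory, transects, cwd, soil)
  )
}

unit_seed_for_test <- function(cfg, i) firecarbon:::unit_seed(cfg, i)

# latent carbon of a simulated stand (trees at the accounting ratios plus
# the continuous fuel state), used for conservation checks on events
latent_fuel_carbon <- function(stand) {
  cc <- carbon_constants()
  f <- stand$fuels
  sum(f$litter_depth * cc$litter_depth_to_biomass * cc$c_litter +
        f$duff_depth * cc$duff_depth_to_biomass * cc$c_duff +
        (f$fwd_1h + f$fwd_10h + f$fwd_100h + f$cwd) * cc$c_wd) /
    nrow(f)
}

latent_live_carbon <- function(stand) {
  live <- stand$trees[stand$trees$status == "live", ]
  if (!nrow(live)) return(0)
  sum(tree_carbon(tree_biomass(live$species, live$dbh, live$height))) /
    plot_geometry()$plot_area_ha / length(unique(stand$fuels$plot_id))
}
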