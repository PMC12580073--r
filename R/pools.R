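#' Shrub carbon density from cover-class records
#'
#' Cover-class midpoints (2.5%, 15%, 63%) give the plot area covered by
#' each shrub species; dividing by the species' mean crown area yields the
#' estimated number of average-sized individuals; multiplying by the
#' per-individual allometric biomass, scaling to a hectare and applying
#' the shrub carbon fraction (0.49) gives MgC/ha. Linear in per-individual
#' biomass by construction.
#'
#' @param understory Understory records (`growth_form == "shrub"` rows are
#'   used): `species`, `cover_class`.
#' @param table Allometry tables ([default_allometry()]); species missing
#'   from the shrub table fall back to the `OTHER` row with a warning.
#' @param constants See [carbon_constants()].
#' @return Shrub carbon in MgC/ha.
#' @export
shrub_carbon <- function(understory, table = default_allometry(),
                         constants = carbon_constants()) {
  sh <- understory[understory$growth_form == "shrub", , drop = FALSE]
  if (!nrow(sh)) return(0)
  idx <- match(sh$species, table$shrub$species)
  if (anyNA(idx)) {
    warning("shrub species without allometry assigned genus-level default")
    idx[is.na(idx)] <- match("OTHER", table$shrub$species)
  }
  cover_frac <- cover_midpoint(sh$cover_class) / 100
  covered_m2_per_ha <- cover_frac * 1e4
  n_indiv <- covered_m2_per_ha / table$shrub$crown_area_m2[idx]
  biomass_mg_ha <- n_indiv * table$shrub$indiv_biomass_kg[idx] / 1000
  sum(biomass_mg_ha) * constants$c_shrub
}

#' Herb carbon density from cover
#'
#' Linear in summed cover midpoints: carbon = coefficient x total cover
#' fraction, with the coefficient expressed as MgC/ha at 100% cover.
#'
#' @inheritParams shrub_carbon
#' @return Herb carbon in MgC/ha.
#' @export
herb_carbon <- function(understory, table = default_allometry()) {
  hb <- understory[understory$growth_form == "herb", , drop = FALSE]
  if (!nrow(hb)) return(0)
  table$herb_coefficient * sum(cover_midpoint(hb$cover_class)) / 100
}

#' Basal-area-weighted composite fuel coefficients
#'
#' Downed-fuel coefficients for a plot are the weighted mean of the
#' species-specific coefficients, with weights from the relative basal
#' area of the live trees present. With no live trees, species are
#' weighted equally.
#'
#' @param trees Live tree records (`species`, `dbh`, `sample_frame`).
#' @param table Allometry tables.
#' @return One-row tibble of composite `qmd_*`, `sec_*`, `sg_*` values.
#' @export
composite_fuel_coefficients <- function(trees, table = default_allometry()) {
  fuel <- table$fuel[table$fuel$species != "OTHER", , drop = FALSE]
  live <- trees[trees$status == "live" & trees$dbh > 0, , drop = FALSE]
  if (nrow(live)) {
    expf <- expansion_factor(live$sample_frame)
    ba <- tapply(pi / 4 * (live$dbh / 100)^2 * expf,
                 factor(ifelse(live$species %in% fuel$species,
                               live$species, fuel$species[1])),
                 sum)
    w <- setNames(rep(0, nrow(fuel)), fuel$species)
    w[names(ba)] <- ba
    w <- w / sum(w)
  } else {
    w <- setNames(rep(1 / nrow(fuel), nrow(fuel)), fuel$species)
  }
  cols <- setdiff(names(fuel), "species")
  out <- lapply(cols, function(cl) sum(w[fuel$species] * fuel[[cl]]))
  tibble::as_tibble(setNames(out, cols))
}

# planar-intercept constant: load (Mg/ha) = (pi^2/8) * sum(d^2) * sec * sg / L
# with piece diameters in cm and sampled length L in m
.planar_G <- pi^2 / 8

#' Fine woody debris load on one transect
#'
#' Brown's line-intercept estimator for tallied timelag classes:
#' \deqn{w = G \, n \, \bar{d^2} \, s \, \rho / L}
#' with \eqn{G = \pi^2/8}, tally \eqn{n}, composite squared mean diameter
#' \eqn{\bar{d^2}} (cm2), secant of lean \eqn{s}, specific gravity
#' \eqn{\rho} (g/cm3), and sampled length \eqn{L} (m: 2 m for 1-h and
#' 10-h, 3 m for 100-h), giving Mg/ha. Linear in the tally.
#'
#' @param count Intersection tally (>= 0).
#' @param comp Composite coefficients from [composite_fuel_coefficients()].
#' @param cls One of `"1h"`, `"10h"`, `"100h"`.
#' @param geometry See [plot_geometry()].
#' @param slope_correction Multiplier for transect slope; 1 assumes
#'   horizontal transects.
#' @return Load in Mg/ha (biomass, not carbon).
#' @export
fwd_load <- function(count, comp, cls = c("1h", "10h", "100h"),
                     geometry = plot_geometry(), slope_correction = 1) {
  cls <- match.arg(cls)
  L <- switch(cls, "1h" = geometry$length_1h, "10h" = geometry$length_10h,
              "100h" = geometry$length_100h)
  if (L <= 0) stop("sampled length must be positive")
  stopifnot(all(count >= 0))
  .planar_G * count * comp[[paste0("qmd_", cls)]] *
    comp[[paste0("sec_", cls)]] * comp[[paste0("sg_", cls)]] *
    slope_correction / L
}

#' Coarse woody debris load on one transect
#'
#' Same planar-intercept form with the measured piece diameters entering
#' as \eqn{\sum d_i^2} over the full 11.3-m transect.
#'
#' @param diameters Piece diameters in cm (1000-h and larger, > 7.62 cm).
#' @inheritParams fwd_load
#' @return Load in Mg/ha (biomass).
#' @export
cwd_load <- function(diameters, comp, geometry = plot_geometry(),
                     slope_correction = 1) {
  L <- geometry$transect_length_m
  if (L <= 0) stop("sampled length must be positive")
  if (!length(diameters)) return(0)
  .planar_G * sum(diameters^2) * comp$sec_1000h * comp$sg_1000h *
    slope_correction / L
}

#' Surface and ground fuel carbon for one plot-year
#'
#' Transect-level loads are computed per timelag class, averaged over the
#' plot's transects, and converted to carbon (woody debris at 0.5). Litter
#' and duff biomass come from the mean of the transect depth points times
#' the depth-to-biomass coefficients, converted at 0.463 and 0.362.
#'
#' @param transects Transect rows for one plot-year.
#' @param cwd CWD piece rows for the same plot-year.
#' @param comp Composite coefficients for the plot.
#' @param constants See [carbon_constants()].
#' @param geometry See [plot_geometry()].
#' @return One-row tibble: `fwd_1h`, `fwd_10h`, `fwd_100h`, `cwd`,
#'   `litter`, `duff` in MgC/ha.
#' @export
plot_fuel_carbon <- function(transects, cwd, comp,
                             constants = carbon_constants(),
                             geometry = plot_geometry()) {
  zero <- tibble::tibble(fwd_1h = 0, fwd_10h = 0, fwd_100h = 0, cwd = 0,
                         litter = 0, duff = 0)
  if (!nrow(transects)) return(zero)
  per_tx <- purrr::pmap_dfr(
    list(transects$transect, transects$counts_1h, transects$counts_10h,
         transects$counts_100h),
    function(tx, n1, n10, n100) {
      d <- cwd$diameter[cwd$transect == tx]
      tibble::tibble(
        fwd_1h = fwd_load(n1, comp, "1h", geometry),
        fwd_10h = fwd_load(n10, comp, "10h", geometry),
        fwd_100h = fwd_load(n100, comp, "100h", geometry),
        cwd = cwd_load(d, comp, geometry)
      )
    }
  )
  woody <- dplyr::summarise(per_tx, dplyr::across(dplyr::everything(), mean))
  litter_depth <- mean(c(transects$litter_depth_1, transects$litter_depth_2))
  duff_depth <- mean(c(transects$duff_depth_1, transects$duff_depth_2))
  tibble::tibble(
    fwd_1h = woody$fwd_1h * constants$c_wd,
    fwd_10h = woody$fwd_10h * constants$c_wd,
    fwd_100h = woody$fwd_100h * constants$c_wd,
    cwd = woody$cwd * constants$c_wd,
    litter = litter_depth * constants$litter_depth_to_biomass *
      constants$c_litter,
    duff = duff_depth * constants$duff_depth_to_biomass * constants$c_duff
  )
}

#' Mineral soil carbon (0-15 cm) from core samples
#'
#' Per sample: bulk density (g/cm3, fine fraction) x layer thickness (cm)
#' x carbon fraction x 100 gives MgC/ha; the plot value is the mean over
#' samples.
#'
#' @param soil Soil sample rows: `bulk_density`, `carbon_pct`,
#'   `depth_top`, `depth_bottom`.
#' @return Soil carbon in MgC/ha (0 when no samples).
#' @export
#' @examples
#' soil_carbon(tibble::tibble(bulk_density = 1, carbon_pct = 1,
#'                            depth_top = 0, depth_bottom = 15))  # 15
soil_carbon <- function(soil) {
  if (!nrow(soil)) return(0)
  thick <- soil$depth_bottom - soil$depth_top
  mean(soil$bulk_density * thick * soil$carbon_pct / 100 * 100)
}

pool_names <- function() {
  c("live_tree", "snag", "understory", "fwd_1h", "fwd_10h", "fwd_100h",
    "cwd", "litter", "duff", "soil_0_15")
}

#' Estimate carbon pools for every plot-year in an inventory
#'
#' The workhorse estimator: converts each plot-year's records into MgC/ha
#' by pool — live tree (allometric biomass x 0.48, expanded by sampling
#' frame), snag (wood biomass x 0.88 x 0.51), understory (shrub + herb),
#' fine woody debris by timelag class and coarse woody debris
#' (planar-intercept loads with basal-area-composited coefficients x 0.5),
#' litter and duff (depth x coefficient x carbon fraction) and mineral
#' soil (0-15 cm) — plus their total.
#'
#' @param inv An `ffs_inventory`.
#' @param table Allometry tables ([default_allometry()]).
#' @param constants See [carbon_constants()].
#' @param geometry See [plot_geometry()].
#' @return Tibble with one row per plot x year: `plot_id`, `unit_id`,
#'   `treatment`, `year`, the ten pool columns and `total`.
#' @export
estimate_pools <- function(inv, table = default_allometry(),
                           constants = carbon_constants(),
                           geometry = plot_geometry()) {
  stopifnot(inherits(inv, "ffs_inventory"))
  plots <- inv$plots
  key <- function(d) paste(d$plot_id, d$year, sep = "\r")
  by_key <- function(d) split(as.data.frame(d), factor(key(d)))
  trees_s <- by_key(inv$trees); under_s <- by_key(inv$understory)
  tx_s <- by_key(inv$transects); cwd_s <- by_key(inv$cwd)
  soil_s <- by_key(inv$soil)
  empty <- empty_tables()
  pick <- function(lst, k, tmpl) lst[[k]] %||% tmpl

  rows <- purrr::pmap_dfr(
    plots[c("plot_id", "year")],
    function(plot_id, year) {
      k <- paste(plot_id, year, sep = "\r")
      tr <- pick(trees_s, k, empty$trees)
      us <- pick(under_s, k, empty$understory)
      tx <- pick(tx_s, k, empty$transects)
      cw <- pick(cwd_s, k, empty$cwd)
      so <- pick(soil_s, k, empty$soil)

      live <- tr[tr$status == "live", ]
      live_c <- if (nrow(live)) {
        sum(tree_carbon(tree_biomass(live$species, live$dbh, live$height,
                                     table), constants) *
              expansion_factor(live$sample_frame, geometry))
      } else 0
      sn <- tr[tr$status == "snag", ]
      snag_c <- if (nrow(sn)) {
        sum(snag_carbon(sn$species, sn$dbh, sn$height, table, constants) *
              expansion_factor(sn$sample_frame, geometry))
      } else 0
      und_c <- shrub_carbon(us, table, constants) + herb_carbon(us, table)
      comp <- composite_fuel_coefficients(tr, table)
      fuels <- plot_fuel_carbon(tx, cw, comp, constants, geometry)
      tibble::tibble(
        plot_id = plot_id, year = year,
        live_tree = live_c, snag = snag_c, understory = und_c,
        fwd_1h = fuels$fwd_1h, fwd_10h = fuels$fwd_10h,
        fwd_100h = fuels$fwd_100h, cwd = fuels$cwd,
        litter = fuels$litter, duff = fuels$duff,
        soil_0_15 = soil_carbon(so)
      )
    }
  )
  rows |>
    dplyr::mutate(total = rowSums(dplyr::pick(dplyr::all_of(pool_names())))) |>
    dplyr::left_join(
      dplyr::distinct(plots, .data$plot_id, .data$year, .data$unit_id,
                      .data$treatment),
      by = c("plot_id", "year")
    ) |>
    dplyr::relocate("unit_id", "treatment", .after = "plot_id")
}
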