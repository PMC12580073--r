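#' Carbon conversion constants
#'
#' Fixed biomass-to-carbon ratios and depth-to-biomass coefficients used
#' throughout pool estimation and the wood-product chain. The carbon
#' fractions are pool-specific: live tree tissue is converted at 0.48
#' (IPCC default for temperate conifers), snag biomass is first reduced by
#' a live-to-dead ratio of 0.88 (decay class 2, applied to all snags) and
#' then converted at 0.51, shrubs at 0.49, downed woody debris at 0.50,
#' litter at 0.463 and duff at 0.362. Litter and duff biomass are predicted
#' from depth with linear coefficients (Mg/ha per cm of depth); these two
#' coefficients are site-calibration defaults and are expected to be
#' replaced when a local depth-to-load regression is available.
#'
#' @param ... Named overrides for any constant, e.g.
#'   `carbon_constants(litter_depth_to_biomass = 6)`.
#'
#' @return A named list with elements `c_tree`, `snag_dead_ratio`, `c_snag`,
#'   `c_shrub`, `c_wd`, `c_litter`, `c_duff`, `litter_depth_to_biomass`,
#'   `duff_depth_to_biomass`, `llp_mill_fraction`, `llp_fossil_deduction`,
#'   `kerf_fraction`, `sawlog_min_dbh`, `sawlog_top_diameter`,
#'   `fuelwood_min_dbh`, `fuelwood_top_diameter`, `discount_rate`,
#'   `base_year`.
#' @export
#' @examples
#' cc <- carbon_constants()
#' cc$c_tree                      # 0.48
#' 100 * cc$snag_dead_ratio * cc$c_snag  # snag carbon from 100 Mg live-equivalent
carbon_constants <- function(...) {
  cc <- list(
    c_tree = 0.48,
    snag_dead_ratio = 0.88,
    c_snag = 0.51,
    c_shrub = 0.49,
    c_wd = 0.5,
    c_litter = 0.463,
    c_duff = 0.362,
    litter_depth_to_biomass = 5.0,  # Mg/ha per cm depth
    duff_depth_to_biomass = 8.0,    # Mg/ha per cm depth
    # harvested wood product chain (California mill efficiency)
    llp_mill_fraction = 0.676,      # share of sawlog volume milled into LLP
    llp_fossil_deduction = 0.05,    # fossil-fuel deduction on the LLP pool
    kerf_fraction = 0.224,          # kerf + trimmings, burned as feedstock
    sawlog_min_dbh = 22.9,          # cm, conifers (0.3-m stump, 15.2-cm top)
    sawlog_top_diameter = 15.2,
    fuelwood_min_dbh = 27.9,        # cm, hardwoods (0.3-m stump, 20.3-cm top)
    fuelwood_top_diameter = 20.3,
    # carbon-cost discounting, start-year equivalent
    discount_rate = 0.04,
    base_year = 2001
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cc))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    cc[names(dots)] <- dots
  }
  fracs <- c("c_tree", "snag_dead_ratio", "c_snag", "c_shrub", "c_wd",
             "c_litter", "c_duff", "llp_mill_fraction", "llp_fossil_deduction",
             "kerf_fraction")
  stopifnot(all(unlist(cc[fracs]) > 0), all(unlist(cc[fracs]) < 1),
            cc$litter_depth_to_biomass > 0, cc$duff_depth_to_biomass > 0)
  cc
}

#' Study geometry: plot and transect dimensions
#'
#' Sampling-frame geometry shared by the estimators and the synthetic
#' generator: 0.04-ha circular main plots, 0.004-ha subplots for small
#' trees, 11.3-m radial fuel transects with class-specific sampled lengths
#' (1-h and 10-h over 0-2 m, 100-h over 0-3 m, 1000-h over the full
#' transect), and the 11.4-cm main-plot dbh floor.
#'
#' @return Named list of geometry constants.
#' @export
plot_geometry <- function() {
  list(
    plot_area_ha = 0.04,
    subplot_area_ha = 0.004,
    main_plot_min_dbh = 11.4,   # cm
    transect_length_m = 11.3,
    length_1h = 2, length_10h = 2, length_100h = 3,
    cwd_min_diameter = 7.62,    # cm, 1000-h class floor
    large_tree_dbh = 76.2,      # cm, wildfire-resistant large-tree threshold
    stable_tree_dbh = 72.6      # cm, stable-carbon (large resistant pine)
  )
}

#' Timelag fuel class diameter limits
#' @return Tibble with class, lower and upper piece diameter (cm).
#' @export
fuel_classes <- function() {
  tibble::tibble(
    class = c("1h", "10h", "100h", "1000h"),
    d_lo = c(0, 0.64, 2.54, 7.62),
    d_hi = c(0.64, 2.54, 7.62, Inf)
  )
}

# six study species + catch-all
study_species <- function() c("ABCO", "CADE", "PSME", "PIPO", "PILA", "QUKE")

resistant_species <- function() c("PIPO", "PILA")
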