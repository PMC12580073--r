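#' Default allometry and fuel coefficient tables
#'
#' Pluggable coefficient tables for the six Sierra Nevada mixed-conifer
#' study species (white fir `ABCO`, incense-cedar `CADE`, Douglas-fir
#' `PSME`, ponderosa pine `PIPO`, sugar pine `PILA`, California black oak
#' `QUKE`) plus a catch-all `OTHER`.
#'
#' The shipped values are documented defaults, replaceable: wood biomass
#' follows a combined-variable power law
#' \deqn{W = a (d^2 h)^b}
#' with \eqn{W} in kg, dbh \eqn{d} in cm and height \eqn{h} in m, the form
#' regional equation systems take for these species; foliage is a fixed
#' ratio of wood biomass; downed-fuel coefficients (composite squared mean
#' diameters by timelag class, secant of particle lean, specific gravity)
#' are literature-plausible Sierra Nevada values. Any table with the same
#' columns can be supplied in their place, so locally fitted equations
#' drop in without code changes.
#'
#' @param species Optional character vector restricting the table.
#'
#' @return A list of tibbles: `wood` (a, b per species), `foliage_ratio`,
#'   `wood_density` (Mg/m3), `form_factor` and `merchantable_fraction`
#'   (stem-volume accounting for the wood-product chain), `fuel`
#'   (per-species `qmd_1h`, `qmd_10h`, `qmd_100h` squared mean diameters in
#'   cm2, `sec_1h`..`sec_1000h` secants of lean, `sg_1h`..`sg_1000h`
#'   specific gravities), `shrub` (mean crown area m2 and per-individual
#'   biomass kg), and `herb_coefficient` (MgC/ha at 100% cover).
#' @export
#' @examples
#' tab <- default_allometry()
#' tree_biomass("PIPO", dbh = 50, height = 30, table = tab)
default_allometry <- function(species = NULL) {
  sp <- c(study_species(), "OTHER")
  wood <- tibble::tibble(
    species = sp,
    a = c(0.049, 0.043, 0.058, 0.052, 0.046, 0.069, 0.050),
    b = c(0.955, 0.950, 0.952, 0.948, 0.951, 0.940, 0.950)
  )
  foliage_ratio <- tibble::tibble(
    species = sp,
    ratio = c(0.105, 0.090, 0.085, 0.070, 0.075, 0.040, 0.080)
  )
  wood_density <- tibble::tibble(
    species = sp,
    density = c(0.37, 0.35, 0.45, 0.38, 0.34, 0.55, 0.40)  # Mg/m3
  )
  fuel <- tibble::tibble(
    species = sp,
    qmd_1h   = c(0.12, 0.11, 0.13, 0.17, 0.16, 0.09, 0.13),
    qmd_10h  = c(1.95, 1.85, 2.10, 2.60, 2.50, 1.50, 2.10),
    qmd_100h = c(21.5, 20.5, 23.0, 26.0, 25.0, 18.0, 22.0),
    sec_1h   = c(1.03, 1.03, 1.03, 1.02, 1.02, 1.04, 1.03),
    sec_10h  = c(1.03, 1.03, 1.03, 1.02, 1.02, 1.04, 1.03),
    sec_100h = c(1.02, 1.02, 1.02, 1.02, 1.02, 1.03, 1.02),
    sec_1000h = c(1.01, 1.01, 1.01, 1.01, 1.01, 1.02, 1.01),
    sg_1h    = c(0.58, 0.55, 0.60, 0.53, 0.51, 0.65, 0.57),
    sg_10h   = c(0.54, 0.51, 0.57, 0.50, 0.48, 0.62, 0.53),
    sg_100h  = c(0.48, 0.46, 0.52, 0.45, 0.43, 0.58, 0.48),
    sg_1000h = c(0.40, 0.38, 0.44, 0.38, 0.36, 0.50, 0.40)
  )
  shrub <- tibble::tibble(
    species = c("CEIN", "ARVI", "CHFO", "OTHER"),
    crown_area_m2 = c(0.9, 1.2, 0.6, 0.9),
    indiv_biomass_kg = c(1.8, 2.6, 1.1, 1.8)
  )
  tab <- list(
    wood = wood, foliage_ratio = foliage_ratio, wood_density = wood_density,
    form_factor = 0.42, merchantable_fraction = 0.90,
    fuel = fuel, shrub = shrub,
    herb_coefficient = 0.5  # MgC/ha at 100% summed cover
  )
  if (!is.null(species)) {
    keep <- function(d) d[d$species %in% c(species, "OTHER"), , drop = FALSE]
    tab$wood <- keep(tab$wood); tab$foliage_ratio <- keep(tab$foliage_ratio)
    tab$wood_density <- keep(tab$wood_density); tab$fuel <- keep(tab$fuel)
  }
  tab
}

# look up a per-species coefficient column, falling back to OTHER
species_coef <- function(species, table, column) {
  idx <- match(species, table$species)
  other <- match("OTHER", table$species)
  idx[is.na(idx)] <- other
  if (anyNA(idx)) stop("species absent from table and no OTHER fallback")
  table[[column]][idx]
}

#' Aboveground wood biomass of a live tree
#'
#' Stem + bark + branch biomass from the power-law wood equation
#' \eqn{W = a (d^2 h)^b}, per tree in Mg. Strictly increasing in both dbh
#' and height.
#'
#' @param species Species code(s).
#' @param dbh Diameter at breast height, cm (> 0).
#' @param height Total height, m (> 0).
#' @param table Allometry tables, see [default_allometry()].
#' @return Wood biomass in Mg per tree (vectorised).
#' @export
tree_wood_biomass <- function(species, dbh, height, table = default_allometry()) {
  stopifnot(all(dbh > 0), all(height > 0))
  a <- species_coef(species, table$wood, "a")
  b <- species_coef(species, table$wood, "b")
  a * (dbh^2 * height)^b / 1000  # kg -> Mg
}

#' Total aboveground biomass of a live tree (wood + foliage)
#'
#' Foliage is added as a species-specific ratio of wood biomass.
#'
#' @inheritParams tree_wood_biomass
#' @return Total aboveground biomass in Mg per tree (vectorised).
#' @export
tree_biomass <- function(species, dbh, height, table = default_allometry()) {
  wood <- tree_wood_biomass(species, dbh, height, table)
  fr <- species_coef(species, table$foliage_ratio, "ratio")
  wood * (1 + fr)
}

#' Convert live-tree biomass to carbon
#'
#' Fixed carbon:biomass ratio of 0.48 for live tree tissue.
#'
#' @param biomass Biomass in Mg (>= 0).
#' @param constants See [carbon_constants()].
#' @return Carbon in MgC.
#' @export
#' @examples
#' tree_carbon(100)  # 48
tree_carbon <- function(biomass, constants = carbon_constants()) {
  stopifnot(all(biomass >= 0))
  constants$c_tree * biomass
}

#' Snag carbon from live-equivalent dimensions
#'
#' A snag's wood+bark biomass is estimated with the live-tree wood
#' equation, reduced by the live-to-dead ratio (0.88, decay class 2,
#' applied uniformly to all snags regardless of recorded decay class), and
#' converted to carbon at the dead-wood fraction 0.51.
#'
#' @inheritParams tree_wood_biomass
#' @param constants See [carbon_constants()].
#' @return Carbon in MgC per snag (vectorised).
#' @export
snag_carbon <- function(species, dbh, height, table = default_allometry(),
                        constants = carbon_constants()) {
  wood <- tree_wood_biomass(species, dbh, height, table)
  wood * constants$snag_dead_ratio * constants$c_snag
}
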