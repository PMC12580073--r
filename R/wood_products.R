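#' Track harvested carbon through the wood-product chain
#'
#' Splits the carbon in a harvested tree list into product fates. Conifer
#' stems above the sawlog threshold (dbh > 22.9 cm, 0.3-m stump to a
#' 15.2-cm top) yield sawlog volume via a form-factor stem-volume
#' equation; volume becomes biomass through species wood density and
#' carbon at 0.48. Of the sawlog carbon, 67.6% is milled into long-lived
#' products (LLP) with a further 5% fossil-fuel deduction for harvest and
#' transport, and 22.4% leaves as kerf and trimmings burned as energy
#' feedstock (an emission); the remainder is mill residue
#' (`residue_other`). Hardwood stems above the fuelwood threshold
#' (dbh > 27.9 cm, to a 20.3-cm top) are an immediate fuelwood emission.
#' Sub-merchantable stems and the non-sawlog portion of merchantable trees
#' (tops, limbs, foliage) stay in the forest as `residue_field`.
#'
#' @param harvested Tree records removed by a harvest: `species`, `dbh`,
#'   `height`, `sample_frame` (for per-ha expansion).
#' @param table Allometry tables; wood density must cover every species.
#' @param constants See [carbon_constants()].
#' @param geometry See [plot_geometry()].
#' @return One-row tibble (class `wood_product_account`): `sawlog_carbon`,
#'   `llp`, `kerf_emission`, `fuelwood_emission`, `residue_field`,
#'   `residue_other`, all MgC/ha. Invariants: `llp = sawlog_carbon x
#'   0.676 x 0.95`, `kerf_emission = sawlog_carbon x 0.224`, and
#'   `llp + kerf + unallocated = sawlog_carbon`.
#' @export
#' @examples
#' wood_product_chain(tibble::tibble(species = "PIPO", dbh = 50,
#'                                   height = 30, sample_frame = "main_plot"))
wood_product_chain <- function(harvested, table = default_allometry(),
                               constants = carbon_constants(),
                               geometry = plot_geometry()) {
  zero <- tibble::tibble(sawlog_carbon = 0, llp = 0, kerf_emission = 0,
                         fuelwood_emission = 0, residue_field = 0,
                         residue_other = 0)
  class(zero) <- c("wood_product_account", class(zero))
  if (is.null(harvested) || !nrow(harvested)) return(zero)

  dens <- species_coef(harvested$species, table$wood_density, "density")
  if (anyNA(dens)) stop("missing wood density for harvested species")
  expf <- expansion_factor(harvested$sample_frame, geometry)

  hardwood <- harvested$species == "QUKE"
  sawlog_ok <- !hardwood & harvested$dbh > constants$sawlog_min_dbh
  fuelwood_ok <- hardwood & harvested$dbh > constants$fuelwood_min_dbh

  # stem volume (m3) via form factor; merchantable share to the top diameter
  stem_vol <- table$form_factor * pi / 4 * (harvested$dbh / 100)^2 *
    harvested$height
  merch_vol <- stem_vol * table$merchantable_fraction
  stem_c <- merch_vol * dens * constants$c_tree * expf      # MgC/ha
  whole_c <- tree_carbon(
    tree_biomass(harvested$species, harvested$dbh, harvested$height, table),
    constants) * expf

  sawlog_c <- sum(stem_c[sawlog_ok])
  fuelwood_c <- sum(stem_c[fuelwood_ok])
  merch <- sawlog_ok | fuelwood_ok
  residue_field <- sum(whole_c[!merch]) +
    sum(pmax(whole_c[merch] - stem_c[merch], 0))

  llp <- sawlog_c * constants$llp_mill_fraction *
    (1 - constants$llp_fossil_deduction)
  kerf <- sawlog_c * constants$kerf_fraction
  residue_other <- sawlog_c - llp - kerf

  out <- tibble::tibble(
    sawlog_carbon = sawlog_c, llp = llp, kerf_emission = kerf,
    fuelwood_emission = fuelwood_c, residue_field = residue_field,
    residue_other = residue_other
  )
  class(out) <- c("wood_product_account", class(out))
  out
}
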