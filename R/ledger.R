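#' Net ecosystem carbon balance between two inventories
#'
#' Stock-change definition: the change in total measured carbon,
#' end minus start. Sign-symmetric: swapping the arguments negates it.
#'
#' @param total_start,total_end Total measured carbon (MgC/ha), either
#'   numeric vectors or pool tibbles with a `total` column.
#' @return NECB in MgC/ha.
#' @export
necb <- function(total_start, total_end) {
  g <- function(x) if (is.data.frame(x)) x$total else x
  g(total_end) - g(total_start)
}

#' Net ecosystem productivity from the ledger identity
#'
#' NEP = NECB - fire emissions - wood removals, with emissions and
#' removals carried as negative ledger entries (an 87.1 MgC/ha prescribed
#' fire emission enters as -87.1), so exported carbon is added back to the
#' balance. Positive entries trigger a warning since they almost always
#' indicate a sign-convention slip.
#'
#' @param necb NECB, MgC/ha.
#' @param fire_emission Prescribed-fire emissions, MgC/ha (<= 0).
#' @param wood_removals Harvest removals, MgC/ha (<= 0).
#' @return NEP in MgC/ha.
#' @export
#' @examples
#' nep(19.6, -87.1, 0)   # 106.7
#' nep(-2.1, 0, -41.8)   # 39.7
nep <- function(necb, fire_emission = 0, wood_removals = 0) {
  if (any(fire_emission > 0) || any(wood_removals > 0)) {
    warning("emissions/removals are expected as negative ledger entries")
  }
  necb - fire_emission - wood_removals
}

#' Annualise a total flux
#'
#' @param total_flux Total flux over the record, MgC/ha.
#' @param years Length of the record in years (19 for 2001-2020).
#' @return Flux in MgC/ha/yr.
#' @export
annualize <- function(total_flux, years) {
  stopifnot(all(years > 0))
  total_flux / years
}

#' Assemble a unit-level flux ledger
#'
#' Combines NECB with fire-emission and wood-removal entries into the
#' ledger tibble, computing NEP via the identity and the annualised NEP.
#'
#' @param unit_id Unit identifiers.
#' @param necb NECB per unit, MgC/ha.
#' @param fire_emission,wood_removals Ledger entries (<= 0), MgC/ha.
#' @param year0,year1 Interval endpoints (calendar years).
#' @return Tibble with class `flux_ledger`: `unit_id`, `year0`, `year1`,
#'   `years`, `necb`, `fire_emission`, `wood_removals`, `nep`,
#'   `annual_nep`.
#' @export
flux_ledger <- function(unit_id, necb, fire_emission = 0, wood_removals = 0,
                        year0 = 2001, year1 = 2020) {
  years <- year1 - year0
  stopifnot(all(years > 0))
  out <- tibble::tibble(
    unit_id = unit_id, year0 = year0, year1 = year1, years = years,
    necb = necb,
    fire_emission = rep_len(fire_emission, length(necb)),
    wood_removals = rep_len(wood_removals, length(necb))
  ) |>
    dplyr::mutate(
      nep = nep(.data$necb, .data$fire_emission, .data$wood_removals),
      annual_nep = annualize(.data$nep, .data$years)
    )
  class(out) <- c("flux_ledger", class(out))
  out
}

#' Prescribed-fire emission ledger entry from consumption fractions
#'
#' A simplified consumption model standing in for a first-order fire
#' effects run: the emission is the dot product of pre-fire combustible
#' pools and per-pool consumption fractions, entered with a negative sign.
#' Fire-effects model output, when available, can be supplied to the
#' ledger directly instead.
#'
#' @param prefire_pools One-row pool tibble (or named vector) holding the
#'   combustible pools: `litter`, `duff`, `fwd_1h`, `fwd_10h`, `fwd_100h`,
#'   `cwd`, `understory`; a `foliage` element may be supplied for canopy
#'   consumption.
#' @param consumption Named numeric vector of fractions in `[0, 1]`; pools
#'   not named are not consumed.
#' @return Emission in MgC/ha, <= 0.
#' @export
#' @examples
#' fire_emission_entry(c(litter = 10), c(litter = 1))  # -10
fire_emission_entry <- function(prefire_pools, consumption) {
  stopifnot(all(consumption >= 0), all(consumption <= 1))
  if (is.data.frame(prefire_pools)) {
    stopifnot(nrow(prefire_pools) == 1)
    prefire_pools <- unlist(prefire_pools[intersect(
      names(prefire_pools),
      c(pool_names(), "foliage"))])
  }
  pools <- names(consumption)
  missing <- setdiff(pools, names(prefire_pools))
  if (length(missing)) stop("consumption names not in pools: ",
                            paste(missing, collapse = ", "))
  -sum(prefire_pools[pools] * consumption)
}

#' Linearly interpolate annual fluxes between inventories
#'
#' Measured changes in carbon storage between two inventories are spread
#' evenly over the years of the interval, so within each interval the
#' annual flux is constant and the fluxes telescope exactly back to the
#' end-to-end change.
#'
#' @param series Tibble with `year` and `total` (MgC/ha), one row per
#'   inventory, or two vectors via `year`/`total` columns.
#' @return Tibble with `year` (each year `y` covers the flux from `y-1` to
#'   `y`) and `flux` (MgC/ha/yr).
#' @export
#' @examples
#' interpolate_annual_flux(tibble::tibble(year = c(2003, 2009),
#'                                        total = c(100, 160)))
interpolate_annual_flux <- function(series) {
  series <- dplyr::arrange(tibble::as_tibble(series), .data$year)
  stopifnot(nrow(series) >= 2, !anyDuplicated(series$year))
  purrr::map_dfr(seq_len(nrow(series) - 1), function(i) {
    y0 <- series$year[i]; y1 <- series$year[i + 1]
    tibble::tibble(year = seq(y0 + 1, y1),
                   flux = (series$total[i + 1] - series$total[i]) / (y1 - y0))
  })
}
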