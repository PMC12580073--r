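#' Wildfire-resistant fractions of live tree carbon
#'
#' Two carbon-weighted fractions of the aboveground live tree pool: the
#' share held in large trees (dbh >= 76.2 cm by default) and the share
#' held in the fire-resistant species (ponderosa and sugar pine). Both
#' are invariant to uniform rescaling of tree carbon; with no live trees
#' they are undefined (`NA`).
#'
#' @param trees Tree records; only `status == "live"` rows enter.
#' @param table Allometry tables.
#' @param constants See [carbon_constants()].
#' @param large_dbh Large-tree threshold in cm (default 76.2; 72.6 is the
#'   alternative anchoring the stable-carbon definition).
#' @return Tibble: `pct_large` and `pct_resistant` (percent of live tree
#'   carbon), `live_tree_carbon` (MgC/ha).
#' @export
resistant_fractions <- function(trees, table = default_allometry(),
                                constants = carbon_constants(),
                                large_dbh = plot_geometry()$large_tree_dbh) {
  live <- trees[trees$status == "live", , drop = FALSE]
  if (!nrow(live)) {
    return(tibble::tibble(pct_large = NA_real_, pct_resistant = NA_real_,
                          live_tree_carbon = 0))
  }
  w <- if ("weight" %in% names(live)) live$weight else 1
  carbon <- tree_carbon(tree_biomass(live$species, live$dbh, live$height,
                                     table), constants) *
    expansion_factor(live$sample_frame) * w
  total <- sum(carbon)
  tibble::tibble(
    pct_large = 100 * sum(carbon[live$dbh >= large_dbh]) / total,
    pct_resistant = 100 * sum(carbon[live$species %in% resistant_species()]) /
      total,
    live_tree_carbon = total
  )
}

#' Stable carbon: large fire-resistant pines
#'
#' Live-tree carbon in ponderosa and sugar pine with dbh >= 72.6 cm —
#' the subset expected to survive a wildfire.
#'
#' @inheritParams resistant_fractions
#' @param dbh_min Threshold in cm (default 72.6).
#' @return Stable carbon in MgC/ha.
#' @export
stable_carbon <- function(trees, table = default_allometry(),
                          constants = carbon_constants(),
                          dbh_min = plot_geometry()$stable_tree_dbh) {
  keep <- trees$status == "live" & trees$species %in% resistant_species() &
    trees$dbh >= dbh_min
  sel <- trees[keep, , drop = FALSE]
  if (!nrow(sel)) return(0)
  w <- if ("weight" %in% names(sel)) sel$weight else 1
  sum(tree_carbon(tree_biomass(sel$species, sel$dbh, sel$height, table),
                  constants) *
        expansion_factor(sel$sample_frame) * w)
}

#' Build a mortality schedule
#'
#' Species- and size-specific kill fractions (basal-area basis) as
#' supplied by an external fire-behaviour simulation, or a documented
#' stand-in: a logistic survival curve in dbh,
#' \eqn{p_{kill}(d) = 1 / (1 + e^{b (d - d_{50})})}, so survival increases
#' monotonically with stem size.
#'
#' @param species Species codes (`"all"` matches any species).
#' @param dbh_min,dbh_max Class limits in cm.
#' @param mortality Kill fractions in `[0, 1]`.
#' @return Tibble of class rules.
#' @export
mortality_schedule <- function(species = "all", dbh_min = 0, dbh_max = Inf,
                               mortality = 0) {
  stopifnot(all(mortality >= 0), all(mortality <= 1))
  tibble::tibble(species = species, dbh_min = dbh_min, dbh_max = dbh_max,
                 mortality = mortality)
}

#' Logistic size-dependent mortality stand-in
#' @param d50 dbh (cm) at 50% mortality.
#' @param slope Logistic steepness per cm.
#' @param breaks dbh class breaks used to discretise the curve.
#' @return A [mortality_schedule()] tibble.
#' @export
logistic_mortality <- function(d50 = 20, slope = 0.12,
                               breaks = c(0, 5, 10, 15, 20, 30, 40, 60, 80,
                                          Inf)) {
  lo <- head(breaks, -1)
  hi <- breaks[-1]
  mids <- ifelse(is.finite(hi), (lo + hi) / 2, lo + 20)
  mortality_schedule(
    species = "all", dbh_min = lo, dbh_max = hi,
    mortality = plogis(-slope * (mids - d50))
  )
}

match_mortality <- function(trees, schedule) {
  frac <- numeric(nrow(trees))
  for (i in seq_len(nrow(schedule))) {
    hit <- (schedule$species[i] == "all" | trees$species == schedule$species[i]) &
      trees$dbh >= schedule$dbh_min[i] & trees$dbh < schedule$dbh_max[i]
    frac[hit] <- schedule$mortality[i]
  }
  frac
}

#' Apply a mortality schedule to a live tree list
#'
#' Deterministic-expectation accounting: each live tree contributes its
#' kill fraction of carbon to the killed pool and survives with the
#' complement. Killed carbon transfers to new snag records (carrying a
#' `weight` column with the killed fraction so expansion-weighted carbon
#' is conserved exactly: survivor + killed = pre-fire live carbon).
#'
#' @param trees Tree records (live rows are processed; snags pass through
#'   unchanged in `survivors`).
#' @param schedule A [mortality_schedule()] tibble.
#' @param table,constants Allometry and constants for the carbon-weighted
#'   summaries.
#' @return List: `killed_carbon` (MgC/ha), `pct_ba_killed` (%P-mort,
#'   basal-area basis), `survivors` (tree tibble with `weight`),
#'   `new_snags` (tree tibble with `weight`, `status = "snag"`).
#' @export
apply_mortality <- function(trees, schedule, table = default_allometry(),
                            constants = carbon_constants()) {
  if (!"weight" %in% names(trees)) trees$weight <- 1
  live <- trees[trees$status == "live", , drop = FALSE]
  rest <- trees[trees$status != "live", , drop = FALSE]
  if (!nrow(live)) {
    return(list(killed_carbon = 0, pct_ba_killed = NA_real_,
                survivors = trees, new_snags = live))
  }
  frac <- match_mortality(live, schedule)
  carbon <- tree_carbon(tree_biomass(live$species, live$dbh, live$height,
                                     table), constants) *
    expansion_factor(live$sample_frame) * live$weight
  ba <- pi / 4 * (live$dbh / 100)^2 * expansion_factor(live$sample_frame) *
    live$weight

  survivors <- live
  survivors$weight <- live$weight * (1 - frac)
  survivors <- survivors[survivors$weight > 0, , drop = FALSE]
  new_snags <- live
  new_snags$weight <- live$weight * frac
  new_snags$status <- "snag"
  new_snags <- new_snags[new_snags$weight > 0, , drop = FALSE]

  list(
    killed_carbon = sum(carbon * frac),
    pct_ba_killed = 100 * sum(ba * frac) / sum(ba),
    survivors = dplyr::bind_rows(survivors, rest),
    new_snags = new_snags
  )
}

#' Immediate carbon ledger of a simulated wildfire
#'
#' Given pre-fire pools, a wildfire emission and the killed live-tree
#' carbon, builds the post-fire pool state under strict conservation:
#' killed carbon moves from the live tree pool to the snag pool, and the
#' emission is drawn first from the combustible surface pools (litter,
#' duff, fine and coarse woody debris, understory) in proportion to their
#' size, with any excess drawn from the post-fire snag pool (crown
#' consumption), so pre-fire total = post-fire total + emission exactly.
#'
#' @param prefire One-row pool tibble (as from [estimate_pools()]).
#' @param emission Wildfire emission magnitude, MgC/ha (>= 0).
#' @param killed Live tree carbon killed, MgC/ha (<= live tree pool).
#' @return List: `postfire` (one-row pool tibble with recomputed `total`),
#'   `emission`, `killed_carbon`.
#' @export
scenario_ledger <- function(prefire, emission, killed) {
  stopifnot(nrow(prefire) == 1, emission >= 0, killed >= 0,
            killed <= prefire$live_tree + 1e-9)
  post <- prefire
  post$live_tree <- prefire$live_tree - killed
  post$snag <- prefire$snag + killed

  combustible <- c("litter", "duff", "fwd_1h", "fwd_10h", "fwd_100h",
                   "cwd", "understory")
  avail <- sum(unlist(post[combustible]))
  surface_burn <- min(emission, avail)
  if (avail > 0) {
    shares <- unlist(post[combustible]) / avail
    for (p in combustible) post[[p]] <- post[[p]] - surface_burn * shares[[p]]
  }
  crown_burn <- emission - surface_burn
  if (crown_burn > post$snag + 1e-9) {
    stop("emission exceeds combustible + killed-tree carbon")
  }
  post$snag <- post$snag - crown_burn
  post$total <- sum(unlist(post[pool_names()]))
  list(postfire = post, emission = emission, killed_carbon = killed)
}

#' Summarise wildfire impacts on a plot's live trees
#'
#' Runs [apply_mortality()] and derives the Table-style metrics: killed
#' carbon, %P-mort, the percent of large-tree carbon killed, the percent
#' of fire-resistant-species carbon killed, and post-fire stable carbon.
#'
#' @inheritParams apply_mortality
#' @param large_dbh Large-tree threshold, cm.
#' @return One-row tibble: `killed_carbon`, `pct_ba_killed`,
#'   `pct_large_dead`, `pct_resistant_dead`, `stable_carbon_post`.
#' @export
wildfire_impacts <- function(trees, schedule, table = default_allometry(),
                             constants = carbon_constants(),
                             large_dbh = plot_geometry()$large_tree_dbh) {
  live <- trees[trees$status == "live", , drop = FALSE]
  if (!"weight" %in% names(live)) live$weight <- 1
  if (!nrow(live)) {
    return(tibble::tibble(killed_carbon = 0, pct_ba_killed = NA_real_,
                          pct_large_dead = NA_real_,
                          pct_resistant_dead = NA_real_,
                          stable_carbon_post = 0))
  }
  frac <- match_mortality(live, schedule)
  carbon <- tree_carbon(tree_biomass(live$species, live$dbh, live$height,
                                     table), constants) *
    expansion_factor(live$sample_frame) * live$weight
  res <- apply_mortality(trees, schedule, table, constants)
  large <- live$dbh >= large_dbh
  resist <- live$species %in% resistant_species()
  pct_dead <- function(sel) {
    if (!any(sel)) return(NA_real_)
    100 * sum(carbon[sel] * frac[sel]) / sum(carbon[sel])
  }
  tibble::tibble(
    killed_carbon = res$killed_carbon,
    pct_ba_killed = res$pct_ba_killed,
    pct_large_dead = pct_dead(large),
    pct_resistant_dead = pct_dead(resist),
    stable_carbon_post = stable_carbon(res$survivors, table, constants)
  )
}
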