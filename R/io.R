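#' Read an inventory dataset from a directory of delimited files
#'
#' Expects UTF-8, comma-delimited files with one header row, one file per
#' record family keyed by `plot_id` + `year`: `plots.csv`, `trees.csv`,
#' `understory.csv`, `transects.csv`, `cwd.csv`, `soil.csv`, plus an
#' optional `config.yml` declaring study years, treatment assignment and
#' the event schedule. Missing optional files yield empty tables; a
#' missing mandatory column is a hard failure naming the column.
#' Unparseable or invariant-violating rows are collected into the error
#' report (see [inventory_errors()]), not silently dropped.
#'
#' @param dir Directory containing the files.
#' @param config Optional path to a YAML config (defaults to
#'   `file.path(dir, "config.yml")` when that file exists).
#' @return A validated [as_inventory()] object; the parsed config, if any,
#'   is attached as attribute `"config"`.
#' @export
read_inventory <- function(dir, config = NULL) {
  stopifnot(dir.exists(dir))
  rd <- function(name, col_types) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) return(NULL)
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  }
  plots <- rd("plots", readr::cols(
    plot_id = "c", unit_id = "c", treatment = "c", year = "i",
    .default = readr::col_guess()
  ))
  if (is.null(plots)) stop("plots.csv is required")
  trees <- rd("trees", readr::cols(
    plot_id = "c", year = "i", tag = "c", species = "c", dbh = "d",
    height = "d", status = "c", crown_class = "c", decay_class = "i",
    sample_frame = "c"
  ))
  understory <- rd("understory", readr::cols(
    plot_id = "c", year = "i", species = "c", cover_class = "c",
    mean_height = "d", growth_form = "c"
  ))
  transects <- rd("transects", readr::cols(
    plot_id = "c", year = "i", transect = "i", azimuth = "d",
    counts_1h = "i", counts_10h = "i", counts_100h = "i",
    litter_depth_1 = "d", litter_depth_2 = "d",
    duff_depth_1 = "d", duff_depth_2 = "d"
  ))
  cwd <- rd("cwd", readr::cols(plot_id = "c", year = "i", transect = "i",
                               diameter = "d"))
  soil <- rd("soil", readr::cols(
    plot_id = "c", year = "i", sample = "i", bulk_density = "d",
    carbon_pct = "d", depth_top = "d", depth_bottom = "d"
  ))

  cfg_path <- config %||% file.path(dir, "config.yml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  events <- NULL
  if (!is.null(cfg$events)) {
    events <- purrr::map_dfr(cfg$events, function(e) {
      tibble::tibble(unit_id = as.character(e$unit_id),
                     year = as.integer(e$year),
                     kind = as.character(e$kind))
    }) |> dplyr::arrange(.data$unit_id, .data$year)
  }

  inv <- as_inventory(plots, trees, understory, transects, cwd, soil, events)
  attr(inv, "config") <- cfg
  inv
}

#' Write an inventory dataset to a directory of delimited files
#'
#' Inverse of [read_inventory()]: writes one CSV per record family plus a
#' `config.yml` holding the event schedule. Text-representable values
#' round-trip exactly.
#'
#' @param inv An `ffs_inventory`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inventory <- function(inv, dir) {
  stopifnot(inherits(inv, "ffs_inventory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("plots", "trees", "understory", "transects", "cwd", "soil")) {
    readr::write_csv(inv[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  cfg <- attr(inv, "config") %||% list()
  if (nrow(inv$events)) {
    cfg$events <- purrr::pmap(inv$events, function(unit_id, year, kind, ...) {
      list(unit_id = unit_id, year = year, kind = kind)
    })
  }
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  invisible(dir)
}
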