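#' Per-year sampling protocol flags
#'
#' The field protocol drifted over the study: small trees
#' (1.0 <= dbh < 11.4 cm) were measured on 0.004-ha subplots in most
#' years, tallied into 2.54-cm bins in 2016, and censused on the whole
#' 0.04-ha plot in 2020; the snag dbh floor rose from 11.4 cm to 20.5 cm
#' in 2016 only. Rather than normalising records at read time, these rules
#' travel with the inventory as per-year flags and downstream estimators
#' decide comparability.
#'
#' @param years Integer vector of inventory years.
#' @return Tibble with `year`, `small_tree_frame` (`"subplot"` or
#'   `"main_plot"`), `small_tree_binned` (logical) and `snag_min_dbh` (cm).
#' @export
default_protocol <- function(years) {
  tibble::tibble(
    year = as.integer(years),
    small_tree_frame = ifelse(years >= 2020, "main_plot", "subplot"),
    small_tree_binned = years == 2016,
    snag_min_dbh = ifelse(years == 2016, 20.5, 11.4)
  )
}

#' Per-hectare expansion factor for a sampling frame
#'
#' Main-plot records expand at 1/0.04 = 25 per ha, subplot records at
#' 1/0.004 = 250 per ha. The 2020 whole-plot small-tree census records
#' carry `sample_frame = "main_plot"` and therefore expand at 25.
#'
#' @param sample_frame Character vector, `"main_plot"` or `"subplot"`.
#' @param geometry See [plot_geometry()].
#' @return Numeric vector of per-hectare multipliers.
#' @export
#' @examples
#' expansion_factor(c("main_plot", "subplot"))  # 25 250
expansion_factor <- function(sample_frame, geometry = plot_geometry()) {
  out <- rep(NA_real_, length(sample_frame))
  out[sample_frame == "main_plot"] <- 1 / geometry$plot_area_ha
  out[sample_frame == "subplot"] <- 1 / geometry$subplot_area_ha
  if (anyNA(out)) {
    stop("unknown sample_frame: ",
         paste(unique(sample_frame[is.na(out)]), collapse = ", "))
  }
  out
}

#' Cover-class midpoints
#'
#' Understory percent cover is recorded in three classes interpreted at
#' central values: <5% -> 2.5%, 5%-25% -> 15%, 25%-100% -> 63%.
#'
#' @param cover_class Character vector in `c("lt5", "5to25", "25to100")`.
#' @return Midpoint cover in percent.
#' @export
cover_midpoint <- function(cover_class) {
  mid <- c(lt5 = 2.5, `5to25` = 15, `25to100` = 63)
  out <- unname(mid[cover_class])
  if (anyNA(out)) {
    stop("unknown cover_class: ",
         paste(unique(cover_class[is.na(out)]), collapse = ", "))
  }
  out
}

empty_tables <- function() {
  list(
    plots = tibble::tibble(
      plot_id = character(), unit_id = character(), treatment = character(),
      year = integer(), small_tree_frame = character(),
      small_tree_binned = logical(), snag_min_dbh = double()
    ),
    trees = tibble::tibble(
      plot_id = character(), year = integer(), tag = character(),
      species = character(), dbh = double(), height = double(),
      status = character(), crown_class = character(),
      decay_class = integer(), sample_frame = character()
    ),
    understory = tibble::tibble(
      plot_id = character(), year = integer(), species = character(),
      cover_class = character(), mean_height = double(),
      growth_form = character()
    ),
    transects = tibble::tibble(
      plot_id = character(), year = integer(), transect = integer(),
      azimuth = double(), counts_1h = integer(), counts_10h = integer(),
      counts_100h = integer(), litter_depth_1 = double(),
      litter_depth_2 = double(), duff_depth_1 = double(),
      duff_depth_2 = double()
    ),
    cwd = tibble::tibble(
      plot_id = character(), year = integer(), transect = integer(),
      diameter = double()
    ),
    soil = tibble::tibble(
      plot_id = character(), year = integer(), sample = integer(),
      bulk_density = double(), carbon_pct = double(),
      depth_top = double(), depth_bottom = double()
    ),
    events = tibble::tibble(
      unit_id = character(), year = integer(), kind = character()
    )
  )
}

#' Assemble and validate an inventory dataset
#'
#' Bundles the record families of a repeated plot inventory — plot roster,
#' trees/snags, understory cover, fuel transects, coarse woody debris
#' pieces, soil cores, and the treatment event schedule — into a single
#' validated object. Rows violating invariants (non-positive dbh, unknown
#' cover classes, negative tallies or depths, out-of-range soil carbon,
#' sub-threshold CWD pieces, frame/dbh mismatches) are removed and
#' collected into an error report available via [inventory_errors()];
#' unknown species codes are reassigned to `"OTHER"` with a warning.
#'
#' @param plots Plot roster: `plot_id`, `unit_id`, `treatment`, `year`,
#'   and optionally the protocol-flag columns from [default_protocol()]
#'   (filled in by year when absent).
#' @param trees,understory,transects,cwd,soil,events Record tables; any may
#'   be omitted. See [read_inventory()] for the column contract.
#' @return An object of class `ffs_inventory`: a named list of tibbles with
#'   an `errors` attribute.
#' @export
as_inventory <- function(plots, trees = NULL, understory = NULL,
                         transects = NULL, cwd = NULL, soil = NULL,
                         events = NULL) {
  tmpl <- empty_tables()
  fill <- function(x, name) {
    if (is.null(x) || nrow(x) == 0) return(tmpl[[name]])
    need <- setdiff(names(tmpl[[name]]), names(x))
    need <- setdiff(need, c("small_tree_frame", "small_tree_binned",
                            "snag_min_dbh"))
    if (length(need)) {
      stop("table '", name, "' is missing mandatory column(s): ",
           paste(need, collapse = ", "))
    }
    tibble::as_tibble(x)
  }
  plots <- fill(plots, "plots")
  if (!all(c("small_tree_frame", "small_tree_binned", "snag_min_dbh") %in%
           names(plots))) {
    plots <- plots |>
      dplyr::select(!dplyr::any_of(c("small_tree_frame", "small_tree_binned",
                                     "snag_min_dbh"))) |>
      dplyr::left_join(default_protocol(sort(unique(plots$year))),
                       by = "year")
  }
  inv <- list(
    plots = plots,
    trees = fill(trees, "trees"),
    understory = fill(understory, "understory"),
    transects = fill(transects, "transects"),
    cwd = fill(cwd, "cwd"),
    soil = fill(soil, "soil"),
    events = fill(events, "events")
  )
  validate_inventory(inv)
}

validate_inventory <- function(inv) {
  errors <- list()
  note <- function(table, rows, reason) {
    if (!length(rows)) return(NULL)
    tibble::tibble(table = table, row = rows, reason = reason)
  }

  # species normalisation: unknown codes -> OTHER with a warning
  known <- c(study_species(), "OTHER")
  unk <- !(inv$trees$species %in% known)
  if (any(unk)) {
    warning(sum(unk), " tree record(s) with unknown species assigned to OTHER")
    inv$trees$species[unk] <- "OTHER"
  }

  tr <- inv$trees
  if (nrow(tr)) {
    proto <- inv$plots |>
      dplyr::distinct(.data$plot_id, .data$year, .data$small_tree_frame)
    tr <- dplyr::left_join(tr, proto, by = c("plot_id", "year"))
    min_dbh <- plot_geometry()$main_plot_min_dbh
    bad <- which(
      !(tr$dbh > 0) |
        (!is.na(tr$height) & !(tr$height > 0)) |
        !(tr$status %in% c("live", "snag")) |
        !(tr$sample_frame %in% c("main_plot", "subplot")) |
        (tr$sample_frame == "subplot" & tr$dbh >= min_dbh) |
        (tr$sample_frame == "main_plot" & tr$status == "live" &
           tr$dbh < min_dbh &
           !(!is.na(tr$small_tree_frame) & tr$small_tree_frame == "main_plot"))
    )
    errors$trees <- note("trees", bad, "invalid tree record")
    inv$trees <- inv$trees[setdiff(seq_len(nrow(inv$trees)), bad), ]
  }

  us <- inv$understory
  if (nrow(us)) {
    bad <- which(!(us$cover_class %in% c("lt5", "5to25", "25to100")) |
                   !(us$growth_form %in% c("shrub", "herb")))
    errors$understory <- note("understory", bad, "invalid understory record")
    inv$understory <- us[setdiff(seq_len(nrow(us)), bad), ]
  }

  tx <- inv$transects
  if (nrow(tx)) {
    cnt <- cbind(tx$counts_1h, tx$counts_10h, tx$counts_100h)
    dep <- cbind(tx$litter_depth_1, tx$litter_depth_2,
                 tx$duff_depth_1, tx$duff_depth_2)
    bad <- which(apply(cnt < 0, 1, any) | apply(dep < 0, 1, any))
    errors$transects <- note("transects", bad, "negative tally or depth")
    inv$transects <- tx[setdiff(seq_len(nrow(tx)), bad), ]
  }

  cw <- inv$cwd
  if (nrow(cw)) {
    bad <- which(!(cw$diameter > plot_geometry()$cwd_min_diameter))
    errors$cwd <- note("cwd", bad, "piece diameter below 1000-h threshold")
    inv$cwd <- cw[setdiff(seq_len(nrow(cw)), bad), ]
  }

  so <- inv$soil
  if (nrow(so)) {
    bad <- which(!(so$carbon_pct > 0 & so$carbon_pct < 60) |
                   !(so$bulk_density > 0))
    errors$soil <- note("soil", bad, "soil carbon or bulk density out of range")
    inv$soil <- so[setdiff(seq_len(nrow(so)), bad), ]
  }

  err <- dplyr::bind_rows(errors)
  if (is.null(err) || nrow(err) == 0) {
    err <- tibble::tibble(table = character(), row = integer(),
                          reason = character())
  }
  structure(inv, errors = err, class = "ffs_inventory")
}

#' Error report from inventory validation
#' @param inv An `ffs_inventory`.
#' @return Tibble of rejected rows (`table`, `row`, `reason`).
#' @export
inventory_errors <- function(inv) {
  attr(inv, "errors") %||%
    tibble::tibble(table = character(), row = integer(), reason = character())
}

#' @export
print.ffs_inventory <- function(x, ...) {
  cat("<ffs_inventory>\n")
  for (nm in c("plots", "trees", "understory", "transects", "cwd", "soil",
               "events")) {
    cat(sprintf("  %-10s %6d rows\n", nm, nrow(x[[nm]])))
  }
  ne <- nrow(inventory_errors(x))
  if (ne) cat("  ", ne, "rejected row(s); see inventory_errors()\n")
  invisible(x)
}

#' Plots measured at every required inventory
#'
#' Carbon balances computed from a shifting set of plots confound
#' treatment effects with sampling effects, so analyses are restricted to
#' plots measured at every required year. Returns exactly those plot ids;
#' the length of the result is the analysis N.
#'
#' @param x An `ffs_inventory` or a plot roster tibble with `plot_id` and
#'   `year`.
#' @param years Required inventory years.
#' @return Character vector of plot ids (sorted).
#' @export
consistently_sampled_plots <- function(x, years) {
  plots <- if (inherits(x, "ffs_inventory")) x$plots else x
  years <- unique(as.integer(years))
  ids <- plots |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::distinct(.data$plot_id, .data$year) |>
    dplyr::count(.data$plot_id) |>
    dplyr::filter(.data$n == length(years)) |>
    dplyr::pull(.data$plot_id)
  if (!length(ids)) warning("no plot was sampled at every required year")
  sort(ids)
}
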