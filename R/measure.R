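# Measurement model: turn the latent stand state of one unit into the
# field records an inventory crew would produce under the year's protocol.

measure_stand <- function(stand, cfg, year) {
  geom <- plot_geometry()
  proto <- default_protocol(year)
  cc <- carbon_constants()
  plots <- stand$fuels$plot_id

  plots_tbl <- tibble::tibble(
    plot_id = plots, unit_id = stand$unit_id, treatment = stand$treatment,
    year = as.integer(year),
    small_tree_frame = proto$small_tree_frame,
    small_tree_binned = proto$small_tree_binned,
    snag_min_dbh = proto$snag_min_dbh
  )

  tr <- stand$trees
  big_live <- tr$status == "live" & tr$dbh >= geom$main_plot_min_dbh
  snag_rec <- tr$status == "snag" & tr$dbh >= proto$snag_min_dbh
  small <- tr$status == "live" & tr$dbh >= 1 & tr$dbh < geom$main_plot_min_dbh

  main <- tr[big_live | snag_rec, , drop = FALSE]
  if (nrow(main)) main$sample_frame <- "main_plot"

  if (proto$small_tree_frame == "main_plot") {
    sm <- tr[small, , drop = FALSE]
    if (nrow(sm)) sm$sample_frame <- "main_plot"
  } else {
    # subplot census: each small stem falls on the 0.004-ha subplot with
    # probability area ratio 0.1
    keep <- small & (runif(nrow(tr)) < geom$subplot_area_ha / geom$plot_area_ha)
    sm <- tr[keep, , drop = FALSE]
    if (nrow(sm)) {
      sm$sample_frame <- "subplot"
      if (proto$small_tree_binned) {
        # 2.54-cm tally bins: midpoint assignment by default, or a seeded
        # uniform draw within the bin
        lo <- 1 + 2.54 * floor((sm$dbh - 1) / 2.54)
        sm$dbh <- if (identical(cfg$bin_assignment, "uniform")) {
          pmin(runif(nrow(sm), lo, lo + 2.54), 11.3)
        } else {
          pmin(lo + 1.27, 11.3)
        }
        sm$height <- sim_height(sm$dbh, cfg)
      }
    }
  }
  trees_tbl <- dplyr::bind_rows(main, sm)
  if (nrow(trees_tbl)) {
    trees_tbl <- trees_tbl |>
      dplyr::mutate(year = as.integer(year)) |>
      dplyr::select("plot_id", "year", "tag", "species", "dbh", "height",
                    "status", "crown_class", "decay_class", "sample_frame")
  }

  under_tbl <- stand$understory |>
    dplyr::mutate(year = as.integer(year)) |>
    dplyr::relocate("year", .after = "plot_id")

  # fuel transects: invert the planar-intercept formula for expected tallies
  tx <- list(); cw <- list()
  for (i in seq_along(plots)) {
    pid <- plots[i]
    ptrees <- trees_tbl[trees_tbl$plot_id == pid, , drop = FALSE]
    comp <- composite_fuel_coefficients(ptrees)
    f <- stand$fuels[i, ]
    exp_n <- function(load, cls, L) {
      load * L / (.planar_G * comp[[paste0("qmd_", cls)]] *
                    comp[[paste0("sec_", cls)]] * comp[[paste0("sg_", cls)]])
    }
    dsd <- cfg$depth_cv
    for (t in 1:2) {
      tx[[length(tx) + 1]] <- tibble::tibble(
        plot_id = pid, year = as.integer(year), transect = t,
        azimuth = round(runif(1, 0, 360), 1),
        counts_1h = rpois(1, exp_n(f$fwd_1h, "1h", 2)),
        counts_10h = rpois(1, exp_n(f$fwd_10h, "10h", 2)),
        counts_100h = rpois(1, exp_n(f$fwd_100h, "100h", 3)),
        litter_depth_1 = f$litter_depth * exp(rnorm(1, 0, dsd)),
        litter_depth_2 = f$litter_depth * exp(rnorm(1, 0, dsd)),
        duff_depth_1 = f$duff_depth * exp(rnorm(1, 0, dsd)),
        duff_depth_2 = f$duff_depth * exp(rnorm(1, 0, dsd))
      )
      # CWD pieces: diameters 7.62 + Exp(mean 6) cm, count matched to the
      # latent load through E[d^2]
      target_d2 <- f$cwd * geom$transect_length_m /
        (.planar_G * comp$sec_1000h * comp$sg_1000h)
      e_d2 <- geom$cwd_min_diameter^2 + 2 * geom$cwd_min_diameter * 6 + 2 * 36
      np <- rpois(1, target_d2 / e_d2)
      if (np > 0) {
        cw[[length(cw) + 1]] <- tibble::tibble(
          plot_id = pid, year = as.integer(year), transect = t,
          diameter = geom$cwd_min_diameter + stats::rexp(np, 1 / 6)
        )
      }
    }
  }
  tx_tbl <- dplyr::bind_rows(tx)
  cw_tbl <- if (length(cw)) dplyr::bind_rows(cw) else empty_tables()$cwd

  soil_tbl <- purrr::map_dfr(seq_along(plots), function(i) {
    tibble::tibble(
      plot_id = plots[i], year = as.integer(year),
      sample = seq_len(cfg$soil_samples),
      bulk_density = stand$soil$bulk_density[i] *
        exp(rnorm(cfg$soil_samples, 0, 0.05)),
      carbon_pct = stand$soil$carbon_pct[i] *
        exp(rnorm(cfg$soil_samples, 0, 0.06)),
      depth_top = 0, depth_bottom = 15
    )
  })

  list(plots = plots_tbl, trees = trees_tbl, understory = under_tbl,
       transects = tx_tbl, cwd = cw_tbl, soil = soil_tbl)
}
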