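#' Pool groups for recovery analysis
#'
#' Live vegetation aggregates the photosynthetic pools (live tree +
#' understory shrub/herb); fine surface fuel aggregates litter and the
#' 1-, 10- and 100-h woody debris classes.
#'
#' @param pools A pool tibble from [estimate_pools()].
#' @param group `"live_vegetation"` or `"surface_fuel"`.
#' @return The input with a `value` column holding the group sum (MgC/ha).
#' @export
pool_group <- function(pools, group = c("live_vegetation", "surface_fuel")) {
  group <- match.arg(group)
  members <- switch(group,
    live_vegetation = c("live_tree", "understory"),
    surface_fuel = c("litter", "fwd_1h", "fwd_10h", "fwd_100h")
  )
  dplyr::mutate(pools,
                value = rowSums(dplyr::pick(dplyr::all_of(members))))
}

#' Interval accumulation or recovery rate
#'
#' Simple difference quotient of a carbon series over defined intervals:
#' for the fire regime each recovery period runs from the first post-fire
#' inventory to the next fire (2003-2009, 2010-2016, 2017-2020); the
#' matching control accumulation periods are 2003-2009, 2009-2016 and
#' 2016-2020. Rates telescope: sum(rate x years) over contiguous
#' intervals equals the end-to-end change exactly.
#'
#' @param series Tibble with `year` and `value` (MgC/ha).
#' @param intervals List of `c(y0, y1)` pairs, or a single pair.
#' @return Tibble: `interval` (label `"y0-y1"`), `y0`, `y1`, `years`,
#'   `rate` (MgC/ha/yr).
#' @export
#' @examples
#' interval_rate(tibble::tibble(year = c(2017, 2020), value = c(0, 18)),
#'               c(2017, 2020))  # 6 MgC/ha/yr
interval_rate <- function(series, intervals) {
  if (!is.list(intervals)) intervals <- list(intervals)
  series <- tibble::as_tibble(series)
  purrr::map_dfr(intervals, function(iv) {
    y0 <- iv[1]; y1 <- iv[2]
    v0 <- series$value[series$year == y0]
    v1 <- series$value[series$year == y1]
    if (length(v0) != 1 || length(v1) != 1) {
      stop("series lacks a unique value at ", y0, " or ", y1)
    }
    tibble::tibble(interval = paste0(y0, "-", y1), y0 = y0, y1 = y1,
                   years = y1 - y0, rate = (v1 - v0) / (y1 - y0))
  })
}

#' Study interval definitions for fire and control units
#' @param treatment `"Fire"` or `"Control"`.
#' @return List of `c(y0, y1)` interval pairs.
#' @export
recovery_intervals <- function(treatment = c("Fire", "Control")) {
  treatment <- match.arg(treatment)
  if (treatment == "Fire") {
    list(c(2003, 2009), c(2010, 2016), c(2017, 2020))
  } else {
    list(c(2003, 2009), c(2009, 2016), c(2016, 2020))
  }
}

#' Annual tree mortality rate from stem counts
#'
#' Default is the compound (exponential-decay) convention,
#' \eqn{m = 1 - (S/N_0)^{1/t}}, reported in %/yr; the simple convention
#' \eqn{m = (1 - S/N_0)/t} is also exposed.
#'
#' @param n_initial Initial live stem count.
#' @param n_survivors Survivors after `years`.
#' @param years Interval length in years.
#' @param method `"compound"` (default) or `"simple"`.
#' @return Mortality in %/yr.
#' @export
#' @examples
#' annual_mortality_rate(100, 90, 6)  # 1.74 %/yr
annual_mortality_rate <- function(n_initial, n_survivors, years,
                                  method = c("compound", "simple")) {
  method <- match.arg(method)
  stopifnot(n_initial > 0, n_survivors >= 0, n_survivors <= n_initial,
            years > 0)
  s <- n_survivors / n_initial
  100 * switch(method,
               compound = 1 - s^(1 / years),
               simple = (1 - s) / years)
}

#' BACI treatment contrast with bootstrap uncertainty
#'
#' Transparent difference-in-differences: the effect is the mean
#' before-to-after change on treated plots minus the mean change on
#' control plots, so any shared temporal trend cancels
#' (translation-invariant). Uncertainty comes from a seeded nonparametric
#' bootstrap resampling plots within each group, with a percentile
#' interval.
#'
#' @param treated Numeric vector of per-plot before-to-after deltas in the
#'   treated group.
#' @param control Per-plot deltas in the control group.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level for the percentile interval.
#' @return A `baci_contrast` object (list): `effect`, `conf_low`,
#'   `conf_high`, `n_treated`, `n_control`, `n_boot`, `conf`, `boot`
#'   (replicate effects).
#' @export
baci_contrast <- function(treated, control, n_boot = 2000, seed = 1,
                          conf = 0.95) {
  stopifnot(length(treated) >= 2, length(control) >= 2, n_boot >= 1)
  effect <- mean(treated) - mean(control)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(treated, replace = TRUE)) -
        mean(sample(control, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(
    list(effect = effect, conf_low = ci[1], conf_high = ci[2],
         n_treated = length(treated), n_control = length(control),
         n_boot = n_boot, conf = conf, boot = boot),
    class = "baci_contrast"
  )
}

#' @export
print.baci_contrast <- function(x, ...) {
  cat(sprintf(
    "<baci_contrast> effect %.3f [%.3f, %.3f] (%d%% percentile CI, %d reps)\n",
    x$effect, x$conf_low, x$conf_high, round(100 * x$conf), x$n_boot))
  invisible(x)
}

#' Tidy a BACI contrast
#' @param x A `baci_contrast`.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `conf_low`, `conf_high`.
#' @export
tidy.baci_contrast <- function(x, ...) {
  tibble::tibble(estimate = x$effect, conf_low = x$conf_low,
                 conf_high = x$conf_high)
}

#' Glance at a BACI contrast
#' @param x A `baci_contrast`.
#' @param ... Unused.
#' @return One-row tibble with sample sizes and bootstrap settings.
#' @export
glance.baci_contrast <- function(x, ...) {
  tibble::tibble(n_treated = x$n_treated, n_control = x$n_control,
                 n_boot = x$n_boot, conf = x$conf)
}

#' Bootstrap distribution of a BACI contrast
#' @param object A `baci_contrast`.
#' @param ... Unused.
#' @return A ggplot histogram of replicate effects with the CI marked.
#' @export
autoplot.baci_contrast <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(boot = object$boot),
                  ggplot2::aes(.data$boot)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$effect) +
    ggplot2::geom_vline(xintercept = c(object$conf_low, object$conf_high),
                        linetype = 2) +
    ggplot2::labs(x = "Bootstrap effect (MgC/ha)", y = "Replicates") +
    ggplot2::theme_minimal()
}
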