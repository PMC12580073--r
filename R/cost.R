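#' Time-discounted carbon cost of a treatment against a dynamic baseline
#'
#' For each year, the cost entry is the control flux minus the treatment
#' flux, with the LLP share of harvested sawlog carbon credited back to
#' the treatment in the year of harvest (stored offsite is not a cost).
#' A positive delta means the treatment stored less carbon than the
#' untreated baseline that year (an emission in cost terms); a negative
#' delta is a sequestration. Each annual delta is discounted to start-year
#' equivalents by \eqn{(1+r)^{-(t - t_0)}} (default r = 0.04/yr,
#' \eqn{t_0} = 2001, so a 2002 delta carries factor 1/1.04) and summed.
#'
#' @param control_flux Tibble `year`, `flux` for the control baseline
#'   (MgC/ha/yr), e.g. from [interpolate_annual_flux()].
#' @param treatment_flux Tibble `year`, `flux` for the treatment; must
#'   cover exactly the same years as `control_flux`.
#' @param llp_by_year Optional tibble `year`, `llp` of wood-product
#'   credits (MgC/ha, positive = stored).
#' @param rate Discount rate per year.
#' @param base_year Discounting reference year.
#' @return A `carbon_cost` object: tibble with `year`, `control`,
#'   `treatment`, `llp_credit`, `delta`, `discount_factor`, `discounted`;
#'   totals available via [glance.carbon_cost()].
#' @export
#' @examples
#' ctl <- tibble::tibble(year = 2002, flux = 1)
#' trt <- tibble::tibble(year = 2002, flux = 0)
#' glance(carbon_cost(ctl, trt))  # discounted 1/1.04
carbon_cost <- function(control_flux, treatment_flux, llp_by_year = NULL,
                        rate = 0.04, base_year = 2001) {
  ctl <- dplyr::arrange(tibble::as_tibble(control_flux), .data$year)
  trt <- dplyr::arrange(tibble::as_tibble(treatment_flux), .data$year)
  if (!identical(as.integer(ctl$year), as.integer(trt$year))) {
    stop("control and treatment flux series cover different years")
  }
  llp <- rep(0, nrow(ctl))
  if (!is.null(llp_by_year) && nrow(llp_by_year)) {
    idx <- match(llp_by_year$year, ctl$year)
    if (anyNA(idx)) stop("llp_by_year contains years outside the flux series")
    llp[idx] <- llp[idx] + llp_by_year$llp
  }
  out <- tibble::tibble(
    year = as.integer(ctl$year),
    control = ctl$flux,
    treatment = trt$flux,
    llp_credit = llp,
    delta = ctl$flux - (trt$flux + llp),
    discount_factor = (1 + rate)^(-(ctl$year - base_year))
  ) |>
    dplyr::mutate(discounted = .data$delta * .data$discount_factor)
  attr(out, "rate") <- rate
  attr(out, "base_year") <- base_year
  class(out) <- c("carbon_cost", class(out))
  out
}

#' @export
print.carbon_cost <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<carbon_cost> %d-%d, rate %.2f/yr (base %d)\n  discounted %.1f MgC/ha, undiscounted %.1f MgC/ha\n",
    min(x$year), max(x$year), attr(x, "rate"), attr(x, "base_year"),
    g$discounted_cost, g$undiscounted_cost))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-year cost table
#' @param x A `carbon_cost` object.
#' @param ... Unused.
#' @return The underlying tibble with one row per year.
#' @export
tidy.carbon_cost <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a carbon-cost series
#' @param x A `carbon_cost` object.
#' @param ... Unused.
#' @return Tibble with `discounted_cost`, `undiscounted_cost`, `rate`,
#'   `base_year`, `n_years`.
#' @export
glance.carbon_cost <- function(x, ...) {
  tibble::tibble(
    discounted_cost = sum(x$discounted),
    undiscounted_cost = sum(x$delta),
    rate = attr(x, "rate"),
    base_year = attr(x, "base_year"),
    n_years = nrow(x)
  )
}

#' Cumulative discounted cost curve
#' @param object A `carbon_cost` object.
#' @param ... Unused.
#' @return A ggplot of cumulative discounted and undiscounted cost.
#' @export
autoplot.carbon_cost <- function(object, ...) {
  df <- tibble::tibble(
    year = rep(object$year, 2),
    cost = c(cumsum(object$discounted), cumsum(object$delta)),
    series = rep(c("discounted", "undiscounted"), each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$cost,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Year", y = "Cumulative carbon cost (MgC/ha)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
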