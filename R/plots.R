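#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the annual cost composition of each option
#'
#' Stacked bars of annualised capital, labour and operating costs per
#' modelled option, the standard way to show where an emptying-and-
#' transport service's money goes and why transfer options are cheaper.
#'
#' @param object A [cost_summary()] result.
#' @param currency `"USD"` (default) or `"BDT"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(cost_summary(bhaluka_scenario()))
#' @export
autoplot.fsm_cost_summary <- function(object, currency = c("USD", "BDT"),
                                      ...) {
  currency <- match.arg(currency)
  suffix <- if (currency == "USD") "_usd" else ""
  comp <- c("annualized_capital", "labour", "operating")
  long <- object |>
    dplyr::select("option_id",
                  dplyr::all_of(paste0(comp, suffix))) |>
    tidyr::pivot_longer(-"option_id", names_to = "component",
                        values_to = "cost") |>
    dplyr::mutate(component = factor(
      sub(suffix, "", .data$component, fixed = TRUE),
      levels = comp,
      labels = c("Annualised capital", "Labour", "Operating")
    ))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$option_id), y = .data$cost,
                               fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Option", y = sprintf("Annual cost (%s/yr)", currency),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted double-bounded WTP model against the data
#'
#' Overlays the fitted normal acceptance curve `P(WTP >= bid)` on the
#' empirical base-bid acceptance shares, a quick visual check that the
#' latent-normal model tracks the observed demand curve.
#'
#' @param object A [fit_dbdc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dbdc_fit <- function(object, ...) {
  d <- object$data
  w <- object$weights
  emp <- d |>
    dplyr::mutate(w = w) |>
    dplyr::group_by(.data$base_bid) |>
    dplyr::summarise(accept = sum(.data$w * .data$y1) / sum(.data$w),
                     .groups = "drop")
  bids <- seq(0, max(d$base_bid) * 1.5, length.out = 200)
  curve <- tibble::tibble(
    bid = bids,
    accept = 1 - stats::pnorm((bids - object$mean_wtp) / object$sigma)
  )
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$bid, y = .data$accept)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = emp,
                        ggplot2::aes(x = .data$base_bid, y = .data$accept)) +
    ggplot2::labs(x = "Bid (BDT)", y = "P(accept bid)") +
    ggplot2::theme_minimal()
}
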