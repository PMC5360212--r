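#' Financing gap between service cost and willingness to pay
#'
#' Joins a costed option with a willingness-to-pay estimate: what share
#' of the per-event cost households would cover, the per-event and annual
#' deficit a provider (or subsidy) must absorb, and the flat subscription
#' tariff that would recover full cost if every latrine-owning household
#' paid it monthly.
#'
#' Coverage is computed on the unrounded estimates; the deficit line uses
#' whole-BDT rounding of both cost and WTP, as tariff gaps are quoted in
#' whole currency. A negative deficit (WTP above cost) is reported as is.
#'
#' @param cost A one-row cost tibble from [cost_breakdown()], or a
#'   [cost_summary()] (the least-cost option is then used).
#' @param wtp A fitted [fit_dbdc()]/[fit_sbdc()] object, a
#'   [bootstrap_wtp()] result, or a plain number (BDT per event).
#' @param fx BDT per USD for the mirrored USD fields (default 78).
#' @return A one-row tibble: `option_id`, `cost_per_event`, `wtp_point`,
#'   `coverage_pct`, `deficit_per_event`, `annual_deficit_bdt`,
#'   `annual_deficit_usd`, `subscription_year_bdt`,
#'   `subscription_month_bdt`, `subscription_month_usd`.
#' @examples
#' scen <- bhaluka_scenario()
#' financing_gap(cost_summary(scen), wtp = 506.66)
#' @export
financing_gap <- function(cost, wtp, fx = 78) {
  if (inherits(cost, "fsm_cost_summary")) {
    cost <- cost[which.min(cost$total_annual), ]
  }
  stopifnot(nrow(cost) == 1)
  if (cost$per_event <= 0) stop("Cost per event must be positive.",
                                call. = FALSE)
  wtp_point <- if (is.numeric(wtp)) wtp else wtp[["mean_wtp"]] %||%
    wtp[["point"]]
  if (is.null(wtp_point) || !is.finite(wtp_point)) {
    stop("Could not extract a WTP point estimate.", call. = FALSE)
  }
  events <- cost$total_annual / cost$per_event
  n_households <- cost$total_annual / cost$per_household_year
  deficit <- round(cost$per_event) - round(wtp_point)
  tibble::tibble(
    option_id = cost$option_id,
    cost_per_event = cost$per_event,
    wtp_point = wtp_point,
    coverage_pct = 100 * wtp_point / cost$per_event,
    deficit_per_event = deficit,
    annual_deficit_bdt = deficit * events,
    annual_deficit_usd = deficit * events / fx,
    subscription_year_bdt = cost$total_annual / n_households,
    subscription_month_bdt = cost$total_annual / n_households / 12,
    subscription_month_usd = cost$total_annual / n_households / 12 / fx
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
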