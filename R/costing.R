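#' Annualised capital cost from first principles
#'
#' Net-present-value annualisation of a replacement cycle: units are
#' purchased at years 0, r, 2r, ... within the horizon, each outlay is
#' discounted to present value, and the NPV is divided by the horizon to
#' give a flat annual charge. This is an internally consistent alternative
#' to supplying per-unit annualised values directly in the technology
#' tables (the default, since published per-unit values often embed
#' spreadsheet conventions that no single discount rate reproduces).
#'
#' @param capital Purchase cost per unit, BDT.
#' @param replacement_period Years between purchases.
#' @param finance A [finance_params()].
#' @return Annualised cost, BDT/year.
#' @examples
#' npv_annualize(1000, 3, finance_params(discount_rate = 0))    # 360
#' npv_annualize(1000, 3, finance_params(discount_rate = 0.11)) # 139.9
#' @export
npv_annualize <- function(capital, replacement_period, finance) {
  stopifnot(capital >= 0, inherits(finance, "fsm_finance"))
  if (replacement_period <= 0) {
    stop("`replacement_period` must be positive.", call. = FALSE)
  }
  times <- seq(0, finance$horizon - 1e-9, by = replacement_period)
  npv <- sum(capital / (1 + finance$discount_rate)^times)
  npv / finance$horizon
}

#' Total capital outlay of a fleet plan
#'
#' @param plan A fleet plan from [size_fleet()].
#' @param scenario An `fsm_scenario`.
#' @return Up-front capital, BDT (sum of unit counts times unit costs).
#' @export
total_capital <- function(plan, scenario) {
  tech <- scenario$emptying[[plan$emptying_tech]]
  plan$emptying_units * tech$capital_cost +
    plan$trucks * scenario$transport$truck$capital_cost +
    plan$tankers * scenario$transport$tanker$capital_cost
}

#' Annualised capital cost of a fleet plan
#'
#' Uses the per-unit annualised values carried by the technology objects
#' (covering capital servicing, capital maintenance and wear and tear).
#' Set `use_npv = TRUE` to derive them with [npv_annualize()] instead.
#'
#' @param plan A fleet plan from [size_fleet()].
#' @param scenario An `fsm_scenario`.
#' @param use_npv Derive per-unit values by NPV annualisation of the
#'   purchase cycle rather than taking them from the technology tables.
#' @return BDT/year.
#' @export
annualized_capital <- function(plan, scenario, use_npv = FALSE) {
  per_unit <- function(tech) {
    if (use_npv) {
      npv_annualize(tech$capital_cost, tech$replacement_period,
                    scenario$finance)
    } else {
      if (is.null(tech$annualized_capital) || is.na(tech$annualized_capital)) {
        stop(sprintf("`%s` has no per-unit annualised capital value; set it ",
                     tech$name),
             "or use `use_npv = TRUE`.", call. = FALSE)
      }
      tech$annualized_capital
    }
  }
  tech <- scenario$emptying[[plan$emptying_tech]]
  plan$emptying_units * per_unit(tech) +
    plan$trucks * per_unit(scenario$transport$truck) +
    plan$tankers * per_unit(scenario$transport$tanker)
}

#' Annual labour cost of a fleet plan
#'
#' Labour is charged on task hours — the hours crews actually spend
#' emptying pits and driving trips — at each crew's hourly rate, not on
#' the standing fleet's full calendar.
#'
#' @param plan A fleet plan from [size_fleet()].
#' @param scenario An `fsm_scenario`.
#' @return BDT/year.
#' @export
labour_cost <- function(plan, scenario) {
  tech <- scenario$emptying[[plan$emptying_tech]]
  plan$emptying_hours * tech$crew_rate +
    plan$truck_hours * scenario$transport$truck$crew_rate +
    plan$tanker_hours * scenario$transport$tanker$crew_rate
}

#' Annual vehicle operating cost (excluding labour)
#'
#' Fuel and consumables charged per kilometre actually driven:
#' `rate = fuel_use * fuel_price + consumables` (truck 6.9, tanker 15.6
#' BDT/km at 68 BDT/L fuel) times annual round-trip kilometres.
#'
#' @param plan A fleet plan from [size_fleet()].
#' @param scenario An `fsm_scenario`.
#' @return BDT/year.
#' @export
operating_cost <- function(plan, scenario) {
  rate <- function(veh) {
    veh$fuel_use * scenario$finance$fuel_price + veh$consumables
  }
  plan$truck_km * rate(scenario$transport$truck) +
    plan$tanker_km * rate(scenario$transport$tanker)
}

#' Full cost breakdown for one option
#'
#' Aggregates capital, annualised capital, labour and operating costs for
#' one modelled option and derives the tariffs: cost per emptying event
#' (annual cost over annual events) and the flat subscription cost per
#' household with a pit (annual cost over all latrines, whether or not a
#' given pit is emptied that year), per year and per month. USD mirrors
#' use the scenario's fixed exchange rate.
#'
#' @param demand A tibble from [compute_demand()] (or an `fsm_scenario`).
#' @param scenario An `fsm_scenario`.
#' @param option_id Which option to cost.
#' @param use_npv Passed to [annualized_capital()].
#' @return A one-row tibble with the plan columns plus `total_capital`,
#'   `annualized_capital`, `labour`, `operating`, `total_annual`,
#'   `per_event`, `per_household_year`, `per_household_month`, and
#'   `*_usd` mirrors of each cost column.
#' @examples
#' scen <- bhaluka_scenario()
#' cost_breakdown(compute_demand(scen), scen, option_id = 4)
#' @export
cost_breakdown <- function(demand, scenario, option_id, use_npv = FALSE) {
  if (inherits(demand, "fsm_scenario")) {
    scenario <- demand
    demand <- compute_demand(scenario)
  }
  if (demand$events_per_year <= 0 || demand$n_latrines <= 0) {
    stop("Demand must have positive events and latrines to derive tariffs.",
         call. = FALSE)
  }
  plan <- size_fleet(demand, scenario, option_id)
  cb <- dplyr::mutate(
    plan,
    total_capital = total_capital(plan, scenario),
    annualized_capital = annualized_capital(plan, scenario, use_npv),
    labour = labour_cost(plan, scenario),
    operating = operating_cost(plan, scenario),
    total_annual = .data$annualized_capital + .data$labour + .data$operating,
    per_event = .data$total_annual / demand$events_per_year,
    per_household_year = .data$total_annual / demand$n_latrines,
    per_household_month = .data$per_household_year / 12
  )
  fx <- scenario$finance$fx
  money <- c("total_capital", "annualized_capital", "labour", "operating",
             "total_annual", "per_event", "per_household_year",
             "per_household_month")
  for (col in money) cb[[paste0(col, "_usd")]] <- cb[[col]] / fx
  cb
}

#' Cost summary over all options
#'
#' One costed row per modelled option, ordered by `option_id`.
#'
#' @param scenario An `fsm_scenario`.
#' @param use_npv Passed to [annualized_capital()].
#' @return A tibble of class `fsm_cost_summary`; see [cost_breakdown()]
#'   for columns.
#' @examples
#' cs <- cost_summary(bhaluka_scenario())
#' cs[, c("option_id", "total_annual", "per_event")]
#' @export
cost_summary <- function(scenario, use_npv = FALSE) {
  demand <- compute_demand(scenario)
  out <- purrr::map_dfr(
    scenario$options$option_id,
    function(i) cost_breakdown(demand, scenario, i, use_npv)
  )
  class(out) <- c("fsm_cost_summary", class(out))
  out
}

#' Display-rounded cost report
#'
#' Rounds a cost summary the way planning reports are usually printed:
#' whole BDT, whole USD, two decimals for per-household USD values.
#'
#' @param costs A tibble from [cost_summary()] or [cost_breakdown()].
#' @return A tibble of the same shape with rounded money columns.
#' @export
round_cost_report <- function(costs) {
  usd_small <- c("per_event_usd", "per_household_year_usd",
                 "per_household_month_usd")
  dplyr::mutate(
    costs,
    dplyr::across(dplyr::where(is.numeric) &
                    !dplyr::any_of(c("option_id", usd_small)), round),
    dplyr::across(dplyr::any_of(usd_small), ~ round(.x, 2))
  )
}
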