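#' Work calendar for service operations
#'
#' Defines the operational time budget of one emptying team or vehicle.
#' The annual hour budget is the product of the three inputs and is the
#' denominator of every fleet-sizing calculation.
#'
#' @param hours_per_day Working hours per operational day.
#' @param days_per_week Operational days per week.
#' @param weeks_per_year Operational weeks per year.
#'
#' @return An object of class `fsm_calendar`: a list with the three inputs
#'   and the derived `hours_per_year`.
#' @examples
#' work_calendar() # 8 h x 4 d x 40 wk = 1,280 h/yr
#' @export
work_calendar <- function(hours_per_day = 8, days_per_week = 4,
                          weeks_per_year = 40) {
  check_positive(hours_per_day, "hours_per_day")
  check_positive(days_per_week, "days_per_week")
  check_positive(weeks_per_year, "weeks_per_year")
  structure(
    list(
      hours_per_day = hours_per_day,
      days_per_week = days_per_week,
      weeks_per_year = weeks_per_year,
      hours_per_year = hours_per_day * days_per_week * weeks_per_year
    ),
    class = "fsm_calendar"
  )
}

#' Latrine stock parameters
#'
#' Describes the stock of single-pit latrines whose sludge must be emptied
#' and transported: how many pits, how many users share each, how fast
#' sludge accumulates and how much a pit effectively holds.
#'
#' The defaults describe Bhaluka subdistrict, Bangladesh. The effective
#' accumulation rate (0.1077 L/person/day) and effective pit volume
#' (733.1 L) are back-calculated from the subdistrict's annual totals
#' (15,219 m3/yr over 77,413 latrines with 5 users each; 20,760 emptying
#' events/yr); the locally measured nominal rate is 0.11 L/person/day and
#' may be supplied instead.
#'
#' @param n_latrines Number of single-pit latrines in the planning area.
#' @param users_per_latrine Mean number of users per latrine (shared use
#'   makes this exceed household size).
#' @param accumulation_rate Sludge accumulation, litres/person/day.
#' @param pit_volume Effective pit volume emptied per event, litres.
#'
#' @return An object of class `fsm_stock`.
#' @examples
#' latrine_stock()
#' latrine_stock(n_latrines = 1000, accumulation_rate = 0.11)
#' @export
latrine_stock <- function(n_latrines = 77413, users_per_latrine = 5,
                          accumulation_rate = 0.1077, pit_volume = 733.1) {
  if (!is.numeric(n_latrines) || length(n_latrines) != 1 ||
      is.na(n_latrines) || n_latrines < 0) {
    stop("`n_latrines` must be a single nonnegative number.", call. = FALSE)
  }
  check_positive(users_per_latrine, "users_per_latrine")
  check_positive(accumulation_rate, "accumulation_rate")
  check_positive(pit_volume, "pit_volume")
  if (users_per_latrine < 1) {
    stop("`users_per_latrine` must be at least 1.", call. = FALSE)
  }
  structure(
    list(
      n_latrines = n_latrines,
      users_per_latrine = users_per_latrine,
      accumulation_rate = accumulation_rate,
      pit_volume = pit_volume
    ),
    class = "fsm_stock"
  )
}

#' Emptying technology
#'
#' Per-unit performance and cost parameters of a pit-emptying technology.
#' The crew hourly rate is derived from crew composition and wage rates;
#' the annualised capital cost per unit is an input (see
#' [npv_annualize()] for an internally consistent alternative).
#'
#' @param name Technology label.
#' @param prep_time Site preparation time per event, minutes.
#' @param empty_time Emptying time for a full pit, minutes.
#' @param crew_skilled,crew_unskilled Crew members per unit by skill class.
#' @param skilled_rate,unskilled_rate Wages, BDT/hour.
#' @param capital_cost Purchase cost per unit, BDT.
#' @param replacement_period Capital replacement period, years.
#' @param capital_maintenance_frac Capital maintenance, fraction of capital
#'   over the replacement cycle.
#' @param wear_frac_per_year Operational wear and tear, fraction of capital
#'   per year.
#' @param annualized_capital Annualised capital cost per unit, BDT/year
#'   (servicing, maintenance and wear folded in).
#'
#' @return An object of class `fsm_emptying_tech` with derived `crew_rate`
#'   (BDT/h) and `crew_size`.
#' @examples
#' emptying_technology("manual", prep_time = 30, empty_time = 150,
#'   crew_skilled = 2, crew_unskilled = 1, capital_cost = 1000,
#'   replacement_period = 3, annualized_capital = 156)
#' @export
emptying_technology <- function(name, prep_time, empty_time,
                                crew_skilled, crew_unskilled = 0,
                                skilled_rate = 20, unskilled_rate = 15,
                                capital_cost = 0, replacement_period = 1,
                                capital_maintenance_frac = 1,
                                wear_frac_per_year = 0.1,
                                annualized_capital = 0) {
  stopifnot(prep_time >= 0, empty_time >= 0, crew_skilled >= 0,
            crew_unskilled >= 0, capital_cost >= 0)
  structure(
    list(
      name = name,
      prep_time = prep_time,
      empty_time = empty_time,
      crew_skilled = crew_skilled,
      crew_unskilled = crew_unskilled,
      skilled_rate = skilled_rate,
      unskilled_rate = unskilled_rate,
      crew_size = crew_skilled + crew_unskilled,
      crew_rate = crew_skilled * skilled_rate + crew_unskilled * unskilled_rate,
      capital_cost = capital_cost,
      replacement_period = replacement_period,
      capital_maintenance_frac = capital_maintenance_frac,
      wear_frac_per_year = wear_frac_per_year,
      annualized_capital = annualized_capital
    ),
    class = "fsm_emptying_tech"
  )
}

#' Transport technology
#'
#' Per-unit performance and cost parameters of a sludge transport vehicle.
#' Handling time (loading at the pit or transfer point, unloading at the
#' destination) is charged once per trip end. The per-kilometre operating
#' rate is `fuel_use * fuel_price + consumables`.
#'
#' @param name Vehicle label.
#' @param capacity Load capacity, litres.
#' @param load_time Loading/emptying time per handling event, minutes.
#' @param speed_track Speed on unmetalled tracks, km/h (`NA` if the vehicle
#'   cannot use tracks).
#' @param speed_road Speed on metalled roads, km/h.
#' @param crew_skilled,crew_unskilled Crew per vehicle by skill class.
#' @param skilled_rate,unskilled_rate Wages, BDT/hour.
#' @param fuel_use Fuel consumption, litres/km.
#' @param consumables Other operating consumables, BDT/km.
#' @param capital_cost Purchase cost per vehicle, BDT.
#' @param replacement_period Capital replacement period, years.
#' @param capital_maintenance_frac Capital maintenance, fraction of capital.
#' @param wear_frac_per_year Wear and tear, fraction of capital per year.
#' @param annualized_capital Annualised capital cost per vehicle, BDT/year.
#'
#' @return An object of class `fsm_transport_tech` with derived `crew_rate`
#'   and `crew_size`.
#' @export
transport_technology <- function(name, capacity, load_time,
                                 speed_track = NA_real_, speed_road,
                                 crew_skilled = 1, crew_unskilled = 1,
                                 skilled_rate = 20, unskilled_rate = 15,
                                 fuel_use = 0, consumables = 0,
                                 capital_cost = 0, replacement_period = 1,
                                 capital_maintenance_frac = 1,
                                 wear_frac_per_year = 0.1,
                                 annualized_capital = 0) {
  check_positive(capacity, "capacity")
  stopifnot(load_time >= 0, speed_road > 0, fuel_use >= 0, consumables >= 0)
  structure(
    list(
      name = name,
      capacity = capacity,
      load_time = load_time,
      speed_track = speed_track,
      speed_road = speed_road,
      crew_skilled = crew_skilled,
      crew_unskilled = crew_unskilled,
      crew_size = crew_skilled + crew_unskilled,
      crew_rate = crew_skilled * skilled_rate + crew_unskilled * unskilled_rate,
      fuel_use = fuel_use,
      consumables = consumables,
      capital_cost = capital_cost,
      replacement_period = replacement_period,
      capital_maintenance_frac = capital_maintenance_frac,
      wear_frac_per_year = wear_frac_per_year,
      annualized_capital = annualized_capital
    ),
    class = "fsm_transport_tech"
  )
}

#' One-way route leg
#'
#' @param track_km One-way distance on unmetalled track, km.
#' @param road_km One-way distance on metalled road, km.
#' @return An object of class `fsm_route_leg`.
#' @examples
#' route_leg(track_km = 3.5, road_km = 0)
#' @export
route_leg <- function(track_km = 0, road_km = 0) {
  stopifnot(track_km >= 0, road_km >= 0)
  structure(list(track_km = track_km, road_km = road_km),
            class = "fsm_route_leg")
}

#' Financial parameters
#'
#' @param discount_rate Annual discount rate (fraction).
#' @param horizon Operational planning horizon, years.
#' @param fx Exchange rate, BDT per USD.
#' @param fuel_price Fuel price, BDT/litre.
#' @return An object of class `fsm_finance`.
#' @export
finance_params <- function(discount_rate = 0.11, horizon = 25, fx = 78,
                           fuel_price = 68) {
  stopifnot(discount_rate >= 0, horizon >= 1, fx > 0, fuel_price >= 0)
  structure(
    list(discount_rate = discount_rate, horizon = horizon, fx = fx,
         fuel_price = fuel_price),
    class = "fsm_finance"
  )
}

#' Service scenario
#'
#' Bundles everything needed to size and cost an emptying-and-transport
#' service: the latrine stock, work calendar, technologies, route legs,
#' financial parameters and the modelled technology options.
#'
#' @param stock An [latrine_stock()] object.
#' @param calendar A [work_calendar()] object.
#' @param emptying Named list of [emptying_technology()] objects.
#' @param transport Named list of [transport_technology()] objects; a
#'   `truck` (first-leg vehicle) and optionally a `tanker` (second-leg
#'   bulk vehicle) are expected by the option definitions.
#' @param leg_first One-way village-to-union leg ([route_leg()]).
#' @param leg_second One-way union-to-subdistrict leg ([route_leg()]).
#' @param finance A [finance_params()] object.
#' @param options Tibble with columns `option_id`, `emptying_tech` (name in
#'   `emptying`), `haul_mode` (`"direct"` or `"transfer"`). Direct haul
#'   drives the concatenated leg village-to-subdistrict with trucks only;
#'   transfer splits the haul at the union, trucks on the first leg and
#'   tankers on the second.
#'
#' @return An object of class `fsm_scenario`.
#' @seealso [bhaluka_scenario()] for the fully parameterised default.
#' @export
fsm_scenario <- function(stock, calendar, emptying, transport,
                         leg_first, leg_second, finance = finance_params(),
                         options = NULL) {
  stopifnot(inherits(stock, "fsm_stock"), inherits(calendar, "fsm_calendar"),
            inherits(leg_first, "fsm_route_leg"),
            inherits(leg_second, "fsm_route_leg"),
            inherits(finance, "fsm_finance"))
  if (is.null(options)) {
    options <- tibble::tibble(
      option_id = seq_along(emptying),
      emptying_tech = names(emptying),
      haul_mode = "direct"
    )
  }
  stopifnot(all(options$haul_mode %in% c("direct", "transfer")),
            all(options$emptying_tech %in% names(emptying)))
  structure(
    list(stock = stock, calendar = calendar, emptying = emptying,
         transport = transport, leg_first = leg_first,
         leg_second = leg_second, finance = finance, options = options),
    class = "fsm_scenario"
  )
}

#' Bhaluka subdistrict scenario fixture
#'
#' The fully parameterised planning scenario for Bhaluka subdistrict,
#' Bangladesh: 77,413 single-pit latrines, manual and diaphragm-pump
#' emptying, barrel-truck and 15,000-L tanker transport, population-weighted
#' average route legs of 3.5 km track (village to union) and 8.9 km road
#' (union to subdistrict), a 1,280 h/yr work calendar, and the four
#' modelled technology options (1: manual + direct trucks, 2: manual +
#' truck/tanker transfer, 3: diaphragm + direct trucks, 4: diaphragm +
#' truck/tanker transfer).
#'
#' @param ... Named overrides passed to [latrine_stock()] (e.g.
#'   `n_latrines`), applied on top of the Bhaluka defaults.
#' @return An `fsm_scenario` object.
#' @examples
#' scen <- bhaluka_scenario()
#' compute_demand(scen$stock)
#' @export
bhaluka_scenario <- function(...) {
  stock_args <- utils::modifyList(
    list(n_latrines = 77413, users_per_latrine = 5,
         accumulation_rate = 0.1077, pit_volume = 733.1),
    list(...)
  )
  fsm_scenario(
    stock = do.call(latrine_stock, stock_args),
    calendar = work_calendar(8, 4, 40),
    emptying = list(
      manual = emptying_technology(
        "manual", prep_time = 30, empty_time = 150,
        crew_skilled = 2, crew_unskilled = 1,
        capital_cost = 1000, replacement_period = 3,
        capital_maintenance_frac = 1, wear_frac_per_year = 0.10,
        annualized_capital = 156),
      diaphragm = emptying_technology(
        "diaphragm", prep_time = 15, empty_time = 20,
        crew_skilled = 1, crew_unskilled = 0,
        capital_cost = 30000, replacement_period = 5,
        capital_maintenance_frac = 1, wear_frac_per_year = 0.15,
        annualized_capital = 3909)
    ),
    transport = list(
      truck = transport_technology(
        "truck", capacity = 120, load_time = 30,
        speed_track = 10, speed_road = 30,
        fuel_use = 0.1, consumables = 0.1,
        capital_cost = 624000, replacement_period = 7.5,
        capital_maintenance_frac = 1, wear_frac_per_year = 0.10,
        annualized_capital = 46124),
      tanker = transport_technology(
        "tanker", capacity = 15000, load_time = 60,
        speed_track = NA_real_, speed_road = 30,
        fuel_use = 0.2, consumables = 2,
        capital_cost = 1560000, replacement_period = 10,
        capital_maintenance_frac = 1, wear_frac_per_year = 0.15,
        annualized_capital = 154003)
    ),
    leg_first = route_leg(track_km = 3.5, road_km = 0),
    leg_second = route_leg(track_km = 0, road_km = 8.9),
    finance = finance_params(discount_rate = 0.11, horizon = 25, fx = 78,
                             fuel_price = 68),
    options = tibble::tibble(
      option_id = 1:4,
      emptying_tech = c("manual", "manual", "diaphragm", "diaphragm"),
      haul_mode = c("direct", "transfer", "direct", "transfer")
    )
  )
}

#' Per-union travel distances for Bhaluka subdistrict
#'
#' Average one-way travel distances by union, with village counts, as used
#' to derive the scenario's default route legs. The scenario defaults (3.5
#' and 8.9 km) are the published population-weighted averages; the
#' population weights themselves are not published, so
#' [weighted_average_distance()] with user weights is provided for
#' re-weighting.
#'
#' @return A tibble with columns `union`, `n_villages`,
#'   `village_to_subdistrict_km`, `village_to_union_km`,
#'   `union_to_subdistrict_km`.
#' @export
bhaluka_distances <- function() {
  tibble::tribble(
    ~union, ~n_villages, ~village_to_subdistrict_km, ~village_to_union_km,
    ~union_to_subdistrict_km,
    "Bhaluka",    6,  2.7, 2.7,  0.0,
    "Birunia",   12, 16.4, 7.2,  9.2,
    "Dakatia",   10, 15.5, 3.2, 12.3,
    "Dhitpur",    6,  8.4, 2.1,  6.3,
    "Habirbari",  7, 10.7, 2.4,  8.3,
    "Kachina",   11, 21.2, 4.9, 16.3,
    "Meduary",   11,  9.7, 3.0,  6.7,
    "Mallikbari",11,  9.6, 3.5,  6.2,
    "Rajai",     10, 11.6, 2.5,  9.1,
    "Uthura",     7, 13.9, 1.6, 12.3,
    "Bharadoba",  4,  5.8, 1.8,  4.0
  )
}

# internal validators ---------------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number.", name),
         call. = FALSE)
  }
  invisible(x)
}
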