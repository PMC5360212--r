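#' Hours required to empty one pit
#'
#' @param tech An [emptying_technology()].
#' @return Hours per emptying event (preparation plus emptying).
#' @examples
#' scen <- bhaluka_scenario()
#' emptying_event_hours(scen$emptying$manual)    # 3 h
#' emptying_event_hours(scen$emptying$diaphragm) # 0.583 h
#' @export
emptying_event_hours <- function(tech) {
  stopifnot(inherits(tech, "fsm_emptying_tech"))
  (tech$prep_time + tech$empty_time) / 60
}

#' Size the emptying fleet
#'
#' Number of emptying teams/units needed to serve the annual demand: total
#' task hours divided by the annual hour budget of one unit, rounded up.
#'
#' @param events_per_year Annual number of emptying events.
#' @param tech An [emptying_technology()].
#' @param calendar A [work_calendar()].
#' @return Integer unit count.
#' @export
size_emptying_fleet <- function(events_per_year, tech, calendar) {
  stopifnot(events_per_year >= 0, inherits(calendar, "fsm_calendar"))
  if (calendar$hours_per_year <= 0) {
    stop("Work calendar has a zero annual hour budget.", call. = FALSE)
  }
  as.integer(ceiling(events_per_year * emptying_event_hours(tech) /
                       calendar$hours_per_year))
}

#' Round-trip time of one transport trip
#'
#' Travel out and back over the leg at the vehicle's track and road speeds,
#' plus one handling event (loading or unloading, each taking the
#' vehicle's `load_time`) at each end of the trip.
#'
#' @param transport A [transport_technology()].
#' @param leg A one-way [route_leg()].
#' @param handling_ends Number of handling events per trip (default 2:
#'   load at origin, unload at destination).
#' @return Hours per round trip.
#' @examples
#' scen <- bhaluka_scenario()
#' trip_hours(scen$transport$truck, route_leg(3.5, 8.9)) # 2.293 h
#' @export
trip_hours <- function(transport, leg, handling_ends = 2) {
  stopifnot(inherits(transport, "fsm_transport_tech"),
            inherits(leg, "fsm_route_leg"), handling_ends >= 0)
  travel <- 0
  if (leg$track_km > 0) {
    if (is.na(transport$speed_track) || transport$speed_track <= 0) {
      stop(sprintf("`%s` has no track speed but the leg has %.1f km of track.",
                   transport$name, leg$track_km), call. = FALSE)
    }
    travel <- travel + leg$track_km / transport$speed_track
  }
  if (leg$road_km > 0) {
    if (is.na(transport$speed_road) || transport$speed_road <= 0) {
      stop("Zero road speed with a nonzero road distance.", call. = FALSE)
    }
    travel <- travel + leg$road_km / transport$speed_road
  }
  2 * travel + handling_ends * transport$load_time / 60
}

# Resolve the legs each vehicle stage drives for a haul mode. Direct haul
# concatenates both legs into one truck trip; transfer splits at the union.
stage_legs <- function(scenario, haul_mode) {
  if (haul_mode == "direct") {
    list(truck = route_leg(
      track_km = scenario$leg_first$track_km + scenario$leg_second$track_km,
      road_km = scenario$leg_first$road_km + scenario$leg_second$road_km
    ))
  } else {
    list(truck = scenario$leg_first, tanker = scenario$leg_second)
  }
}

#' Size the transport fleet for one option
#'
#' Annual trips per stage are the annual sludge volume divided by the
#' vehicle capacity (kept fractional; only unit counts are rounded up).
#' In transfer mode both the truck stage (village to union) and the tanker
#' stage (union to subdistrict) carry the full annual volume.
#'
#' @param annual_volume_l Annual sludge volume, litres.
#' @param scenario An `fsm_scenario`.
#' @param haul_mode `"direct"` or `"transfer"`.
#' @return A one-row tibble: `trucks`, `tankers`, `truck_trips`,
#'   `tanker_trips`, `truck_hours`, `tanker_hours`, `truck_km`, `tanker_km`
#'   (annual task hours and round-trip kilometres per stage).
#' @export
size_transport_fleet <- function(annual_volume_l, scenario,
                                 haul_mode = c("direct", "transfer")) {
  haul_mode <- match.arg(haul_mode)
  stopifnot(annual_volume_l >= 0)
  hpy <- scenario$calendar$hours_per_year
  legs <- stage_legs(scenario, haul_mode)
  out <- list(trucks = 0L, tankers = 0L, truck_trips = 0, tanker_trips = 0,
              truck_hours = 0, tanker_hours = 0, truck_km = 0, tanker_km = 0)
  for (stage in names(legs)) {
    veh <- scenario$transport[[stage]]
    if (is.null(veh)) {
      stop(sprintf("Scenario has no `%s` transport technology.", stage),
           call. = FALSE)
    }
    if (veh$capacity <= 0) stop("Vehicle capacity must be positive.",
                                call. = FALSE)
    trips <- annual_volume_l / veh$capacity
    hours <- trips * trip_hours(veh, legs[[stage]])
    out[[paste0(stage, "_trips")]] <- trips
    out[[paste0(stage, "_hours")]] <- hours
    out[[paste0(stage, "_km")]] <-
      trips * 2 * (legs[[stage]]$track_km + legs[[stage]]$road_km)
    out[[paste0(stage, "s")]] <- as.integer(ceiling(hours / hpy))
  }
  tibble::as_tibble(out)
}

#' Size the full fleet for one modelled option
#'
#' Runs the demand through emptying- and transport-fleet sizing for one of
#' the scenario's technology options and attaches total staffing.
#'
#' @param demand A demand tibble from [compute_demand()] (or an
#'   `fsm_scenario`, in which case demand is computed from its stock).
#' @param scenario An `fsm_scenario`.
#' @param option_id Which row of `scenario$options` to size.
#' @return A one-row tibble (`fleet plan`): option metadata, unit counts
#'   (`emptying_units`, `trucks`, `tankers`), annual task hours and
#'   kilometres per stage, and `staffing`.
#' @examples
#' scen <- bhaluka_scenario()
#' size_fleet(compute_demand(scen), scen, option_id = 4)
#' @export
size_fleet <- function(demand, scenario, option_id) {
  if (inherits(demand, "fsm_scenario")) {
    scenario <- demand
    demand <- compute_demand(scenario)
  }
  opt <- scenario$options[scenario$options$option_id == option_id, ]
  if (nrow(opt) != 1) stop("Unknown `option_id`.", call. = FALSE)
  tech <- scenario$emptying[[opt$emptying_tech]]
  units <- size_emptying_fleet(demand$events_per_year, tech,
                               scenario$calendar)
  tr <- size_transport_fleet(demand$annual_volume_l, scenario, opt$haul_mode)
  plan <- dplyr::bind_cols(
    tibble::tibble(
      option_id = option_id,
      emptying_tech = opt$emptying_tech,
      haul_mode = opt$haul_mode,
      emptying_units = units,
      emptying_hours = demand$events_per_year * emptying_event_hours(tech)
    ),
    tr
  )
  plan$staffing <- total_staffing(plan, scenario)
  plan
}

#' Jobs created or maintained by a fleet plan
#'
#' Staffing is the standing fleet times its crew size: every sized unit is
#' crewed whether or not it is fully utilised.
#'
#' @param plan A fleet-plan tibble from [size_fleet()].
#' @param scenario An `fsm_scenario`.
#' @return Total persons employed.
#' @export
total_staffing <- function(plan, scenario) {
  tech <- scenario$emptying[[plan$emptying_tech]]
  plan$emptying_units * tech$crew_size +
    plan$trucks * scenario$transport$truck$crew_size +
    plan$tankers * scenario$transport$tanker$crew_size
}

#' Fleet summary over all options
#'
#' @param scenario An `fsm_scenario`.
#' @return One fleet-plan row per option.
#' @export
fleet_summary <- function(scenario) {
  demand <- compute_demand(scenario)
  purrr::map_dfr(scenario$options$option_id,
                 function(i) size_fleet(demand, scenario, i))
}

#' Weighted average distance
#'
#' Weighted mean of a distance column, e.g. to aggregate per-union average
#' distances into a planning-area average using village counts or
#' population weights.
#'
#' @param data A data frame of per-unit distances.
#' @param distance Column holding distances (tidy-eval).
#' @param weight Column holding weights (tidy-eval); omit for the
#'   unweighted mean.
#' @return The weighted average, km.
#' @examples
#' weighted_average_distance(bhaluka_distances(), village_to_union_km,
#'                           n_villages)
#' @export
weighted_average_distance <- function(data, distance, weight = NULL) {
  d <- dplyr::pull(data, {{ distance }})
  w <- rlang::enquo(weight)
  w <- if (rlang::quo_is_null(w)) rep(1, length(d)) else
    dplyr::pull(data, !!w)
  if (length(d) != length(w)) stop("Distances and weights differ in length.",
                                   call. = FALSE)
  if (all(w == 0)) stop("All weights are zero.", call. = FALSE)
  sum(w * d) / sum(w)
}
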