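# Shared fixtures built in code.

bhaluka <- bhaluka_scenario()
bhaluka_demand <- compute_demand(bhaluka)

# A deliberately simple scenario for brute-force logistics checks:
# trips take a whole number of hours that divides the daily budget, so a
# trip-by-trip simulation and the closed-form ceiling must agree exactly.
toy_scenario <- function(capacity = 100, road_km = 30, speed = 30,
                         load_min = 0, hours_per_day = 8) {
  fsm_scenario(
    stock = latrine_stock(n_latrines = 10, users_per_latrine = 5,
                          accumulation_rate = 0.11, pit_volume = 500),
    calendar = work_calendar(hours_per_day, 1, 1),
    emptying = list(
      pump = emptying_technology("pump", prep_time = 30, empty_time = 30,
                                 crew_skilled = 1, annualized_capital = 10)
    ),
    transport = list(
      truck = transport_technology("truck", capacity = capacity,
                                   load_time = load_min, speed_track = 10,
                                   speed_road = speed, fuel_use = 0.1,
                                   consumables = 0.1, capital_cost = 1000,
                                   annualized_capital = 100),
      tanker = transport_technology("tanker", capacity = capacity * 10,
                                    load_time = load_min, speed_road = speed,
                                    fuel_use = 0.2, consumables = 2,
                                    capital_cost = 5000,
                                    annualized_capital = 500)
    ),
    leg_first = route_leg(track_km = 0, road_km = road_km / 2),
    leg_second = route_leg(track_km = 0, road_km = road_km / 2),
    options = tibble::tibble(option_id = 1:2, emptying_tech = "pump",
                             haul_mode = c("direct", "transfer"))
  )
}

# Trip-by-trip simulation of fleet needs: vehicles work through whole
# trips against a fixed annual hour budget; a new vehicle is opened when
# the current one cannot finish another full trip.
simulate_fleet_size <- function(n_trips, hours_per_trip, hours_per_year) {
  trips_per_vehicle <- floor(hours_per_year / hours_per_trip)
  if (n_trips == 0) return(0L)
  as.integer(ceiling(n_trips / trips_per_vehicle))
}
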