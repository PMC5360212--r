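test_that("per-event hours follow the technology time budgets", {
  expect_equal(emptying_event_hours(bhaluka$emptying$manual), 3)
  expect_equal(emptying_event_hours(bhaluka$emptying$diaphragm), 35 / 60)
  zero <- emptying_technology("instant", 0, 0, crew_skilled = 1)
  expect_equal(emptying_event_hours(zero), 0)
})

test_that("emptying fleet sizes match the published teams", {
  cal <- bhaluka$calendar
  expect_equal(cal$hours_per_year, 1280)
  expect_equal(size_emptying_fleet(20760, bhaluka$emptying$manual, cal), 49L)
  expect_equal(size_emptying_fleet(20760, bhaluka$emptying$diaphragm, cal),
               10L)
  expect_equal(size_emptying_fleet(0, bhaluka$emptying$manual, cal), 0L)
  broken <- structure(list(hours_per_year = 0), class = "fsm_calendar")
  expect_error(size_emptying_fleet(10, bhaluka$emptying$manual, broken),
               "hour budget")
})

test_that("trip hours combine round-trip travel and handling at both ends", {
  truck <- bhaluka$transport$truck
  tanker <- bhaluka$transport$tanker
  expect_equal(trip_hours(truck, route_leg(3.5, 8.9)),
               2 * (3.5 / 10 + 8.9 / 30) + 1)
  expect_equal(trip_hours(truck, route_leg(3.5, 0)), 0.7 + 1)
  expect_equal(trip_hours(tanker, route_leg(0, 8.9)), 2 * 8.9 / 30 + 2)
  # tankers have no track speed, so a track leg is an error
  expect_error(trip_hours(tanker, route_leg(3.5, 0)), "track")
})

test_that("transport fleet sizes match the published fleets", {
  vol <- bhaluka_demand$annual_volume_l
  direct <- size_transport_fleet(vol, bhaluka, "direct")
  expect_equal(direct$trucks, 228L)
  expect_equal(direct$tankers, 0L)
  transfer <- size_transport_fleet(vol, bhaluka, "transfer")
  expect_equal(transfer$trucks, 169L)
  expect_equal(transfer$tankers, 3L)
  expect_equal(transfer$tanker_trips, vol / 15000)
  none <- size_transport_fleet(0, bhaluka, "transfer")
  expect_equal(none$trucks + none$tankers, 0L)
})

test_that("fleet summary reproduces unit counts and staffing for all options", {
  fs <- fleet_summary(bhaluka)
  expect_equal(fs$emptying_units, c(49L, 49L, 10L, 10L))
  expect_equal(fs$trucks, c(228L, 169L, 228L, 169L))
  expect_equal(fs$tankers, c(0L, 3L, 0L, 3L))
  expect_equal(fs$staffing, c(603L, 491L, 466L, 354L))
  empty_plan <- size_fleet(compute_demand(latrine_stock(n_latrines = 0)),
                           bhaluka, 1)
  expect_equal(total_staffing(empty_plan, bhaluka), 0L)
})

test_that("unit counts satisfy the ceiling property and monotonicity", {
  hpy <- bhaluka$calendar$hours_per_year
  vols <- seq(0.5e6, 2e7, length.out = 12)
  prev <- c(trucks = -1L, tankers = -1L)
  for (v in vols) {
    tr <- size_transport_fleet(v, bhaluka, "transfer")
    for (stage in c("truck", "tanker")) {
      units <- tr[[paste0(stage, "s")]]
      req <- tr[[paste0(stage, "_hours")]] / hpy
      expect_lt(units - 1, req)
      expect_gte(units, req)
    }
    expect_gte(tr$trucks, prev[["trucks"]])
    expect_gte(tr$tankers, prev[["tankers"]])
    prev <- c(trucks = tr$trucks, tankers = tr$tankers)
  }
})

test_that("faster vehicles never take longer per trip", {
  leg <- route_leg(3.5, 8.9)
  speeds <- c(10, 20, 30, 50)
  hours <- sapply(speeds, function(s) {
    veh <- transport_technology("t", capacity = 120, load_time = 30,
                                speed_track = s, speed_road = 30)
    trip_hours(veh, leg)
  })
  expect_true(all(diff(hours) <= 0))
})

test_that("transfer mode needs no more trucks than direct when its leg is shorter", {
  for (v in c(1e6, 5e6, 15215719)) {
    expect_lte(size_transport_fleet(v, bhaluka, "transfer")$trucks,
               size_transport_fleet(v, bhaluka, "direct")$trucks)
  }
})

test_that("closed-form fleet sizes agree with a trip-by-trip simulation", {
  scen <- toy_scenario() # 2 h/trip against an 8 h budget
  hpy <- scen$calendar$hours_per_year
  for (n_trips in c(0, 1, 4, 5, 17, 40)) {
    vol <- n_trips * scen$transport$truck$capacity
    tr <- size_transport_fleet(vol, scen, "direct")
    tph <- trip_hours(scen$transport$truck,
                      route_leg(0, 30)) # concatenated direct leg
    expect_equal(tr$trucks, simulate_fleet_size(n_trips, tph, hpy))
  }
})

test_that("weighted average distance matches hand-computed aggregates", {
  dist <- bhaluka_distances()
  expect_equal(weighted_average_distance(dist, village_to_union_km),
               sum(dist$village_to_union_km) / 11)
  expect_equal(weighted_average_distance(dist, village_to_union_km),
               34.9 / 11)
  one <- dist[3, ]
  expect_equal(weighted_average_distance(one, village_to_union_km,
                                         n_villages),
               one$village_to_union_km)
  two <- tibble::tibble(d = c(2, 4), w = c(1, 1))
  expect_equal(weighted_average_distance(two, d, w), 3)
  expect_error(weighted_average_distance(tibble::tibble(d = 1, w = 0), d, w),
               "zero")
})
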