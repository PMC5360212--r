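printed_t7 <- tibble::tibble(
  option_id = 1:4,
  total_capital = c(142321000, 110185000, 142572000, 110436000),
  annualized_capital = c(10523891, 8264596, 10555314, 8296020),
  labour = c(13595855, 11061555, 10412666, 7878366),
  operating = c(21654197, 6402234, 21654197, 6402234),
  total_annual = c(45773943, 25728385, 42622178, 22576620)
)

test_that("NPV annualisation follows the replacement-cycle cash flow", {
  expect_equal(npv_annualize(1000, 3, finance_params(discount_rate = 0)),
               9000 / 25)
  expect_equal(npv_annualize(1000, 3, finance_params(discount_rate = 0.11)),
               139.9, tolerance = 1e-3)
  # a single purchase when the asset outlives the horizon
  expect_equal(npv_annualize(1000, 30, finance_params(discount_rate = 0)),
               1000 / 25)
  expect_error(npv_annualize(1000, 0, finance_params()), "positive")
})

test_that("capital totals are exact and annualised capital matches to 0.1%", {
  cs <- cost_summary(bhaluka)
  expect_equal(cs$total_capital, printed_t7$total_capital)
  expect_equal(cs$annualized_capital, printed_t7$annualized_capital,
               tolerance = 1e-3)
  empty <- size_fleet(compute_demand(latrine_stock(n_latrines = 0)),
                      bhaluka, 1)
  expect_equal(total_capital(empty, bhaluka), 0)
  expect_equal(annualized_capital(empty, bhaluka), 0)
})

test_that("labour charged on task hours matches the published cells", {
  cs <- cost_summary(bhaluka)
  expect_equal(cs$labour, printed_t7$labour, tolerance = 1e-3)
})

test_that("operating costs use the per-km fuel+consumable rates", {
  fin <- bhaluka$finance
  truck <- bhaluka$transport$truck
  tanker <- bhaluka$transport$tanker
  expect_equal(truck$fuel_use * fin$fuel_price + truck$consumables, 6.9)
  expect_equal(tanker$fuel_use * fin$fuel_price + tanker$consumables, 15.6)
  cs <- cost_summary(bhaluka)
  expect_equal(cs$operating, printed_t7$operating, tolerance = 5e-3)
})

test_that("totals decompose exactly and reproduce the published ordering", {
  cs <- cost_summary(bhaluka)
  expect_equal(cs$total_annual,
               cs$annualized_capital + cs$labour + cs$operating)
  expect_equal(cs$total_annual, printed_t7$total_annual, tolerance = 5e-3)
  totals <- setNames(cs$total_annual, cs$option_id)
  expect_true(totals["4"] < totals["2"] &&
                totals["2"] < totals["3"] &&
                totals["3"] < totals["1"])
  expect_equal(cs$total_annual_usd, cs$total_annual / 78)
})

test_that("tariffs round to the published per-event and per-household values", {
  cb <- round_cost_report(cost_breakdown(bhaluka_demand, bhaluka, 4))
  expect_equal(cb$per_event, 1088)
  expect_equal(cb$per_household_month, 24)
  expect_equal(cb$per_household_month_usd, 0.31)
})

test_that("doubling the fuel price doubles the fuel share and nothing else", {
  dear_fuel <- bhaluka
  dear_fuel$finance <- finance_params(fuel_price = 2 * 68)
  plan <- size_fleet(bhaluka_demand, bhaluka, 1)
  base_op <- operating_cost(plan, bhaluka)
  dear_op <- operating_cost(plan, dear_fuel)
  fuel_share <- plan$truck_km * 0.1 * 68
  expect_equal(dear_op - base_op, fuel_share)
  expect_equal(labour_cost(plan, dear_fuel), labour_cost(plan, bhaluka))
  expect_equal(annualized_capital(plan, dear_fuel),
               annualized_capital(plan, bhaluka))
})

test_that("NPV-derived annualisation is available as an alternative", {
  cb_npv <- cost_breakdown(bhaluka_demand, bhaluka, 4, use_npv = TRUE)
  cb_tab <- cost_breakdown(bhaluka_demand, bhaluka, 4)
  expect_equal(cb_npv$labour, cb_tab$labour)
  expect_equal(cb_npv$operating, cb_tab$operating)
  expect_false(isTRUE(all.equal(cb_npv$annualized_capital,
                                cb_tab$annualized_capital)))
  per_truck <- npv_annualize(624000, 7.5, bhaluka$finance)
  per_tanker <- npv_annualize(1560000, 10, bhaluka$finance)
  per_pump <- npv_annualize(30000, 5, bhaluka$finance)
  expect_equal(cb_npv$annualized_capital,
               10 * per_pump + 169 * per_truck + 3 * per_tanker)
})
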