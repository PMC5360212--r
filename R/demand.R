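#' Annual emptying demand from latrine-stock parameters
#'
#' Converts a latrine stock into the annual demand it generates for an
#' emptying-and-transport service. Sludge accumulates at
#' `users_per_latrine * accumulation_rate` litres/day per pit, so a pit of
#' effective volume V fills every `V / (users * rate * 365)` years; each
#' fill is one emptying event of V litres. All internal volumes are in
#' litres; cubic metres are reported alongside for convenience.
#'
#' @param stock An [latrine_stock()] object (or an `fsm_scenario`, whose
#'   stock is used).
#'
#' @return A one-row tibble with columns `n_latrines`,
#'   `emptying_interval_yr`, `events_per_year`, `volume_per_event_l`,
#'   `annual_volume_l`, `annual_volume_m3`.
#' @examples
#' compute_demand(latrine_stock())        # Bhaluka defaults
#' compute_demand(latrine_stock(n_latrines = 1, accumulation_rate = 0.11))
#' @export
compute_demand <- function(stock) {
  if (inherits(stock, "fsm_scenario")) stock <- stock$stock
  stopifnot(inherits(stock, "fsm_stock"))
  daily_l <- stock$users_per_latrine * stock$accumulation_rate
  if (daily_l <= 0) {
    stop("Accumulation rate and users must be positive.", call. = FALSE)
  }
  interval <- stock$pit_volume / (daily_l * 365)
  annual_l <- stock$n_latrines * daily_l * 365
  tibble::tibble(
    n_latrines = stock$n_latrines,
    emptying_interval_yr = interval,
    events_per_year = stock$n_latrines / interval,
    volume_per_event_l = stock$pit_volume,
    annual_volume_l = annual_l,
    annual_volume_m3 = annual_l / 1000
  )
}
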