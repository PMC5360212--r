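#' Write a scenario to a YAML configuration file
#'
#' Serialises an `fsm_scenario` to a structured YAML file with sections
#' `stock`, `calendar`, `emptying`, `transport`, `routes`, `finance` and
#' `options`. Derived quantities (crew rates, annual hours) are not
#' written; they are recomputed on read, so a write/read round trip
#' reproduces the scenario exactly.
#'
#' @param scenario An `fsm_scenario`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_scenario(bhaluka_scenario(), f)
#' scen <- read_scenario(f)
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "fsm_scenario"))
  strip <- function(obj, drop) {
    out <- unclass(obj)
    out[setdiff(names(out), drop)]
  }
  cfg <- list(
    stock = strip(scenario$stock, character()),
    calendar = strip(scenario$calendar, "hours_per_year"),
    emptying = lapply(scenario$emptying, strip,
                      drop = c("crew_size", "crew_rate")),
    transport = lapply(scenario$transport, strip,
                       drop = c("crew_size", "crew_rate")),
    routes = list(
      leg_first = unclass(scenario$leg_first),
      leg_second = unclass(scenario$leg_second)
    ),
    finance = strip(scenario$finance, character()),
    options = lapply(seq_len(nrow(scenario$options)), function(i) {
      as.list(scenario$options[i, ])
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a scenario from a YAML configuration file
#'
#' @param path File written by [write_scenario()] (or hand-authored with
#'   the same sections).
#' @return An `fsm_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("stock", "calendar", "emptying", "transport", "routes",
              "finance", "options")
  missing_sections <- setdiff(needed, names(cfg))
  if (length(missing_sections)) {
    stop("Scenario config is missing section(s): ",
         paste(missing_sections, collapse = ", "), call. = FALSE)
  }
  as_num_na <- function(lst) {
    lapply(lst, function(v) if (is.null(v)) NA_real_ else v)
  }
  fsm_scenario(
    stock = do.call(latrine_stock, cfg$stock),
    calendar = do.call(work_calendar, cfg$calendar),
    emptying = lapply(cfg$emptying,
                      function(t) do.call(emptying_technology, as_num_na(t))),
    transport = lapply(cfg$transport,
                       function(t) do.call(transport_technology,
                                           as_num_na(t))),
    leg_first = do.call(route_leg, cfg$routes$leg_first),
    leg_second = do.call(route_leg, cfg$routes$leg_second),
    finance = do.call(finance_params, cfg$finance),
    options = dplyr::bind_rows(lapply(cfg$options, tibble::as_tibble))
  )
}
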