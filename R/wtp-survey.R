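#' Sample size for a clustered prevalence survey
#'
#' Standard design-based sample size for estimating a proportion:
#' `n = ceil( z^2 p (1 - p) / margin^2 * deff * (1 + nonresponse) )`,
#' where `deff` is the design effect inflating variance for cluster
#' sampling and `nonresponse` is a contingency margin.
#'
#' @param p Anticipated proportion (0.5 is the conservative default).
#' @param confidence Confidence level.
#' @param margin Absolute margin of error on the proportion.
#' @param deff Design effect for village-level clustering.
#' @param nonresponse Non-response contingency (fraction added on top).
#' @return Required number of households (integer).
#' @examples
#' sample_size_cv() # 807 under the default clustered design
#' sample_size_cv(deff = 1, nonresponse = 0) # 385, simple random sampling
#' @export
sample_size_cv <- function(p = 0.5, confidence = 0.95, margin = 0.05,
                           deff = 2, nonresponse = 0.05) {
  stopifnot(p > 0, p < 1, confidence > 0, confidence < 1, deff > 0,
            nonresponse >= 0)
  if (margin <= 0) stop("`margin` must be positive.", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / margin^2 * deff *
                       (1 + nonresponse)))
}

#' Tabulate double-bounded responses by bid vector
#'
#' Counts and row shares of the four response branches (no/no, no/yes,
#' yes/no, yes/yes) within each base-bid arm, the standard diagnostic
#' table for a double-bounded survey.
#'
#' @param data Survey data frame with `base_bid`, `y1`, `y2`.
#' @return A tibble with one row per base bid: `n`, branch counts
#'   `n_no_no` ... `n_yes_yes`, and percentage shares `pct_*` summing to
#'   100 within each row.
#' @examples
#' tabulate_responses(simulate_survey(seed = 1))
#' @export
tabulate_responses <- function(data) {
  stopifnot(all(c("base_bid", "y1", "y2") %in% names(data)))
  data |>
    dplyr::mutate(branch = dplyr::case_when(
      y1 == 0 & y2 == 0 ~ "no_no",
      y1 == 0 & y2 == 1 ~ "no_yes",
      y1 == 1 & y2 == 0 ~ "yes_no",
      TRUE ~ "yes_yes"
    )) |>
    dplyr::count(.data$base_bid, .data$branch) |>
    tidyr::pivot_wider(names_from = "branch", values_from = "n",
                       names_prefix = "n_", values_fill = 0L) |>
    (\(d) {
      for (b in c("n_no_no", "n_no_yes", "n_yes_no", "n_yes_yes")) {
        if (!b %in% names(d)) d[[b]] <- 0L
      }
      d
    })() |>
    dplyr::mutate(
      n = .data$n_no_no + .data$n_no_yes + .data$n_yes_no + .data$n_yes_yes,
      dplyr::across(dplyr::starts_with("n_"),
                    ~ ifelse(n > 0, 100 * .x / n, 0),
                    .names = "pct_{sub('n_', '', .col)}")
    ) |>
    dplyr::select("base_bid", "n", dplyr::starts_with("n_"),
                  dplyr::starts_with("pct_")) |>
    dplyr::arrange(.data$base_bid)
}

#' Published Bhaluka response tabulation
#'
#' The observed branch counts of the 1,091-household Bhaluka contingent
#' valuation survey, by bid vector: the empirical anchor for the
#' intercept-only WTP fit when the household-level microdata are not
#' available.
#'
#' @return A tibble with columns `base_bid`, `bid_up`, `bid_down`,
#'   `n_no_no`, `n_no_yes`, `n_yes_no`, `n_yes_yes`.
#' @seealso [counts_to_responses()] to expand into per-household rows.
#' @export
bhaluka_response_counts <- function() {
  tibble::tribble(
    ~base_bid, ~bid_up, ~bid_down, ~n_no_no, ~n_no_yes, ~n_yes_no, ~n_yes_yes,
    400,  600, 300,  27,  91, 127, 41,
    600,  700, 400,  73, 144,  38, 25,
    700,  800, 600, 167,  82,  21, 12,
    800, 1000, 700, 180,  31,  27,  5
  )
}

#' Expand branch counts into per-household response rows
#'
#' Inverse of [tabulate_responses()]: turns a per-bid-vector count table
#' into one row per household with the implied `(y1, y2)` pair, ready for
#' [fit_dbdc()].
#'
#' @param counts A tibble shaped like [bhaluka_response_counts()].
#' @return A survey tibble with columns `household_id`, `base_bid`,
#'   `bid_up`, `bid_down`, `y1`, `y2`, `weight` (all 1).
#' @examples
#' fit_dbdc(counts_to_responses(bhaluka_response_counts()))
#' @export
counts_to_responses <- function(counts) {
  branches <- tibble::tibble(
    branch = c("n_no_no", "n_no_yes", "n_yes_no", "n_yes_yes"),
    y1 = c(0L, 0L, 1L, 1L),
    y2 = c(0L, 1L, 0L, 1L)
  )
  out <- counts |>
    tidyr::pivot_longer(dplyr::all_of(branches$branch),
                        names_to = "branch", values_to = "n") |>
    dplyr::inner_join(branches, by = "branch") |>
    tidyr::uncount(.data$n) |>
    dplyr::select("base_bid", "bid_up", "bid_down", "y1", "y2")
  out$household_id <- seq_len(nrow(out))
  out$weight <- 1
  dplyr::relocate(out, "household_id")
}

#' Grid-search maximiser of the intercept-only WTP likelihood
#'
#' Exhaustive `(mu, sigma)` grid evaluation of the interval-censored
#' likelihood for intercept-only data. Slow by construction; intended as
#' an independent check on the gradient-based optimiser, not for routine
#' fitting.
#'
#' @param data Survey data frame (see [fit_dbdc()]).
#' @param mu_grid,sigma_grid Numeric grids to search over.
#' @param truncate_at_zero Passed to [response_to_interval()].
#' @return A list with `mu`, `sigma`, `loglik` at the grid maximum.
#' @export
grid_search_wtp <- function(data, mu_grid, sigma_grid,
                            truncate_at_zero = FALSE) {
  iv <- response_to_interval(data, truncate_at_zero)
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  best <- list(mu = NA_real_, sigma = NA_real_, loglik = -Inf)
  for (s in sigma_grid) {
    for (m in mu_grid) {
      ll <- sum(w * log(pmax(
        interval_prob(m, s, iv$wtp_lower, iv$wtp_upper), 1e-300)))
      if (ll > best$loglik) best <- list(mu = m, sigma = s, loglik = ll)
    }
  }
  best
}
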