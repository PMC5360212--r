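#' Bootstrap the mean WTP estimate
#'
#' Resamples the survey with replacement (households by default, whole
#' villages with `cluster`), refits, and summarises the replicate mean-WTP
#' estimates: bootstrap standard error, normal-approximation CI around the
#' full-sample point estimate, and the bias-corrected percentile CI.
#' Replicates whose refit fails or does not converge are dropped and
#' counted.
#'
#' @param data Survey data frame (see [fit_dbdc()]).
#' @param fit_fn Fitting function, [fit_dbdc()] (default) or [fit_sbdc()].
#' @param B Number of bootstrap replicates.
#' @param seed Random seed (required: every stochastic operation in this
#'   package takes one).
#' @param cluster Optional name of a cluster id column (e.g.
#'   `"village_id"`); resampling then draws whole clusters with
#'   replacement, reflecting village-level survey clustering.
#' @param level Confidence level.
#' @param ... Passed on to `fit_fn` (e.g. `covariates`).
#'
#' @return An object of class `wtp_boot`: a list with `point`, `se`,
#'   `ci_normal`, `ci_bias_corrected`, `replicates` (the replicate
#'   estimates), `n_failed`, `B`, `seed`.
#' @examples
#' survey <- simulate_survey(seed = 1)
#' bootstrap_wtp(survey, B = 20, seed = 2)
#' @export
bootstrap_wtp <- function(data, fit_fn = fit_dbdc, B = 100, seed,
                          cluster = NULL, level = 0.95, ...) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (B < 2) stop("`B` must be at least 2.", call. = FALSE)
  full <- fit_fn(data, ...)
  point <- full$mean_wtp

  set.seed(seed)
  draw <- function() {
    if (is.null(cluster)) {
      data[sample.int(nrow(data), replace = TRUE), , drop = FALSE]
    } else {
      ids <- unique(data[[cluster]])
      take <- sample(ids, length(ids), replace = TRUE)
      dplyr::bind_rows(lapply(take, function(i) {
        data[data[[cluster]] == i, , drop = FALSE]
      }))
    }
  }
  reps <- vapply(seq_len(B), function(b) {
    fit <- tryCatch(suppressWarnings(fit_fn(draw(), ...)),
                    error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) NA_real_ else fit$mean_wtp
  }, numeric(1))
  ok <- reps[is.finite(reps)]
  n_failed <- B - length(ok)
  if (length(ok) < 2) stop("Too few converged bootstrap replicates.",
                           call. = FALSE)

  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- stats::sd(ok)
  # bias-corrected percentile CI (BC, not accelerated)
  z0 <- stats::qnorm(pmin(pmax(mean(ok < point), 1 / (2 * length(ok))),
                          1 - 1 / (2 * length(ok))))
  probs <- stats::pnorm(c(2 * z0 - z, 2 * z0 + z))
  structure(
    list(
      point = point, se = se,
      ci_normal = point + c(-1, 1) * z * se,
      ci_bias_corrected = unname(stats::quantile(ok, probs)),
      replicates = ok, n_failed = n_failed, B = B, seed = seed,
      level = level, model = full$model
    ),
    class = "wtp_boot"
  )
}

#' @export
print.wtp_boot <- function(x, ...) {
  cat(sprintf("Bootstrap of mean WTP (%s, B = %d, %d failed)\n",
              x$model, x$B, x$n_failed))
  cat(sprintf("  point %.2f, SE %.2f\n", x$point, x$se))
  cat(sprintf("  normal CI [%.2f, %.2f]; bias-corrected CI [%.2f, %.2f]\n",
              x$ci_normal[1], x$ci_normal[2],
              x$ci_bias_corrected[1], x$ci_bias_corrected[2]))
  invisible(x)
}

#' @rdname glance.dbdc_fit
#' @export
glance.wtp_boot <- function(x, ...) {
  tibble::tibble(
    model = x$model, mean_wtp = x$point, se = x$se,
    ci_lower = x$ci_normal[1], ci_upper = x$ci_normal[2],
    bc_lower = x$ci_bias_corrected[1], bc_upper = x$ci_bias_corrected[2],
    n_replicates = length(x$replicates), n_failed = x$n_failed
  )
}
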