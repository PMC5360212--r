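#' Fit the double-bounded WTP model by maximum likelihood
#'
#' Maximises the interval-censored normal likelihood over `(beta, sigma)`
#' (internally parameterised as `(beta, log sigma)` so the scale stays
#' positive) with BFGS from a least-squares initialiser on interval
#' pseudo-midpoints, plus a dispersed second start; the better maximum
#' wins. Mean willingness to pay is the (weight-)averaged linear
#' predictor `mean(x)'beta`, with a delta-method standard error from the
#' inverse observed information.
#'
#' Perfectly collinear covariate columns are dropped with a warning (the
#' fit keeps all rows). At least two distinct response intervals are
#' required for `(mu, sigma)` to be identified.
#'
#' @param data Survey data frame with columns `base_bid`, `bid_up`,
#'   `bid_down`, `y1`, `y2`, optionally `weight`, plus any covariates.
#' @param covariates Character vector of covariate column names entering
#'   the linear predictor (an intercept is always included); `NULL` fits
#'   the intercept-only model.
#' @param weights Optional name of a frequency-weight column; `NULL`
#'   (default) fits unweighted.
#' @param truncate_at_zero Passed to [response_to_interval()].
#' @param start Optional named list with `beta` and `sigma` start values.
#' @param control Passed to [stats::optim()] (defaults: BFGS,
#'   `reltol 1e-10`, `maxit 500`).
#'
#' @return An object of class `dbdc_fit`: coefficients, `sigma`,
#'   `mean_wtp`, `se`, `ci_normal`, `loglik`, `vcov`, `n_used`,
#'   `converged`, `dropped_covariates`.
#' @seealso [fit_sbdc()] for the single-bound check, [bootstrap_wtp()]
#'   for resampled uncertainty.
#' @examples
#' survey <- simulate_survey(seed = 1)
#' fit <- fit_dbdc(survey)
#' glance(fit)
#' @export
fit_dbdc <- function(data, covariates = NULL, weights = NULL,
                     truncate_at_zero = FALSE, start = NULL,
                     control = list()) {
  iv <- response_to_interval(data, truncate_at_zero)
  x <- build_model_matrix(data, covariates)
  w <- resolve_weights(data, weights)
  if (any(!is.finite(x))) stop("Covariates contain non-finite values.",
                               call. = FALSE)

  branches <- paste(iv$y1, iv$y2)
  if (length(unique(branches)) < 2 ||
      nrow(unique(iv[, c("wtp_lower", "wtp_upper")])) < 2) {
    stop("All responses imply the same WTP interval; `sigma` is not ",
         "identified.", call. = FALSE)
  }

  drop <- drop_collinear(x)
  x <- drop$x
  p <- ncol(x)

  # pseudo-midpoint least-squares initialiser; open-ended intervals get a
  # midpoint one bid-spread beyond their finite bound
  spread <- stats::sd(iv$base_bid)
  if (!is.finite(spread) || spread == 0) spread <- max(iv$base_bid) / 2
  mid <- ifelse(is.finite(iv$wtp_lower) & is.finite(iv$wtp_upper),
                (iv$wtp_lower + iv$wtp_upper) / 2,
         ifelse(is.finite(iv$wtp_lower), iv$wtp_lower + spread,
                iv$wtp_upper - spread))
  b0 <- tryCatch(stats::lm.wfit(x, mid, w)$coefficients,
                 error = function(e) NULL)
  if (is.null(b0) || any(is.na(b0))) {
    b0 <- c(stats::weighted.mean(mid, w), rep(0, p - 1))
  }
  s0 <- max(stats::sd(mid), spread / 2, 1)

  starts <- list(c(b0, log(s0)))
  starts[[2]] <- c(stats::weighted.mean(iv$base_bid, w), rep(0, p - 1),
                   log(2 * s0))
  if (!is.null(start)) {
    starts <- c(list(c(start$beta, log(start$sigma))), starts)
  }

  negll <- function(par) {
    -dbdc_loglik_quiet(par[seq_len(p)], exp(par[p + 1]), x,
                       iv$wtp_lower, iv$wtp_upper, w)
  }
  control <- utils::modifyList(list(reltol = 1e-10, maxit = 500), control)
  fits <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, negll, method = "BFGS", control = control),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("Optimisation failed from all starts.",
                          call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  beta <- best$par[seq_len(p)]
  names(beta) <- colnames(x)
  sigma <- exp(best$par[p + 1])
  hess <- tryCatch(stats::optimHess(best$par, negll),
                   error = function(e) NULL)
  vc <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL)
  xbar <- drop(crossprod(w, x)) / sum(w)
  mean_wtp <- drop(xbar %*% beta)
  se <- if (!is.null(vc)) {
    g <- c(xbar, 0) # mean WTP does not depend on log sigma
    sqrt(max(drop(t(g) %*% vc %*% g), 0))
  } else NA_real_
  converged <- best$convergence == 0 && !is.null(vc) && is.finite(se)
  if (!converged) {
    warning("Double-bounded fit did not fully converge; inspect `converged`.",
            call. = FALSE)
  }

  structure(
    list(
      coefficients = beta, sigma = sigma, mean_wtp = mean_wtp, se = se,
      ci_normal = mean_wtp + c(-1, 1) * stats::qnorm(0.975) * se,
      loglik = -best$value, vcov = vc, n_used = nrow(x),
      converged = converged, dropped_covariates = drop$dropped,
      model = "dbdc", truncate_at_zero = truncate_at_zero,
      data = iv[, c("base_bid", "wtp_lower", "wtp_upper", "y1", "y2")],
      weights = w, xbar = xbar
    ),
    class = "dbdc_fit"
  )
}

# loglik without the floor warning (the optimiser roams freely early on)
dbdc_loglik_quiet <- function(beta, sigma, x, lower, upper, weights) {
  xb <- drop(as.matrix(x) %*% beta)
  p <- pmax(interval_prob(xb, sigma, lower, upper), 1e-12)
  sum(weights * log(p))
}

#' Fit the single-bound WTP model (probit on the base bid only)
#'
#' Discards the follow-up responses and fits a probit of the base-bid
#' response on the covariates and the bid:
#' `P(yes) = Phi(x'beta_r - bid/sigma)` in reduced form, so mean WTP is
#' recovered as `-mean(x)'beta_r / beta_bid`. Comparing this estimate with
#' the double-bounded one is the standard check for starting-point
#' (anchoring) bias; its standard error (delta method) is expected to be
#' larger because the follow-up information is discarded.
#'
#' @inheritParams fit_dbdc
#' @return An object of class `sbdc_fit` with the same core fields as
#'   [fit_dbdc()] (`mean_wtp`, `se`, `ci_normal`, `converged`, ...).
#' @examples
#' survey <- simulate_survey(seed = 1)
#' glance(fit_sbdc(survey))
#' @export
fit_sbdc <- function(data, covariates = NULL, weights = NULL) {
  x <- build_model_matrix(data, covariates)
  w <- resolve_weights(data, weights)
  drop <- drop_collinear(x)
  x <- drop$x
  xmat <- cbind(x, bid = data$base_bid)
  fit <- suppressWarnings(
    stats::glm.fit(xmat, data$y1, weights = w,
                   family = stats::binomial(link = "probit"))
  )
  cf <- fit$coefficients
  b_bid <- cf["bid"]
  if (!is.finite(b_bid) || abs(b_bid) < 1e-10) {
    stop("Bid coefficient is zero; WTP is undefined.", call. = FALSE)
  }
  separated <- any(abs(fit$fitted.values - 0.5) > 0.5 - 1e-8)
  beta_r <- cf[seq_len(ncol(x))]
  xbar <- drop(crossprod(w, x)) / sum(w)
  mean_wtp <- drop(-xbar %*% beta_r / b_bid)

  # delta method on (beta_r, b_bid)
  qr_w <- qr(xmat * sqrt(fit$weights))
  vc <- tryCatch(chol2inv(qr.R(qr_w)), error = function(e) NULL)
  se <- if (!is.null(vc)) {
    g <- c(-xbar / b_bid, drop(xbar %*% beta_r) / b_bid^2)
    sqrt(max(drop(t(g) %*% vc %*% g), 0))
  } else NA_real_
  converged <- fit$converged && !separated && is.finite(se)
  if (separated) {
    warning("Possible perfect separation in the single-bound probit.",
            call. = FALSE)
  }

  structure(
    list(
      coefficients = cf, sigma = -1 / b_bid, mean_wtp = mean_wtp, se = se,
      ci_normal = mean_wtp + c(-1, 1) * stats::qnorm(0.975) * se,
      loglik = -fit$deviance / 2, vcov = vc, n_used = nrow(x),
      converged = converged, dropped_covariates = drop$dropped,
      model = "sbdc", xbar = xbar
    ),
    class = "sbdc_fit"
  )
}

# shared helpers --------------------------------------------------------

build_model_matrix <- function(data, covariates) {
  n <- nrow(data)
  x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    missing_cols <- setdiff(covariates, names(data))
    if (length(missing_cols)) {
      stop("Covariate columns not found: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    x <- cbind(x, as.matrix(data[, covariates, drop = FALSE]))
  }
  x
}

resolve_weights <- function(data, weights) {
  if (is.null(weights)) return(rep(1, nrow(data)))
  if (!weights %in% names(data)) {
    stop(sprintf("Weight column `%s` not found.", weights), call. = FALSE)
  }
  w <- data[[weights]]
  if (any(w <= 0)) stop("Weights must be positive.", call. = FALSE)
  w
}

drop_collinear <- function(x) {
  qr_x <- qr(x)
  if (qr_x$rank == ncol(x)) return(list(x = x, dropped = character()))
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  dropped <- colnames(x)[-keep]
  warning("Dropping perfectly collinear covariate column(s): ",
          paste(dropped, collapse = ", "), call. = FALSE)
  list(x = x[, sort(keep), drop = FALSE], dropped = dropped)
}

# broom-style accessors --------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a WTP fit
#'
#' @param x A `dbdc_fit` or `sbdc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient plus the scale `sigma`.
#' @export
tidy.dbdc_fit <- function(x, ...) {
  est <- c(x$coefficients, sigma = x$sigma)
  se <- rep(NA_real_, length(est))
  if (!is.null(x$vcov)) {
    p <- length(x$coefficients)
    se[seq_len(p)] <- sqrt(pmax(diag(x$vcov)[seq_len(p)], 0))
    se[p + 1] <- x$sigma * sqrt(max(diag(x$vcov)[p + 1], 0)) # delta, log scale
  }
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = se)
}

#' @rdname tidy.dbdc_fit
#' @export
tidy.sbdc_fit <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else
    rep(NA_real_, length(x$coefficients))
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients), std.error = se)
}

#' Glance at a WTP fit
#'
#' @param x A `dbdc_fit` or `sbdc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `mean_wtp`, `se`, normal 95% CI bounds,
#'   `sigma`, `loglik`, `n_used`, `converged`.
#' @export
glance.dbdc_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, mean_wtp = x$mean_wtp, se = x$se,
    ci_lower = x$ci_normal[1], ci_upper = x$ci_normal[2],
    sigma = x$sigma, loglik = x$loglik, n_used = x$n_used,
    converged = x$converged
  )
}

#' @rdname glance.dbdc_fit
#' @export
glance.sbdc_fit <- glance.dbdc_fit

#' @export
print.dbdc_fit <- function(x, ...) {
  cat("Double-bounded dichotomous-choice WTP fit",
      "(interval-censored normal MLE)\n")
  cat(sprintf("  mean WTP: %.2f BDT (SE %.2f), 95%% CI [%.2f, %.2f]\n",
              x$mean_wtp, x$se, x$ci_normal[1], x$ci_normal[2]))
  cat(sprintf("  sigma: %.2f  loglik: %.2f  n: %d  converged: %s\n",
              x$sigma, x$loglik, x$n_used, x$converged))
  invisible(x)
}

#' @export
print.sbdc_fit <- function(x, ...) {
  cat("Single-bound (base bid only) probit WTP fit\n")
  cat(sprintf("  mean WTP: %.2f BDT (SE %.2f), 95%% CI [%.2f, %.2f]\n",
              x$mean_wtp, x$se, x$ci_normal[1], x$ci_normal[2]))
  cat(sprintf("  n: %d  converged: %s\n", x$n_used, x$converged))
  invisible(x)
}
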