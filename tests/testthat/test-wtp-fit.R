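published <- counts_to_responses(bhaluka_response_counts())

test_that("the optimiser agrees with a dense grid search on published counts", {
  fit <- fit_dbdc(published)
  oracle <- grid_search_wtp(published, mu_grid = seq(450, 560, by = 0.5),
                            sigma_grid = seq(120, 250, by = 0.5))
  expect_lt(abs(fit$mean_wtp - oracle$mu), 0.5)
  expect_lt(abs(fit$sigma - oracle$sigma), 0.5)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
  expect_true(fit$converged)
})

test_that("the fit agrees with an independent interval-regression oracle", {
  iv <- response_to_interval(published)
  surv_data <- data.frame(
    lower = ifelse(is.finite(iv$wtp_lower), iv$wtp_lower, NA),
    upper = ifelse(is.finite(iv$wtp_upper), iv$wtp_upper, NA)
  )
  oracle <- survival::survreg(
    survival::Surv(lower, upper, type = "interval2") ~ 1,
    data = surv_data, dist = "gaussian"
  )
  fit <- fit_dbdc(published)
  expect_equal(fit$mean_wtp, unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(fit$sigma, oracle$scale, tolerance = 1e-4)
})

test_that("the estimator recovers a known truth on a simulated survey", {
  survey <- simulate_survey(seed = 101)
  fit <- fit_dbdc(survey)
  expect_true(fit$converged)
  expect_lt(abs(fit$mean_wtp - 507), 3 * fit$se)
  expect_equal(fit$ci_normal,
               fit$mean_wtp + c(-1, 1) * qnorm(0.975) * fit$se)
})

test_that("shifting all bids and the latent WTP shifts the estimate exactly", {
  survey <- simulate_survey(seed = 7, covariates = FALSE)
  shift <- 250
  shifted <- dplyr::mutate(survey,
                           base_bid = base_bid + shift,
                           bid_up = bid_up + shift,
                           bid_down = bid_down + shift)
  f0 <- fit_dbdc(survey)
  f1 <- fit_dbdc(shifted)
  expect_equal(f1$mean_wtp, f0$mean_wtp + shift, tolerance = 1e-5)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-5)
})

test_that("frequency weights are equivalent to duplicating rows", {
  survey <- simulate_survey(
    survey_design(allocation = c(60, 60, 60, 60), n_villages = 8),
    seed = 5, covariates = FALSE
  )
  survey$weight <- rep(c(1, 2), length.out = nrow(survey))
  duplicated_rows <- survey[rep(seq_len(nrow(survey)), survey$weight), ]
  fw <- fit_dbdc(survey, weights = "weight")
  fd <- fit_dbdc(duplicated_rows)
  expect_equal(fw$mean_wtp, fd$mean_wtp, tolerance = 1e-5)
  expect_equal(fw$sigma, fd$sigma, tolerance = 1e-5)
})

test_that("covariate effects enter the mean and collinear columns are dropped", {
  survey <- simulate_survey(
    beta = c("(Intercept)" = 300, household_size = 40, brick_walls = 60),
    seed = 21
  )
  fit <- fit_dbdc(survey, covariates = c("household_size", "brick_walls"))
  expect_true(fit$converged)
  expect_lt(abs(fit$mean_wtp -
                  mean(300 + 40 * survey$household_size +
                         60 * survey$brick_walls)), 4 * fit$se)
  survey$dup <- 2 * survey$household_size
  expect_warning(
    fit2 <- fit_dbdc(survey, covariates = c("household_size", "dup")),
    "collinear"
  )
  expect_equal(fit2$dropped_covariates, "dup")
})

test_that("unidentifiable response patterns raise errors", {
  same <- tibble::tibble(base_bid = 400, bid_up = 600, bid_down = 300,
                         y1 = rep(1L, 20), y2 = rep(1L, 20))
  expect_error(fit_dbdc(same), "identified")
  expect_error(fit_dbdc(published, covariates = "not_a_column"), "not found")
})

test_that("single-bound probit recovers WTP and is less precise than DBDC", {
  survey <- simulate_survey(seed = 31)
  sb <- fit_sbdc(survey)
  db <- fit_dbdc(survey)
  expect_true(sb$converged)
  expect_lt(abs(sb$mean_wtp - 507), 3 * sb$se)
  expect_gt(sb$se, db$se) # follow-up responses add information
})

test_that("single-bound WTP is equivariant to scaling bids and truth", {
  base <- simulate_survey(seed = 13, covariates = FALSE)
  scaled <- simulate_survey(
    survey_design(base_bid = 10 * c(400, 600, 700, 800),
                  bid_up = 10 * c(600, 700, 800, 1000),
                  bid_down = 10 * c(300, 400, 600, 700)),
    beta = c("(Intercept)" = 5070), sigma = 2000, seed = 13,
    covariates = FALSE
  )
  f1 <- fit_sbdc(base)
  f10 <- fit_sbdc(scaled)
  expect_equal(f10$mean_wtp, 10 * f1$mean_wtp, tolerance = 1e-6)
})

test_that("a zero bid coefficient is rejected rather than divided by", {
  flat <- tibble::tibble(
    base_bid = 400, bid_up = 600, bid_down = 300,
    y1 = rep(c(0L, 1L), 25), y2 = rep(c(0L, 1L), 25)
  )
  expect_error(fit_sbdc(flat), "undefined|zero")
})

test_that("tidy and glance return well-formed summaries", {
  fit <- fit_dbdc(published)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "sigma"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$n_used, 1091)
  expect_equal(gl$mean_wtp, fit$mean_wtp)
  sb <- fit_sbdc(published)
  expect_s3_class(tidy(sb), "tbl_df")
  expect_equal(glance(sb)$model, "sbdc")
})
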