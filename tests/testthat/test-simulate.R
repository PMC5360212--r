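test_that("default design reproduces the survey's bid allocation exactly", {
  survey <- simulate_survey(seed = 1)
  counts <- table(survey$base_bid)
  expect_equal(as.integer(counts[c("400", "600", "700", "800")]),
               c(286, 280, 282, 243))
  expect_equal(nrow(survey), 1091)
  expect_equal(length(unique(survey$village_id)), 44)
  expect_true(all(survey$weight > 0))
})

test_that("identical seeds give byte-identical surveys", {
  s1 <- simulate_survey(seed = 33)
  s2 <- simulate_survey(seed = 33)
  expect_identical(s1, s2)
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(s1, f1, row.names = FALSE)
  write.csv(s2, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(s1, simulate_survey(seed = 34)))
})

test_that("responses always bracket the latent draw", {
  survey <- simulate_survey(seed = 17)
  iv <- response_to_interval(survey)
  expect_true(all(survey$wtp_true >= iv$wtp_lower &
                    survey$wtp_true < iv$wtp_upper))
})

test_that("a degenerate latent scale yields deterministic responses", {
  survey <- simulate_survey(beta = c("(Intercept)" = 507), sigma = 1e-9,
                            seed = 3, covariates = FALSE)
  arm400 <- survey[survey$base_bid == 400, ]
  expect_true(all(arm400$y1 == 1 & arm400$y2 == 0)) # 507 in [400, 600)
  arm800 <- survey[survey$base_bid == 800, ]
  expect_true(all(arm800$y1 == 0 & arm800$y2 == 0)) # 507 below 700
})

test_that("acceptance shares match the latent normal at large n", {
  big <- survey_design(base_bid = 400, bid_up = 600, bid_down = 300,
                       allocation = 10000, n_villages = 1)
  survey <- simulate_survey(big, beta = c("(Intercept)" = 500), sigma = 100,
                            seed = 8, covariates = FALSE)
  expect_equal(mean(survey$y1), pnorm(1), tolerance = 0.01)
})

test_that("generated covariates reproduce the sample's published moments", {
  survey <- simulate_survey(seed = 12)
  targets <- list(
    household_size = c(4.56, 1.71),
    pit_liners = c(2.36, 1.14),
    income_usd = c(1245.61, 1077.83),
    educ_primary = c(0.34, NA),
    educ_secondary = c(0.46, NA),
    nonfarm_income = c(0.67, NA),
    brick_walls = c(0.68, NA),
    metal_roof = c(0.97, NA)
  )
  for (v in names(targets)) {
    expect_equal(mean(survey[[v]]), targets[[v]][1], tolerance = 0.05,
                 label = sprintf("mean(%s)", v))
  }
  # sds of the skewed generators need a larger sample than one survey to
  # estimate within 5%; check them on a 15x replicated design
  wide <- survey_design(allocation = 15 * c(286, 280, 282, 243))
  big <- simulate_survey(wide, seed = 12)
  for (v in c("household_size", "pit_liners", "income_usd")) {
    expect_equal(sd(big[[v]]), targets[[v]][2], tolerance = 0.05,
                 label = sprintf("sd(%s)", v))
  }
})

test_that("simulation inputs are validated", {
  expect_error(simulate_survey(), "seed")
  expect_error(simulate_survey(beta = c(mu = 507), seed = 1), "Intercept")
  expect_error(simulate_survey(beta = c("(Intercept)" = 507, ghost = 1),
                               seed = 1), "ghost")
  expect_error(survey_design(bid_down = c(500, 400, 600, 700)),
               "bid_down < base_bid")
})
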