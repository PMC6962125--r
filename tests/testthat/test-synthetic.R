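test_that("blocked designs are balanced, distinct and seed-deterministic", {
  d32 <- make_bws_design(32, 4, seed = 3)
  expect_equal(nrow(d32), 32L)
  expect_equal(as.vector(table(d32$block)), rep(8L, 4))
  expect_false(anyDuplicated(d32$profile) > 0)
  lev <- parse_state(d32$profile)
  for (p in 1:8) expect_setequal(unique(lev[, p]), 1:4)

  d64 <- make_bws_design(64, 8, seed = 3)
  expect_equal(as.vector(table(d64$block)), rep(8L, 8))

  expect_identical(make_bws_design(32, 4, seed = 3), d32)
  expect_error(make_bws_design(30, 4, seed = 1), "divisible")
})

test_that("a dominant item is almost always picked best", {
  # one huge utility: occupation level 1 at +10, all else 0
  dom <- data.frame(domain = ascot_domains()$short[ascot_domains()$p != 5],
                    estimate = 0, se = NA)
  lev <- data.frame(domain = rep(ascot_domains()$short, each = 3),
                    level = rep(1:3, 8), estimate = 0, se = NA)
  lev$estimate[lev$domain == "occupation" & lev$level == 1] <- 10
  truth <- ascot_truth(coefficients = bws_coefficients(dom, lev),
                       conversion = new_ascot_conversion(0.2, 0.1))
  # profiles where occupation is at level 1
  design <- data.frame(block = 1L, profile = c("11111111", "21314121"))
  bws <- simulate_bws(truth, design, n_respondents = 1000, seed = 2)
  # P(best) >= exp(10) / (exp(10) + 7) ~ 0.99968 per task
  expect_gte(mean(bws$best == "occupation"), 0.99)
})

test_that("with flat utilities each domain is best about 1/8 of the time", {
  dom <- data.frame(domain = ascot_domains()$short[ascot_domains()$p != 5],
                    estimate = 0, se = NA)
  lev <- data.frame(domain = rep(ascot_domains()$short, each = 3),
                    level = rep(1:3, 8), estimate = 0, se = NA)
  truth <- ascot_truth(coefficients = bws_coefficients(dom, lev),
                       conversion = new_ascot_conversion(0.2, 0.1))
  design <- data.frame(block = 1L, profile = "12341234")
  bws <- simulate_bws(truth, design, n_respondents = 4000, seed = 5)
  freq <- table(factor(bws$best, levels = ascot_domains()$short)) / nrow(bws)
  # binomial MC error: sqrt(p(1-p)/n) ~ 0.0052; allow 4 sigma
  expect_true(all(abs(freq - 1 / 8) < 4 * sqrt(0.125 * 0.875 / 4000)))
})

test_that("best-choice frequencies match conditional-logit probabilities on a skewed toy", {
  # utilities via level effects: three distinct values spread across domains
  dom <- data.frame(domain = ascot_domains()$short[ascot_domains()$p != 5],
                    estimate = 0, se = NA)
  lev <- data.frame(domain = rep(ascot_domains()$short, each = 3),
                    level = rep(1:3, 8), estimate = 0, se = NA)
  lev$estimate[lev$domain == "control" & lev$level == 1] <- 1
  lev$estimate[lev$domain == "food" & lev$level == 1] <- -1
  truth <- ascot_truth(coefficients = bws_coefficients(dom, lev),
                       conversion = new_ascot_conversion(0.2, 0.1))
  design <- data.frame(block = 1L, profile = "11114444")  # control, cleanliness, food, safety at L1
  v <- c(1, 0, -1, 0, 0, 0, 0, 0)  # control, cleanliness(0), food, safety + 4 domains at L4
  # per-domain utilities in p order for this profile
  names(v) <- c("control", "cleanliness", "food", "safety",
                "accommodation", "participation", "dignity", "occupation")
  pr <- exp(v) / sum(exp(v))
  n <- 4000
  bws <- simulate_bws(truth, design, n_respondents = n, seed = 11)
  freq <- table(factor(bws$best, levels = names(pr))) / n
  se <- sqrt(pr * (1 - pr) / n)
  expect_true(all(abs(freq - pr) < 3.5 * se))
})

test_that("simulated respondents with 4 blocks each value 8 profiles", {
  sc <- small_bws_scenario(n_respondents = 20)
  expect_equal(as.vector(table(sc$bws$respondent_id)), rep(8L, 20))
  expect_length(unique(sc$bws$block), 4L)
})

test_that("bws simulation is byte-identical under a fixed seed", {
  t1 <- simulate_bws(ascot_truth(), make_bws_design(32, 4, 5), 30, seed = 9)
  t2 <- simulate_bws(ascot_truth(), make_bws_design(32, 4, 5), 30, seed = 9)
  expect_identical(t1, t2)
  t3 <- simulate_bws(ascot_truth(), make_bws_design(32, 4, 5), 30, seed = 10)
  expect_false(identical(t1, t3))
})

test_that("noise-free TTO responses invert exactly through tto_score", {
  # slope/intercept chosen so state values cover BTD, WTD and the -1 floor
  truth <- ascot_truth(conversion = new_ascot_conversion(0.4, -1.4),
                       tto_noise_sd = 0, answer_grid = 1e-9)
  design <- data.frame(block = 1L,
                       profile = c("11111111", "44444444", "13241324"))
  tariff <- truth_tariff(truth)
  tto <- simulate_tto(truth, design, n_respondents = 5, seed = 3)
  v <- pmin(pmax(0.4 * latent_bws_score(tto$state, tariff) - 1.4, -1), 1)
  expect_equal(tto_score(tto$wtd, tto$answer_years), unname(v), tolerance = 1e-7)
  expect_true(all(tto$wtd == (v < 0)))
  # the worst state under this map is clamped at the lead-time floor
  worst <- tto[tto$state == "44444444", ]
  expect_true(all(worst$wtd & worst$answer_years == 0))
})

test_that("mean simulated TTO score converges to the true value away from the bounds", {
  # states chosen with true values well inside (-1, 1) so clamping is inert
  truth <- ascot_truth(tto_noise_sd = 0.1)
  design <- data.frame(block = 1L, profile = c("22222222", "33333333"))
  tariff <- truth_tariff(truth)
  n <- 500
  tto <- simulate_tto(truth, design, n_respondents = n, seed = 21)
  sm <- tto_state_means(tto)
  truev <- scqaly_score(sm$state, tariff, truth$conversion)
  expect_true(all(abs(truev) < 0.9))
  # grid rounding (0.5 y = 0.05 utility) adds at most 0.025 absolute bias
  expect_true(all(abs(sm$mean_tto - truev) < 2 * sm$sd / sqrt(sm$n) + 0.025))
})

test_that("response-time defaults leave the exclusion filters exercisable", {
  sc <- small_bws_scenario(n_respondents = 400, seed = 31)
  tt <- small_tto_scenario(n_respondents = 400, seed = 32)
  bt <- tapply(sc$bws$total_bws_minutes, sc$bws$respondent_id, max)
  ttm <- tapply(tt$tto$total_tto_minutes, tt$tto$respondent_id, max)
  expect_gt(mean(bt < 4.5), 0)      # some BWS respondents fall under 4.5 min
  expect_lt(mean(bt < 4.5), 0.2)
  expect_gt(mean(ttm < 5.0), 0)
  expect_lt(mean(ttm < 5.0), 0.2)
})

test_that("survey writer emits the documented files with a truth sidecar", {
  dir <- withr::local_tempdir()
  sc <- small_bws_scenario(n_respondents = 10)
  tt <- small_tto_scenario(n_respondents = 10)
  write_survey(sc$bws, tt$tto, sc$truth, dir, seed = 42)
  expect_true(all(file.exists(file.path(
    dir, c("bws_responses.csv", "tto_responses.csv", "truth.json")))))
  side <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(side$seed, 42)
  expect_equal(side$conversion$slope, 0.221)
})
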