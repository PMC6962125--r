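test_that("occasion log-probabilities are symmetric and match brute-force softmax", {
  beta <- rep(0, 31)
  X2 <- rbind(code_choice_row("food", 1, 1), code_choice_row("safety", 2, 1))
  expect_equal(occasion_logprob(X2, 1, beta), log(1 / 2))

  X8 <- t(vapply(ascot_domains()$short, function(d) code_choice_row(d, 4, 1),
                 numeric(31)))
  expect_equal(occasion_logprob(X8, 3, beta), log(1 / 8))

  # brute-force enumeration oracle on a 3-alternative toy with V = (1, 0, -1)
  beta <- rep(0, 31); names(beta) <- names(code_choice_row("food", 1, 1))
  beta["l_control_1"] <- 1
  beta["l_food_1"] <- -1
  X3 <- rbind(code_choice_row("control", 1, 1),
              code_choice_row("safety", 4, 1),
              code_choice_row("food", 1, 1))
  v <- c(1, 0, -1)
  expect_equal(occasion_logprob(X3, 1, beta), v[1] - log(sum(exp(v))),
               tolerance = 1e-12)

  # probabilities over the occasion normalize to 1
  lp <- vapply(1:3, function(i) occasion_logprob(X3, i, beta), numeric(1))
  expect_equal(sum(exp(lp)), 1)
})

test_that("likelihood is invariant under large linear indices (overflow guard)", {
  beta <- rep(0, 31); names(beta) <- names(code_choice_row("food", 1, 1))
  beta["l_control_1"] <- 699
  X <- rbind(code_choice_row("control", 1, 1), code_choice_row("safety", 4, 1))
  lp <- occasion_logprob(X, 1, beta)
  expect_true(is.finite(lp))
  expect_equal(lp, -log(1 + exp(-699)))
})

test_that("conditional logit recovers the generating parameters", {
  sc <- small_bws_scenario(n_respondents = 100, seed = 101)
  fit100 <- fit_bws_mnl(sc$long)
  z <- coef_z_scores(fit100, sc$truth$coefficients)
  expect_true(all(abs(z) < 4))

  # estimation error shrinks with more respondents
  sc400 <- small_bws_scenario(n_respondents = 400, seed = 101)
  fit400 <- fit_bws_mnl(sc400$long)
  mae <- function(fit) mean(abs(ascotval:::.coef_vector(fit) -
                                ascotval:::.coef_vector(sc$truth$coefficients)))
  expect_lt(mae(fit400), mae(fit100))
})

test_that("fitted optimum has vanishing score and beats the null model", {
  sc <- small_bws_scenario(n_respondents = 60, seed = 55)
  fit <- fit_bws_mnl(sc$long)
  cd <- ascotval:::.prepare_choice_data(sc$long)
  ev <- ascotval:::.mnl_eval(ascotval:::.coef_vector(fit), cd)
  expect_lt(max(abs(ev$grad)) / cd$n_occ, 1e-5)
  null_ll <- ascotval:::.mnl_eval(rep(0, 31), cd)$ll
  expect_gt(fit$log_likelihood, null_ll)
})

test_that("point estimates are invariant to duplicating every respondent", {
  sc <- small_bws_scenario(n_respondents = 40, seed = 19)
  dup <- sc$bws
  dup$respondent_id <- dup$respondent_id + max(dup$respondent_id)
  both <- rbind(sc$bws, dup)
  f1 <- fit_bws_mnl(sc$long)
  f2 <- fit_bws_mnl(explode_bws(both))
  expect_equal(ascotval:::.coef_vector(f2), ascotval:::.coef_vector(f1),
               tolerance = 1e-5)
})

test_that("degenerate single-occasion data raise an identifiability error", {
  sc <- small_bws_scenario(n_respondents = 1)
  one_task <- sc$bws[1, , drop = FALSE]
  long <- explode_bws(one_task)
  expect_error(fit_bws_mnl(long), "identifiability")
})

test_that("estimates agree with survival::clogit on the same exploded data", {
  skip_if_not_installed("survival")
  withr::local_package("survival")   # clogit builds an unqualified coxph call
  sc <- small_bws_scenario(n_respondents = 60, seed = 23)
  fit <- fit_bws_mnl(sc$long)
  X <- bws_design_matrix(sc$long)
  df <- data.frame(chosen = sc$long$chosen, occ = sc$long$occ_id, X)
  fml <- stats::reformulate(c(colnames(X), "strata(occ)"), response = "chosen")
  cl <- survival::clogit(fml, data = df)
  expect_equal(unname(ascotval:::.coef_vector(fit)),
               unname(stats::coef(cl)[colnames(X)]), tolerance = 1e-4)
})

test_that("sign-coding equivariance: a flipped occasion at -beta has the same probability", {
  # flipping an occasion from the best side to the worst side negates its
  # coded rows, so evaluating the mirrored occasion at -beta reproduces the
  # original choice probability exactly
  beta <- ascotval:::.coef_vector(ascot_jp_mnl_coefficients())
  doms <- c("control", "food", "dignity", "occupation", "safety")
  lvls <- c(1, 2, 3, 4, 2)
  X_best <- t(mapply(code_choice_row, doms, lvls, MoreArgs = list(sign = +1)))
  X_worst <- t(mapply(code_choice_row, doms, lvls, MoreArgs = list(sign = -1)))
  for (ch in seq_along(doms)) {
    expect_equal(occasion_logprob(X_best, ch, beta),
                 occasion_logprob(X_worst, ch, -beta))
  }
})
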