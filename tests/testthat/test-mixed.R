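# Mixed-logit checks run at deliberately small sizes; the full-scale
# recovery study lives in the acceptance suite.

test_that("with one draw and zero scales the simulated likelihood collapses to MNL", {
  sc <- small_bws_scenario(n_respondents = 30, seed = 13)
  md <- ascotval:::.mixed_data(sc$long, "respondent", n_draws = 1L, seed = 4)
  cd <- ascotval:::.prepare_choice_data(sc$long)
  beta <- ascotval:::.coef_vector(sc$truth$coefficients)
  theta <- c(beta[grep("^l_", names(beta))], beta[grep("^d_", names(beta))],
             rep(0, 7))
  expect_equal(ascotval:::.mixed_eval(theta, md, "normal", want_grad = FALSE)$ll,
               ascotval:::.mnl_eval(beta, cd)$ll, tolerance = 1e-10)
})

test_that("analytic simulated-likelihood gradient matches finite differences", {
  sc <- small_bws_scenario(n_respondents = 15, seed = 29)
  md <- ascotval:::.mixed_data(sc$long, "respondent", n_draws = 25L, seed = 4)
  beta <- ascotval:::.coef_vector(sc$truth$coefficients)
  theta <- c(beta[grep("^l_", names(beta))], beta[grep("^d_", names(beta))],
             rep(0.3, 7))
  for (dist in c("normal", "lognormal")) {
    th <- theta
    if (dist == "lognormal") th[25:31] <- log(pmax(th[25:31], 0.05))
    ev <- ascotval:::.mixed_eval(th, md, dist)
    f <- function(t) ascotval:::.mixed_eval(t, md, dist, want_grad = FALSE)$ll
    for (i in c(3, 17, 26, 30, 33, 38)) {
      h <- 1e-6
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      expect_equal(unname(ev$grad[i]), (f(tp) - f(tm)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("simulated likelihood is deterministic in the seed and invariant to cluster order", {
  sc <- small_bws_scenario(n_respondents = 20, seed = 37)
  beta <- ascotval:::.coef_vector(sc$truth$coefficients)
  theta <- c(beta[grep("^l_", names(beta))], beta[grep("^d_", names(beta))],
             rep(0.2, 7))
  ll_of <- function(long) {
    md <- ascotval:::.mixed_data(long, "respondent", n_draws = 40L, seed = 8)
    ascotval:::.mixed_eval(theta, md, "normal", want_grad = FALSE)$ll
  }
  base_ll <- ll_of(sc$long)
  expect_identical(base_ll, ll_of(sc$long))
  # present respondents in reverse order: draws follow identity, not order
  rev_long <- sc$long[order(-sc$long$respondent_id, sc$long$occ_id), ]
  rev_long$occ_id <- match(rev_long$occ_id, unique(rev_long$occ_id))
  expect_equal(ll_of(rev_long), base_ll, tolerance = 1e-12)
})

test_that("respondent_by_sign clustering splits each respondent into two clusters", {
  sc <- small_bws_scenario(n_respondents = 12, seed = 41)
  cd1 <- ascotval:::.prepare_choice_data(sc$long, "respondent")
  cd2 <- ascotval:::.prepare_choice_data(sc$long, "respondent_by_sign")
  expect_equal(cd1$n_cluster, 12L)
  expect_equal(cd2$n_cluster, 24L)
  # each sign-side cluster contains only occasions of one side
  side <- tapply(sc$long$sign, cd2$cluster, function(s) length(unique(s)))
  expect_true(all(side == 1))
})

test_that("a small mixed fit recovers a strong mixing signal", {
  truth <- ascot_truth(mixing = "normal",
                       mixing_sd = c(occupation = 0.6))
  sc <- small_bws_scenario(n_respondents = 150, seed = 53, truth = truth)
  fit <- fit_bws_mixed(sc$long, "normal", "respondent",
                       n_draws = 60, seed = 3)
  occ <- fit$mixing[fit$mixing$domain == "occupation", ]
  expect_lt(abs(occ$estimate - 0.6), 3 * occ$se)
  expect_gt(occ$estimate / occ$se, 2)     # clearly nonzero
  expect_equal(fit$model_id, "mixed_normal")
  expect_equal(fit$n_draws, 60L)
  # mixed fit should not be worse than MNL at the optimum
  expect_gte(fit$log_likelihood, fit_bws_mnl(sc$long)$log_likelihood - 1e-6)
})
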