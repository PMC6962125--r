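# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small except where a check is about sampling error.

small_bws_scenario <- function(n_respondents = 60, seed = 42,
                               truth = ascot_truth()) {
  design <- make_bws_design(32, 4, seed = seed)
  bws <- simulate_bws(truth, design, n_respondents = n_respondents, seed = seed + 1)
  list(truth = truth, design = design, bws = bws, long = explode_bws(bws))
}

small_tto_scenario <- function(n_respondents = 200, seed = 7,
                               truth = ascot_truth()) {
  design <- make_bws_design(64, 8, seed = seed)
  tto <- simulate_tto(truth, design, n_respondents = n_respondents, seed = seed + 1)
  list(truth = truth, design = design, tto = tto)
}

# truth/fit comparison on the 31 structural parameters
coef_z_scores <- function(fit, truth_coefs) {
  tv <- ascotval:::.coef_vector(truth_coefs)
  fv <- ascotval:::.coef_vector(fit)
  se <- c(stats::setNames(fit$domain$se, paste0("d_", fit$domain$domain)),
          stats::setNames(fit$level$se,
                          paste0("l_", fit$level$domain, "_", fit$level$level)))
  (fv - tv[names(fv)]) / se[names(fv)]
}
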