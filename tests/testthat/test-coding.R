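test_that("exploding yields occasions of sizes 8/7/6/5 with sequential removal", {
  sc <- small_bws_scenario(n_respondents = 10)
  long <- sc$long
  sizes <- table(long$occ_id)
  expect_true(all(sizes %in% c(8L, 7L, 6L, 5L)))
  expect_equal(nrow(long), 10 * 8 * 26)          # 26 alternative rows per task
  expect_equal(max(long$occ_id), 10 * 8 * 4)     # 32 occasions per respondent

  # picked domains disappear from later occasions of the same task
  one <- long[long$respondent_id == long$respondent_id[1] & long$task_index == 1, ]
  best <- one$alt[one$occasion == "best" & one$chosen == 1]
  expect_false(best %in% one$alt[one$occasion == "worst"])
  worst <- one$alt[one$occasion == "worst" & one$chosen == 1]
  expect_false(any(c(best, worst) %in% one$alt[one$occasion == "second_best"]))
})

test_that("exploding then regrouping recovers the original pick sequence", {
  sc <- small_bws_scenario(n_respondents = 25)
  long <- sc$long
  picks <- do.call(rbind, lapply(split(long, ~ respondent_id + task_index), function(g) {
    g <- g[g$chosen == 1, ]
    data.frame(respondent_id = g$respondent_id[1], task_index = g$task_index[1],
               best = g$alt[g$occasion == "best"],
               worst = g$alt[g$occasion == "worst"],
               second_best = g$alt[g$occasion == "second_best"],
               second_worst = g$alt[g$occasion == "second_worst"])
  }))
  key <- c("respondent_id", "task_index")
  picks <- picks[do.call(order, picks[key]), ]
  orig <- sc$bws[do.call(order, sc$bws[key]), c(key, "best", "worst", "second_best", "second_worst")]
  rownames(picks) <- rownames(orig) <- NULL
  expect_equal(picks, orig)
})

test_that("duplicate picks are rejected", {
  sc <- small_bws_scenario(n_respondents = 2)
  bad <- sc$bws
  bad$worst <- bad$best
  expect_error(explode_bws(bad), "distinct")
})

test_that("single-row coding follows the sign and double-reference rules", {
  r <- code_choice_row("occupation", 1, +1)
  expect_equal(unname(r["d_occupation"]), 1)
  expect_equal(unname(r["l_occupation_1"]), 1)
  expect_equal(sum(r != 0), 2L)

  expect_equal(sum(code_choice_row("control", 4, -1) != 0), 0L)  # double reference

  r <- code_choice_row("safety", 2, -1)
  expect_equal(unname(r["d_safety"]), -1)
  expect_equal(unname(r["l_safety_2"]), -1)
  expect_equal(sum(r != 0), 2L)
})

test_that("design matrix has 31 columns and matches a brute-force row-by-row oracle", {
  sc <- small_bws_scenario(n_respondents = 15, seed = 77)
  long <- sc$long
  X <- bws_design_matrix(long)
  expect_equal(ncol(X), 31L)
  expect_true(all(X %in% c(-1, 0, 1)))
  expect_true(all(rowSums(X != 0) <= 2))

  # independent re-coding straight from the rule text
  oracle <- t(mapply(function(alt, level, sign) {
    cols <- stats::setNames(numeric(31), colnames(X))
    if (alt != "control") cols[paste0("d_", alt)] <- sign
    if (level != 4) cols[paste0("l_", alt, "_", level)] <- sign
    cols
  }, long$alt, long$level, long$sign))
  dimnames(oracle) <- dimnames(X)
  expect_equal(X, oracle)

  # nonzero entries all carry the occasion's sign
  expect_true(all(apply(X, 1, function(r) all(r[r != 0] == r[r != 0][1]))))
})

test_that("time filters are strict, phase-specific and validate inputs", {
  bws <- data.frame(respondent_id = c(1, 1, 2, 3),
                    total_bws_minutes = c(4.4, 4.4, 4.5, 9))
  tto <- data.frame(respondent_id = c(1, 2, 3),
                    total_tto_minutes = c(20, 5.0, 3.1))
  out <- filter_respondents(bws, tto)
  expect_identical(unique(out$bws$respondent_id), c(2, 3))   # 4.4 < 4.5 excluded
  expect_identical(unique(out$tto$respondent_id), c(1, 2))   # 5.0 retained (strict <)
  expect_equal(out$report$bws$n_excluded, 1L)
  expect_equal(out$report$tto$n_excluded, 1L)

  none <- filter_respondents(bws, tto, bws_min = 0, tto_min = 0)
  expect_equal(nrow(none$bws), nrow(bws))
  expect_equal(nrow(none$tto), nrow(tto))

  bad <- bws; bad$total_bws_minutes[1] <- -1
  expect_error(filter_respondents(bad, tto), "negative", ignore.case = TRUE)
})
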