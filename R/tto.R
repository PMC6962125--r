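# Composite time trade-off scoring.

#' TTO score of a single response
#'
#' Better-than-dead responses (conventional TTO: `x` years in full
#' SCRQoL state indifferent to 10 years in the presented state) score
#' `x / 10` in `[0, 1]`. Worse-than-dead responses (lead-time TTO: `y`
#' years of full state indifferent to 10 years full + 10 years presented)
#' score `y / 10 - 1` in `[-1, 0]`, which bounds the scale below at -1.
#' The scale is continuous at dead: both branches meet at 0.
#'
#' @param wtd Logical vector: worse-than-dead (lead-time) record?
#' @param answer_years Indifference answer in years, in `[0, 10]`.
#' @return Numeric vector of utilities in `[-1, 1]`.
#' @examples
#' tto_score(c(FALSE, TRUE), c(7.5, 5))  # 0.75, -0.5
#' @export
tto_score <- function(wtd, answer_years) {
  if (any(answer_years < 0 | answer_years > 10))
    stop("answer_years must lie in [0, 10]")
  ifelse(wtd, answer_years / 10 - 1, answer_years / 10)
}

#' Per-state mean TTO values
#'
#' Scores each retained response with [tto_score()] and aggregates by
#' state: mean, SD and number of respondents. Each response counts once
#' (no within-respondent aggregation). States present in `design_states`
#' but valued by zero retained respondents are reported with `n = 0` and
#' a warning rather than silently dropped.
#'
#' @param responses cTTO response table (columns `state`, `wtd`,
#'   `answer_years`), typically already filtered with
#'   [filter_respondents()].
#' @param design_states Optional character vector of states that should be
#'   present (the valuation design).
#' @return Data frame with columns `state`, `mean_tto`, `sd`, `n`,
#'   ordered by state string.
#' @seealso [tto_summary()]
#' @export
tto_state_means <- function(responses, design_states = NULL) {
  sc <- tto_score(responses$wtd, responses$answer_years)
  st <- as.character(responses$state)
  agg <- data.frame(
    state = sort(unique(st)),
    stringsAsFactors = FALSE)
  agg$mean_tto <- as.vector(tapply(sc, st, mean)[agg$state])
  agg$sd <- as.vector(tapply(sc, st, stats::sd)[agg$state])
  agg$n <- as.vector(tapply(sc, st, length)[agg$state])
  if (!is.null(design_states)) {
    missing_states <- setdiff(design_states, agg$state)
    if (length(missing_states)) {
      warning(length(missing_states),
              " design state(s) have no retained responses: ",
              paste(missing_states, collapse = ", "))
      agg <- rbind(agg, data.frame(state = missing_states, mean_tto = NA_real_,
                                   sd = NA_real_, n = 0L))
      agg <- agg[order(agg$state), , drop = FALSE]
    }
  }
  rownames(agg) <- NULL
  agg
}

#' Summary of state-level TTO values
#'
#' @param state_means Data frame from [tto_state_means()].
#' @return List with `n_states`, `min`, `max`, `median` of the state means,
#'   the best and worst states, and `n_wtd` (states with negative mean,
#'   i.e. valued worse than dead).
#' @export
tto_summary <- function(state_means) {
  ok <- state_means[state_means$n > 0, , drop = FALSE]
  list(n_states = nrow(ok),
       min = min(ok$mean_tto),
       worst_state = ok$state[which.min(ok$mean_tto)],
       max = max(ok$mean_tto),
       best_state = ok$state[which.max(ok$mean_tto)],
       median = stats::median(ok$mean_tto),
       n_wtd = sum(ok$mean_tto < 0))
}
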