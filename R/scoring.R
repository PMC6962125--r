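# State scoring: latent BWS score and SC-QALY score.

#' Latent BWS score of ASCOT states
#'
#' The latent BWS score of a state is the sum over the 8 domains of the
#' tariff weight at the state's level (multi-attribute additive scoring).
#' It is not yet on the QALY scale; see [scqaly_score()].
#'
#' @param states State strings (see [parse_state()]) or an n x 8 level
#'   matrix in p-index order.
#' @param tariff An `ascot_tariff`.
#' @return Numeric vector of latent scores.
#' @examples
#' latent_bws_score(c("11111111", "44444444"), ascot_tariff("JP"))
#' @export
latent_bws_score <- function(states, tariff) {
  stopifnot(inherits(tariff, "ascot_tariff"))
  w <- tariff$weights
  if (anyNA(w)) stop("tariff integrity error: missing weight entries")
  lev <- .state_levels(states)
  out <- numeric(nrow(lev))
  for (p in 1:8) out <- out + w[p, lev[, p]]
  unname(out)
}

#' SC-QALY score of ASCOT states
#'
#' Applies the linear conversion `slope * latent + intercept` to the latent
#' BWS score, giving a utility anchored at 1 for the best state
#' (`11111111`) and 0 for dead; negative values are worse than dead.
#'
#' @inheritParams latent_bws_score
#' @param conversion An `ascot_conversion`.
#' @return Numeric vector of SC-QALY scores.
#' @examples
#' scqaly_score("44444444", ascot_tariff("JP"), ascot_conversion("JP"))
#' @export
scqaly_score <- function(states, tariff, conversion) {
  stopifnot(inherits(conversion, "ascot_conversion"))
  conversion$slope * latent_bws_score(states, tariff) + conversion$intercept
}
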