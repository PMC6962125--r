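# Anchoring latent BWS scores to the SC-QALY scale.
#
# The map TTO_i = a * BWS_i + b + e_i is fitted over the valued states
# under the constraint that the best state [11111111] maps exactly to 1:
# a * BWS_max + b = 1. Substituting b = 1 - a * BWS_max leaves a single
# free parameter with the closed form
#   a = sum((TTO_i - 1) (BWS_i - BWS_max)) / sum((BWS_i - BWS_max)^2).

#' Fit the constrained anchoring regression
#'
#' Least squares of mean TTO values on latent BWS scores, constrained so
#' the best state's latent score maps to 1. State means enter unweighted
#' (one observation per state). R-squared is `1 - SSR/SST` with SST about
#' the mean of the TTO values; the squared Pearson correlation between
#' fitted and observed values is also reported. The slope's standard
#' error comes from the one-parameter residual variance and the
#' intercept's by the delta method through `b = 1 - a * BWS_max`.
#'
#' @param state_means Data frame from [tto_state_means()] (states with
#'   `n = 0` are dropped).
#' @param tariff The `ascot_tariff` providing latent scores.
#' @return An object of class `anchoring_fit` with elements `conv`
#'   (an `ascot_conversion`), `r_squared`, `pearson_sq`, `slope_se`,
#'   `slope_t`, `intercept_t`, `n_states`, `bws_max`.
#' @export
fit_anchoring <- function(state_means, tariff) {
  obs <- state_means[state_means$n > 0, , drop = FALSE]
  if (nrow(obs) < 2L) stop("need at least 2 valued states")
  bws <- latent_bws_score(obs$state, tariff)
  if (length(unique(bws)) < 2L)
    stop("degenerate regression: all latent BWS scores are equal")
  tto <- obs$mean_tto
  bws_max <- latent_bws_score("11111111", tariff)
  dx <- bws - bws_max
  a <- sum((tto - 1) * dx) / sum(dx^2)
  b <- 1 - a * bws_max
  fitted <- a * bws + b
  ssr <- sum((tto - fitted)^2)
  sst <- sum((tto - mean(tto))^2)
  n <- length(tto)
  sigma2 <- ssr / (n - 1)                 # one free parameter
  se_a <- sqrt(sigma2 / sum(dx^2))
  se_b <- abs(bws_max) * se_a
  structure(list(
    conv = new_ascot_conversion(a, b, label = "anchored"),
    r_squared = 1 - ssr / sst,
    pearson_sq = stats::cor(fitted, tto)^2,
    slope_se = se_a,
    slope_t = a / se_a,
    intercept_t = b / se_b,
    n_states = n,
    bws_max = bws_max,
    residuals = tto - fitted), class = "anchoring_fit")
}

#' @export
print.anchoring_fit <- function(x, ...) {
  cat(sprintf(
    "Anchoring fit over %d states: SC-QALY = %.3f * latent %+.3f\n",
    x$n_states, x$conv$slope, x$conv$intercept))
  cat(sprintf("  slope t = %.1f, intercept t = %.1f, R-squared = %.3f\n",
              x$slope_t, x$intercept_t, x$r_squared))
  cat(sprintf("  constraint: slope * %.3f + intercept = %.6f\n",
              x$bws_max, x$conv$slope * x$bws_max + x$conv$intercept))
  invisible(x)
}

#' Score states with an anchoring fit
#'
#' Applies the fitted conversion to states under the same tariff (delegates
#' to [scqaly_score()]).
#'
#' @param fit An `anchoring_fit`.
#' @param states State strings or level matrix.
#' @param tariff The tariff the fit was estimated with.
#' @return Numeric vector of SC-QALY scores.
#' @export
apply_anchoring <- function(fit, states, tariff) {
  stopifnot(inherits(fit, "anchoring_fit"))
  scqaly_score(states, tariff, fit$conv)
}

#' Serialize an anchoring fit
#'
#' @param fit An `anchoring_fit`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_anchoring <- function(fit, path) {
  jsonlite::write_json(list(
    slope = fit$conv$slope, intercept = fit$conv$intercept,
    r_squared = fit$r_squared, pearson_sq = fit$pearson_sq,
    slope_se = fit$slope_se, slope_t = fit$slope_t,
    intercept_t = fit$intercept_t,
    n_states = fit$n_states, bws_max = fit$bws_max),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
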