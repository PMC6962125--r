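# Rescaling estimated coefficients to a tariff.

#' Item coefficients from a fitted model
#'
#' Collapses the 31 estimated parameters into 32 item coefficients on the
#' logit scale: the coefficient of level q in domain p is the domain
#' constant plus the level effect, `beta_p + beta_pq`, with the reference
#' conventions `beta_5 = 0` (control) and `beta_p4 = 0` (level 4). Control
#' level 4 therefore has item coefficient exactly 0.
#'
#' @param coefs A `bws_coefficients` object.
#' @return Data frame with columns `domain`, `level`, `value` (32 rows,
#'   domains in p-index order, levels 1-4 within domain).
#' @export
item_coefficients <- function(coefs) {
  stopifnot(inherits(coefs, "bws_coefficients"))
  dom_beta <- stats::setNames(rep(0, 8L), .domain_shorts)
  dom_beta[coefs$domain$domain] <- coefs$domain$estimate
  lev_beta <- matrix(0, 8L, 4L, dimnames = list(.domain_shorts, NULL))
  lev_beta[cbind(match(coefs$level$domain, .domain_shorts), coefs$level$level)] <-
    coefs$level$estimate
  data.frame(domain = rep(.domain_shorts, each = 4L),
             level = rep(1:4, times = 8L),
             value = as.vector(t(lev_beta + dom_beta)),
             stringsAsFactors = FALSE)
}

#' Rescale item coefficients to a tariff
#'
#' Linearly transforms the 32 item coefficients so that control level 1
#' maps to 1 and control level 4 maps to 0:
#' `weight(p, q) = (value(p, q) - value(control, 4)) /
#' (value(control, 1) - value(control, 4))`.
#' Because control level 4 is the double reference (coefficient 0 by
#' construction), this reduces to division by the control level 1 item
#' coefficient. Weights are kept at full precision; rounding to the
#' published 3 decimals happens only in [write_tariff()].
#'
#' @param items Data frame from [item_coefficients()].
#' @param label Tariff label.
#' @return An `ascot_tariff`.
#' @export
rescale_weights <- function(items, label = "estimated") {
  need <- c("domain", "level", "value")
  if (!all(need %in% names(items)) || nrow(items) != 32L)
    stop("expected the 32-row item-coefficient table")
  v <- matrix(NA_real_, 8L, 4L, dimnames = list(.domain_shorts, paste0("L", 1:4)))
  v[cbind(match(items$domain, .domain_shorts), items$level)] <- items$value
  if (anyNA(v)) stop("item-coefficient table is incomplete")
  lo <- v["control", 4L]
  hi <- v["control", 1L]
  if (abs(hi - lo) < .Machine$double.eps^0.5)
    stop("degenerate scale: control level 1 and level 4 coefficients coincide")
  new_ascot_tariff((v - lo) / (hi - lo), label)
}
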