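# Coefficient tables for the sequential best-worst utility model.
#
# The model has 31 parameters: 7 domain constants (control, p = 5, is the
# reference) and 24 level effects (3 per domain; level 4 is the reference).
# Mixed-logit fits additionally carry mixing scale estimates for the domain
# constants.

#' Construct a BWS coefficient table
#'
#' @param domain Data frame with columns `domain` (the 7 non-reference
#'   short names), `estimate`, `se`.
#' @param level Data frame with columns `domain` (all 8 short names),
#'   `level` (1-3), `estimate`, `se`; 24 rows.
#' @param model_id One of `"mnl"`, `"mixed_normal"`, `"mixed_lognormal"`.
#' @param cluster_scheme `"respondent"` or `"respondent_by_sign"`.
#' @param log_likelihood Maximized log-likelihood.
#' @param n_draws Simulation draws (0 for plain conditional logit).
#' @param seed Seed used for the draws (NA for plain conditional logit).
#' @param mixing Optional data frame with columns `domain`, `estimate`,
#'   `se` holding the mixing scale parameters of a mixed-logit fit.
#' @return An object of class `bws_coefficients`.
#' @export
bws_coefficients <- function(domain, level,
                             model_id = c("mnl", "mixed_normal", "mixed_lognormal"),
                             cluster_scheme = c("respondent", "respondent_by_sign"),
                             log_likelihood = NA_real_, n_draws = 0L,
                             seed = NA_integer_, mixing = NULL) {
  model_id <- match.arg(model_id)
  cluster_scheme <- match.arg(cluster_scheme)
  domain <- domain[match(.nonref_shorts, domain$domain), , drop = FALSE]
  if (anyNA(domain$estimate) || nrow(domain) != 7L)
    stop("coefficient table needs estimates for the 7 non-reference domains")
  key <- paste(level$domain, level$level)
  want <- paste(rep(.domain_shorts, each = 3L), rep(1:3, times = 8L))
  level <- level[match(want, key), , drop = FALSE]
  if (anyNA(level$estimate) || nrow(level) != 24L)
    stop("coefficient table needs 24 level effects (levels 1-3 of 8 domains)")
  rownames(domain) <- rownames(level) <- NULL
  if (!is.na(log_likelihood) && !is.finite(log_likelihood))
    stop("log-likelihood must be finite")
  structure(list(domain = domain, level = level, mixing = mixing,
                 model_id = model_id, cluster_scheme = cluster_scheme,
                 log_likelihood = log_likelihood,
                 n_draws = as.integer(n_draws), seed = seed),
            class = "bws_coefficients")
}

#' @export
print.bws_coefficients <- function(x, ...) {
  cat(sprintf("BWS utility model (%s, cluster: %s)\n", x$model_id, x$cluster_scheme))
  if (is.finite(x$log_likelihood))
    cat(sprintf("log-likelihood: %.1f\n", x$log_likelihood))
  if (x$n_draws > 0) cat(sprintf("simulation draws: %d\n", x$n_draws))
  cat("\nDomain constants (control = reference):\n")
  print(x$domain, row.names = FALSE, digits = 4)
  cat("\nLevel effects (level 4 = reference):\n")
  print(x$level, row.names = FALSE, digits = 4)
  if (!is.null(x$mixing)) {
    cat("\nMixing scales (domain constants):\n")
    print(x$mixing, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

# Full 31-vector in the canonical order used by the design matrix:
# 7 domain columns (p order, control omitted) then 24 level columns.
.coef_vector <- function(coefs) {
  stopifnot(inherits(coefs, "bws_coefficients"))
  c(stats::setNames(coefs$domain$estimate, paste0("d_", coefs$domain$domain)),
    stats::setNames(coefs$level$estimate,
                    paste0("l_", coefs$level$domain, "_", coefs$level$level)))
}

#' Published Japanese conditional-logit coefficients
#'
#' The 31 coefficient estimates (with standard errors) of the plain
#' conditional-logit model from the published Japanese ASCOT SCT4
#' valuation study - the model whose rescaled coefficients define the
#' published Japanese tariff. Useful as a realistic ground truth for the
#' synthetic-survey generator and as the input of the tariff-rescaling
#' regression test.
#'
#' @return A `bws_coefficients` object.
#' @examples
#' rescale_weights(item_coefficients(ascot_jp_mnl_coefficients()))
#' @export
ascot_jp_mnl_coefficients <- function() {
  dom <- data.frame(
    domain = .nonref_shorts,
    estimate = c(0.2124, 0.3620, 0.3487, 0.5743, 0.1330, 0.0005, 0.5452),
    se       = c(0.0572, 0.0585, 0.0602, 0.0566, 0.0553, 0.0576, 0.0582),
    stringsAsFactors = FALSE)
  lev <- data.frame(
    domain = rep(.domain_shorts, each = 3L),
    level = rep(1:3, times = 8L),
    estimate = c(3.5226, 3.1502, 0.5459,   # accommodation
                 2.5613, 1.2074, 0.2753,   # safety
                 3.2185, 2.9394, 0.6573,   # food
                 2.4154, 2.2212, 0.3894,   # cleanliness
                 4.0760, 3.8895, 0.3610,   # control
                 3.1844, 2.9607, 1.2745,   # participation
                 2.8675, 1.4144, 0.2387,   # dignity
                 3.6034, 3.4306, 0.3436),  # occupation
    se = c(0.0635, 0.0634, 0.0562,
           0.0625, 0.0587, 0.0569,
           0.0645, 0.0637, 0.0572,
           0.0617, 0.0623, 0.0567,
           0.0586, 0.0584, 0.0545,
           0.0615, 0.0618, 0.0579,
           0.0643, 0.0592, 0.0566,
           0.0641, 0.0637, 0.0564),
    stringsAsFactors = FALSE)
  bws_coefficients(dom, lev, model_id = "mnl", log_likelihood = -44764)
}

#' Read / write coefficient tables
#'
#' Coefficient tables are stored as a CSV (columns `term`, `domain`,
#' `level`, `estimate`, `se`) next to a JSON metadata file
#' (`<path>.meta.json`) holding model id, cluster scheme, log-likelihood,
#' draws and seed.
#'
#' @param coefs A `bws_coefficients` object.
#' @param path CSV path.
#' @return `read_coefficients()` returns a `bws_coefficients`;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
write_coefficients <- function(coefs, path) {
  df <- rbind(
    data.frame(term = "domain", domain = coefs$domain$domain, level = NA_integer_,
               estimate = coefs$domain$estimate, se = coefs$domain$se),
    data.frame(term = "level", domain = coefs$level$domain, level = coefs$level$level,
               estimate = coefs$level$estimate, se = coefs$level$se))
  if (!is.null(coefs$mixing)) {
    df <- rbind(df, data.frame(term = "mixing_sd", domain = coefs$mixing$domain,
                               level = NA_integer_, estimate = coefs$mixing$estimate,
                               se = coefs$mixing$se))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(model_id = coefs$model_id, cluster_scheme = coefs$cluster_scheme,
               log_likelihood = coefs$log_likelihood, n_draws = coefs$n_draws,
               seed = coefs$seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  mix <- df[df$term == "mixing_sd", c("domain", "estimate", "se")]
  bws_coefficients(
    domain = df[df$term == "domain", c("domain", "estimate", "se")],
    level = df[df$term == "level", c("domain", "level", "estimate", "se")],
    model_id = meta$model_id %||% "mnl",
    cluster_scheme = meta$cluster_scheme %||% "respondent",
    log_likelihood = meta$log_likelihood %||% NA_real_,
    n_draws = meta$n_draws %||% 0L,
    seed = meta$seed %||% NA_integer_,
    mixing = if (nrow(mix)) mix else NULL)
}
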