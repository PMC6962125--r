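# Tariffs (value sets) and conversion parameters.
#
# A tariff is an 8 x 4 matrix of dimensionless preference weights, rows in
# p-index order, columns levels 1-4, normalized so that control level 1 = 1
# and control level 4 = 0. The built-in Japanese and UK tariffs are
# transcribed to exactly 3 decimals as published; they are not re-derived at
# load time.

.jp_weights <- matrix(c(
  # L1,   L2,    L3,    L4
  0.916, 0.825, 0.186, 0.052,  # accommodation
  0.717, 0.385, 0.156, 0.089,  # safety
  0.875, 0.807, 0.247, 0.086,  # food
  0.734, 0.686, 0.236, 0.141,  # cleanliness
  1.000, 0.954, 0.089, 0.000,  # control
  0.814, 0.759, 0.345, 0.033,  # participation
  0.704, 0.347, 0.059, 0.000,  # dignity
  1.018, 0.975, 0.218, 0.134), # occupation
  nrow = 8, byrow = TRUE,
  dimnames = list(.domain_shorts, paste0("L", 1:4)))

.uk_weights <- matrix(c(
  0.863, 0.780, 0.374, 0.288,
  0.880, 0.452, 0.298, 0.114,
  0.879, 0.775, 0.294, 0.184,
  0.911, 0.789, 0.265, 0.195,
  1.000, 0.919, 0.541, 0.000,
  0.873, 0.748, 0.497, 0.241,
  0.847, 0.637, 0.295, 0.263,
  0.962, 0.927, 0.567, 0.170),
  nrow = 8, byrow = TRUE,
  dimnames = list(.domain_shorts, paste0("L", 1:4)))

#' Construct a tariff (weight table)
#'
#' @param weights 8 x 4 numeric matrix of weights, rows in p-index order
#'   (see [ascot_domains()]), columns levels 1-4.
#' @param label Short tariff name, e.g. `"JP"`.
#' @return An object of class `ascot_tariff`.
#' @export
new_ascot_tariff <- function(weights, label = "custom") {
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(8L, 4L))) stop("a tariff needs 8 x 4 = 32 weights")
  if (anyNA(weights) || !all(is.finite(weights)))
    stop("tariff integrity error: missing or non-finite weight entries")
  dimnames(weights) <- list(.domain_shorts, paste0("L", 1:4))
  structure(list(weights = weights, label = label), class = "ascot_tariff")
}

#' Built-in published tariffs
#'
#' The published Japanese and UK ASCOT SCT4 weight tables, stored to the
#' 3 decimals at which they were published. Both are normalized so control
#' level 1 has weight 1 and control level 4 weight 0, and weights are
#' non-increasing in level within every domain.
#'
#' @param label `"JP"` or `"UK"`.
#' @return An `ascot_tariff`.
#' @examples
#' ascot_tariff("JP")$weights
#' @export
ascot_tariff <- function(label = c("JP", "UK")) {
  label <- match.arg(label)
  new_ascot_tariff(switch(label, JP = .jp_weights, UK = .uk_weights), label)
}

#' @export
print.ascot_tariff <- function(x, ...) {
  cat(sprintf("ASCOT SCT4 tariff '%s'\n", x$label))
  print(round(x$weights, 3))
  invisible(x)
}

#' @export
as.data.frame.ascot_tariff <- function(x, ...) {
  data.frame(domain = rep(rownames(x$weights), times = 4L),
             level = rep(1:4, each = 8L),
             weight = as.vector(x$weights),
             stringsAsFactors = FALSE)
}

#' Read / write tariff tables as delimited text
#'
#' The on-disk format is a CSV with columns `domain`, `level`, `weight`;
#' `domain` uses the short names of [ascot_domains()].
#'
#' @param tariff An `ascot_tariff`.
#' @param path File path.
#' @param digits Decimals used when writing (the published convention is 3;
#'   use `NA` to keep full precision).
#' @return `read_tariff()` returns an `ascot_tariff`; `write_tariff()`
#'   returns `path` invisibly.
#' @export
write_tariff <- function(tariff, path, digits = 3) {
  df <- as.data.frame(tariff)
  if (!is.na(digits)) df$weight <- round(df$weight, digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tariff
#' @param label Tariff label for the object read back.
#' @export
read_tariff <- function(path, label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("domain", "level", "weight")
  if (!all(need %in% names(df))) stop("tariff file needs columns domain, level, weight")
  w <- matrix(NA_real_, 8L, 4L, dimnames = list(.domain_shorts, paste0("L", 1:4)))
  idx <- cbind(match(df$domain, .domain_shorts), df$level)
  if (anyNA(idx[, 1])) stop("unknown domain name in tariff file")
  w[idx] <- df$weight
  new_ascot_tariff(w, label %||% tools::file_path_sans_ext(basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conversion parameters (latent score to SC-QALY scale)
#'
#' The linear map `SC-QALY = slope * latent + intercept` anchoring latent
#' BWS scores to the QALY scale. `ascot_conversion()` returns the published
#' parameters: Japan `(0.221, -0.496)`, UK `(0.203, -0.466)`; by
#' construction of the anchoring constraint, `slope * latent(11111111) +
#' intercept = 1` up to the published rounding.
#'
#' @param label `"JP"` or `"UK"`.
#' @param slope,intercept Numeric scalars, `slope > 0`.
#' @return An object of class `ascot_conversion`.
#' @examples
#' ascot_conversion("JP")
#' @export
ascot_conversion <- function(label = c("JP", "UK")) {
  label <- match.arg(label)
  switch(label,
         JP = new_ascot_conversion(0.221, -0.496, "JP"),
         UK = new_ascot_conversion(0.203, -0.466, "UK"))
}

#' @rdname ascot_conversion
#' @export
new_ascot_conversion <- function(slope, intercept, label = "custom") {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            length(slope) == 1L, length(intercept) == 1L)
  if (!is.finite(slope) || slope <= 0) stop("conversion slope must be positive")
  structure(list(slope = slope, intercept = intercept, label = label),
            class = "ascot_conversion")
}

#' @export
print.ascot_conversion <- function(x, ...) {
  cat(sprintf("SC-QALY conversion '%s': score = %.3f * latent %+.3f\n",
              x$label, x$slope, x$intercept))
  invisible(x)
}
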