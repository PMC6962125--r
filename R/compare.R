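# Cross-tariff comparison over the full state space.

#' Intraclass correlation of paired scores
#'
#' Two-way intraclass correlation from the standard mean-squares
#' decomposition of the n x 2 score matrix. The default variant is
#' absolute-agreement single-measures ICC(A,1); consistency and
#' average-measures variants are available. Absolute-agreement variants
#' are sensitive to affine rescaling of one score vector; consistency
#' variants are not.
#'
#' @param x,y Numeric vectors of paired scores.
#' @param variant `"A1"` (absolute agreement, single measures; default),
#'   `"C1"` (consistency, single), `"A2"`, `"C2"` (average measures).
#' @return ICC value (scalar).
#' @export
icc_agreement <- function(x, y, variant = c("A1", "C1", "A2", "C2")) {
  variant <- match.arg(variant)
  if (length(x) != length(y) || length(x) < 2L) stop("need >= 2 pairs")
  m <- cbind(x, y)
  n <- nrow(m); k <- 2
  mu <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_total <- sum((m - mu)^2)
  ss_row <- k * sum((row_m - mu)^2)
  ss_col <- n * sum((col_m - mu)^2)
  if (ss_total <= .Machine$double.eps) stop("undefined ICC: zero variance")
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- (ss_total - ss_row - ss_col) / ((n - 1) * (k - 1))
  switch(variant,
         A1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
         C1 = (msr - mse) / (msr + (k - 1) * mse),
         A2 = (msr - mse) / (msr + (msc - mse) * k / n),
         C2 = (msr - mse) / msr)
}

#' Compare two tariffs over the full ASCOT state space
#'
#' Scores all `4^8 = 65536` states under two tariff/conversion pairs and
#' reports the agreement statistics: the number and percentage of states
#' where the second score strictly exceeds the first (ties counted
#' separately), the Pearson correlation, the agreement ICC (with a sweep
#' over all variants for transparency), and per-tariff score ranges.
#'
#' @param tariff_a,tariff_b `ascot_tariff` objects.
#' @param conv_a,conv_b Matching `ascot_conversion` objects.
#' @param icc_variant ICC variant reported as `icc` (see
#'   [icc_agreement()]).
#' @return An object of class `tariff_comparison`; its `scores` element is
#'   the full joint score table (`state`, `score_a`, `score_b`).
#' @examples
#' \donttest{
#' cmp <- compare_tariffs(ascot_tariff("JP"), ascot_conversion("JP"),
#'                        ascot_tariff("UK"), ascot_conversion("UK"))
#' cmp
#' }
#' @export
compare_tariffs <- function(tariff_a, conv_a, tariff_b, conv_b,
                            icc_variant = "A1") {
  states <- enumerate_states()
  lev <- parse_state(states)
  sa <- scqaly_score(lev, tariff_a, conv_a)
  sb <- scqaly_score(lev, tariff_b, conv_b)
  n <- length(states)
  sweep_v <- vapply(c("A1", "C1", "A2", "C2"),
                    function(v) icc_agreement(sa, sb, v), numeric(1))
  structure(list(
    label_a = tariff_a$label, label_b = tariff_b$label,
    n_states = n,
    n_b_higher = sum(sb > sa),
    n_a_higher = sum(sa > sb),
    n_ties = sum(sa == sb),
    pct_b_higher = 100 * mean(sb > sa),
    pearson = stats::cor(sa, sb),
    icc = unname(sweep_v[icc_variant]),
    icc_variant = icc_variant,
    icc_sweep = sweep_v,
    range_a = range(sa), range_b = range(sb),
    scores = data.frame(state = states, score_a = sa, score_b = sb,
                        stringsAsFactors = FALSE)),
    class = "tariff_comparison")
}

#' @export
print.tariff_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %d ASCOT states: %s (a) vs %s (b)\n",
              x$n_states, x$label_a, x$label_b))
  cat(sprintf("  b > a: %d states (%.1f%%); a > b: %d; ties: %d\n",
              x$n_b_higher, x$pct_b_higher, x$n_a_higher, x$n_ties))
  cat(sprintf("  Pearson r = %.3f; ICC(%s) = %.3f\n",
              x$pearson, x$icc_variant, x$icc))
  cat("  ICC sweep:",
      paste(sprintf("%s=%.3f", names(x$icc_sweep), x$icc_sweep), collapse = ", "),
      "\n")
  cat(sprintf("  score range a: [%.3f, %.3f]; b: [%.3f, %.3f]\n",
              x$range_a[1], x$range_a[2], x$range_b[1], x$range_b[2]))
  invisible(x)
}

#' Serialize a tariff comparison
#'
#' Writes `comparison.csv` (state, score_a, score_b) and
#' `comparison_summary.json` into `dir`.
#'
#' @param cmp A `tariff_comparison`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(cmp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cmp$scores, file.path(dir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(
    cmp[c("label_a", "label_b", "n_states", "n_b_higher", "n_a_higher",
          "n_ties", "pct_b_higher", "pearson", "icc", "icc_variant",
          "icc_sweep", "range_a", "range_b")],
    file.path(dir, "comparison_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
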