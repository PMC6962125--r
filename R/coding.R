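# Exploding sequential best-worst responses into sign-coded choice sets
# and building the 31-column design matrix.
#
# Each BWS task yields four choice occasions with shrinking alternative
# sets (8, 7, 6, 5): best, worst, second-best, second-worst, in pick
# order. Best-side occasions carry sign +1, worst-side occasions sign -1;
# the sign multiplies the domain and level indicators of every alternative
# in the occasion (the "-1 coding" of worst choices).

#' @include domains.R
NULL

.occasion_names <- c("best", "worst", "second_best", "second_worst")
.occasion_signs <- c(best = 1, worst = -1, second_best = 1, second_worst = -1)

#' Explode BWS responses into choice occasions
#'
#' Turns each (respondent, task) row into 26 alternative rows across four
#' choice occasions, removing previously picked domains in pick order.
#'
#' @param responses Data frame as produced by [simulate_bws()] (columns
#'   `respondent_id`, `task_index`, `profile`, `best`, `worst`,
#'   `second_best`, `second_worst`; extra columns are ignored).
#' @return Long data frame with one row per (occasion, alternative):
#'   `respondent_id`, `task_index`, `occasion` (one of best, worst,
#'   second_best, second_worst), `occ_id` (unique occasion index), `sign`,
#'   `alt` (domain short name), `level` (the profile's level of that
#'   domain) and `chosen` (0/1).
#' @export
explode_bws <- function(responses) {
  need <- c("respondent_id", "task_index", "profile", .occasion_names)
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  picks <- as.matrix(responses[, .occasion_names])
  pick_p <- matrix(match(picks, .domain_shorts), nrow = nrow(responses))
  if (anyNA(pick_p)) stop("picks must be domain short names")
  if (any(apply(pick_p, 1L, anyDuplicated) > 0L))
    stop("invalid response: the four picks must be distinct domains")

  nT <- nrow(responses)
  lev <- parse_state(responses$profile)
  avail <- matrix(TRUE, nT, 8L)
  out <- vector("list", 4L)
  for (k in 1:4) {
    idx <- which(t(avail))                      # task-major (row) order
    task_row <- (idx - 1L) %/% 8L + 1L
    alt_p <- (idx - 1L) %% 8L + 1L
    out[[k]] <- data.frame(
      respondent_id = responses$respondent_id[task_row],
      task_index = responses$task_index[task_row],
      occasion = .occasion_names[k],
      occ_id = (task_row - 1L) * 4L + k,
      sign = unname(.occasion_signs[k]),
      alt = .domain_shorts[alt_p],
      level = lev[cbind(task_row, alt_p)],
      chosen = as.integer(alt_p == pick_p[task_row, k]),
      stringsAsFactors = FALSE)
    avail[cbind(seq_len(nT), pick_p[, k])] <- FALSE
  }
  long <- do.call(rbind, out)
  long <- long[order(long$occ_id), , drop = FALSE]
  rownames(long) <- NULL
  # renumber occasions contiguously
  long$occ_id <- match(long$occ_id, unique(long$occ_id))
  long
}

.design_colnames <- c(
  paste0("d_", .nonref_shorts),
  paste0("l_", rep(.domain_shorts, each = 3L), "_", rep(1:3, times = 8L)))

#' Sign-coded design row for one alternative
#'
#' The 31-column coding of a single alternative: the domain indicator
#' equals the occasion sign (omitted for the reference domain, control)
#' and the level indicator for (domain, level) equals the sign (omitted
#' for the reference level 4). A control level-4 alternative codes to the
#' all-zero row.
#'
#' @param domain Domain short name (see [ascot_domains()]).
#' @param level Level 1-4.
#' @param sign +1 (best-side occasion) or -1 (worst-side occasion).
#' @return Named numeric vector of length 31.
#' @examples
#' code_choice_row("occupation", 1, +1)
#' @export
code_choice_row <- function(domain, level, sign) {
  p <- match(domain, .domain_shorts)
  if (is.na(p)) stop("unknown domain: ", domain)
  if (!level %in% 1:4) stop("level must be in 1-4")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  row <- stats::setNames(numeric(31L), .design_colnames)
  if (domain != "control") row[paste0("d_", domain)] <- sign
  if (level != 4L) row[paste0("l_", domain, "_", level)] <- sign
  row
}

#' Design matrix for exploded choice data
#'
#' Builds the n x 31 sign-coded matrix (7 domain indicator columns, control
#' omitted; 24 level indicator columns, level 4 omitted) for the long table
#' from [explode_bws()].
#'
#' @param long Long data frame from [explode_bws()].
#' @return Numeric matrix with 31 named columns, one row per alternative.
#' @export
bws_design_matrix <- function(long) {
  n <- nrow(long)
  p <- match(long$alt, .domain_shorts)
  X <- matrix(0, n, 31L, dimnames = list(NULL, .design_colnames))
  nonref <- p != 5L
  X[cbind(which(nonref), match(paste0("d_", long$alt[nonref]), .design_colnames))] <-
    long$sign[nonref]
  lv <- long$level != 4L
  X[cbind(which(lv),
          match(paste0("l_", long$alt[lv], "_", long$level[lv]), .design_colnames))] <-
    long$sign[lv]
  X
}

#' Apply response-time exclusion filters
#'
#' Excludes respondents with a total BWS time below `bws_min` minutes from
#' the BWS analysis set and respondents with a total cTTO time below
#' `tto_min` minutes from the TTO analysis set. The two filters are
#' independent (a respondent can remain in one set and not the other) and
#' both thresholds are strict: a respondent exactly at the threshold is
#' retained.
#'
#' @param bws BWS response table with columns `respondent_id`,
#'   `total_bws_minutes` (or `NULL`).
#' @param tto cTTO response table with columns `respondent_id`,
#'   `total_tto_minutes` (or `NULL`).
#' @param bws_min,tto_min Thresholds in minutes (defaults 4.5 and 5.0, the
#'   published exclusion rules).
#' @return List with the filtered `bws` and `tto` tables and a `report`
#'   listing counts and excluded respondent ids for each phase.
#' @export
filter_respondents <- function(bws = NULL, tto = NULL,
                               bws_min = 4.5, tto_min = 5.0) {
  one <- function(tab, col, thr) {
    if (is.null(tab)) return(list(tab = NULL, excluded = integer(), n = 0L))
    tm <- tab[[col]]
    if (is.null(tm)) stop("missing time column ", col)
    if (any(tm < 0)) stop("negative response times are invalid")
    per <- tapply(tm, tab$respondent_id, max)
    drop_ids <- names(per)[per < thr]
    list(tab = tab[!tab$respondent_id %in% drop_ids, , drop = FALSE],
         excluded = drop_ids, n = length(per))
  }
  b <- one(bws, "total_bws_minutes", bws_min)
  t <- one(tto, "total_tto_minutes", tto_min)
  list(bws = b$tab, tto = t$tab,
       report = list(
         bws = list(n_respondents = b$n, n_excluded = length(b$excluded),
                    excluded_ids = b$excluded, threshold_minutes = bws_min),
         tto = list(n_respondents = t$n, n_excluded = length(t$excluded),
                    excluded_ids = t$excluded, threshold_minutes = tto_min)))
}
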