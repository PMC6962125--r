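# ASCOT SCT4 domain model.
#
# Two orderings coexist and must not be confused:
#   * p-index: the estimation convention used for coefficients (control over
#     daily life is the reference domain, p = 5);
#   * questionnaire position: the order domains appear in the 8-digit state
#     string (control first), which is the order of the SCT4 instrument.
# All level matrices in this package are column-ordered by p-index; state
# strings are in questionnaire order. parse_state()/format_state() are the
# only places that translate between the two.

.domain_table <- data.frame(
  p = 1:8,
  short = c("accommodation", "safety", "food", "cleanliness",
            "control", "participation", "dignity", "occupation"),
  name = c("Accommodation cleanliness and comfort",
           "Personal safety",
           "Food and drink",
           "Personal cleanliness and comfort",
           "Control over daily life",
           "Social participation and involvement",
           "Dignity",
           "Occupation"),
  position = c(7L, 4L, 3L, 2L, 1L, 5L, 6L, 8L),
  stringsAsFactors = FALSE
)

# position k -> p-index of the domain printed at that position
.pos_to_p <- order(.domain_table$position)

.domain_shorts <- .domain_table$short
.nonref_shorts <- .domain_table$short[.domain_table$p != 5L]

#' ASCOT SCT4 scoring domains
#'
#' The eight scoring domains of the ASCOT four-level self-completion
#' questionnaire (SCT4). Each domain has a `p` index (the coefficient-table
#' convention, with "control over daily life" as reference domain `p = 5`)
#' and a `position` giving where the domain's level digit sits in the
#' 8-character state string (control first).
#'
#' The SCT4 instrument itself has nine items; the first dignity item is not
#' used in scoring and therefore does not appear here.
#'
#' @return A data frame with columns `p`, `short`, `name` and `position`.
#' @examples
#' ascot_domains()
#' @export
ascot_domains <- function() .domain_table

#' Parse ASCOT state strings
#'
#' Converts 8-digit state strings (questionnaire order, control first; digit
#' `1` is the best level, `4` the worst) into a matrix of levels with one
#' column per domain in p-index order.
#'
#' @param x Character vector of 8-character strings over the digits 1-4,
#'   e.g. `"24313222"` (second level of control, fourth level of personal
#'   cleanliness, ...).
#' @return Integer matrix with `length(x)` rows and 8 columns named by
#'   domain, columns in p-index order.
#' @examples
#' parse_state("24313222")
#' @seealso [format_state()], [enumerate_states()]
#' @export
parse_state <- function(x) {
  x <- as.character(x)
  if (anyNA(x)) stop("state strings must not be NA")
  bad_len <- nchar(x) != 8L
  if (any(bad_len)) {
    stop(sprintf("state '%s' does not have 8 characters", x[which(bad_len)[1]]))
  }
  digits <- matrix(utf8ToInt("0"), nrow = length(x), ncol = 8L)
  chars <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                  ncol = 8L, byrow = TRUE)
  lev <- suppressWarnings(array(as.integer(chars), dim = dim(chars)))
  bad <- is.na(lev) | lev < 1L | lev > 4L
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "state '%s': character '%s' at position %d is not a level in 1-4",
      x[i[1]], chars[i[1], i[2]], i[2]))
  }
  out <- lev[, .domain_table$position, drop = FALSE]
  colnames(out) <- .domain_shorts
  rownames(out) <- x
  out
}

#' Format level matrices as state strings
#'
#' Inverse of [parse_state()]: turns a matrix of levels (columns in p-index
#' order) back into 8-digit strings in questionnaire order.
#'
#' @param levels Integer matrix with 8 columns in p-index order (or a single
#'   length-8 vector), entries in 1-4.
#' @return Character vector of state strings.
#' @export
format_state <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  stopifnot(ncol(levels) == 8L)
  if (any(levels < 1L | levels > 4L)) stop("levels must be in 1-4")
  qo <- levels[, .pos_to_p, drop = FALSE]
  unname(apply(qo, 1L, paste0, collapse = ""))
}

#' Enumerate the full ASCOT state space
#'
#' All `4^8 = 65536` SCT4 states as strings, in lexicographic order of the
#' questionnaire-order state string (so the first state is `"11111111"` and
#' the last is `"44444444"`).
#'
#' @return Character vector of length 65536.
#' @examples
#' head(enumerate_states())
#' @export
enumerate_states <- function() {
  # expand.grid varies the first factor fastest; feed positions 8..1 so the
  # last string position ticks fastest, giving lexicographic string order
  g <- as.matrix(expand.grid(rep(list(1:4), 8L), KEEP.OUT.ATTRS = FALSE))
  g <- g[, 8:1, drop = FALSE]
  do.call(paste0, as.data.frame(g))
}

# Accepts either state strings or a pre-parsed level matrix; returns the
# level matrix (columns in p-index order).
.state_levels <- function(states) {
  if (is.character(states) || is.factor(states)) return(parse_state(as.character(states)))
  if (is.matrix(states) && ncol(states) == 8L) {
    storage.mode(states) <- "integer"
    if (any(states < 1L | states > 4L)) stop("levels must be in 1-4")
    return(states)
  }
  if (is.numeric(states) && length(states) == 8L) return(.state_levels(matrix(states, nrow = 1L)))
  stop("states must be 8-digit strings or an n x 8 level matrix")
}
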