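# Synthetic-survey generator.
#
# Generates BWS and cTTO datasets with the statistical structure the
# estimation pipeline assumes, so every downstream stage can be validated
# by parameter recovery in the absence of raw survey data. The defaults
# reproduce the published study conditions: 1050 respondents, 4 BWS blocks
# of 8 profiles drawn from a 32-profile design, 8 cTTO blocks of 8 states
# (64 states), sequential best/worst/second-best/second-worst choices from
# a latent utility with additive Gumbel noise, and log-normal response
# times placing a few percent of respondents under the exclusion
# thresholds (4.5 min BWS, 5.0 min cTTO).

#' Ground truth for the synthetic survey
#'
#' Bundles the data-generating parameters: the true utility coefficients,
#' optional respondent heterogeneity on the domain constants, the true
#' linear map from latent scores to the TTO scale, TTO noise, the answer
#' grid of the graduated 0-10 bar, and the response-time distributions.
#'
#' The true tariff implied by the coefficients (via [item_coefficients()]
#' and [rescale_weights()]) is used to generate TTO responses, keeping
#' generator and analyzer on the same scale.
#'
#' @param coefficients True `bws_coefficients`; defaults to the published
#'   Japanese conditional-logit estimates.
#' @param mixing Heterogeneity distribution of the domain constants:
#'   `"none"`, `"normal"` (`beta_p = m_p + s_p * eta`, `eta ~ N(0,1)`) or
#'   `"lognormal"` (`beta_p = exp(m_p + s_p * eta)`).
#' @param mixing_sd Scale `s_p`: a scalar or a vector named by the 7
#'   non-reference domain short names. Must be 0 when `mixing = "none"`.
#' @param conversion True `ascot_conversion` mapping latent scores to the
#'   TTO scale; defaults to the published Japanese parameters.
#' @param tto_noise_sd SD of the Gaussian noise added to the true state
#'   value of each cTTO response (utility units).
#' @param answer_grid Granularity of TTO answers in years (the graduated
#'   bar; 0.5 by default).
#' @param bws_time_meanlog,bws_time_sdlog,tto_time_meanlog,tto_time_sdlog
#'   Log-normal response-time parameters (minutes). Defaults match the
#'   observed medians (9.6 / 10.1 min) and put roughly 3-5% of respondents
#'   under the exclusion thresholds.
#' @return An object of class `ascot_truth`.
#' @export
ascot_truth <- function(coefficients = ascot_jp_mnl_coefficients(),
                        mixing = c("none", "normal", "lognormal"),
                        mixing_sd = 0,
                        conversion = ascot_conversion("JP"),
                        tto_noise_sd = 0.1,
                        answer_grid = 0.5,
                        bws_time_meanlog = log(9.6), bws_time_sdlog = 0.445,
                        tto_time_meanlog = log(10.1), tto_time_sdlog = 0.427) {
  mixing <- match.arg(mixing)
  stopifnot(inherits(coefficients, "bws_coefficients"),
            inherits(conversion, "ascot_conversion"),
            tto_noise_sd >= 0, answer_grid > 0)
  sd_vec <- stats::setNames(rep(0, 7L), .nonref_shorts)
  if (length(mixing_sd) == 1L && is.null(names(mixing_sd))) {
    sd_vec[] <- mixing_sd
  } else {
    bad <- setdiff(names(mixing_sd), .nonref_shorts)
    if (length(bad)) stop("unknown domain in mixing_sd: ", paste(bad, collapse = ", "))
    sd_vec[names(mixing_sd)] <- mixing_sd
  }
  if (any(sd_vec < 0)) stop("mixing_sd must be non-negative")
  if (mixing == "none" && any(sd_vec > 0))
    stop("mixing_sd must be zero when mixing = 'none'")
  structure(list(coefficients = coefficients, mixing = mixing,
                 mixing_sd = sd_vec, conversion = conversion,
                 tto_noise_sd = tto_noise_sd, answer_grid = answer_grid,
                 bws_time_meanlog = bws_time_meanlog, bws_time_sdlog = bws_time_sdlog,
                 tto_time_meanlog = tto_time_meanlog, tto_time_sdlog = tto_time_sdlog),
            class = "ascot_truth")
}

#' Tariff implied by a truth object
#'
#' The tariff obtained by rescaling the truth's (mean) coefficients - the
#' scale on which the generator produces TTO values.
#'
#' @param truth An `ascot_truth`.
#' @return An `ascot_tariff`.
#' @export
truth_tariff <- function(truth) {
  stopifnot(inherits(truth, "ascot_truth"))
  rescale_weights(item_coefficients(truth$coefficients), label = "truth")
}

#' Balanced blocked profile design
#'
#' Draws `n_profiles` distinct profiles, level-balanced within every domain
#' (each level appears `n_profiles / 4` times per domain, so every level of
#' every domain is represented), and splits them into `n_blocks` blocks.
#' The exact fractional-factorial design of the original studies is not
#' public; this balanced random design is the package's stand-in and is
#' fully determined by `seed`.
#'
#' @param n_profiles Total number of profiles (default 32, the BWS design;
#'   use 64 for the cTTO state design). Must be divisible by `n_blocks`
#'   and at least 4.
#' @param n_blocks Number of blocks respondents are randomized over.
#' @param seed Integer seed.
#' @return Data frame with columns `block` and `profile` (state string).
#' @examples
#' make_bws_design(32, 4, seed = 1)
#' @export
make_bws_design <- function(n_profiles = 32L, n_blocks = 4L, seed = 1L) {
  if (n_profiles %% n_blocks != 0)
    stop("design error: n_profiles must be divisible by n_blocks")
  if (n_profiles < 4L)
    stop("design error: need at least 4 profiles to cover all levels")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  for (try in 1:100) {
    lev <- vapply(1:8, function(p) sample(rep_len(1:4, n_profiles)),
                  integer(n_profiles))
    profiles <- format_state(lev)
    if (!anyDuplicated(profiles)) break
    if (try == 100) stop("design error: could not draw distinct balanced profiles")
  }
  data.frame(block = rep(seq_len(n_blocks), each = n_profiles / n_blocks),
             profile = profiles[sample.int(n_profiles)],
             stringsAsFactors = FALSE)
}

# RNG bookkeeping so simulators are seed-deterministic without clobbering
# the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.rgumbel <- function(n) -log(-log(stats::runif(n)))

# Respondent-level domain constants (n x 8 matrix, p order) under the
# truth's mixing distribution. Control (p = 5) is the fixed reference 0.
.respondent_betas <- function(truth, n) {
  cf <- .coef_vector(truth$coefficients)
  m <- stats::setNames(rep(0, 8L), .domain_shorts)
  m[.nonref_shorts] <- cf[paste0("d_", .nonref_shorts)]
  B <- matrix(rep(m, each = n), n, 8L, dimnames = list(NULL, .domain_shorts))
  if (truth$mixing != "none") {
    eta <- matrix(stats::rnorm(n * 7L), n, 7L)
    s <- truth$mixing_sd[.nonref_shorts]
    shifted <- sweep(eta, 2L, s, `*`)
    if (truth$mixing == "normal") {
      B[, .nonref_shorts] <- B[, .nonref_shorts] + shifted
    } else {
      B[, .nonref_shorts] <- exp(sweep(shifted, 2L,
                                       m[.nonref_shorts], `+`))
    }
  }
  B
}

#' Simulate best-worst scaling responses
#'
#' Each respondent is allocated one design block and values its profiles by
#' four sequential choices: best among 8 domains, worst among the remaining
#' 7, second-best among 6, second-worst among 5. Choices maximize
#' `V + Gumbel` (best side) or `-V + Gumbel` (worst side) with fresh Gumbel
#' draws at every choice occasion, matching the independence assumption of
#' the exploded conditional-logit likelihood. `V` for a domain is its
#' (possibly respondent-specific) domain constant plus the level effect of
#' the level shown in the profile.
#'
#' @param truth An `ascot_truth`.
#' @param design Blocked profile design from [make_bws_design()].
#' @param n_respondents Number of respondents (default 1050).
#' @param seed Integer seed.
#' @return Data frame with one row per (respondent, task): `respondent_id`,
#'   `block`, `task_index`, `profile`, `best`, `worst`, `second_best`,
#'   `second_worst` (domain short names) and `total_bws_minutes`.
#' @export
simulate_bws <- function(truth, design = make_bws_design(seed = seed),
                         n_respondents = 1050L, seed = 1L) {
  stopifnot(inherits(truth, "ascot_truth"), n_respondents >= 1L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n_blocks <- max(design$block)
  block_of <- sample(rep_len(seq_len(n_blocks), n_respondents))
  betas <- .respondent_betas(truth, n_respondents)
  cf <- .coef_vector(truth$coefficients)
  lev_eff <- matrix(0, 8L, 4L, dimnames = list(.domain_shorts, NULL))
  lev_eff[cbind(rep(1:8, each = 3L), rep(1:3, 8L))] <-
    cf[paste0("l_", rep(.domain_shorts, each = 3L), "_", rep(1:3, 8L))]

  per_block <- split(design$profile, design$block)
  tasks_per <- length(per_block[[1]])
  resp <- rep(seq_len(n_respondents), each = tasks_per)
  task <- rep(seq_len(tasks_per), times = n_respondents)
  prof <- unlist(per_block[block_of], use.names = FALSE)
  lev <- parse_state(prof)                       # (n*tasks) x 8, p order
  nT <- length(prof)

  # deterministic utility of each domain within each task
  V <- betas[resp, , drop = FALSE]
  for (p in 1:8) V[, p] <- V[, p] + lev_eff[p, lev[, p]]

  picks <- matrix(NA_integer_, nT, 4L)
  avail <- matrix(TRUE, nT, 8L)
  sgn <- c(1, -1, 1, -1)                         # best, worst, 2nd-best, 2nd-worst
  for (k in 1:4) {
    U <- sgn[k] * V + matrix(.rgumbel(nT * 8L), nT, 8L)
    U[!avail] <- -Inf
    picks[, k] <- max.col(U, ties.method = "first")
    avail[cbind(seq_len(nT), picks[, k])] <- FALSE
  }
  times <- stats::rlnorm(n_respondents, truth$bws_time_meanlog, truth$bws_time_sdlog)
  data.frame(respondent_id = resp,
             block = block_of[resp],
             task_index = task,
             profile = prof,
             best = .domain_shorts[picks[, 1]],
             worst = .domain_shorts[picks[, 2]],
             second_best = .domain_shorts[picks[, 3]],
             second_worst = .domain_shorts[picks[, 4]],
             total_bws_minutes = times[resp],
             stringsAsFactors = FALSE)
}

#' Simulate composite time trade-off responses
#'
#' Each respondent is allocated one block of states and values each state
#' once. The true value is the truth conversion applied to the state's
#' latent score under the truth tariff, plus Gaussian noise, clamped to
#' `[-1, 1]` (the lead-time design bounds scores below at -1). Values
#' `>= 0` produce a better-than-dead record with `answer_years = 10 * v`;
#' negative values produce a worse-than-dead (lead-time) record with
#' `answer_years = 10 * (v + 1)`. Answers are rounded to the truth's
#' answer grid.
#'
#' @param truth An `ascot_truth`.
#' @param design Blocked state design (e.g. `make_bws_design(64, 8, seed)`).
#' @param n_respondents Number of respondents (default 1050).
#' @param seed Integer seed.
#' @return Data frame with columns `respondent_id`, `block`, `state`,
#'   `wtd` (logical worse-than-dead flag), `answer_years` and
#'   `total_tto_minutes`.
#' @export
simulate_tto <- function(truth, design = make_bws_design(64L, 8L, seed = seed),
                         n_respondents = 1050L, seed = 1L) {
  stopifnot(inherits(truth, "ascot_truth"), n_respondents >= 1L)
  if (nrow(design) == 0L) stop("state design is empty")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n_blocks <- max(design$block)
  block_of <- sample(rep_len(seq_len(n_blocks), n_respondents))
  tariff <- truth_tariff(truth)
  true_v <- stats::setNames(
    scqaly_score(design$profile, tariff, truth$conversion), design$profile)

  per_block <- split(design$profile, design$block)
  states_per <- length(per_block[[1]])
  resp <- rep(seq_len(n_respondents), each = states_per)
  st <- unlist(per_block[block_of], use.names = FALSE)
  v <- true_v[st] + stats::rnorm(length(st), 0, truth$tto_noise_sd)
  v <- pmin(pmax(v, -1), 1)
  wtd <- v < 0
  years <- ifelse(wtd, 10 * (v + 1), 10 * v)
  years <- pmin(pmax(round(years / truth$answer_grid) * truth$answer_grid, 0), 10)
  times <- stats::rlnorm(n_respondents, truth$tto_time_meanlog, truth$tto_time_sdlog)
  data.frame(respondent_id = resp,
             block = block_of[resp],
             state = st,
             wtd = unname(wtd),
             answer_years = unname(years),
             total_tto_minutes = times[resp],
             stringsAsFactors = FALSE)
}

#' Write a synthetic survey to disk
#'
#' Writes `bws_responses.csv`, `tto_responses.csv` and a `truth.json`
#' sidecar recording the true parameters and seeds.
#'
#' @param bws,tto Data frames from [simulate_bws()] / [simulate_tto()].
#' @param truth The `ascot_truth` that generated them.
#' @param dir Output directory (created if needed).
#' @param seed Seed(s) to record in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_survey <- function(bws, tto, truth, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bws, file.path(dir, "bws_responses.csv"), row.names = FALSE)
  utils::write.csv(tto, file.path(dir, "tto_responses.csv"), row.names = FALSE)
  cf <- truth$coefficients
  side <- list(
    seed = seed,
    mixing = truth$mixing,
    mixing_sd = as.list(truth$mixing_sd),
    conversion = list(slope = truth$conversion$slope,
                      intercept = truth$conversion$intercept),
    tto_noise_sd = truth$tto_noise_sd,
    answer_grid = truth$answer_grid,
    domain_constants = stats::setNames(as.list(cf$domain$estimate), cf$domain$domain),
    level_effects = stats::setNames(as.list(cf$level$estimate),
                                    paste0(cf$level$domain, "_", cf$level$level)))
  jsonlite::write_json(side, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
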