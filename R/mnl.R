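# Plain conditional logit (exploded maximum likelihood) for the
# sequential best-worst model.

# Internal container shared by the MNL and mixed estimators.
# Rows are ordered by occasion; occasions are contiguous.
.prepare_choice_data <- function(long,
                                 cluster_scheme = c("respondent", "respondent_by_sign")) {
  cluster_scheme <- match.arg(cluster_scheme)
  long <- long[order(long$occ_id), , drop = FALSE]
  occ <- long$occ_id
  chosen <- long$chosen == 1L
  occ_sizes <- tabulate(occ)
  if (any(tabulate(occ[chosen]) != 1L))
    stop("each occasion must have exactly one chosen alternative")
  clus_key <- if (cluster_scheme == "respondent") {
    as.character(long$respondent_id)
  } else {
    paste0(long$respondent_id, "/", ifelse(long$sign > 0, "best", "worst"))
  }
  # number clusters by radix-sorted key so downstream draw assignment is
  # invariant to row/cluster ordering of the input
  cluster <- match(clus_key, sort(unique(clus_key), method = "radix"))
  # occasion-level cluster (constant within occasion)
  occ_first <- which(!duplicated(occ))
  list(X = bws_design_matrix(long),
       occ = occ, chosen = chosen, cluster = cluster,
       cluster_occ = cluster[occ_first],
       n_occ = max(occ), n_cluster = max(cluster),
       pidx = match(long$alt, .domain_shorts),
       sgn = long$sign,
       cluster_scheme = cluster_scheme)
}

# log-likelihood, gradient and (optionally) Hessian of the exploded
# conditional logit at beta
.mnl_eval <- function(beta, cd, hessian = FALSE) {
  eta <- drop(cd$X %*% beta)
  if (max(abs(eta)) > 50) {
    # rare (line-search overshoot): per-occasion max-subtraction
    occ_max <- vapply(split(eta, cd$occ), max, numeric(1))
  } else {
    occ_max <- numeric(cd$n_occ)
  }
  e <- exp(eta - occ_max[cd$occ])
  denom <- drop(rowsum(e, cd$occ))
  P <- e / denom[cd$occ]
  ll <- sum(eta[cd$chosen]) - sum(log(denom) + occ_max)
  resid <- (cd$chosen - P)
  grad <- drop(crossprod(cd$X, resid))
  out <- list(ll = ll, grad = grad, P = P, resid = resid)
  if (hessian) {
    W <- cd$X * P
    M <- rowsum(W, cd$occ)
    out$hess <- -(crossprod(cd$X, W) - crossprod(M))
  }
  out
}

#' Log-probability of one choice occasion
#'
#' Conditional-logit log-probability of the chosen alternative in a single
#' sign-coded occasion: `log[exp(V_chosen) / sum_alt exp(V_alt)]`, where
#' `V` is the linear index `X %*% beta` of the sign-coded rows (the sign
#' is already folded into `X`, so worst-side occasions need no special
#' handling here). Numerically guarded by max-subtraction.
#'
#' @param X Numeric matrix of coded alternatives (rows) by parameters
#'   (columns), e.g. built with [code_choice_row()].
#' @param chosen Row index of the chosen alternative.
#' @param beta Coefficient vector conformable with `X`.
#' @return Log-probability (scalar).
#' @examples
#' X <- rbind(code_choice_row("food", 1, 1), code_choice_row("safety", 2, 1))
#' occasion_logprob(X, 1, rep(0, 31))  # log(1/2)
#' @export
occasion_logprob <- function(X, chosen, beta) {
  v <- drop(as.matrix(X) %*% beta)
  m <- max(v)
  unname(v[chosen] - m - log(sum(exp(v - m))))
}

#' Fit the sequential best-worst conditional logit
#'
#' Maximizes the exploded conditional-logit likelihood over all choice
#' occasions (best from 8, worst from 7, second-best from 6, second-worst
#' from 5, worst-side occasions sign-coded with -1). Estimation is by
#' BFGS with analytic gradient followed by Newton polishing with the
#' analytic Hessian; standard errors are cluster-robust (sandwich) by
#' respondent.
#'
#' @param long Long choice data from [explode_bws()].
#' @param start Optional start vector (length 31); defaults to zero.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @return A [bws_coefficients] object (`model_id = "mnl"`).
#' @export
fit_bws_mnl <- function(long, start = NULL, reltol = 1e-10) {
  cd <- .prepare_choice_data(long, "respondent")
  qrX <- qr(cd$X)
  if (qrX$rank < ncol(cd$X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    bad <- setdiff(colnames(cd$X), colnames(cd$X)[keep])
    stop("identifiability error: collinear or unobserved columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- start %||% numeric(31L)
  cache <- new.env(parent = emptyenv())
  evalat <- function(b) {
    key <- paste(b, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- .mnl_eval(b, cd)
      cache$key <- key
    }
    cache$val
  }
  opt <- stats::optim(beta, fn = function(b) -evalat(b)$ll,
                      gr = function(b) -evalat(b)$grad,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = reltol))
  beta <- opt$par
  # Newton polish: drive the mean score below tolerance
  for (i in 1:50) {
    ev <- .mnl_eval(beta, cd, hessian = TRUE)
    if (max(abs(ev$grad)) / cd$n_occ < 1e-9) break
    step <- tryCatch(solve(ev$hess, ev$grad), error = function(e) NULL)
    if (is.null(step)) break
    cand <- beta - step
    if (.mnl_eval(cand, cd)$ll < ev$ll - 1e-8) break
    beta <- cand
  }
  ev <- .mnl_eval(beta, cd, hessian = TRUE)
  if (max(abs(ev$grad)) / cd$n_occ > 1e-5)
    stop("estimation error: conditional logit did not converge ",
         sprintf("(mean score %.2e, log-likelihood %.2f)",
                 max(abs(ev$grad)) / cd$n_occ, ev$ll))
  bread <- solve(-ev$hess)
  S <- rowsum(cd$X * ev$resid, cd$cluster)
  vc <- bread %*% crossprod(S) %*% bread
  se <- sqrt(diag(vc))
  names(beta) <- names(se) <- colnames(cd$X)
  .make_coef_table(beta, se, model_id = "mnl", cluster_scheme = "respondent",
                   log_likelihood = ev$ll, n_draws = 0L, seed = NA_integer_)
}

.make_coef_table <- function(beta, se, model_id, cluster_scheme,
                             log_likelihood, n_draws, seed, mixing = NULL) {
  dom_idx <- paste0("d_", .nonref_shorts)
  lev_idx <- paste0("l_", rep(.domain_shorts, each = 3L), "_", rep(1:3, 8L))
  bws_coefficients(
    domain = data.frame(domain = .nonref_shorts,
                        estimate = unname(beta[dom_idx]),
                        se = unname(se[dom_idx]), stringsAsFactors = FALSE),
    level = data.frame(domain = rep(.domain_shorts, each = 3L),
                       level = rep(1:3, times = 8L),
                       estimate = unname(beta[lev_idx]),
                       se = unname(se[lev_idx]), stringsAsFactors = FALSE),
    model_id = model_id, cluster_scheme = cluster_scheme,
    log_likelihood = log_likelihood, n_draws = n_draws, seed = seed,
    mixing = mixing)
}
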