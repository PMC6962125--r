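# Mixed logit by simulated maximum likelihood.
#
# Random coefficients are placed on the 7 non-reference domain constants
# (the level effects are fixed), with normal mixing
#   beta_p = m_p + s_p * eta,  eta ~ N(0, 1)
# or log-normal mixing
#   beta_p = exp(m_p + s_p * eta).
# The likelihood contribution of a cluster (a respondent, or a
# respondent's best/worst side under the "respondent_by_sign" scheme) is
# the average over draws of the product of its occasions' conditional-
# logit probabilities. Draws are burned-in Halton sequences with a seeded
# Cranley-Patterson rotation, a fixed segment per cluster, so the
# simulated likelihood is deterministic given the seed and invariant to
# the ordering of clusters in the data.

.halton_primes <- c(2, 3, 5, 7, 11, 13, 17)

.radical_inverse <- function(i, base) {
  r <- numeric(length(i))
  f <- 1 / base
  while (any(i > 0)) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

# n x dim Halton matrix, burned and rotated (shift in [0,1)^dim)
.halton <- function(n, dim, burn = 50L, shift = NULL) {
  idx <- seq.int(burn + 1L, burn + n)
  H <- vapply(seq_len(dim), function(d) .radical_inverse(idx, .halton_primes[d]),
              numeric(n))
  if (!is.null(shift)) H <- sweep(H, 2L, shift, `+`) %% 1
  pmin(pmax(H, 1e-10), 1 - 1e-10)
}

# Precomputed structures for the simulated likelihood.
# EM is the (n_cluster * 7) x n_draws matrix of standard-normal draws,
# rows blocked by mixing dimension d = 1..7, within block by cluster id
# (clusters are numbered by the radix-sorted cluster key, so the draw a
# cluster receives does not depend on row order).
.mixed_data <- function(long, cluster_scheme, n_draws, seed) {
  cd <- .prepare_choice_data(long, cluster_scheme)
  lev_cols <- grep("^l_", colnames(cd$X))
  dom_of_p <- c(1:4, NA, 5:7)            # p-index -> mixing dimension
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  shift <- stats::runif(7L)
  H <- .halton(cd$n_cluster * n_draws, 7L, shift = shift)
  # row (c-1)*n_draws + r, dim d  ->  EM[(d-1)*n_c + c, r]
  EM <- matrix(0, cd$n_cluster * 7L, n_draws)
  for (d in 1:7) {
    EM[(d - 1L) * cd$n_cluster + seq_len(cd$n_cluster), ] <-
      t(matrix(stats::qnorm(H[, d]), nrow = n_draws))
  }
  hasdom <- cd$pidx != 5L
  domcol <- dom_of_p[cd$pidx]
  emrow <- (domcol - 1L) * cd$n_cluster + cd$cluster  # NA for control rows
  # 0-based structures for the compiled kernel; occasions are contiguous
  occ_sizes <- tabulate(cd$occ)
  list(cd = cd,
       Xlev = cd$X[, lev_cols, drop = FALSE],
       hasdom = hasdom,
       domcol = domcol,
       emrow = emrow,
       EM = EM, n_draws = n_draws,
       k_emrow = ifelse(hasdom, emrow - 1L, -1L),
       k_occ_ptr = c(0L, cumsum(occ_sizes)),
       k_chosen_row = which(cd$chosen) - 1L,
       k_cluster_occ = cd$cluster_occ - 1L,
       k_cluster_row = cd$cluster - 1L)
}

# Simulated log-likelihood (and analytic gradient / per-cluster scores).
# theta = (24 level effects, 7 means, 7 raw scales); scales enter as |s|.
# The draw loop runs in the compiled kernel (src/mixed_kernel.cpp); the
# gradient and OPG scores are assembled here from the kernel's per-row
# weighted residual factors.
.mixed_eval <- function(theta, md, distribution, want_grad = TRUE) {
  cd <- md$cd
  lev <- theta[1:24]; m <- theta[25:31]; s <- theta[32:38]
  # the likelihood is smooth in the raw scale (sign is unidentified because
  # eta is symmetric); |s| is taken only when reporting
  n_c <- cd$n_cluster
  base <- drop(md$Xlev %*% lev)
  dom_rep <- rep(1:7, each = n_c)
  linEM <- md$EM * s[dom_rep] + m[dom_rep]
  bM <- if (distribution == "lognormal") exp(linEM) else linEM

  k <- mixed_kernel(base, bM, md$EM, md$k_emrow, cd$sgn,
                    md$k_occ_ptr, md$k_chosen_row, cd$chosen,
                    md$k_cluster_occ, md$k_cluster_row,
                    n_c, distribution == "lognormal", want_grad)
  if (!want_grad) return(list(ll = k$ll))
  ll <- k$ll
  sgn <- cd$sgn; hd <- md$hasdom
  A <- k$A
  Bm <- if (distribution == "lognormal") k$Bm else k$A
  Bs <- k$Bs
  grad_lev <- drop(crossprod(md$Xlev, A))
  gm <- .sum_by7((sgn * Bm)[hd], md$domcol[hd])
  gs <- .sum_by7((sgn * Bs)[hd], md$domcol[hd])
  grad <- c(grad_lev, gm, gs)

  # per-cluster scores (OPG standard errors)
  n <- length(base)
  Srow <- matrix(0, n, 38L)
  Srow[, 1:24] <- md$Xlev * A
  Srow[cbind(which(hd), 24L + md$domcol[hd])] <- (sgn * Bm)[hd]
  Srow[cbind(which(hd), 31L + md$domcol[hd])] <- (sgn * Bs)[hd]
  S <- rowsum(Srow, cd$cluster)
  list(ll = ll, grad = grad, scores = S)
}

.sum_by7 <- function(x, g) {
  out <- numeric(7L)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Fit the sequential best-worst mixed logit
#'
#' Simulated maximum likelihood for the exploded best-worst model with
#' random domain constants (normal or log-normal mixing; level effects
#' fixed). The simulated likelihood averages, over burned-in rotated
#' Halton draws, the product of each cluster's occasion probabilities;
#' clusters are whole respondents (`"respondent"`) or each respondent's
#' best and worst sides separately (`"respondent_by_sign"`). Scale
#' parameters are estimated unconstrained and reported as `|s|`. Standard
#' errors are from the outer product of per-cluster score gradients (BHHH).
#'
#' For log-normal mixing the reported domain parameters are the
#' log-location `m_p` and log-scale `s_p` of `beta_p = exp(m_p + s_p eta)`,
#' not the median or mean of `beta_p`.
#'
#' @param long Long choice data from [explode_bws()].
#' @param distribution `"normal"` or `"lognormal"` mixing.
#' @param cluster_scheme `"respondent"` or `"respondent_by_sign"`.
#' @param n_draws Halton draws per cluster (at least 50; default 500).
#' @param seed Seed for the Halton rotation.
#' @param start Optional `bws_coefficients` (e.g. an MNL fit) supplying
#'   start values; by default an MNL fit is run first.
#' @param s_start Start value for the mixing scales.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum BFGS iterations.
#' @return A [bws_coefficients] with the mixing scales in `$mixing`.
#' @export
fit_bws_mixed <- function(long, distribution = c("normal", "lognormal"),
                          cluster_scheme = c("respondent", "respondent_by_sign"),
                          n_draws = 500L, seed = 1L, start = NULL,
                          s_start = 0.1, reltol = 1e-8, maxit = 200L) {
  distribution <- match.arg(distribution)
  cluster_scheme <- match.arg(cluster_scheme)
  if (n_draws < 1L) stop("n_draws must be positive")
  md <- .mixed_data(long, cluster_scheme, n_draws, seed)
  if (is.null(start)) start <- fit_bws_mnl(long)
  sv <- .coef_vector(start)
  m0 <- sv[paste0("d_", .nonref_shorts)]
  if (distribution == "lognormal") m0 <- log(pmax(m0, 0.05))
  theta <- c(sv[grep("^l_", names(sv))], m0, rep(s_start, 7L))

  cache <- new.env(parent = emptyenv())
  evalat <- function(t) {
    key <- paste(t, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- .mixed_eval(t, md, distribution)
      cache$key <- key
    }
    cache$val
  }
  opt <- stats::optim(theta, fn = function(t) -evalat(t)$ll,
                      gr = function(t) -evalat(t)$grad,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0 && opt$convergence != 1)
    stop("estimation error: mixed logit optimizer failed (code ",
         opt$convergence, ")")
  ev <- evalat(opt$par)
  opg <- crossprod(ev$scores)
  vc <- tryCatch(solve(opg), error = function(e) {
    warning("near-singular information matrix; ridge-regularized SEs")
    solve(opg + diag(1e-6 * max(diag(opg)), nrow(opg)))
  })
  se <- sqrt(pmax(diag(vc), 0))
  beta <- opt$par
  nm <- c(paste0("l_", rep(.domain_shorts, each = 3L), "_", rep(1:3, 8L)),
          paste0("d_", .nonref_shorts),
          paste0("s_", .nonref_shorts))
  names(beta) <- names(se) <- nm
  mixing <- data.frame(domain = .nonref_shorts,
                       estimate = abs(unname(beta[paste0("s_", .nonref_shorts)])),
                       se = unname(se[paste0("s_", .nonref_shorts)]),
                       stringsAsFactors = FALSE)
  .make_coef_table(beta[c(paste0("d_", .nonref_shorts),
                          paste0("l_", rep(.domain_shorts, each = 3L), "_", rep(1:3, 8L)))],
                   se[c(paste0("d_", .nonref_shorts),
                        paste0("l_", rep(.domain_shorts, each = 3L), "_", rep(1:3, 8L)))],
                   model_id = paste0("mixed_", distribution),
                   cluster_scheme = cluster_scheme,
                   log_likelihood = ev$ll, n_draws = n_draws, seed = seed,
                   mixing = mixing)
}
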