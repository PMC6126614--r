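## Negative binomial dispersion estimation: per-gene adjusted profile
## maximum likelihood, a parametric mean-dispersion trend, and empirical
## Bayes shrinkage toward that trend.

ALPHA_MIN <- 1e-8
ALPHA_MAX <- 10

## Adjusted profile log-likelihood of dispersion `alpha` for one gene,
## holding the fitted cell means fixed. The adjustment term
## -1/2 log det(X'WX) (here: the cell-mean parameterization, so the
## determinant factorizes over cells) compensates the downward bias of
## plain ML when several mean parameters are estimated from few samples.
nb_adj_profile_ll <- function(alpha, k, mu, group_idx) {
  ok <- mu > 0
  ll <- sum(stats::dnbinom(k[ok], size = 1 / alpha, mu = mu[ok], log = TRUE))
  w <- mu / (1 + alpha * mu)
  cr <- 0
  for (idx in group_idx) {
    s <- sum(w[idx])
    if (s > 0) cr <- cr + log(s)
  }
  ll - 0.5 * cr
}

## Precomputed per-cell sample indices for a grouping factor.
group_indices <- function(groups) split(seq_along(groups), groups)

## Fitted cell means given offsets: q_g = sum(k)/sum(sf), mu_j = sf_j q_g.
cell_means_mu <- function(k, group_idx, sf) {
  mu <- numeric(length(k))
  for (idx in group_idx)
    mu[idx] <- sf[idx] * (sum(k[idx]) / sum(sf[idx]))
  mu
}

maximize_ll <- function(f, lower = log(ALPHA_MIN), upper = log(ALPHA_MAX)) {
  opt <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = 1e-7)
  cand <- c(opt$maximum, lower, upper)
  vals <- c(opt$objective, f(lower), f(upper))
  cand[which.max(vals)]
}

#' Genewise dispersion estimate for one gene
#'
#' Maximizes the negative binomial likelihood of a single gene's counts
#' over the dispersion, profiling out the mean structure (fitted cell
#' means with size-factor offsets) and applying a degrees-of-freedom
#' adjustment. The estimate is bounded to `[1e-8, 10]`.
#'
#' @param counts_gene integer vector of counts for one gene.
#' @param groups factor assigning each sample to a design cell.
#' @param sf size factors, same length as `counts_gene`.
#' @return dispersion estimate, or `NA` for an all-zero gene.
#' @export
genewise_dispersion <- function(counts_gene, groups, sf) {
  groups <- as.factor(groups)
  if (length(counts_gene) - nlevels(groups) < 2L)
    stop_fmt("need at least 2 residual degrees of freedom")
  if (all(counts_gene == 0)) return(NA_real_)
  gi <- group_indices(groups)
  mu <- cell_means_mu(counts_gene, gi, sf)
  f <- function(l) nb_adj_profile_ll(exp(l), counts_gene, mu, gi)
  exp(maximize_ll(f))
}

#' Fit the parametric mean-dispersion trend
#'
#' Iterated weighted least-squares fit of `alpha ~ a0 + a1 / mu`.
#' Genewise dispersion estimates have multiplicative, right-skewed
#' errors, so each pass weights genes by the inverse squared fitted
#' value (a Gamma-family working model) and excludes outliers whose
#' ratio to the current fit falls outside `[1e-4, 15]`; this removes
#' the downward bias a plain least-squares fit shows on skewed
#' estimates. Both coefficients are constrained non-negative. With fewer
#' than 10 usable genes the fit falls back to a constant trend at the
#' median genewise estimate, with a warning.
#'
#' @param alpha_hat genewise dispersion estimates.
#' @param mu_bar mean normalized counts per gene.
#' @return list with elements `a0`, `a1` and `fn(mu)` evaluating the trend.
#' @export
fit_dispersion_trend <- function(alpha_hat, mu_bar) {
  use <- is.finite(alpha_hat) & is.finite(mu_bar) & mu_bar >= 1
  y <- alpha_hat[use]
  x <- 1 / mu_bar[use]
  if (length(y) < 10L) {
    warning("fewer than 10 usable genes; constant dispersion trend")
    a0 <- stats::median(alpha_hat, na.rm = TRUE)
    return(list(a0 = a0, a1 = 0, fn = function(mu) rep(a0, length(mu))))
  }
  co <- c(mean(y), 0)
  for (it in seq_len(20L)) {
    f <- pmax(co[1L] + co[2L] * x, 1e-8)
    ratio <- y / f
    keep <- ratio > 1e-4 & ratio < 15
    w <- 1 / f^2
    X <- cbind(1, x)[keep, , drop = FALSE]
    wk <- w[keep]
    co_new <- tryCatch(
      as.numeric(solve(crossprod(X * sqrt(wk)), crossprod(X * wk, y[keep]))),
      error = function(e) co)
    if (co_new[2L] < 0)
      co_new <- c(max(sum(wk * y[keep]) / sum(wk), 0), 0)
    if (co_new[1L] < 0)
      co_new <- c(0, max(sum(wk * x[keep] * y[keep]) / sum(wk * x[keep]^2), 0))
    if (max(abs(co_new - co)) < 1e-8 * (1 + max(abs(co)))) {
      co <- co_new
      break
    }
    co <- co_new
  }
  a0 <- co[1L]
  a1 <- co[2L]
  list(a0 = a0, a1 = a1, fn = function(mu) a0 + a1 / mu)
}

## Width of the log-normal dispersion prior: spread of log genewise
## estimates around the trend minus the expected sampling variance of a
## log dispersion estimate at `df` residual degrees of freedom, floored
## at sd 0.25.
estimate_prior_sd <- function(alpha_hat, alpha_trend, df) {
  use <- is.finite(alpha_hat) & is.finite(alpha_trend) & alpha_trend > 0
  r <- log(alpha_hat[use]) - log(alpha_trend[use])
  s2 <- if (sum(use) >= 3L) stats::mad(r)^2 else 0
  samp_var <- trigamma(max(df / 2, 0.5))
  sqrt(max(s2 - samp_var, 0.25^2))
}

#' Shrink genewise dispersions toward the trend
#'
#' Maximum a posteriori estimate combining each gene's adjusted profile
#' likelihood with a log-normal prior centered at the trend value. The
#' prior width is estimated from the spread of log genewise estimates
#' around the trend, minus the expected sampling variance
#' (`trigamma((m - p) / 2)`), and floored at 0.25. The shrunken value
#' always lies between the genewise estimate and the trend in log space.
#'
#' @param counts count matrix restricted to the analyzed samples.
#' @param groups factor of design cells, one entry per sample.
#' @param sf size factors.
#' @param alpha_hat genewise estimates (`NA` for flagged genes).
#' @param alpha_trend trend evaluated at each gene's mean normalized count.
#' @param prior_sd prior standard deviation on the log scale; estimated
#'   when `NULL`.
#' @return numeric vector of shrunken dispersions (`NA` where
#'   `alpha_hat` is `NA`).
#' @export
shrink_dispersions <- function(counts, groups, sf, alpha_hat, alpha_trend,
                               prior_sd = NULL) {
  groups <- as.factor(groups)
  if (is.null(prior_sd))
    prior_sd <- estimate_prior_sd(alpha_hat, alpha_trend,
                                  length(sf) - nlevels(groups))
  gi <- group_indices(groups)
  out <- rep(NA_real_, length(alpha_hat))
  for (i in seq_along(alpha_hat)) {
    ah <- alpha_hat[i]
    at <- alpha_trend[i]
    if (!is.finite(ah)) next
    if (!is.finite(at) || at <= 0) {
      out[i] <- ah
      next
    }
    lo <- min(log(ah), log(at))
    hi <- max(log(ah), log(at))
    if (hi - lo < 1e-10) {
      out[i] <- ah
      next
    }
    k <- counts[i, ]
    mu <- cell_means_mu(k, gi, sf)
    lat <- log(at)
    f <- function(l)
      nb_adj_profile_ll(exp(l), k, mu, gi) - (l - lat)^2 / (2 * prior_sd^2)
    out[i] <- exp(maximize_ll(f, lo, hi))
  }
  out
}

#' Full dispersion workflow for a count matrix
#'
#' Genewise adjusted-profile estimates, a parametric trend fitted on
#' genes with mean normalized count of at least 1, and empirical Bayes
#' shrinkage toward the trend.
#'
#' @inheritParams shrink_dispersions
#' @return data frame with columns `gene`, `mu_bar`, `alpha_genewise`,
#'   `alpha_trend`, `alpha_final` and logical `flagged` (all-zero genes);
#'   the trend coefficients and prior sd are attached as attributes
#'   `trend` and `prior_sd`.
#' @export
estimate_dispersions <- function(counts, groups, sf, prior_sd = NULL) {
  validate_count_matrix(counts)
  groups <- as.factor(groups)
  norm <- normalize_counts(counts, stats::setNames(sf, colnames(counts)))
  mu_bar <- rowMeans(norm)
  n <- nrow(counts)
  gi <- group_indices(groups)
  alpha_gw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    k <- counts[i, ]
    if (all(k == 0)) next
    mu <- cell_means_mu(k, gi, sf)
    f <- function(l) nb_adj_profile_ll(exp(l), k, mu, gi)
    alpha_gw[i] <- exp(maximize_ll(f))
  }
  trend <- fit_dispersion_trend(alpha_gw, mu_bar)
  alpha_tr <- trend$fn(pmax(mu_bar, 1e-8))
  alpha_tr <- pmin(pmax(alpha_tr, ALPHA_MIN), ALPHA_MAX)
  if (is.null(prior_sd))
    prior_sd <- estimate_prior_sd(alpha_gw, alpha_tr,
                                  length(sf) - nlevels(groups))
  alpha_final <- shrink_dispersions(counts, groups, sf, alpha_gw, alpha_tr,
                                    prior_sd = prior_sd)
  res <- data.frame(gene = rownames(counts), mu_bar = mu_bar,
                    alpha_genewise = alpha_gw, alpha_trend = alpha_tr,
                    alpha_final = alpha_final,
                    flagged = !is.finite(alpha_gw),
                    row.names = NULL)
  attr(res, "trend") <- c(a0 = trend$a0, a1 = trend$a1)
  attr(res, "prior_sd") <- prior_sd
  res
}
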