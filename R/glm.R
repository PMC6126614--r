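## Per-gene negative binomial GLM with log link and size-factor offsets,
## Wald tests on single coefficients, and Benjamini-Hochberg adjustment.
## Coefficients are fitted in natural log and reported in log2.

#' Build the 2x2 interaction design matrix
#'
#' Treatment (0/1) coding with declared reference levels: column 1 is
#' the intercept, column 2 indicates the non-reference strain, column 3
#' the non-reference RNA fraction (polysomal when `type_ref = "total"`),
#' and column 4 their product, the interaction whose Wald test defines
#' differential translational efficiency.
#'
#' @param design sample design data frame (see [read_sample_table()]).
#' @param strain_ref reference strain (the "strain B" of the TE ratio).
#' @param type_ref reference RNA fraction, default `"total"`.
#' @return numeric matrix with one row per sample and columns
#'   `intercept`, `strain`, `fraction`, `interaction`.
#' @export
build_design <- function(design, strain_ref, type_ref = "total") {
  validate_sample_design(design)
  strains <- unique(design$strain)
  if (length(strains) != 2L)
    stop_fmt("TE contrast needs exactly 2 strains (got %d); run pairwise",
             length(strains))
  if (!strain_ref %in% strains)
    stop_fmt("reference strain '%s' not among: %s", strain_ref,
             paste(strains, collapse = ", "))
  fractions <- unique(design$fraction)
  if (length(fractions) != 2L)
    stop_fmt("need both total and polysomal samples")
  xs <- as.numeric(design$strain != strain_ref)
  xt <- as.numeric(design$fraction != type_ref)
  X <- cbind(intercept = 1, strain = xs, fraction = xt,
             interaction = xs * xt)
  if (qr(X)$rank < 4L)
    stop_fmt("design is not full rank: a strain/fraction cell is missing")
  rownames(X) <- design$sample_id
  X
}

## Vectorized IRLS across genes sharing one design matrix.
## counts: G x N; X: N x p; sf: N; alpha: length G.
## Returns log2-scale coefficients and standard errors.
nb_glm_matrix <- function(counts, X, sf, alpha, tol = 1e-8, max_iter = 100L) {
  G <- nrow(counts)
  N <- ncol(counts)
  p <- ncol(X)
  off <- log(sf)
  K <- counts
  ## start from weighted LS on the log of pseudo-normalized counts
  Z0 <- log(sweep(K + 0.5, 2L, sf, "/"))
  B <- Z0 %*% X %*% solve(crossprod(X))
  converged <- rep(FALSE, G)
  diverged <- rep(FALSE, G)
  active <- rep(TRUE, G)
  for (iter in seq_len(max_iter)) {
    idx <- which(active)
    if (length(idx) == 0L) break
    ETA <- B[idx, , drop = FALSE] %*% t(X)
    ETA <- sweep(ETA, 2L, off, "+")
    if (any(bad <- apply(abs(ETA) > 50, 1L, any))) {
      diverged[idx[bad]] <- TRUE
      active[idx[bad]] <- FALSE
      idx <- idx[!bad]
      if (length(idx) == 0L) break
      ETA <- ETA[!bad, , drop = FALSE]
    }
    MU <- exp(ETA)
    A <- alpha[idx]
    W <- MU / (1 + A * MU)
    Z <- ETA - rep(off, each = length(idx)) + (K[idx, , drop = FALSE] - MU) / MU
    for (r in seq_along(idx)) {
      g <- idx[r]
      w <- W[r, ]
      Xw <- X * w
      bnew <- tryCatch(
        as.numeric(solve(crossprod(X, Xw), crossprod(Xw, Z[r, ]))),
        error = function(e) rep(NA_real_, p))
      if (anyNA(bnew)) {
        diverged[g] <- TRUE
        active[g] <- FALSE
        next
      }
      delta <- max(abs(bnew - B[g, ])) / log(2)
      B[g, ] <- bnew
      if (delta < tol) {
        converged[g] <- TRUE
        active[g] <- FALSE
      }
    }
  }
  ## observed Fisher information at the optimum
  SE <- matrix(NA_real_, G, p)
  MUhat <- matrix(NA_real_, G, N)
  for (g in which(converged)) {
    eta <- as.numeric(X %*% B[g, ]) + off
    mu <- exp(eta)
    MUhat[g, ] <- mu
    wobs <- mu * (1 + alpha[g] * K[g, ]) / (1 + alpha[g] * mu)^2
    info <- crossprod(X * wobs, X)
    SE[g, ] <- tryCatch(sqrt(diag(solve(info))),
                        error = function(e) rep(NA_real_, p))
  }
  colnames(B) <- colnames(SE) <- colnames(X)
  list(beta = B / log(2), se = SE / log(2), mu_hat = MUhat,
       converged = converged & !diverged)
}

#' Fit the negative binomial GLM for one gene
#'
#' Iteratively reweighted least squares on the log link with fixed
#' dispersion and `log(sf)` offsets. Convergence requires the maximum
#' coefficient change to fall below `1e-8` (log2 units) within 100
#' iterations; genes whose likelihood diverges (e.g. an all-zero design
#' cell) are flagged unconverged.
#'
#' @param counts_gene integer count vector for one gene.
#' @param dm design matrix from [build_design()] (or any full-rank
#'   design).
#' @param sf size factors.
#' @param alpha fixed NB dispersion for this gene.
#' @return list with `beta` (log2), `se` (log2), `mu_hat` (fitted
#'   means), and logical `converged`.
#' @export
fit_nb_glm <- function(counts_gene, dm, sf, alpha) {
  fit <- nb_glm_matrix(matrix(as.numeric(counts_gene), nrow = 1L), dm, sf,
                       alpha)
  list(beta = fit$beta[1L, ], se = fit$se[1L, ], mu_hat = fit$mu_hat[1L, ],
       converged = fit$converged[1L])
}

#' Wald test of a single GLM coefficient
#'
#' @param fit result of [fit_nb_glm()].
#' @param coef_index index of the tested coefficient (4 = interaction).
#' @return list with `stat` (z), `p` (two-sided normal), and the tested
#'   index. Unconverged fits or non-finite standard errors give `NA`.
#' @export
wald_test <- function(fit, coef_index) {
  b <- unname(fit$beta[coef_index])
  s <- unname(fit$se[coef_index])
  if (!isTRUE(fit$converged) || !is.finite(s) || s <= 0)
    return(list(stat = NA_real_, p = NA_real_, coef_index = coef_index))
  z <- b / s
  list(stat = z, p = 2 * stats::pnorm(-abs(z)), coef_index = coef_index)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min over j >= i of min(1, m p_(j) / j)` over the sorted
#' p-values; missing values are excluded from `m` and returned as `NA`.
#'
#' @param p vector of p-values in `[0, 1]`, `NA` allowed.
#' @return vector of adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop_fmt("p-values must lie in [0, 1]")
  o <- order(pv)
  adj <- pmin(1, m * pv[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out[ok[o]] <- adj
  out
}

## Shared engine: size factors, dispersions, per-gene GLM and Wald test
## on one coefficient, BH across tested genes.
nb_pipeline <- function(counts, design, X, groups, coef_index,
                        sf_scope = "joint", prior_sd = NULL) {
  design <- align_design(counts, design)
  sf <- size_factors_scoped(counts, design, sf_scope)
  testable <- rowSums(counts > 0) >= 2L
  disp <- estimate_dispersions(counts[testable, , drop = FALSE], groups, sf)
  fit <- nb_glm_matrix(counts[testable, , drop = FALSE], X, sf,
                       disp$alpha_final)
  norm <- normalize_counts(counts, sf)
  base_mean <- rowMeans(norm)
  G <- nrow(counts)
  res <- data.frame(gene = rownames(counts), baseMean = base_mean,
                    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, padj = NA_real_, converged = FALSE,
                    row.names = NULL)
  b <- fit$beta[, coef_index]
  s <- fit$se[, coef_index]
  z <- ifelse(fit$converged & is.finite(s) & s > 0, b / s, NA_real_)
  res$log2fc[testable] <- ifelse(fit$converged, b, NA_real_)
  res$se[testable] <- ifelse(fit$converged, s, NA_real_)
  res$stat[testable] <- z
  res$p[testable] <- 2 * stats::pnorm(-abs(z))
  res$converged[testable] <- fit$converged
  res$padj <- adjust_bh(res$p)
  attr(res, "size_factors") <- sf
  attr(res, "dispersions") <- disp
  attr(res, "fit") <- fit
  attr(res, "testable") <- testable
  res
}

#' Two-group differential expression within one RNA fraction
#'
#' Composes the pipeline used for the per-fraction differential
#' expression runs: median-ratio size factors on the analyzed subset,
#' dispersion estimation and shrinkage, a per-gene NB GLM with a single
#' strain coefficient, Wald test, and BH adjustment. Genes with nonzero
#' counts in fewer than 2 subset samples are reported with missing
#' statistics.
#'
#' @param counts full count matrix.
#' @param design sample design covering all columns of `counts`.
#' @param contrast character triple `(factor, levelA, levelB)`; only
#'   `"strain"` is supported as factor. `log2fc > 0` means higher in
#'   `levelA`.
#' @param subset named character vector filtering samples, e.g.
#'   `c(fraction = "total")`.
#' @param sf_scope `"joint"` (default) or `"per-fraction"` size factors.
#' @return data frame with columns `gene`, `baseMean`, `log2fc`, `se`,
#'   `stat`, `p`, `padj`, `converged`; size factors and dispersion table
#'   are attached as attributes.
#' @export
run_de <- function(counts, design, contrast, subset = NULL,
                   sf_scope = "joint") {
  stopifnot(length(contrast) == 3L)
  if (contrast[1L] != "strain")
    stop_fmt("only contrasts on 'strain' are supported")
  design <- align_design(counts, design)
  keep <- rep(TRUE, nrow(design))
  if (!is.null(subset))
    for (nm in names(subset)) keep <- keep & design[[nm]] == subset[[nm]]
  keep <- keep & design$strain %in% contrast[2:3]
  design <- design[keep, , drop = FALSE]
  counts <- counts[, design$sample_id, drop = FALSE]
  if (contrast[2L] == contrast[3L]) {
    ## degenerate contrast of a level against itself: no difference by
    ## construction
    return(data.frame(gene = rownames(counts),
                      baseMean = rowMeans(counts), log2fc = 0, se = NA_real_,
                      stat = 0, p = 1, padj = 1, converged = TRUE,
                      row.names = NULL))
  }
  missing_lv <- setdiff(contrast[2:3], unique(design$strain))
  if (length(missing_lv) > 0L)
    stop_fmt("strain level(s) absent: %s", paste(missing_lv, collapse = ", "))
  xs <- as.numeric(design$strain == contrast[2L])
  X <- cbind(intercept = 1, strain = xs)
  groups <- factor(design$strain, levels = contrast[3:2])
  nb_pipeline(counts, design, X, groups, coef_index = 2L,
              sf_scope = sf_scope)
}
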