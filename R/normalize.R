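#' Median-of-ratios size factors
#'
#' Computes per-sample size factors by the median-ratio method: each
#' gene positive in every sample contributes the ratio of its count to
#' its geometric mean across samples, and the size factor of a sample is
#' the median of these ratios. Factors are deliberately not rescaled to
#' geometric mean one; only their ratios matter downstream.
#'
#' @param counts count matrix (genes x samples).
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_ratio <- function(counts) {
  validate_count_matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop_fmt(paste("no gene has positive counts in every sample;",
                   "filter samples or supply a pseudo-reference"))
  k <- counts[ref, , drop = FALSE]
  log_geo <- rowMeans(log(k))
  sf <- apply(log(k) - log_geo, 2L, stats::median)
  sf <- exp(sf)
  stopifnot(all(is.finite(sf)), all(sf > 0))
  sf
}

#' Divide counts by size factors
#'
#' @param counts count matrix.
#' @param sf named size-factor vector covering every sample in `counts`.
#' @return real-valued matrix of normalized counts, `counts[i, j] / sf[j]`.
#' @export
normalize_counts <- function(counts, sf) {
  validate_count_matrix(counts)
  missing <- setdiff(colnames(counts), names(sf))
  if (length(missing) > 0L)
    stop_fmt("no size factor for sample(s): %s",
             paste(missing, collapse = ", "))
  sweep(counts, 2L, sf[colnames(counts)], "/")
}

## Size factors for a subset of samples, either jointly or separately
## within each RNA fraction. Per-fraction mirrors the source study's
## "each condition individually" normalization.
size_factors_scoped <- function(counts, design, scope = c("joint", "per-fraction")) {
  scope <- match.arg(scope)
  design <- align_design(counts, design)
  if (scope == "joint") return(size_factors_median_ratio(counts))
  sf <- numeric(ncol(counts))
  names(sf) <- colnames(counts)
  for (fr in unique(design$fraction)) {
    cols <- design$sample_id[design$fraction == fr]
    sf[cols] <- size_factors_median_ratio(counts[, cols, drop = FALSE])
  }
  sf
}
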