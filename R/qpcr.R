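## qPCR relative expression: per-sample normalization to the geometric
## mean of reference genes, condition fold changes, and replicate
## testing with family-wise error control.

#' Validate a Cq table
#'
#' @param cq data frame with columns `sample_id`, `condition`, `gene`,
#'   `cq` (quantification cycle, in (0, 45)), logical `is_reference`,
#'   and optional `efficiency` (per-gene amplification efficiency,
#'   default 2).
#' @return the table, invisibly, with `efficiency` filled in.
#' @export
validate_cq_table <- function(cq) {
  need <- c("sample_id", "condition", "gene", "cq", "is_reference")
  missing <- setdiff(need, names(cq))
  if (length(missing) > 0L)
    stop_fmt("Cq table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(!is.finite(cq$cq)) || any(cq$cq <= 0 | cq$cq >= 45))
    stop_fmt("Cq values must lie in (0, 45)")
  if (is.null(cq$efficiency)) cq$efficiency <- 2
  if (any(cq$efficiency <= 1))
    stop_fmt("amplification efficiency must exceed 1")
  invisible(cq)
}

#' Relative expression from Cq values
#'
#' Per sample, the normalization factor is the geometric mean over
#' reference genes of `E^(-Cq)`; the relative level of gene `g` is
#' `E_g^(-Cq_g)` divided by that factor. Fold changes against the
#' reference condition are ratios of condition means. Samples missing
#' any reference gene are dropped with a warning.
#'
#' @param cq validated Cq table (see [validate_cq_table()]).
#' @param condition_ref reference condition for fold changes.
#' @return list with `levels` (per sample and gene: `rel_level`) and
#'   `fold_change` (per gene and condition, vs `condition_ref`).
#' @export
relative_expression <- function(cq, condition_ref) {
  cq <- validate_cq_table(cq)
  if (is.null(cq$efficiency)) cq$efficiency <- 2
  if (!condition_ref %in% cq$condition)
    stop_fmt("reference condition '%s' not present", condition_ref)
  ref_genes <- unique(cq$gene[cq$is_reference])
  if (length(ref_genes) == 0L) stop_fmt("no reference genes in table")
  keep <- vapply(split(cq, cq$sample_id),
                 function(d) all(ref_genes %in% d$gene[d$is_reference]),
                 logical(1))
  dropped <- names(keep)[!keep]
  if (length(dropped) > 0L) {
    warning(sprintf("dropping sample(s) missing reference genes: %s",
                    paste(dropped, collapse = ", ")))
    cq <- cq[!cq$sample_id %in% dropped, , drop = FALSE]
  }
  cq$quantity <- cq$efficiency^(-cq$cq)
  nf <- vapply(split(cq, cq$sample_id),
               function(d) geometric_mean(d$quantity[d$is_reference]),
               numeric(1))
  cq$rel_level <- cq$quantity / nf[cq$sample_id]
  levels <- cq[, c("sample_id", "condition", "gene", "is_reference",
                   "rel_level")]
  agg <- stats::aggregate(rel_level ~ gene + condition, data = levels,
                          FUN = mean)
  ref_mean <- agg[agg$condition == condition_ref, c("gene", "rel_level")]
  names(ref_mean)[2L] <- "ref_level"
  fc <- merge(agg, ref_mean, by = "gene")
  fc$fold_change <- fc$rel_level / fc$ref_level
  fc <- fc[, c("gene", "condition", "fold_change")]
  list(levels = levels, fold_change = fc[order(fc$gene, fc$condition), ])
}

#' Test relative expression between conditions
#'
#' `method = "holm_sidak_t"`: per-gene two-sample t-test between exactly
#' two conditions, Holm-Sidak adjusted across genes (family-wise error
#' control). `method = "anova_sidak"`: per-gene one-way ANOVA across all
#' conditions with Sidak-adjusted pairwise t contrasts.
#'
#' @param levels `levels` component of [relative_expression()] (or any
#'   data frame with columns `gene`, `condition`, `rel_level`).
#' @param method testing procedure, see above.
#' @param alpha significance level recorded in the output.
#' @return for `holm_sidak_t`: data frame `gene`, `stat`, `p`, `p_adj`,
#'   `significant`. For `anova_sidak`: data frame `gene`, `contrast`,
#'   `p_anova`, `p`, `p_adj`.
#' @export
test_expression <- function(levels, method = c("holm_sidak_t", "anova_sidak"),
                            alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "condition", "rel_level") %in% names(levels)))
  conds <- unique(levels$condition)
  by_gene <- split(levels, levels$gene)
  if (any(vapply(by_gene, function(d)
    any(table(factor(d$condition, conds)) < 2), logical(1))))
    stop_fmt("need at least 2 replicates per condition for every gene")
  if (method == "holm_sidak_t") {
    if (length(conds) != 2L)
      stop_fmt("holm_sidak_t requires exactly 2 conditions (got %d)",
               length(conds))
    res <- do.call(rbind, lapply(names(by_gene), function(g) {
      d <- by_gene[[g]]
      a <- d$rel_level[d$condition == conds[1L]]
      b <- d$rel_level[d$condition == conds[2L]]
      if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
        return(data.frame(gene = g, stat = 0, p = 1))
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(gene = g, stat = unname(tt$statistic), p = tt$p.value)
    }))
    res$p_adj <- holm_sidak(res$p)
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
    return(res)
  }
  pairs <- utils::combn(as.character(conds), 2L, simplify = FALSE)
  do.call(rbind, lapply(names(by_gene), function(g) {
    d <- by_gene[[g]]
    fit <- stats::aov(rel_level ~ condition, data = d)
    p_anova <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    rows <- lapply(pairs, function(pr) {
      a <- d$rel_level[d$condition == pr[1L]]
      b <- d$rel_level[d$condition == pr[2L]]
      p <- if (stats::sd(c(a - mean(a), b - mean(b))) == 0) 1
           else stats::t.test(a, b, var.equal = TRUE)$p.value
      data.frame(gene = g, contrast = paste(pr, collapse = " vs "),
                 p_anova = p_anova, p = p,
                 p_adj = min(1, 1 - (1 - p)^length(pairs)))
    })
    do.call(rbind, rows)
  }))
}
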