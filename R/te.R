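## Differential translational efficiency: the interaction Wald test and
## the plug-in log2 ratio-of-ratios, plus the Venn-style classification
## of genes from separate polysomal and total DE runs.

#' Plug-in TE log2 fold change
#'
#' `log2((A_poly / A_total) / (B_poly / B_total))` from four positive
#' normalized group means. Any zero or non-finite mean yields `NA`.
#'
#' @param a_poly,a_total,b_poly,b_total normalized group means
#'   (vectorized).
#' @return numeric vector of TE log2 fold changes.
#' @export
plug_in_te_lfc <- function(a_poly, a_total, b_poly, b_total) {
  out <- log2((a_poly / a_total) / (b_poly / b_total))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Differential translational efficiency between two strains
#'
#' Fits the full interaction model to all total and polysomal samples
#' of the two strains (treatment coding, reference = `strain_b`, total
#' fraction), tests the interaction coefficient with a Wald test, and
#' adjusts with Benjamini-Hochberg. A positive `log2fc` means the
#' polysomal:total ratio is higher in `strain_a` than in `strain_b`
#' (higher translational efficiency in `strain_a`). The plug-in estimate
#' from arithmetic normalized group means is reported alongside the GLM
#' estimate.
#'
#' @param counts count matrix.
#' @param design sample design.
#' @param strain_a,strain_b the two compared strains; `strain_b` is the
#'   reference of the ratio-of-ratios.
#' @param sf_scope `"joint"` (default) or `"per-fraction"` size factors;
#'   per-fraction reproduces normalization of each RNA fraction
#'   individually.
#' @return data frame with columns `gene`, `baseMean`, `log2fc` (GLM
#'   interaction estimate), `te_lfc_plugin`, `se`, `stat`, `p`, `padj`,
#'   `converged`.
#' @export
run_te <- function(counts, design, strain_a, strain_b,
                   sf_scope = "joint") {
  design <- align_design(counts, design)
  keep <- design$strain %in% c(strain_a, strain_b)
  design <- design[keep, , drop = FALSE]
  counts <- counts[, design$sample_id, drop = FALSE]
  for (st in c(strain_a, strain_b)) for (fr in c("total", "polysomal"))
    if (!any(design$strain == st & design$fraction == fr))
      stop_fmt("missing %s/%s samples: the 2x2 layout is incomplete", st, fr)
  X <- build_design(design, strain_ref = strain_b)
  groups <- factor(paste(design$strain, design$fraction, sep = "."))
  res <- nb_pipeline(counts, design, X, groups, coef_index = 4L,
                     sf_scope = sf_scope)
  sf <- attr(res, "size_factors")
  norm <- normalize_counts(counts, sf)
  gm <- function(st, fr)
    rowMeans(norm[, design$strain == st & design$fraction == fr,
                  drop = FALSE])
  res$te_lfc_plugin <- plug_in_te_lfc(gm(strain_a, "polysomal"),
                                      gm(strain_a, "total"),
                                      gm(strain_b, "polysomal"),
                                      gm(strain_b, "total"))
  cols <- c("gene", "baseMean", "log2fc", "te_lfc_plugin", "se", "stat",
            "p", "padj", "converged")
  out <- res[, cols]
  for (a in c("size_factors", "dispersions", "fit", "testable"))
    attr(out, a) <- attr(res, a)
  out
}

#' Classify genes from separate polysomal and total DE runs
#'
#' Venn-style partition of the shared gene universe at an adjusted
#' p-value threshold: a gene is up (down) on an axis when it is
#' significant with positive (negative) log2 fold change in that run.
#' Labels are `poly_only_up`, `both_up`, `total_only_up`,
#' `poly_only_down`, `both_down`, `total_only_down` and `ns`. In the
#' rare conflicting case (significant up on one axis, down on the
#' other) the polysomal axis takes precedence. Genes not tested in both
#' runs are labeled `ns` and flagged.
#'
#' @param de_poly,de_total result tables from [run_de()] over the same
#'   strain contrast in the polysomal and total fraction.
#' @param alpha adjusted p-value threshold, default 0.01.
#' @return data frame with columns `gene`, `class` (factor over the
#'   seven labels) and logical `untested`.
#' @export
classify_genes <- function(de_poly, de_total, alpha = 0.01) {
  if (!setequal(de_poly$gene, de_total$gene) ||
      nrow(de_poly) != nrow(de_total))
    stop_fmt("DE tables cover different gene universes")
  de_total <- de_total[match(de_poly$gene, de_total$gene), , drop = FALSE]
  sig_p <- !is.na(de_poly$padj) & de_poly$padj < alpha
  sig_t <- !is.na(de_total$padj) & de_total$padj < alpha
  up_p <- sig_p & de_poly$log2fc > 0
  dn_p <- sig_p & de_poly$log2fc < 0
  up_t <- sig_t & de_total$log2fc > 0
  dn_t <- sig_t & de_total$log2fc < 0
  lvl <- c("poly_only_up", "both_up", "total_only_up",
           "poly_only_down", "both_down", "total_only_down", "ns")
  cls <- rep("ns", nrow(de_poly))
  cls[up_t] <- "total_only_up"
  cls[dn_t] <- "total_only_down"
  cls[up_p & up_t] <- "both_up"
  cls[dn_p & dn_t] <- "both_down"
  cls[up_p & !up_t] <- "poly_only_up"
  cls[dn_p & !dn_t] <- "poly_only_down"
  untested <- is.na(de_poly$p) | is.na(de_total$p)
  data.frame(gene = de_poly$gene, class = factor(cls, levels = lvl),
             untested = untested, row.names = NULL)
}
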