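# Independent oracles used to cross-check the GLM code path.

# One-parameter NB cell-mean estimate: solves the score equation
# sum_j (k_j - sf_j q) / (1 + alpha sf_j q) = 0 by bisection, a code
# path entirely separate from the multi-coefficient IRLS solver.
oracle_cell_mean <- function(k, sf, alpha) {
  if (sum(k) == 0) return(0)
  score <- function(q) sum((k - sf * q) / (1 + alpha * sf * q))
  upper <- max(k / sf) * 10 + 10
  stats::uniroot(score, c(1e-12, upper), tol = 1e-13)$root
}

# Ratio-of-ratios TE estimate from the four independent cell solves.
oracle_te_lfc <- function(counts_gene, design, sf, alpha,
                          strain_a, strain_b) {
  q <- function(st, fr) {
    sel <- design$strain == st & design$fraction == fr
    oracle_cell_mean(counts_gene[sel], sf[sel], alpha)
  }
  log2((q(strain_a, "polysomal") / q(strain_a, "total")) /
         (q(strain_b, "polysomal") / q(strain_b, "total")))
}

# Small deterministic count matrix with dimnames, for io tests.
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_counts <- function(body, genes = NULL, samples = NULL) {
  m <- as.matrix(body)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes %||% paste0("g", seq_len(nrow(m))),
                      samples %||% paste0("s", seq_len(ncol(m))))
  m
}
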