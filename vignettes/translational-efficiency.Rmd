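---
title: "Methods: differential translational efficiency from paired total and polysomal RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential translational efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teprof)
```

## The question and the model

Polysome profiling yields two RNA pools per animal strain: the **total**
transcriptome and the **polysome-associated** subset that is being actively
translated. Comparing strains within either pool is ordinary differential
expression. The interesting biology — transcripts whose ribosome loading
changes independently of abundance — lives in the *interaction*: does the
polysomal:total ratio of a gene differ between strains?

`teprof` models raw counts for gene $i$, sample $j$ as negative binomial with
mean $s_j q_{ij}$ and dispersion $\alpha_i$ (variance
$\mu + \alpha\mu^2$), where

$$\log q_{ij} = \beta_0 + \beta_1 X_{\text{strain}} +
\beta_2 X_{\text{fraction}} + \beta_3 X_{\text{strain}}X_{\text{fraction}}$$

with treatment coding: $X_{\text{strain}} = 1$ for the non-reference strain,
$X_{\text{fraction}} = 1$ for polysomal RNA. $\beta_3$, reported in log2, is
exactly the TE log2 fold change
$\log_2\frac{A_{\text{poly}}/A_{\text{total}}}{B_{\text{poly}}/B_{\text{total}}}$,
and its Wald test defines differential TE. All coefficients are fitted by IRLS
in natural log (offset $\log s_j$, fixed $\alpha$), converged when the largest
coefficient change falls below $10^{-8}$ log2 units, and reported in log2.
Genes whose likelihood diverges — typically an all-zero design cell, where the
MLE sits at $-\infty$ — are flagged unconverged and excluded from testing
rather than reported at an arbitrary boundary.

## Normalization

Size factors use the median-of-ratios method: with reference set $R$ (genes
positive in every sample), $s_j = \text{median}_{i \in R}\,
k_{ij}/(\prod_j k_{ij})^{1/n}$. Factors are deliberately *not* rescaled to
geometric mean one; every downstream quantity depends only on their ratios.
Zeros are handled by the strict all-positive reference set — no
pseudo-reference is used, and an empty reference set is an error directing the
user to filter.

The source study normalized each RNA fraction separately, which is available
as `sf_scope = "per-fraction"`; the default is joint estimation across the
tested samples. The choice barely matters for the interaction estimate: a
per-fraction rescale multiplies both strains' polysomal means equally and
cancels from the ratio of ratios. It does shift the per-fraction baselines, so
both modes are exposed and recorded in output attributes.

## Dispersion

Per-gene dispersion is estimated by maximizing the *adjusted* profile
likelihood: the NB log-likelihood at fixed fitted cell means, plus
$-\tfrac12 \log\det(X^TWX)$, which here factorizes into per-cell sums of IRLS
weights. The adjustment matters: with four cell means estimated from twelve
samples, unadjusted ML underestimates $\alpha$ by roughly $p/m$ (a third),
which propagates into standard errors that are too small and a null
type-I error near 10% at the nominal 5%. With the adjustment the observed
null fraction of raw $p < 0.05$ sits near 6% (see the acceptance suite).
Estimates are bounded to $[10^{-8}, 10]$; constant genes land on the floor,
all-zero genes are flagged and never tested.

The mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted to genewise
estimates of genes with mean normalized count of at least 1, by iterated
weighted least squares with weights $1/\hat f^2$ (a Gamma-family working
model) and exclusion of genes whose ratio to the current fit leaves
$[10^{-4}, 15]$. Genewise dispersion estimates have right-skewed,
multiplicative errors; an unweighted or bisquare fit is attenuated by 20–35%
on the $a_1$ component in our recovery simulations, while the Gamma-weighted
fit recovers both coefficients within a few percent at 5,000 genes. Both
coefficients are constrained non-negative; with fewer than 10 usable genes the
trend degrades to the median genewise estimate with a warning.

Shrinkage maximizes the adjusted profile likelihood plus a log-normal prior
centered at the trend. The prior sd is the spread (MAD) of log genewise
estimates around the log trend minus the expected sampling variance
$\psi_1((m-p)/2)$, floored at 0.25 — the floor prevents the prior from
collapsing when the genewise spread is mostly sampling noise. The optimizer
searches the log-interval between the genewise estimate and the trend value,
which both guarantees the documented betweenness invariant and is the global
optimum whenever the profile likelihood is unimodal (the generic case).
Deliberate simplifications relative to heavier production pipelines: no
dispersion-outlier refit rule, no iterating means and dispersions to a joint
fixed point.

## Testing and classification

Wald statistics use standard errors from the inverse observed Fisher
information at the optimum; two-sided p-values come from the standard normal,
and adjustment is Benjamini–Hochberg step-up, the convention of this
analysis stack. Genes tested
are those with nonzero counts in at least two samples of the analyzed subset.
No independent filtering, no fold-change shrinkage, no outlier-count
refitting: each omission is a documented simplification, and downstream gene
counts will differ from pipelines that apply them.

`classify_genes()` partitions the shared universe of two per-fraction DE runs
at an adjusted-p threshold into `poly_only_up`, `both_up`, `total_only_up`,
their down-regulated mirrors, and `ns`. One corner case is genuinely
ambiguous: a gene significantly up on one axis and down on the other belongs
to two Venn sets. To keep the labels a partition, the polysomal axis wins;
such genes are vanishingly rare in practice (they require opposite significant
strain effects in the two fractions).

Two TE estimates are reported side by side: the GLM interaction coefficient
(`log2fc`) and the plug-in ratio-of-ratios of arithmetic normalized group
means (`te_lfc_plugin`). They agree closely but not identically when size
factors differ within a cell — the saturated-design MLE solves
$\sum_j (k_j - s_j q)/(1 + \alpha s_j q) = 0$, a *weighted* normalized mean.
The test suite exploits this: an independent per-cell bisection solver
reproduces the IRLS interaction estimate to $10^{-10}$, which validates the
solver without ever comparing it to itself.

## The synthetic-data generator

`simulate_counts()` inverts the model above, so every planted effect is known
exactly. Defaults state the world the package is tested in:

| parameter | default | why |
|---|---|---|
| layout | 2 strains × 2 fractions × 3 replicates | the study design it emulates |
| genes | 5,000 | desk-scale but large enough for stable FDR/trend estimates |
| baseline abundance | lognormal, median 250, sdlog 1.5 | ~20M reads over ~20k genes |
| dispersion trend | $a_0 = 0.02$, $a_1 = 2$ | typical isogenic whole-worm bulk RNA-seq |
| size factors | uniform on (0.75, 1.3) | realistic library-size spread |
| TE effects | 10% of genes, \|log2FC\| ∈ [0.25, 1.65] | spans the magnitudes in the packaged tables |

The generator emulates NB counts with a mean–dispersion trend, library-size
variation, and fraction- or strain-specific planted effects. It does **not**
emulate GC/length bias, batch effects, outlier counts, correlated genes, or
the fact that polysomal RNA is physically a subset of total RNA. A green
recovery test therefore establishes that the estimator chain is correct and
calibrated *under the stated model* — not that any real library is free of
artifacts the model omits.

`simulate_trace()` builds A254 gradient profiles as Gaussian peaks on a
baseline with optional white noise; `simulate_qpcr()` generates Cq values as
$\text{Cq} = \text{base} - \log(\text{abundance})/\log E$ with reference genes
pinned across conditions. All three generators are bit-reproducible given a
seed, and restore the caller's RNG state.

## Trace quantification and qPCR

Peak detection smooths with a centered moving average (default window 5
points), keeps local maxima by topographic prominence, merges apices closer
than a minimum separation (keeping the taller), and bounds each peak by the
minima toward its neighbors. The manual ImageJ workflow the field uses leaves
baseline and boundary conventions unstated, so both baseline modes — zero and
chord-between-valleys — are explicit arguments recorded in the output; the
chord mode makes areas invariant to a constant offset. Areas are trapezoidal
integrals of the raw (unsmoothed) signal; negative net areas are clipped to
zero and flagged. Group comparisons use equal-variance t-tests per peak
(Welch via a flag) with Holm–Šidák step-down adjustment,
$\tilde p_{(i)} = \max_{j \le i}\, 1 - (1 - p_{(j)})^{m - j + 1}$.

qPCR relative levels divide $E^{-\text{Cq}}$ by the geometric mean of the
reference genes' $E^{-\text{Cq}}$ per sample, making them invariant to any
per-sample additive Cq shift. Efficiency defaults to 2 per gene (amplification
efficiencies are accepted per gene but rarely printed). Two test procedures are
implemented behind one flag — per-gene t-tests with Holm–Šidák across genes,
and one-way ANOVA with Šidák-adjusted pairwise contrasts — because the source
workflows used both in different figures; the reference-gene set is always
explicit user input.

## Known limitations

- Two-strain, two-fraction designs only; larger factors need pairwise runs.
- No continuous covariates, likelihood-ratio tests, or >2-level factors.
- The dispersion machinery intentionally omits several production-grade
  refinements (outlier refitting, joint mean-dispersion iteration); on very
  small or very dirty datasets a mature DE framework will be more robust.
- Overlapping gradient peaks are split at the valley, not deconvolved.
- The open discrepancy in the source material between 466 and 477
  exclusively-polysomal down-regulated genes is recorded but not resolved;
  neither number enters any computation here.
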