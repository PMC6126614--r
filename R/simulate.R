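## Synthetic data with known ground truth: NB count matrices under the
## interaction model, Gaussian-peak absorbance traces, and Cq tables.

#' Simulation configuration
#'
#' Defaults mirror the study layout the package targets: two strains
#' (a long-lived mutant and its rescue) times two RNA fractions with 3
#' biological replicates each, 5,000 genes, log-normal gene abundances
#' scaled for a ~20M-read library (median normalized count 250),
#' dispersion trend `alpha(mu) = a0 + a1/mu`, per-sample library size
#' factors drawn uniformly, and 10% of genes carrying planted
#' translational-efficiency (interaction) effects with |log2FC| spanning
#' 0.25-1.65.
#'
#' @param n_genes number of genes.
#' @param strains character vector of exactly 2 strain names; the first
#'   is "strain A" of the TE ratio, the second the reference.
#' @param n_replicates biological replicates per (strain, fraction)
#'   cell, at least 2.
#' @param mean_log_mu,sd_log_mu natural-log mean and sd of the baseline
#'   gene abundance distribution (reference strain, total fraction).
#' @param a0,a1 dispersion trend coefficients, both non-negative.
#' @param sf_range range from which per-sample size factors are drawn
#'   uniformly; use `c(1, 1)` for equal libraries.
#' @param effect_sets named list of planted effect sets. Each set is a
#'   list with `frac` (fraction of genes) or `n` (count), and any of
#'   `beta1`, `beta2`, `beta3` (log2 units): scalars are used as is, a
#'   length-2 vector gives a range for uniform draws of the magnitude,
#'   with the sign of its entries.
#' @param seed mandatory RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L,
                       strains = c("mutant", "rescue"),
                       n_replicates = 3L,
                       mean_log_mu = log(250),
                       sd_log_mu = 1.5,
                       a0 = 0.02, a1 = 2,
                       sf_range = c(0.75, 1.3),
                       effect_sets = list(
                         TEup = list(frac = 0.05, beta3 = c(0.25, 1.65)),
                         TEdown = list(frac = 0.05, beta3 = c(-0.25, -1.65))),
                       seed) {
  if (missing(seed)) stop_fmt("a seed is mandatory")
  if (n_genes < 1L) stop_fmt("n_genes must be at least 1")
  if (length(strains) != 2L) stop_fmt("exactly 2 strains are supported")
  if (n_replicates < 2L) stop_fmt("need at least 2 replicates per cell")
  if (a0 < 0 || a1 < 0) stop_fmt("dispersion trend coefficients must be >= 0")
  structure(list(n_genes = as.integer(n_genes), strains = strains,
                 n_replicates = as.integer(n_replicates),
                 mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
                 a0 = a0, a1 = a1, sf_range = sf_range,
                 effect_sets = effect_sets, seed = as.integer(seed)),
            class = "sim_config")
}

## Draw a coefficient for one effect set: scalar = fixed value,
## length-2 = uniform between the two entries (carrying their sign).
draw_beta <- function(spec, n) {
  if (is.null(spec)) return(rep(0, n))
  if (length(spec) == 1L) return(rep(spec, n))
  stats::runif(n, min(spec), max(spec))
}

#' Simulate a count matrix under the interaction model
#'
#' Counts are drawn `NB(mean = sf_j * q_ij, dispersion = alpha_i)` with
#' `log2 q_ij = beta0_i + beta1_i X_strain + beta2_i X_fraction +
#' beta3_i X_strain X_fraction` (treatment coding, reference = second
#' strain, total fraction). Identical seeds reproduce identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix), `design` (sample
#'   design data frame), `truth` (per-gene data frame of true log2
#'   coefficients, dispersion and effect-set membership), and
#'   `size_factors` (true per-sample factors).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    genes <- sprintf("gene%05d", seq_len(G))
    q0 <- exp(stats::rnorm(G, config$mean_log_mu, config$sd_log_mu))
    alpha <- config$a0 + config$a1 / q0
    beta1 <- beta2 <- beta3 <- rep(0, G)
    set_member <- rep("none", G)
    free <- seq_len(G)
    for (nm in names(config$effect_sets)) {
      es <- config$effect_sets[[nm]]
      n_set <- if (!is.null(es$n)) es$n else round((es$frac %||% 0) * G)
      n_set <- min(n_set, length(free))
      if (n_set == 0L) next
      idx <- sample(free, n_set)
      free <- setdiff(free, idx)
      beta1[idx] <- draw_beta(es$beta1, n_set)
      beta2[idx] <- draw_beta(es$beta2, n_set)
      beta3[idx] <- draw_beta(es$beta3, n_set)
      set_member[idx] <- nm
    }
    design <- expand.grid(replicate = seq_len(config$n_replicates),
                          fraction = c("total", "polysomal"),
                          strain = config$strains,
                          stringsAsFactors = FALSE)
    design <- design[, c("strain", "fraction", "replicate")]
    design$sample_id <- sprintf("%s_%s_r%d", design$strain,
                                substr(design$fraction, 1, 4),
                                design$replicate)
    design <- design[, c("sample_id", "strain", "fraction", "replicate")]
    sf <- stats::runif(nrow(design), config$sf_range[1L], config$sf_range[2L])
    names(sf) <- design$sample_id
    xs <- as.numeric(design$strain == config$strains[1L])
    xt <- as.numeric(design$fraction == "polysomal")
    counts <- matrix(0L, G, nrow(design),
                     dimnames = list(genes, design$sample_id))
    log2q0 <- log2(q0)
    poislim <- alpha < 1e-12   # Poisson limit of the NB
    for (j in seq_len(nrow(design))) {
      log2q <- log2q0 + beta1 * xs[j] + beta2 * xt[j] + beta3 * xs[j] * xt[j]
      mu <- sf[j] * 2^log2q
      kj <- integer(G)
      if (any(poislim)) kj[poislim] <- stats::rpois(sum(poislim), mu[poislim])
      if (any(!poislim))
        kj[!poislim] <- stats::rnbinom(sum(!poislim), mu = mu[!poislim],
                                       size = 1 / alpha[!poislim])
      counts[, j] <- kj
    }
    storage.mode(counts) <- "integer"
    truth <- data.frame(gene = genes, beta0 = log2q0, beta1 = beta1,
                        beta2 = beta2, beta3 = beta3, alpha = alpha,
                        set = set_member, row.names = NULL)
    list(counts = counts, design = design, truth = truth,
         size_factors = sf)
  })
}

#' Simulate an absorbance trace
#'
#' Sum of Gaussian peaks on a constant baseline with optional white
#' noise, sampled on a regular position grid.
#'
#' @param peak_spec data frame (or coercible) with columns `center`
#'   (strictly increasing), `width` (Gaussian sd, positive) and `area`.
#' @param baseline constant baseline absorbance.
#' @param noise_sd Gaussian noise sd (0 = noiseless).
#' @param seed RNG seed (used only when `noise_sd > 0`, but always
#'   accepted for reproducibility).
#' @param from,to,step sampling grid; defaults cover all peaks plus 4
#'   widths of margin at 0.01 steps.
#' @return trace data frame (`position`, `absorbance`).
#' @export
simulate_trace <- function(peak_spec, baseline = 0, noise_sd = 0, seed = 1,
                           from = NULL, to = NULL, step = 0.01) {
  peak_spec <- as.data.frame(peak_spec)
  stopifnot(all(c("center", "width", "area") %in% names(peak_spec)))
  if (anyDuplicated(peak_spec$center))
    stop_fmt("peak centers must be distinct")
  if (is.unsorted(peak_spec$center, strictly = TRUE))
    stop_fmt("peak centers must be strictly increasing")
  if (any(peak_spec$width <= 0)) stop_fmt("peak widths must be positive")
  from <- from %||% (min(peak_spec$center - 4 * peak_spec$width))
  to <- to %||% (max(peak_spec$center + 4 * peak_spec$width))
  x <- seq(from, to, by = step)
  y <- rep(baseline, length(x))
  for (i in seq_len(nrow(peak_spec)))
    y <- y + peak_spec$area[i] *
      stats::dnorm(x, peak_spec$center[i], peak_spec$width[i])
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  data.frame(position = x, absorbance = y)
}

#' Simulate a qPCR Cq table
#'
#' Cq values are generated from specified relative abundances as
#' `Cq = base_cq - log(abundance) / log(E)` plus optional noise;
#' reference genes are held at abundance 1 in every condition.
#'
#' @param conditions character vector of condition names.
#' @param n_replicates samples per condition.
#' @param abundances named list: gene -> numeric vector of relative
#'   abundance per condition (recycled if scalar).
#' @param reference_genes genes to flag as references (held constant).
#' @param efficiency amplification efficiency, must exceed 1 (default 2).
#' @param base_cq baseline quantification cycle (default 25).
#' @param noise_sd Gaussian Cq noise sd.
#' @param seed RNG seed.
#' @return Cq table data frame (see [validate_cq_table()]).
#' @export
simulate_qpcr <- function(conditions, n_replicates, abundances,
                          reference_genes = character(), efficiency = 2,
                          base_cq = 25, noise_sd = 0, seed = 1) {
  if (efficiency <= 1) stop_fmt("amplification efficiency must exceed 1")
  for (g in reference_genes) abundances[[g]] <- 1
  genes <- names(abundances)
  with_seed(seed, {
    rows <- list()
    for (ci in seq_along(conditions)) for (r in seq_len(n_replicates)) {
      sid <- sprintf("%s_r%d", conditions[ci], r)
      for (g in genes) {
        ab <- rep(abundances[[g]], length.out = length(conditions))[ci]
        cqv <- base_cq - log(ab) / log(efficiency) +
          stats::rnorm(1, 0, noise_sd)
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = sid, condition = conditions[ci], gene = g,
                     cq = cqv, is_reference = g %in% reference_genes,
                     efficiency = efficiency)
      }
    }
    do.call(rbind, rows)
  })
}
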