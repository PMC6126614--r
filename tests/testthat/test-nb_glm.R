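make_design_2x2 <- function(strains = c("mutant", "rescue"), reps = 3) {
  d <- expand.grid(replicate = seq_len(reps),
                   fraction = c("total", "polysomal"), strain = strains,
                   stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_r%d", d$strain, substr(d$fraction, 1, 4),
                         d$replicate)
  d[, c("sample_id", "strain", "fraction", "replicate")]
}

test_that("treatment coding puts the interaction on (non-ref strain, polysomal)", {
  d <- make_design_2x2()
  X <- build_design(d, strain_ref = "rescue")
  expect_equal(colnames(X), c("intercept", "strain", "fraction",
                              "interaction"))
  on <- d$strain == "mutant" & d$fraction == "polysomal"
  expect_equal(unname(X[, "interaction"]), as.numeric(on))
  expect_true(all(X[, c("strain", "fraction", "interaction")] %in% 0:1))
})

test_that("swapping the strain reference flips beta1 and beta3", {
  d <- make_design_2x2()
  set.seed(8)
  k <- stats::rnbinom(12, mu = 100, size = 10)
  sf <- rep(1, 12)
  f1 <- fit_nb_glm(k, build_design(d, "rescue"), sf, 0.05)
  f2 <- fit_nb_glm(k, build_design(d, "mutant"), sf, 0.05)
  expect_equal(unname(f2$beta["strain"]), unname(-f1$beta["strain"]),
               tolerance = 1e-6)
  expect_equal(unname(f2$beta["interaction"]),
               unname(-f1$beta["interaction"]), tolerance = 1e-6)
  w1 <- wald_test(f1, 4)
  w2 <- wald_test(f2, 4)
  expect_equal(w1$p, w2$p, tolerance = 1e-6)
})

test_that("a missing design cell is a rank error", {
  d <- make_design_2x2()
  d <- d[!(d$strain == "mutant" & d$fraction == "polysomal"), ]
  expect_error(build_design(d, "rescue"), "full rank")
  d3 <- make_design_2x2(strains = c("a", "b"))
  d3$strain[1] <- "c"
  expect_error(build_design(d3, "b"), "exactly 2 strains")
})

test_that("the saturated fit reproduces closed-form group means", {
  d <- make_design_2x2()
  # normalized group means 10 / 10 / 20 / 10 -> beta3 = log2(2) = 1
  k <- integer(12)
  k[d$strain == "rescue"] <- 10L
  k[d$strain == "mutant" & d$fraction == "total"] <- 10L
  k[d$strain == "mutant" & d$fraction == "polysomal"] <- 20L
  fit <- fit_nb_glm(k, build_design(d, "rescue"), rep(1, 12), 0.1)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), c(log2(10), 0, 0, 1), tolerance = 1e-7)
  grp <- paste(d$strain, d$fraction)
  expect_equal(as.numeric(tapply(fit$mu_hat, grp, mean)[
    c("mutant polysomal", "mutant total")]), c(20, 10), tolerance = 1e-6)

  flat <- fit_nb_glm(rep(7L, 12), build_design(d, "rescue"), rep(1, 12), 0.1)
  expect_equal(unname(flat$beta[2:4]), c(0, 0, 0), tolerance = 1e-8)
})

test_that("IRLS agrees with the independent per-cell solver", {
  sim <- simulate_counts(sim_config(n_genes = 400, seed = 13))
  d <- sim$design
  sf <- size_factors_median_ratio(sim$counts)
  X <- build_design(d, "rescue")
  set.seed(1)
  idx <- sample(nrow(sim$counts), 60)
  for (i in idx) {
    k <- sim$counts[i, ]
    if (sum(k > 0) < 4) next
    a <- 0.08
    fit <- fit_nb_glm(k, X, sf, a)
    if (!fit$converged) next
    lfc <- oracle_te_lfc(k, d, sf, a, "mutant", "rescue")
    expect_equal(unname(fit$beta["interaction"]), lfc, tolerance = 1e-6)
  }
})

test_that("Wald statistics behave at the null and under divergence flags", {
  d <- make_design_2x2()
  k <- integer(12)
  k[d$fraction == "polysomal"] <- 20L
  k[d$fraction == "total"] <- 10L
  fit <- fit_nb_glm(k, build_design(d, "rescue"), rep(1, 12), 0.05)
  w <- wald_test(fit, 4)
  expect_equal(w$stat, 0, tolerance = 1e-6)
  expect_equal(w$p, 1, tolerance = 1e-6)
  bad <- fit
  bad$converged <- FALSE
  expect_true(is.na(wald_test(bad, 4)$p))
})

test_that("Benjamini-Hochberg step-up matches hand computation and stats oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (i in 1:10) {
    p <- stats::runif(50)^2
    expect_equal(adjust_bh(p), stats::p.adjust(p, "BH"))
    perm <- sample(50)
    expect_equal(adjust_bh(p[perm]), adjust_bh(p)[perm])
  }
  p_na <- c(0.01, NA, 0.04)
  adj <- adjust_bh(p_na)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], stats::p.adjust(c(0.01, 0.04), "BH"))
})

test_that("run_de recovers planted strain effects in the total fraction", {
  cfg <- sim_config(n_genes = 5000, seed = 7,
                    effect_sets = list(DEup = list(frac = 0.05, beta1 = 1),
                                       DEdown = list(frac = 0.05, beta1 = -1)))
  sim <- simulate_counts(cfg)
  de <- run_de(sim$counts, sim$design, c("strain", "mutant", "rescue"),
               subset = c(fraction = "total"))
  disc <- !is.na(de$padj) & de$padj < 0.01
  planted <- sim$truth$set != "none"
  expect_gte(sum(disc & planted) / sum(planted), 0.7)
  expect_lte(sum(disc & !planted) / max(sum(disc), 1), 0.05)
  up <- sim$truth$set == "DEup" & de$converged
  expect_lt(abs(mean(de$log2fc[up]) - 1), 0.1)
})

test_that("a null dataset yields (almost) no discoveries", {
  sim <- simulate_counts(sim_config(n_genes = 3000, seed = 17,
                                    effect_sets = list()))
  de <- run_de(sim$counts, sim$design, c("strain", "mutant", "rescue"),
               subset = c(fraction = "total"))
  disc <- !is.na(de$padj) & de$padj < 0.01
  expect_lte(mean(disc), 0.002)
})

test_that("a self-contrast is identically zero", {
  sim <- simulate_counts(sim_config(n_genes = 50, seed = 2))
  de <- run_de(sim$counts, sim$design, c("strain", "mutant", "mutant"),
               subset = c(fraction = "total"))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p == 1))
})
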