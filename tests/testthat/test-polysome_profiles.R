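# A seven-peak profile shaped like a sucrose-gradient trace: subunits,
# monosome, and a decaying polysome series.
seven_peak_spec <- function(scale = 1) {
  data.frame(center = c(1, 1.8, 2.8, 4, 5, 6, 7),
             width = rep(0.15, 7),
             area = c(0.3, 0.5, 1.5, scale * c(1, 0.7, 0.45, 0.3)))
}

test_that("traces round-trip through files, with or without header", {
  tr <- simulate_trace(seven_peak_spec(), baseline = 0.1, noise_sd = 0.002,
                       seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_trace(path)
  expect_equal(back$position, tr$position)
  expect_equal(back$absorbance, tr$absorbance)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tr, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_equal(read_trace(path2)$absorbance, tr$absorbance)
  shuffled <- tr[sample(nrow(tr)), ]
  utils::write.table(shuffled, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_trace(path2), "increasing")
})

test_that("all seven generated peaks are found at their centers", {
  spec <- seven_peak_spec()
  tr <- simulate_trace(spec, baseline = 0.05, noise_sd = 0.002, seed = 11)
  peaks <- detect_peaks(tr, min_prominence = 0.1)
  expect_equal(nrow(peaks), 7L)
  step <- diff(tr$position[1:2])
  expect_true(all(abs(peaks$apex_position - spec$center) <= 3 * step))
  expect_equal(peaks$name,
               c("40S", "60S", "monosome", "P1", "P2", "P3", "P4"))
})

test_that("a flat trace yields an empty peak set with a warning", {
  tr <- data.frame(position = seq(0, 10, 0.1), absorbance = rep(1, 101))
  expect_warning(peaks <- detect_peaks(tr, min_prominence = 0.01), "no peaks")
  expect_equal(nrow(peaks), 0L)
})

test_that("peaks closer than min_separation merge into the taller apex", {
  spec <- data.frame(center = c(3, 3.8, 7), width = c(0.2, 0.2, 0.2),
                     area = c(1, 0.6, 1))
  tr <- simulate_trace(spec)
  all_peaks <- detect_peaks(tr, min_prominence = 0.05)
  expect_equal(nrow(all_peaks), 3L)
  merged <- detect_peaks(tr, min_prominence = 0.05, min_separation = 1)
  expect_equal(nrow(merged), 2L)
  expect_lt(abs(merged$apex_position[1] - 3), 0.15)
})

test_that("AUC matches analytic areas under both baseline modes", {
  tr <- simulate_trace(data.frame(center = 5, width = 0.3, area = 1))
  peaks <- detect_peaks(tr, min_prominence = 0.2)
  q0 <- quantify_auc(tr, peaks, "zero")
  expect_equal(q0$auc, 1, tolerance = 0.01)
  tr_up <- tr
  tr_up$absorbance <- tr_up$absorbance + 0.5
  q1 <- quantify_auc(tr_up, detect_peaks(tr_up, min_prominence = 0.2),
                     "linear")
  expect_equal(q1$auc, 1, tolerance = 0.02)
})

test_that("the trapezoid rule is exact on a triangle and additive", {
  x <- seq(0, 2, by = 0.04)
  y <- 1 - abs(x - 1)
  expect_equal(teprof:::trapz(x, y), 1)
  cut <- 26
  expect_equal(teprof:::trapz(x[1:cut], y[1:cut]) +
                 teprof:::trapz(x[cut:length(x)], y[cut:length(x)]),
               teprof:::trapz(x, y))
})

test_that("detection and linear-baseline AUC ignore constant offsets", {
  tr <- simulate_trace(seven_peak_spec(), baseline = 0, noise_sd = 0.002,
                       seed = 8)
  tr_shift <- tr
  tr_shift$absorbance <- tr$absorbance + 2
  p1 <- detect_peaks(tr, min_prominence = 0.1)
  p2 <- detect_peaks(tr_shift, min_prominence = 0.1)
  expect_equal(p1$apex_position, p2$apex_position)
  q1 <- quantify_auc(tr, p1, "linear")
  q2 <- quantify_auc(tr_shift, p2, "linear")
  expect_equal(q1$auc, q2$auc, tolerance = 1e-9)
})

test_that("fold changes are referenced to the stated peak and linear", {
  quants <- expand.grid(group = c("wt", "mut"), replicate = 1:3,
                        peak = c("P1", "P2"), stringsAsFactors = FALSE)
  quants$auc <- c(wt = 2, mut = 1)[quants$group] *
    c(P1 = 1, P2 = 0.5)[quants$peak]
  fc <- peak_fold_changes(quants, c(group = "wt", peak = "P1"))
  expect_equal(fc$fold_change[fc$group == "wt" & fc$peak == "P1"], 1)
  expect_equal(fc$fold_change[fc$group == "mut" & fc$peak == "P2"], 0.25)
  doubled <- quants
  doubled$auc <- doubled$auc * 2
  fc2 <- peak_fold_changes(doubled, c(group = "wt", peak = "P1"))
  expect_equal(fc2$mean_auc, fc$mean_auc * 2)
  expect_error(peak_fold_changes(quants, c(group = "wt", peak = "P9")),
               "reference peak")
})

test_that("a planted 0.5x polysome suppression is recovered", {
  quantify_group <- function(scale, seeds) {
    do.call(rbind, lapply(seeds, function(s) {
      tr <- simulate_trace(seven_peak_spec(scale), baseline = 0.05,
                           noise_sd = 0.004, seed = s)
      peaks <- detect_peaks(tr, min_prominence = 0.1)
      q <- quantify_auc(tr, peaks, "linear")
      data.frame(replicate = s, peak = q$name, auc = q$auc)
    }))
  }
  qa <- quantify_group(1, 1:4)
  qb <- quantify_group(0.5, 5:8)
  for (p in c("P1", "P2", "P3")) {
    ratio <- mean(qb$auc[qb$peak == p]) / mean(qa$auc[qa$peak == p])
    expect_lt(abs(ratio - 0.5), 0.05)
  }
  cmp <- compare_peaks(qa, qb)
  expect_true(all(cmp$significant[cmp$peak %in% c("P1", "P2", "P3")]))
  expect_false(any(cmp$significant[cmp$peak %in% c("40S", "60S",
                                                   "monosome")]))
})

test_that("Holm-Sidak follows the step-down formula", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04),
               tolerance = 1e-10)
  expect_equal(holm_sidak(0.3), 0.3)
  set.seed(5)
  for (i in 1:5) {
    p <- stats::runif(8)
    adj <- holm_sidak(p)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    perm <- sample(8)
    expect_equal(holm_sidak(p[perm]), adj[perm])
  }
})

test_that("compare_peaks handles ties and scant replication", {
  qa <- data.frame(peak = rep("P1", 3), auc = c(1, 2, 3))
  cmp <- compare_peaks(qa, qa)
  expect_equal(cmp$stat, 0)
  expect_equal(cmp$p, 1)
  qb <- data.frame(peak = "P1", auc = 2)
  cmp2 <- compare_peaks(qa, qb)
  expect_true(cmp2$skipped)
  expect_true(is.na(cmp2$p))
})
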