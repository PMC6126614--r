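## Sucrose-gradient absorbance trace quantification: peak detection on a
## smoothed A254 signal, valley-bounded trapezoidal areas, fold changes
## against a reference peak, and replicate comparisons with Holm-Sidak
## correction.

DEFAULT_PEAK_NAMES <- c("40S", "60S", "monosome", paste0("P", 1:6))

validate_trace <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("position", "absorbance") %in% names(trace)))
  if (nrow(trace) < 3L) stop_fmt("trace needs at least 3 points")
  if (any(diff(trace$position) <= 0))
    stop_fmt("trace positions must be strictly increasing")
  if (nrow(trace) < 50L)
    warning("trace has fewer than 50 points; results may be unreliable")
  invisible(trace)
}

#' Read an absorbance trace
#'
#' Expects two numeric columns (position, A254 absorbance), tab-, comma-
#' or whitespace-separated; a single header line is skipped
#' automatically when present.
#'
#' @param path path to the trace file.
#' @param label optional trace label.
#' @return data frame with columns `position` and `absorbance`.
#' @export
read_trace <- function(path, label = NULL) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[\t, ]+")[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_fmt("trace file needs two numeric columns")
  trace <- data.frame(position = as.numeric(df[[1L]]),
                      absorbance = as.numeric(df[[2L]]))
  if (anyNA(trace)) stop_fmt("non-numeric values in trace file")
  validate_trace(trace)
  attr(trace, "label") <- label %||% basename(path)
  trace
}

## Centered moving average; window is forced odd, ends use shrinking
## windows.
moving_average <- function(y, window) {
  if (window <= 1L) return(y)
  half <- floor(window / 2)
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(y[lo:hi])
  }, numeric(1))
}

#' Detect peaks in an absorbance trace
#'
#' Local maxima of the moving-average-smoothed signal whose topographic
#' prominence exceeds `min_prominence`. Peaks closer than
#' `min_separation` (in position units) are merged, keeping the larger
#' apex. Peak boundaries are the minima of the smoothed signal between
#' adjacent kept apices (valley-to-valley), and names are assigned
#' left-to-right from a template.
#'
#' @param trace data frame from [read_trace()] or [simulate_trace()].
#' @param min_prominence minimum prominence in absorbance units.
#' @param min_separation minimum apex separation in position units.
#' @param smooth_window moving-average window in points (default 5).
#' @param names name template assigned left-to-right; peaks beyond the
#'   template are `"unassigned"`.
#' @return data frame with one row per peak: `name`, `apex_position`,
#'   `apex_height`, `prominence`, `left`, `right` (valley positions).
#'   Zero detected peaks yield an empty data frame with a warning.
#' @export
detect_peaks <- function(trace, min_prominence, min_separation = 0,
                         smooth_window = 5L, names = DEFAULT_PEAK_NAMES) {
  validate_trace(trace)
  x <- trace$position
  y <- moving_average(trace$absorbance, smooth_window)
  n <- length(y)
  empty <- data.frame(name = character(), apex_position = numeric(),
                      apex_height = numeric(), prominence = numeric(),
                      left = numeric(), right = numeric())
  d <- diff(y)
  apex <- which(c(FALSE, d > 0) & c(d <= 0, FALSE))
  if (length(apex) == 0L) {
    warning("no peaks detected")
    return(empty)
  }
  prominence <- vapply(apex, function(i) {
    left_min <- y[i]
    j <- i
    while (j > 1L && y[j] <= y[i]) {
      j <- j - 1L
      left_min <- min(left_min, y[j])
    }
    if (j == 1L && y[1L] <= y[i]) left_min <- min(left_min, y[1L])
    right_min <- y[i]
    j <- i
    while (j < n && y[j] <= y[i]) {
      j <- j + 1L
      right_min <- min(right_min, y[j])
    }
    y[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- prominence >= min_prominence
  apex <- apex[keep]
  prominence <- prominence[keep]
  if (length(apex) == 0L) {
    warning("no peaks detected")
    return(empty)
  }
  ## merge apices closer than min_separation, keeping the taller
  if (min_separation > 0) {
    repeat {
      if (length(apex) < 2L) break
      gaps <- diff(x[apex])
      close_i <- which(gaps < min_separation)
      if (length(close_i) == 0L) break
      i <- close_i[1L]
      drop <- if (y[apex[i]] >= y[apex[i + 1L]]) i + 1L else i
      apex <- apex[-drop]
      prominence <- prominence[-drop]
    }
  }
  m <- length(apex)
  left_idx <- integer(m)
  right_idx <- integer(m)
  bounds <- c(1L, apex, n)
  for (p in seq_len(m)) {
    lo <- bounds[p]
    hi <- bounds[p + 2L]
    seg_l <- lo:apex[p]
    seg_r <- apex[p]:hi
    left_idx[p] <- seg_l[which.min(y[seg_l])]
    right_idx[p] <- seg_r[which.min(y[seg_r])]
  }
  nm <- rep("unassigned", m)
  nm[seq_len(min(m, length(names)))] <- names[seq_len(min(m, length(names)))]
  data.frame(name = nm, apex_position = x[apex], apex_height = y[apex],
             prominence = prominence, left = x[left_idx],
             right = x[right_idx], row.names = NULL)
}

## Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Quantify area under the curve for detected peaks
#'
#' Trapezoidal integral of the raw absorbance minus a baseline over each
#' valley-bounded peak interval. `baseline_mode = "zero"` integrates the
#' signal as is; `"linear"` subtracts the chord between the two valley
#' points, which makes the area invariant to adding a constant to the
#' whole trace. Negative net areas are clipped to zero and flagged.
#'
#' @param trace the trace that `peaks` were detected on.
#' @param peaks data frame from [detect_peaks()].
#' @param baseline_mode `"zero"` or `"linear"`.
#' @return `peaks` with added columns `auc`, `baseline_mode`, `clipped`.
#' @export
quantify_auc <- function(trace, peaks, baseline_mode = c("zero", "linear")) {
  baseline_mode <- match.arg(baseline_mode)
  validate_trace(trace)
  x <- trace$position
  y <- trace$absorbance
  auc <- numeric(nrow(peaks))
  clipped <- logical(nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    sel <- x >= peaks$left[p] & x <= peaks$right[p]
    xs <- x[sel]
    ys <- y[sel]
    if (baseline_mode == "linear") {
      chord <- ys[1L] + (ys[length(ys)] - ys[1L]) *
        (xs - xs[1L]) / (xs[length(xs)] - xs[1L])
      ys <- ys - chord
    }
    a <- trapz(xs, ys)
    if (a < 0) {
      a <- 0
      clipped[p] <- TRUE
    }
    auc[p] <- a
  }
  peaks$auc <- auc
  peaks$baseline_mode <- baseline_mode
  peaks$clipped <- clipped
  peaks
}

#' Fold changes of peak areas against a reference peak
#'
#' Mean AUC of every (group, peak) combination divided by the mean AUC
#' of the reference peak in the reference group.
#'
#' @param quants data frame with columns `group`, `replicate`, `peak`,
#'   `auc` (one row per replicate trace and peak).
#' @param reference named character vector `c(group = ..., peak = ...)`.
#' @return data frame with columns `group`, `peak`, `mean_auc`,
#'   `fold_change`.
#' @export
peak_fold_changes <- function(quants, reference) {
  stopifnot(all(c("group", "peak", "auc") %in% names(quants)))
  ref <- quants$auc[quants$group == reference[["group"]] &
                    quants$peak == reference[["peak"]]]
  if (length(ref) == 0L)
    stop_fmt("reference peak '%s' not found in group '%s'",
             reference[["peak"]], reference[["group"]])
  ref_mean <- mean(ref)
  agg <- stats::aggregate(auc ~ group + peak, data = quants, FUN = mean)
  names(agg)[names(agg) == "auc"] <- "mean_auc"
  agg$fold_change <- agg$mean_auc / ref_mean
  agg[order(agg$group, agg$peak), , drop = FALSE]
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the p-values ascending and sets
#' `adj_(i) = max over j <= i of 1 - (1 - p_(j))^(m - j + 1)`, capped at
#' 1; a family-wise error rate correction for small comparison families.
#'
#' @param p vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
holm_sidak <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop_fmt("p-values must lie in [0, 1]")
  o <- order(pv)
  adj <- pmin(1, 1 - (1 - pv[o])^(m - seq_len(m) + 1))
  adj <- cummax(adj)
  out[ok[o]] <- adj
  out
}

#' Compare peak areas between two groups of replicate profiles
#'
#' Per-peak two-sample t-test (equal variance by default, Welch via
#' `var_equal = FALSE`) on replicate AUCs, with Holm-Sidak adjustment
#' across peaks. Peaks with fewer than 2 replicates in either group are
#' skipped and flagged.
#'
#' @param quants_a,quants_b data frames with columns `peak` and `auc`,
#'   one row per replicate and peak.
#' @param alpha significance level recorded in the output, default 0.05.
#' @param var_equal use the pooled-variance t-test (default `TRUE`).
#' @return data frame with columns `peak`, `mean_a`, `mean_b`, `stat`,
#'   `p`, `p_adj`, `significant`, `skipped`.
#' @export
compare_peaks <- function(quants_a, quants_b, alpha = 0.05,
                          var_equal = TRUE) {
  peaks <- intersect(unique(quants_a$peak), unique(quants_b$peak))
  if (length(peaks) == 0L) stop_fmt("no shared peaks to compare")
  res <- data.frame(peak = peaks, mean_a = NA_real_, mean_b = NA_real_,
                    stat = NA_real_, p = NA_real_, skipped = FALSE)
  for (i in seq_along(peaks)) {
    a <- quants_a$auc[quants_a$peak == peaks[i]]
    b <- quants_b$auc[quants_b$peak == peaks[i]]
    res$mean_a[i] <- mean(a)
    res$mean_b[i] <- mean(b)
    if (length(a) < 2L || length(b) < 2L) {
      res$skipped[i] <- TRUE
      next
    }
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
      res$stat[i] <- 0
      res$p[i] <- 1
      next
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res$stat[i] <- unname(tt$statistic)
    res$p[i] <- tt$p.value
  }
  res$p_adj <- holm_sidak(res$p)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}
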