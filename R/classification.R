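#' Balanced subsample of an imbalanced cohort
#'
#' Retains every member of the minority class and a uniform
#' without-replacement subsample of the majority class of equal size, so
#' the hyperplane is not biased towards the larger group. With 22
#' converters and 52 non-converters this yields balanced cohorts of 44;
#' with 31/39, cohorts of 62. An already balanced cohort is returned
#' unchanged (same patients, original order).
#'
#' @param cohort a [cohort_matrix()] with both classes non-empty.
#' @param seed integer seed for the majority-class draw.
#' @return A balanced [cohort_matrix()] of size 2 x minority size.
#' @export
balanced_subsample <- function(cohort, seed) {
  rows <- balanced_indices(cohort$y, seed)
  subset_cohort(cohort, rows)
}

balanced_indices <- function(y, seed) {
  pos <- which(y == 1)
  neg <- which(y == -1)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be non-empty")
  if (length(pos) == length(neg)) return(seq_along(y))
  minority <- if (length(pos) < length(neg)) pos else neg
  majority <- if (length(pos) < length(neg)) neg else pos
  picked <- with_seed(seed, sample(majority, length(minority)))
  sort(c(minority, picked))
}

#' Derive the five classification metrics from confusion counts
#'
#' Accuracy is the percentage of patients correctly classified either way;
#' sensitivity the percentage of true converters classified as converters;
#' specificity the percentage of true non-converters classified as
#' non-converters; PPV/NPV the precision of converter / non-converter
#' predictions. A ratio with zero denominator is reported as `NaN`
#' (not-a-value), never as 0.
#'
#' @param tp,fp,tn,fn non-negative confusion counts, total > 0.
#' @return A `cv_metrics` object: the four counts plus the five rates in
#'   percent.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0")
  total <- sum(counts)
  if (total <= 0) stop("total count must be > 0")
  rate <- function(num, den) if (den > 0) 100 * num / den else NaN
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy    = 100 * (tp + tn) / total,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv         = rate(tp, tp + fp),
    npv         = rate(tn, tn + fn)
  ), class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf(paste0("<cv_metrics> n = %d (tp %d, fp %d, tn %d, fn %d)\n",
                     "  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, ",
                     "PPV %.1f%%, NPV %.1f%%\n"),
              x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn,
              x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Leave-one-out cross-validation of the SVM on a cohort
#'
#' Each patient in turn is held out, the SVM is trained on the remaining
#' n - 1 (with per-fold standardization), and the held-out patient is
#' classified; confusion counts are aggregated over all n folds. The
#' slight class imbalance inside each training fold (e.g. 21 vs 22 in a
#' balanced cohort of 44) affects both classes symmetrically and is
#' accepted unweighted. Folds whose solver fails to converge are counted
#' in the `n_nonconverged` attribute and flagged with a warning.
#'
#' @param cohort a [cohort_matrix()] of size >= 4 with >= 2 patients per
#'   class.
#' @param features feature names to use (default: all).
#' @param spec an [svm_spec()].
#' @return A [metrics_from_confusion()] result with attributes `n`,
#'   `n_train` (= n - 1) and `n_nonconverged`.
#' @export
loo_cv <- function(cohort, features = NULL, spec = svm_spec()) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  n <- nrow(cohort$X)
  if (n < 4) stop("LOO-CV needs a cohort of size >= 4")
  if (min(sum(cohort$y == 1), sum(cohort$y == -1)) < 2)
    stop("each class needs >= 2 patients, else a training fold loses a class")
  cols <- if (is.null(features)) seq_len(ncol(cohort$X))
          else feature_columns(cohort, features)
  res <- loo_cv_cpp(cohort$X[, cols, drop = FALSE], as.integer(cohort$y),
                    spec$degree, spec$coef0, spec$cost, spec$standardize,
                    spec$tol, spec$max_iter)
  if (res$n_nonconverged > 0)
    warning(res$n_nonconverged, " LOO fold(s) did not converge", call. = FALSE)
  m <- metrics_from_confusion(res$tp, res$fp, res$tn, res$fn)
  attr(m, "n") <- n
  attr(m, "n_train") <- n - 1L
  attr(m, "n_nonconverged") <- res$n_nonconverged
  m
}

METRIC_NAMES <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")

#' Balanced-bootstrap evaluation of a feature subset
#'
#' Draws `B` balanced subsamples of the cohort (seeds derived
#' deterministically from `seed`), runs LOO-CV on each, and summarises
#' each metric by its mean, 95% percentile confidence interval
#' (2.5th/97.5th percentiles of the B values) and min-max range.
#'
#' @param cohort a [cohort_matrix()].
#' @param features feature names (default: all).
#' @param spec an [svm_spec()].
#' @param B number of bootstrap cohorts (>= 2, default 100).
#' @param seed master seed.
#' @return A `bootstrap_summary`: `values` (B x 5 metric matrix),
#'   `summary` data.frame (mean, ci95_low, ci95_high, range_min,
#'   range_max per metric), `B`, `seed`, and `n_flagged` bootstraps with
#'   non-converged folds.
#' @export
bootstrap_evaluate <- function(cohort, features = NULL, spec = svm_spec(),
                               B = 100, seed = 1) {
  if (B < 2) stop("`B` must be >= 2")
  idx_list <- draw_balanced_indices(cohort$y, B, seed)
  cols <- if (is.null(features)) seq_len(ncol(cohort$X))
          else feature_columns(cohort, features)
  Xc <- cohort$X[, cols, drop = FALSE]
  y <- as.integer(cohort$y)
  dd <- dedupe_indices(idx_list)
  uvals <- matrix(NA_real_, length(dd$unique), length(METRIC_NAMES))
  uflag <- logical(length(dd$unique))
  for (u in seq_along(dd$unique)) {
    idx <- dd$unique[[u]]
    res <- loo_cv_cpp(Xc[idx, , drop = FALSE], y[idx], spec$degree,
                      spec$coef0, spec$cost, spec$standardize, spec$tol,
                      spec$max_iter)
    uflag[u] <- res$n_nonconverged > 0
    m <- metrics_from_confusion(res$tp, res$fp, res$tn, res$fn)
    uvals[u, ] <- unlist(m[METRIC_NAMES])
  }
  vals <- uvals[dd$map, , drop = FALSE]
  colnames(vals) <- METRIC_NAMES
  summarize_bootstraps(vals, B, seed, sum(uflag[dd$map]))
}

draw_balanced_indices <- function(y, B, seed) {
  seeds <- derive_seeds(seed, B)
  lapply(seeds, function(s) balanced_indices(y, s))
}

summarize_bootstraps <- function(vals, B, seed, flagged) {
  smry <- do.call(rbind, lapply(METRIC_NAMES, function(m) {
    x <- vals[, m]
    x <- x[!is.na(x) & !is.nan(x)]
    if (!length(x))
      return(data.frame(metric = m, mean = NaN, ci95_low = NaN,
                        ci95_high = NaN, range_min = NaN, range_max = NaN))
    q <- unname(quantile(x, c(0.025, 0.975)))
    data.frame(metric = m, mean = mean(x), ci95_low = q[1], ci95_high = q[2],
               range_min = min(x), range_max = max(x))
  }))
  rownames(smry) <- NULL
  if (flagged > 0)
    warning(flagged, " bootstrap(s) contained non-converged folds",
            call. = FALSE)
  structure(list(values = vals, summary = smry, B = B, seed = seed,
                 n_flagged = flagged),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> B = %d balanced bootstrap cohorts (seed %s)\n",
              x$B, format(x$seed)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s mean %5.1f%%  95%% CI [%5.1f, %5.1f]  range [%5.1f, %5.1f]\n",
                s$metric[i], s$mean[i], s$ci95_low[i], s$ci95_high[i],
                s$range_min[i], s$range_max[i]))
  if (x$n_flagged > 0)
    cat(sprintf("  ! %d bootstrap(s) with non-converged folds\n", x$n_flagged))
  invisible(x)
}
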