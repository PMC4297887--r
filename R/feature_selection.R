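# Wrapper feature-combination search. Both strategies share one fixed set
# of balanced bootstrap subsamples (drawn once from the master seed), so
# candidate subsets are compared on identical resamples: a paired
# comparison that removes resampling noise from the selection decision.

# Deduplicate a list of bootstrap index sets: identical subsamples (the
# rule rather than the exception on an already balanced cohort) are
# evaluated once and weighted by multiplicity.
dedupe_indices <- function(idx_list) {
  keys <- vapply(idx_list, paste, "", collapse = ",")
  first <- !duplicated(keys)
  list(unique = idx_list[first],
       weight = as.vector(table(keys)[keys[first]]),
       map = match(keys, keys[first]))
}

# Evaluate one candidate subset at every degree on the shared subsamples;
# the subset is represented by its best degree (ties -> lower degree).
eval_subset <- function(Xc, y, cols, idx_list, degrees, spec) {
  degrees <- sort(as.integer(degrees))   # ascending: ties resolve to lower d
  dd <- dedupe_indices(idx_list)
  w <- dd$weight / sum(dd$weight)
  accs <- vapply(degrees, function(d) {
    sum(w * vapply(dd$unique, function(idx) {
      res <- loo_cv_cpp(Xc[idx, cols, drop = FALSE], y[idx], d, spec$coef0,
                        spec$cost, spec$standardize, spec$tol, spec$max_iter)
      100 * (res$tp + res$tn) / length(idx)
    }, 0))
  }, 0)
  best <- which.max(accs)          # first max: lower degree wins ties
  list(degree = degrees[best], accuracy = accs[best],
       per_degree = stats::setNames(accs, degrees))
}

new_selection_result <- function(trace, best_subset, best_degree,
                                 best_summary, strategy, ...) {
  structure(c(list(trace = trace, best_subset = best_subset,
                   best_degree = best_degree, best_summary = best_summary,
                   strategy = strategy), list(...)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> strategy: %s\n", x$strategy))
  cat(sprintf("  best subset: {%s}, degree %d, mean accuracy %.1f%%\n",
              paste(x$best_subset, collapse = ", "), x$best_degree,
              x$best_summary$summary$mean[x$best_summary$summary$metric == "accuracy"]))
  invisible(x)
}

#' Forward feature-combination search
#'
#' The greedy wrapper search of the original method: step 0 evaluates
#' every feature alone (each at its best polynomial degree among
#' `degrees`) and keeps the most accurate; every later step evaluates
#' adding each remaining feature to the incumbent set and keeps the best
#' addition; the search stops as soon as the best enlarged set's mean
#' bootstrap accuracy does not exceed the incumbent's (non-strict stop:
#' a plateau ends the search). Because one feature is added at a time, a
#' feature duplicating information already in the incumbent set is never
#' needed — an inherent redundancy control.
#'
#' Ties between candidates are broken deterministically: lower degree
#' first, then the earlier feature in canonical order.
#'
#' @param cohort a [cohort_matrix()].
#' @param features candidate feature names (default: all features of the
#'   cohort's feature map; >= 2 required).
#' @param degrees polynomial degrees to consider (subset of 1..5).
#' @param B bootstrap cohorts per evaluation.
#' @param seed master seed (shared across all candidates).
#' @param spec base [svm_spec()] supplying cost/coef0/standardization.
#' @return A `selection_result`: `trace` (one row per accepted step:
#'   step, feature added, subset, degree, mean accuracy), `best_subset`,
#'   `best_degree`, `best_summary` ([bootstrap_evaluate()] of the winner
#'   on the same seed), `strategy = "forward"`, and `candidates`, the
#'   accuracy of every candidate evaluated at every step.
#' @export
forward_select <- function(cohort, features = NULL, degrees = 1:5, B = 100,
                           seed = 1, spec = svm_spec()) {
  features <- features %||% names(cohort$feature_map)
  if (length(features) < 2) stop("need >= 2 candidate features")
  stopifnot(all(degrees %in% 1:5))
  idx_list <- draw_balanced_indices(cohort$y, B, seed)
  y <- as.integer(cohort$y)
  Xc <- cohort$X
  col_of <- lapply(features, function(f) feature_columns(cohort, f))
  names(col_of) <- features

  incumbent <- character(0)
  inc_cols <- integer(0)
  inc_acc <- -Inf
  inc_deg <- NA_integer_
  trace <- list()
  cand_log <- list()
  step <- 0L
  remaining <- features
  repeat {
    evals <- lapply(remaining, function(f)
      eval_subset(Xc, y, c(inc_cols, col_of[[f]]), idx_list, degrees, spec))
    acc <- vapply(evals, `[[`, 0, "accuracy")
    deg <- vapply(evals, `[[`, 0L, "degree")
    cand_log[[step + 1L]] <- data.frame(step = step, candidate = remaining,
                                        degree = deg, mean_accuracy = acc)
    # best candidate: highest accuracy, then lower degree, then canonical order
    ord <- order(-acc, deg, match(remaining, features))
    best <- ord[1]
    if (step > 0L && acc[best] <= inc_acc) break   # "does not increase anymore"
    incumbent <- c(incumbent, remaining[best])
    inc_cols <- c(inc_cols, col_of[[remaining[best]]])
    inc_acc <- acc[best]
    inc_deg <- deg[best]
    trace[[step + 1L]] <- data.frame(
      step = step, feature_added = remaining[best],
      subset = paste(incumbent, collapse = "+"),
      degree = inc_deg, mean_accuracy = inc_acc)
    remaining <- setdiff(remaining, remaining[best])
    step <- step + 1L
    if (!length(remaining)) break
  }
  best_summary <- bootstrap_evaluate(cohort, incumbent,
                                     svm_spec(inc_deg, spec$coef0, spec$cost,
                                              spec$tol, spec$max_iter,
                                              spec$standardize),
                                     B = B, seed = seed)
  new_selection_result(do.call(rbind, trace), incumbent, inc_deg,
                       best_summary, "forward",
                       candidates = do.call(rbind, cand_log))
}

#' Enumerate all subsets of a feature list
#'
#' @param features character vector of feature names (<= 20).
#' @return List of all `2^length(features)` subsets (character vectors),
#'   the empty subset first, in binary counting order.
#' @export
enumerate_feature_subsets <- function(features) {
  p <- length(features)
  if (p > 20) stop("refusing to enumerate more than 2^20 subsets")
  lapply(0:(2^p - 1), function(m) features[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
}

#' Exhaustive feature-combination search
#'
#' Enumerates every subset of the candidate features (2^12 = 4096 models
#' for the full feature set; the empty subset is enumerated but skipped
#' for evaluation), evaluates each at every degree on the same bootstrap
#' subsamples as [forward_select()] would use for the same seed, and
#' returns the argmax of mean bootstrap accuracy. Ties are broken by
#' lower degree, then smaller subset, then canonical feature order.
#'
#' Testing thousands of models on one small cohort invites spuriously
#' good combinations (a multiple-comparisons problem); the result carries
#' that caveat as a warning and in the `note` field, and no statistical
#' correction is applied.
#'
#' @inheritParams forward_select
#' @return A `selection_result` with `strategy = "exhaustive"`, the
#'   per-subset `trace` (subset, size, degree, mean accuracy),
#'   `n_subsets` enumerated and `n_evaluated`.
#' @export
exhaustive_search <- function(cohort, features = NULL, degrees = 1:5,
                              B = 100, seed = 1, spec = svm_spec()) {
  features <- features %||% names(cohort$feature_map)
  stopifnot(all(degrees %in% 1:5))
  subsets <- enumerate_feature_subsets(features)
  idx_list <- draw_balanced_indices(cohort$y, B, seed)
  y <- as.integer(cohort$y)
  Xc <- cohort$X
  nonempty <- subsets[lengths(subsets) > 0]
  rows <- lapply(nonempty, function(s) {
    ev <- eval_subset(Xc, y, feature_columns(cohort, s), idx_list, degrees, spec)
    data.frame(subset = paste(s, collapse = "+"), size = length(s),
               degree = ev$degree, mean_accuracy = ev$accuracy)
  })
  trace <- do.call(rbind, rows)
  key <- order(-trace$mean_accuracy, trace$degree, trace$size,
               vapply(nonempty, function(s)
                 paste(sprintf("%02d", sort(match(s, features))), collapse = ""),
                 ""))
  best_i <- key[1]
  best_subset <- nonempty[[best_i]]
  best_degree <- trace$degree[best_i]
  best_summary <- bootstrap_evaluate(cohort, best_subset,
                                     svm_spec(best_degree, spec$coef0,
                                              spec$cost, spec$tol,
                                              spec$max_iter, spec$standardize),
                                     B = B, seed = seed)
  note <- paste("exhaustive search over", length(subsets), "models on one",
                "cohort is prone to spuriously optimal subsets",
                "(multiple comparisons; no correction applied)")
  warning(note, call. = FALSE)
  new_selection_result(trace, best_subset, best_degree, best_summary,
                       "exhaustive", n_subsets = length(subsets),
                       n_evaluated = length(nonempty), note = note)
}

#' Compare forward and exhaustive selection
#'
#' Runs both strategies with identical bootstrap seeds and reports them
#' side by side. The exhaustive optimum's accuracy can never fall below
#' the forward result's (the forward subset is among the enumerated
#' ones); the gap quantifies how greedily suboptimal the forward search
#' was on this cohort. Either result whose 95% bootstrap CI of accuracy
#' covers 50% is flagged as chance-level.
#'
#' @inheritParams forward_select
#' @return A `strategy_comparison` list: both `selection_result`s,
#'   `same_subset`, `accuracy_gap` (exhaustive minus forward, >= 0) and
#'   chance-level flags.
#' @export
compare_strategies <- function(cohort, features = NULL, degrees = 1:5,
                               B = 100, seed = 1, spec = svm_spec()) {
  fwd <- forward_select(cohort, features, degrees, B, seed, spec)
  exh <- suppressWarnings(
    exhaustive_search(cohort, features, degrees, B, seed, spec))
  acc_of <- function(r)
    r$best_summary$summary$mean[r$best_summary$summary$metric == "accuracy"]
  chance <- function(r) {
    s <- r$best_summary$summary
    a <- s[s$metric == "accuracy", ]
    a$ci95_low <= 50 && 50 <= a$ci95_high
  }
  fa <- fwd$trace$mean_accuracy[nrow(fwd$trace)]
  ea <- exh$trace$mean_accuracy[match(paste(exh$best_subset, collapse = "+"),
                                      exh$trace$subset)]
  structure(list(
    forward = fwd, exhaustive = exh,
    same_subset = setequal(fwd$best_subset, exh$best_subset),
    forward_accuracy = fa, exhaustive_accuracy = ea,
    accuracy_gap = ea - fa,
    forward_chance_level = chance(fwd),
    exhaustive_chance_level = chance(exh),
    note = exh$note
  ), class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison>\n")
  cat(sprintf("  forward:    {%s} d=%d  %.1f%%%s\n",
              paste(x$forward$best_subset, collapse = ", "),
              x$forward$best_degree, x$forward_accuracy,
              if (x$forward_chance_level) "  [chance level]" else ""))
  cat(sprintf("  exhaustive: {%s} d=%d  %.1f%%%s\n",
              paste(x$exhaustive$best_subset, collapse = ", "),
              x$exhaustive$best_degree, x$exhaustive_accuracy,
              if (x$exhaustive_chance_level) "  [chance level]" else ""))
  cat(sprintf("  accuracy gap (exhaustive - forward): %.1f points\n",
              x$accuracy_gap))
  invisible(x)
}
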