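test_that("balanced subsampling matches the published cohort arithmetic", {
  set.seed(15)
  # 22 converters vs 52 non-converters -> balanced cohort of 44
  cm <- make_cohort(matrix(rnorm(74 * 3), 74, 3),
                    c(rep(1, 22), rep(-1, 52)))
  bal <- balanced_subsample(cm, seed = 4)
  expect_identical(nrow(bal$X), 44L)
  expect_identical(sum(bal$y == 1), 22L)
  expect_identical(sum(bal$y == -1), 22L)
  expect_true(all(cm$ids[cm$y == 1] %in% bal$ids))   # minority fully retained
  expect_identical(anyDuplicated(bal$ids), 0L)       # without replacement

  # 31 vs 39 -> 62
  cm3 <- make_cohort(matrix(rnorm(70 * 2), 70, 2), c(rep(1, 31), rep(-1, 39)))
  expect_identical(nrow(balanced_subsample(cm3, seed = 1)$X), 62L)

  # already balanced: the very same patients come back
  cmb <- make_cohort(matrix(rnorm(20 * 2), 20, 2), rep(c(1, -1), 10))
  expect_identical(balanced_subsample(cmb, seed = 99), cmb)

  expect_error(balanced_subsample(
    make_cohort(matrix(rnorm(8), 4, 2), rep(1, 4)), seed = 1), "non-empty")
})

test_that("LOO-CV trains on n-1 patients and aggregates all n verdicts", {
  set.seed(16)
  cm <- make_cohort(matrix(rnorm(44 * 2), 44, 2), rep(c(1, -1), each = 22))
  m <- loo_cv(cm, spec = svm_spec(1))
  expect_identical(attr(m, "n"), 44L)
  expect_identical(attr(m, "n_train"), 43L)
  expect_identical(m$tp + m$fp + m$tn + m$fn, 44L)

  # wide-margin separable cohort: 100% LOO accuracy
  Xs <- rbind(matrix(rnorm(20 * 2, 6), 20, 2), matrix(rnorm(20 * 2, -6), 20, 2))
  sep <- make_cohort(Xs, rep(c(1, -1), each = 20))
  expect_equal(loo_cv(sep, spec = svm_spec(1))$accuracy, 100)

  expect_error(loo_cv(make_cohort(matrix(rnorm(6), 3, 2), c(1, -1, 1))), ">= 4")
  expect_error(loo_cv(make_cohort(matrix(rnorm(10), 5, 2), c(1, -1, -1, -1, -1))),
               ">= 2 per class|>= 2 patients")
})

test_that("label shuffles bring LOO accuracy to chance", {
  set.seed(17)
  n <- 44
  X <- matrix(rnorm(n * 3), n, 3)
  accs <- vapply(1:100, function(i) {
    y <- sample(rep(c(1, -1), each = n / 2))
    loo_cv(make_cohort(X, y), spec = svm_spec(1))$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 50), 5)
})

test_that("metrics are exact functions of the confusion counts", {
  m <- metrics_from_confusion(17, 7, 15, 5)
  expect_equal(m$accuracy, 100 * 32 / 44, tolerance = 1e-12)
  expect_equal(round(m$accuracy, 1), 72.7)
  expect_equal(round(m$sensitivity, 1), 77.3)
  expect_equal(round(m$specificity, 1), 68.2)
  expect_equal(m$ppv, 100 * 17 / 24)
  expect_equal(m$npv, 100 * 15 / 20)

  perfect <- metrics_from_confusion(10, 0, 10, 0)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv")]) == 100))

  # zero denominators are not-a-value, never 0
  degenerate <- metrics_from_confusion(0, 0, 10, 10)
  expect_equal(degenerate$sensitivity, 0)
  expect_true(is.nan(degenerate$ppv))
  expect_equal(degenerate$specificity, 100)

  expect_error(metrics_from_confusion(-1, 0, 1, 0), ">= 0")
  expect_error(metrics_from_confusion(0, 0, 0, 0), "> 0")
})

test_that("bootstrap summaries are reproducible and correctly ordered", {
  set.seed(18)
  X <- matrix(rnorm(60 * 2), 60, 2)
  X[1:20, 1] <- X[1:20, 1] + 2
  cm <- make_cohort(X, c(rep(1, 20), rep(-1, 40)))

  a <- bootstrap_evaluate(cm, "f1", svm_spec(1), B = 15, seed = 42)
  b <- bootstrap_evaluate(cm, "f1", svm_spec(1), B = 15, seed = 42)
  expect_identical(a, b)
  c2 <- bootstrap_evaluate(cm, "f1", svm_spec(1), B = 15, seed = 43)
  expect_false(identical(a$values, c2$values))

  expect_identical(nrow(a$values), 15L)
  s <- a$summary
  for (i in seq_len(nrow(s))) {
    expect_lte(s$range_min[i], s$ci95_low[i])
    expect_lte(s$ci95_low[i], s$mean[i] + 1e-9)
    expect_lte(s$mean[i], s$ci95_high[i] + 1e-9)
    expect_lte(s$ci95_high[i], s$range_max[i])
  }

  # degenerate: an already balanced cohort makes every bootstrap identical,
  # so ranges collapse to zero width
  bal <- make_cohort(X[1:40, ], rep(c(1, -1), each = 20))
  zb <- bootstrap_evaluate(bal, "f1", svm_spec(1), B = 2, seed = 1)
  expect_identical(zb$summary$range_min, zb$summary$range_max)

  expect_error(bootstrap_evaluate(cm, "f1", svm_spec(1), B = 1, seed = 1), ">= 2")
})

test_that("every emitted metric satisfies its defining identity", {
  set.seed(19)
  for (i in 1:25) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    tn <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + fp + tn + fn == 0) tp <- 1
    m <- metrics_from_confusion(tp, fp, tn, fn)
    total <- tp + fp + tn + fn
    expect_equal(m$accuracy, 100 * (tp + tn) / total)
    if (tp + fn > 0) expect_equal(m$sensitivity, 100 * tp / (tp + fn))
    else expect_true(is.nan(m$sensitivity))
    if (tn + fp > 0) expect_equal(m$specificity, 100 * tn / (tn + fp))
    else expect_true(is.nan(m$specificity))
    if (tp + fp > 0) expect_equal(m$ppv, 100 * tp / (tp + fp))
    else expect_true(is.nan(m$ppv))
    if (tn + fn > 0) expect_equal(m$npv, 100 * tn / (tn + fn))
    else expect_true(is.nan(m$npv))
  }
})
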