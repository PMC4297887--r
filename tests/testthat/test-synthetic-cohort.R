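# all cohorts in this file use reduced lattices; the generator's physical
# defaults (256x256x46 native, 91x109x91 template) are exercised implicitly
# through cohort_config's validation and are too large for routine tests
small_dims <- list(native_dims = c(28, 28, 14), native_voxel_mm = c(1, 1, 3),
                   template_dims = c(22, 26, 22), template_voxel_mm = c(2, 2, 2))

small_config <- function(...) {
  do.call(cohort_config, c(list(...), small_dims))
}

test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- small_config(n_converters = 5, n_nonconverters = 5, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_length(a, 10)
  expect_identical(vapply(a, `[[`, "", "label"),
                   rep(c("converter", "non-converter"), each = 5))
  # inclusion criterion: every native mask has >= 1 lesion voxel
  for (rec in a) {
    expect_gte(sum(rec$native_mask$values), 1)
    expect_gte(sum(rec$template_mask$values), 1)
    expect_true(all(connected_components(rec$native_mask)$component_sizes >= 1))
    expect_identical(dim(rec$pd_volume), dim(rec$native_mask))
    expect_true(all(rec$pd_volume$values >= 0))
    expect_true(rec$edss >= 0 && rec$edss <= 10)
    expect_true(rec$cis_type %in% c("optic_neuritis", "spinal_cord",
                                    "brainstem", "other"))
  }
})

test_that("zero effect sizes produce no systematic class differences", {
  cfg <- small_config(n_converters = 30, n_nonconverters = 30, seed = 31,
                      effect_sizes = default_effect_sizes() * 0)
  co <- generate_cohort(cfg)
  ft <- extract_feature_table(co)
  lab <- vapply(co, `[[`, "", "label")
  for (f in c("lesion_load", "lesion_count", "min_axis_dist", "mean_dist_center")) {
    t <- t.test(ft[[f]][lab == "converter"], ft[[f]][lab == "non-converter"])
    expect_lt(abs(t$statistic), 4)
  }
  age <- vapply(co, `[[`, 0, "age")
  expect_lt(abs(t.test(age[lab == "converter"], age[lab == "non-converter"])$statistic), 4)
})

test_that("the default planted effects raise converter lesion load in >= 95/100 replicates", {
  hits <- 0L
  for (s in 1:100) {
    cfg <- cohort_config(n_converters = 22, n_nonconverters = 22, seed = s,
                         native_dims = c(20, 20, 10), native_voxel_mm = c(1, 1, 3),
                         template_dims = c(16, 20, 16), template_voxel_mm = c(2, 2, 2))
    co <- generate_cohort(cfg)
    load <- vapply(co, function(r) sum(r$native_mask$values), 0)
    lab <- vapply(co, `[[`, "", "label")
    if (mean(load[lab == "converter"]) > mean(load[lab == "non-converter"]))
      hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("lesion counts are calibrated to the published bin proportions", {
  counts <- draw_lesion_counts(1000, list(mu = 13.98, size = 0.983), seed = 5)
  expect_true(all(counts >= 1))
  props <- c(mean(counts <= 3), mean(counts > 3 & counts <= 10), mean(counts > 10))
  target <- c(14, 23, 37) / 74
  expect_true(all(abs(props - target) <= 0.10))
})

test_that("stronger planted effects widen the class-mean gap monotonically", {
  params <- list(mu = 13.98, size = 0.983)
  gaps <- vapply(c(0, 0.8, 1.6), function(es) {
    mean(draw_lesion_counts(4000, params, effect = es, seed = 17)) -
      mean(draw_lesion_counts(4000, params, effect = 0, seed = 18))
  }, 0)
  expect_true(all(diff(gaps) > 0))

  # radial placement effect: stronger (more negative) min_axis_dist shift
  # pulls converter lesion centroids towards the vertical axis
  axis_means <- vapply(c(0, -0.8, -1.6), function(es) {
    cfg <- small_config(n_converters = 15, n_nonconverters = 2, seed = 23,
                        effect_sizes = c(min_axis_dist = es))
    co <- generate_cohort(cfg)
    conv <- co[vapply(co, `[[`, "", "label") == "converter"]
    mean(vapply(conv, function(r) min_centroid_axis_distance(r$template_mask), 0))
  }, 0)
  expect_true(all(diff(axis_means) < 0))
})

test_that("null cohorts have coin-flip labels independent of the features", {
  expect_error(generate_null_cohort(3, 1), "even")
  expect_error(generate_null_cohort(7, 1), "even")

  co <- do.call(generate_null_cohort, c(list(n = 44, seed = 1), small_dims))
  expect_length(co, 44)
  expect_true(all(vapply(co, `[[`, "", "label") %in% c("converter", "non-converter")))

  # label vs gender chi-square: scaled-down replicate study (20 seeds x 100
  # records at tiny lattices); expect non-significance at alpha = 0.01
  tiny <- list(native_dims = c(14, 14, 8), native_voxel_mm = c(1, 1, 3),
               template_dims = c(12, 14, 12), template_voxel_mm = c(2, 2, 2),
               lesion_count_params = list(mu = 2, size = 1),
               lesion_size_params = list(prob = 0.2, max_voxels = 20))
  nonsig <- 0L
  for (s in 1:20) {
    co <- do.call(generate_null_cohort, c(list(n = 100, seed = 1000 + s), tiny))
    lab <- vapply(co, `[[`, "", "label")
    gen <- vapply(co, `[[`, "", "gender")
    p <- suppressWarnings(chisq.test(table(lab, gen))$p.value)
    if (is.na(p) || p > 0.01) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 19)
})

test_that("cohorts round-trip through NIfTI + CSV on disk", {
  cfg <- small_config(n_converters = 2, n_nonconverters = 2, seed = 3)
  co <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_identical(
    readLines(file.path(dir, "clinical.csv"), n = 1),
    "\"id\",\"age\",\"gender\",\"cis_type\",\"edss\",\"label_1y\",\"label_3y\"")
  back <- read_cohort(dir)
  expect_length(back, 4)
  for (i in seq_along(co)) {
    expect_identical(back[[i]]$id, co[[i]]$id)
    expect_identical(back[[i]]$native_mask$values, co[[i]]$native_mask$values)
    expect_identical(back[[i]]$template_mask$values, co[[i]]$template_mask$values)
    expect_equal(back[[i]]$pd_volume$values, co[[i]]$pd_volume$values,
                 tolerance = 1e-6)
    expect_identical(back[[i]]$gender, co[[i]]$gender)
    expect_equal(back[[i]]$edss, co[[i]]$edss)
  }
  unlink(dir, recursive = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_converters = 0), ">= 1")
  expect_error(cohort_config(noise_sd = 0), "> 0")
  expect_error(cohort_config(lesion_size_params = list(prob = 1.5, max_voxels = 10)),
               "voxel")
  cfg3 <- cohort_config(horizon = "3y")
  expect_identical(cfg3$n_converters, 31L)
  expect_identical(cfg3$n_nonconverters, 39L)
  cfg1 <- cohort_config()
  expect_identical(cfg1$n_converters + cfg1$n_nonconverters, 74L)
})
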