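grid_from_voxels <- function(dims, voxels, voxel_mm = c(1, 1, 1)) {
  v <- array(0L, dims)
  for (vx in voxels) v[vx[1], vx[2], vx[3]] <- 1L
  voxel_grid(v, voxel_mm)
}

test_that("18-connectivity joins edge neighbours but not corner-only contacts", {
  edge <- grid_from_voxels(c(3, 3, 3), list(c(1, 1, 1), c(2, 2, 1)))
  expect_identical(connected_components(edge, 18)$n_components, 1L)

  corner <- grid_from_voxels(c(3, 3, 3), list(c(1, 1, 1), c(2, 2, 2)))
  expect_identical(connected_components(corner, 18)$n_components, 2L)
  expect_identical(connected_components(corner, 26)$n_components, 1L)
  expect_identical(connected_components(corner, 6)$n_components, 2L)
  expect_identical(lesion_count(corner), 2L)

  face <- grid_from_voxels(c(3, 3, 3), list(c(1, 1, 1), c(2, 1, 1)))
  expect_identical(connected_components(face, 6)$n_components, 1L)
})

test_that("component labelling matches a brute-force flood-fill oracle", {
  set.seed(101)
  for (i in 1:50) {
    dims <- sample(3:12, 3, replace = TRUE)
    mask <- random_mask(dims, p = runif(1, 0.05, 0.3))
    for (conn in c(6, 18, 26)) {
      got <- connected_components(mask, conn)
      want <- oracle_components(mask$values, conn)
      expect_identical(got$n_components, want$n)
      expect_identical(got$label_grid$values, want$lab)
      expect_identical(got$component_sizes, want$sizes)
    }
  }
})

test_that("distance and cube features follow the stated mm conventions", {
  d <- c(9, 9, 9); vs <- c(2, 2, 2)
  ci <- floor(d / 2) + 1    # central voxel

  center <- grid_from_voxels(d, list(ci), vs)
  expect_equal(mean_distance_to_center(center), 0)
  expect_identical(central_cube_presence(center), 1L)
  expect_equal(min_centroid_axis_distance(center), 0)

  # single voxel 3 voxels along one axis at 2 mm spacing -> 6 mm
  off <- grid_from_voxels(d, list(ci + c(3, 0, 0)), vs)
  expect_equal(mean_distance_to_center(off), 6)

  # cube membership is a closed interval: exactly 5 mm on one axis is in
  boundary <- grid_from_voxels(d, list(ci + c(0, 0, 2)), c(2, 2, 2.5))
  expect_identical(central_cube_presence(boundary), 1L)
  outside <- grid_from_voxels(d, list(ci + c(0, 0, 2)), c(2, 2, 2.6))
  expect_identical(central_cube_presence(outside), 0L)

  # min over two component centroids at in-plane 4 mm and 9 mm
  two <- grid_from_voxels(c(19, 19, 9), list(c(12, 10, 5), c(10, 19, 5)),
                          c(2, 1, 1))
  expect_equal(min_centroid_axis_distance(two), 4)
})

test_that("size profile respects the 1-15 / 16-36 / 37+ bin edges", {
  line_blob <- function(start, len) lapply(seq_len(len) - 1, function(k) start + c(k, 0, 0))
  d <- c(45, 40, 8)
  m <- grid_from_voxels(d, c(line_blob(c(2, 2, 2), 3),
                             line_blob(c(2, 6, 2), 20),
                             line_blob(c(2, 10, 2), 40)))
  expect_identical(size_profile(m), c(n_small = 1L, n_medium = 1L, n_large = 1L))

  m2 <- grid_from_voxels(d, c(line_blob(c(2, 2, 2), 15),
                              line_blob(c(2, 6, 2), 16),
                              line_blob(c(2, 10, 2), 36),
                              line_blob(c(2, 14, 2), 37)))
  expect_identical(size_profile(m2), c(n_small = 1L, n_medium = 2L, n_large = 1L))
  expect_identical(sum(size_profile(m2)), sum(lesion_count(m2)))
})

test_that("intensity means and loads match loop oracles and validate inputs", {
  set.seed(102)
  dims <- c(8, 7, 6); vs <- c(1.2, 0.8, 2)
  mask <- random_mask(dims, 0.2, vs)
  vol <- voxel_grid(array(rnorm(prod(dims), 100, 15), dims), vs)
  want <- mean(vol$values[mask$values == 1])
  expect_equal(mean_lesion_intensity(mask, vol), want)
  expect_identical(lesion_load(mask), sum(mask$values))

  const <- voxel_grid(array(100, dims), vs)
  expect_equal(mean_lesion_intensity(mask, const), 100)

  empty <- voxel_grid(array(0L, dims), vs)
  expect_error(lesion_count(empty), "empty")
  expect_error(lesion_load(empty), "empty")
  expect_error(mean_distance_to_center(empty), "empty")
  expect_error(mean_lesion_intensity(empty, vol), "empty")
  expect_error(central_cube_presence(mask, side_mm = 0), "> 0")
  bad <- voxel_grid(array(2, dims), vs)
  expect_error(connected_components(bad), "binary")
  small <- voxel_grid(array(1L, c(2, 2, 2)), vs)
  expect_error(mean_lesion_intensity(small, vol), "lattice|dimensions")
})

test_that("all eight features agree with brute-force oracles on random masks", {
  set.seed(103)
  for (i in 1:30) {
    dims <- sample(4:14, 3, replace = TRUE)
    vs <- round(runif(3, 0.5, 3), 3)
    mask <- random_mask(dims, runif(1, 0.05, 0.25), vs)
    vol <- voxel_grid(array(rnorm(prod(dims), 100, 10), dims), vs)
    want_cc <- oracle_components(mask$values, 18)
    expect_identical(lesion_count(mask), want_cc$n)
    expect_identical(lesion_load(mask), sum(mask$values))
    expect_equal(mean_lesion_intensity(mask, vol),
                 mean(vol$values[mask$values == 1]), tolerance = 1e-12)
    expect_equal(mean_distance_to_center(mask),
                 oracle_mean_dist(mask$values, vs), tolerance = 1e-9)
    expect_identical(central_cube_presence(mask), oracle_cube(mask$values, vs))
    expect_equal(min_centroid_axis_distance(mask),
                 oracle_axis_dist(mask$values, vs), tolerance = 1e-9)
    expect_identical(unname(size_profile(mask)), as.integer(oracle_profile(mask$values)))
    # partition property
    expect_identical(sum(want_cc$sizes), lesion_load(mask))
    expect_identical(sum(size_profile(mask)), lesion_count(mask))
  }
})

test_that("features are invariant under translation and monotone under growth", {
  set.seed(104)
  base <- random_mask(c(8, 8, 8), 0.15, c(1, 1, 1))
  shifted <- array(0L, c(12, 12, 12))
  shifted[3:10, 4:11, 2:9] <- base$values
  shifted <- voxel_grid(shifted, c(1, 1, 1))
  expect_identical(lesion_count(shifted), lesion_count(base))
  expect_identical(lesion_load(shifted), lesion_load(base))
  expect_identical(size_profile(shifted), size_profile(base))

  # adding a voxel never decreases load; bridging two components reduces count
  two <- array(0L, c(7, 3, 3)); two[c(1, 2), 2, 2] <- 1L; two[c(5, 6), 2, 2] <- 1L
  two <- voxel_grid(two, c(1, 1, 1))
  expect_identical(lesion_count(two), 2L)
  bridged <- two; bridged$values[3:4, 2, 2] <- 1L
  expect_identical(lesion_count(bridged), 1L)
  expect_gte(lesion_load(bridged), lesion_load(two))
})

test_that("extract_features composes the individual operations", {
  # one 5-voxel lesion at the template centre
  td <- c(21, 25, 21); tvs <- c(2, 2, 2); ci <- floor(td / 2) + 1
  tmask <- array(0L, td)
  for (k in -2:2) tmask[ci[1] + k, ci[2], ci[3]] <- 1L
  nd <- c(16, 16, 8); nvs <- c(1, 1, 3)
  nmask <- array(0L, nd); nmask[4:8, 5, 3] <- 1L
  rec <- list(id = "toy",
              native_mask = voxel_grid(nmask, nvs),
              template_mask = voxel_grid(tmask, tvs),
              pd_volume = voxel_grid(array(120, nd), nvs),
              t2_volume = voxel_grid(array(80, nd), nvs))
  fs <- extract_features(rec)
  expect_identical(fs$lesion_count, 1L)
  expect_identical(fs$lesion_load, 5L)
  expect_equal(fs$mean_pd, 120)
  expect_equal(fs$mean_t2, 80)
  expect_identical(fs$central_cube, 1L)
  expect_equal(fs$min_axis_dist, 0)
  expect_lt(fs$mean_dist_center, sqrt(sum(tvs^2)) * 2)
  expect_identical(c(fs$n_small, fs$n_medium, fs$n_large), c(1L, 0L, 0L))

  # cross-check every field against the individual operations
  expect_identical(fs$lesion_count, lesion_count(rec$native_mask))
  expect_identical(fs$lesion_load, lesion_load(rec$native_mask))
  expect_equal(fs$mean_dist_center, mean_distance_to_center(rec$template_mask))
  expect_equal(fs$min_axis_dist, min_centroid_axis_distance(rec$template_mask))
})
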