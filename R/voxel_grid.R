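#' 3D voxel lattice with physical spacing
#'
#' A `voxel_grid` is the carrier for all image-like objects in the package:
#' binary lesion masks and PD/T2 intensity volumes. It wraps a 3D array of
#' finite scalars together with the per-axis physical voxel size in
#' millimetres, which all distance-based lesion features use; distances
#' computed on voxel indices alone would be geometrically wrong for
#' anisotropic native-space voxels (e.g. 0.9375 x 0.9375 x 3 mm).
#'
#' @param values 3D numeric (or logical, coerced to integer) array.
#' @param voxel_size_mm positive numeric triple, mm per voxel along each axis.
#' @return An object of class `voxel_grid` with elements `values` and
#'   `voxel_size_mm`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), c(1, 1, 1))
#' dim(g)
#' @export
voxel_grid <- function(values, voxel_size_mm = c(1, 1, 1)) {
  if (is.logical(values)) storage.mode(values) <- "integer"
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 1L)) stop("all dims must be >= 1")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be a positive triple")
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite")
  structure(list(values = values, voxel_size_mm = voxel_size_mm),
            class = "voxel_grid")
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  nz <- sum(x$values != 0)
  cat(sprintf("  nonzero voxels: %d (%.2f%%)\n", nz, 100 * nz / prod(d)))
  invisible(x)
}

# 1-based index of the central voxel: floor(dim/2) in 0-based indexing.
grid_center_index <- function(grid) {
  floor(dim(grid) / 2) + 1L
}

is_binary_grid <- function(grid) {
  v <- grid$values
  all(v == 0 | v == 1)
}

stop_if_not_binary <- function(grid, what = "mask") {
  if (!is_binary_grid(grid)) stop(sprintf("`%s` must be binary (0/1)", what))
  invisible(grid)
}

stop_if_empty <- function(grid, what = "mask") {
  if (!any(grid$values != 0))
    stop(sprintf("`%s` is empty: included patients must have >= 1 lesion voxel", what))
  invisible(grid)
}

same_lattice <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm))
}
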