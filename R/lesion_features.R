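#' Label connected components of a binary lesion mask
#'
#' Lesions are defined as connected components of the binary mask under an
#' 18-neighbourhood: two voxels belong to the same lesion iff a chain of
#' face- or edge-adjacent voxels links them (corner-only contacts do not
#' connect). 6- and 26-connectivity are available for comparison.
#' Components are labelled 1..n in the order their first voxel is met in
#' raster order (first array index fastest), which makes labelling, and any
#' downstream tie-breaking, deterministic.
#'
#' @param mask binary [voxel_grid()].
#' @param connectivity 6 (faces), 18 (faces + edges, default) or 26 (+ corners).
#' @return A `labeled_components` object: `label_grid` (integer
#'   [voxel_grid()]), `n_components`, and `component_sizes` in voxels.
#' @examples
#' m <- array(0L, c(3, 3, 3)); m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L
#' connected_components(voxel_grid(m), 18)$n_components  # corner contact: 2
#' @export
connected_components <- function(mask, connectivity = 18) {
  stopifnot(inherits(mask, "voxel_grid"))
  stop_if_not_binary(mask)
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  v <- mask$values
  d <- dim(v)
  offs <- neighbor_offsets(connectivity)
  nofs <- nrow(offs)
  lab <- array(0L, d)
  seeds <- which(v == 1)          # linear index order == raster order
  ncomp <- 0L
  sizes <- integer(0)
  for (s in seeds) {
    if (lab[s] != 0L) next
    ncomp <- ncomp + 1L
    lab[s] <- ncomp
    size <- 1L
    frontier <- arrayInd(s, d)
    while (nrow(frontier) > 0L) {
      nf <- nrow(frontier)
      nb <- frontier[rep(seq_len(nf), each = nofs), , drop = FALSE] +
        offs[rep(seq_len(nofs), times = nf), , drop = FALSE]
      keep <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) == 0L) break
      lin <- unique(nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L))
      lin <- lin[v[lin] == 1 & lab[lin] == 0L]
      if (length(lin) == 0L) break
      lab[lin] <- ncomp
      size <- size + length(lin)
      frontier <- arrayInd(lin, d)
    }
    sizes <- c(sizes, size)
  }
  structure(list(label_grid = voxel_grid(lab, mask$voxel_size_mm),
                 n_components = ncomp,
                 component_sizes = sizes),
            class = "labeled_components")
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  max_ord <- c(`6` = 1L, `18` = 2L, `26` = 3L)[[as.character(connectivity)]]
  storage.mode(g) <- "integer"
  g[ord >= 1L & ord <= max_ord, , drop = FALSE]
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d component(s), sizes: %s\n",
              x$n_components, paste(x$component_sizes, collapse = ", ")))
  invisible(x)
}

#' Number of lesions in a native-space mask
#'
#' Count of 18-connected components of the binary native lesion mask.
#'
#' @param mask binary, non-empty [voxel_grid()].
#' @return Integer count (>= 1).
#' @export
lesion_count <- function(mask) {
  stop_if_empty(mask)
  connected_components(mask, 18)$n_components
}

#' Total lesion load in voxels
#'
#' @param mask binary, non-empty [voxel_grid()].
#' @return Number of lesional (nonzero) voxels.
#' @export
lesion_load <- function(mask) {
  stop_if_not_binary(mask)
  stop_if_empty(mask)
  sum(mask$values == 1)
}

#' Mean intensity over lesional voxels
#'
#' Arithmetic mean of an intensity volume (PD or T2) over the mask-positive
#' voxels. Mask and volume must share the same lattice.
#'
#' @param mask binary, non-empty [voxel_grid()].
#' @param volume intensity [voxel_grid()] on the same lattice.
#' @return Mean intensity (scalar).
#' @export
mean_lesion_intensity <- function(mask, volume) {
  stop_if_not_binary(mask)
  stop_if_empty(mask)
  if (!same_lattice(mask, volume))
    stop("mask and volume must share dimensions and voxel sizes")
  mean(volume$values[mask$values == 1])
}

#' Mean distance of lesional voxels to the brain centre
#'
#' Mean, over all lesional voxels of the template-space mask, of the
#' Euclidean distance in millimetres between the voxel centre and the
#' centre of the template lattice (the central voxel, index floor(dim/2)
#' per axis, 0-based). Captures how spread out lesions are after spatial
#' normalisation.
#'
#' @param template_mask binary, non-empty template-space [voxel_grid()].
#' @return Distance in mm (>= 0).
#' @export
mean_distance_to_center <- function(template_mask) {
  stop_if_not_binary(template_mask)
  stop_if_empty(template_mask)
  idx <- arrayInd(which(template_mask$values == 1), dim(template_mask))
  delta <- sweep(idx, 2, grid_center_index(template_mask))
  delta <- sweep(delta, 2, template_mask$voxel_size_mm, `*`)
  mean(sqrt(rowSums(delta^2)))
}

#' Lesion presence near the brain centre
#'
#' 1 if any lesional voxel centre lies within a closed cube of side
#' `side_mm` (default 10 mm, i.e. 1 cm^3) centred on the central voxel of
#' the template lattice, else 0. Midline lesions (e.g. corpus callosum)
#' trigger this flag.
#'
#' @param template_mask binary, non-empty template-space [voxel_grid()].
#' @param side_mm cube side length in mm (> 0).
#' @return 0 or 1.
#' @export
central_cube_presence <- function(template_mask, side_mm = 10) {
  if (!is.numeric(side_mm) || side_mm <= 0) stop("`side_mm` must be > 0")
  stop_if_not_binary(template_mask)
  stop_if_empty(template_mask)
  idx <- arrayInd(which(template_mask$values == 1), dim(template_mask))
  delta <- sweep(idx, 2, grid_center_index(template_mask))
  delta <- abs(sweep(delta, 2, template_mask$voxel_size_mm, `*`))
  as.integer(any(rowSums(delta <= side_mm / 2) == 3L))
}

#' Shortest centroid distance to the vertical brain axis
#'
#' For each 18-connected lesion of the template-space mask, computes the
#' unweighted centroid (mean voxel-centre coordinate in mm) and its
#' in-plane Euclidean distance to the vertical (inferior-superior) axis
#' through the central voxel, i.e. the intersection line of the
#' midsagittal and midcoronal planes; returns the minimum over lesions.
#' The third array axis is taken as inferior-superior.
#'
#' @param template_mask binary, non-empty template-space [voxel_grid()].
#' @return Distance in mm (>= 0).
#' @export
min_centroid_axis_distance <- function(template_mask) {
  stop_if_empty(template_mask)
  cc <- connected_components(template_mask, 18)
  lab <- cc$label_grid$values
  idx <- arrayInd(which(lab > 0L), dim(template_mask))
  labs <- lab[lab > 0L]
  vs <- template_mask$voxel_size_mm
  ci <- grid_center_index(template_mask)
  cx <- tapply(idx[, 1], labs, mean)
  cy <- tapply(idx[, 2], labs, mean)
  min(sqrt(((cx - ci[1]) * vs[1])^2 + ((cy - ci[2]) * vs[2])^2))
}

#' Lesion size profile
#'
#' Counts of 18-connected native-space lesions falling in three size bins:
#' small (1-15 voxels), medium (16-36 voxels) and large (37+ voxels).
#'
#' @param mask binary, non-empty native-space [voxel_grid()].
#' @return Named integer triple `c(n_small, n_medium, n_large)`.
#' @export
size_profile <- function(mask) {
  stop_if_empty(mask)
  sizes <- connected_components(mask, 18)$component_sizes
  c(n_small  = sum(sizes >= 1 & sizes <= 15),
    n_medium = sum(sizes >= 16 & sizes <= 36),
    n_large  = sum(sizes >= 37))
}

#' Extract the eight lesion features of one patient
#'
#' Count, load, mean intensities and the size profile are computed on the
#' native-space mask and PD/T2 volumes; the three distance-based features
#' on the template-space mask (after spatial normalisation, distances to a
#' fixed template centre are comparable across patients).
#'
#' @param record a `patient_record` (see [generate_cohort()]), or any list
#'   with elements `native_mask`, `template_mask`, `pd_volume`, `t2_volume`.
#' @return A `lesion_feature_set`: named list of the 8 features (the size
#'   profile spanning three counts).
#' @export
extract_features <- function(record) {
  nm <- record$native_mask
  tm <- record$template_mask
  prof <- size_profile(nm)
  structure(list(
    lesion_count          = lesion_count(nm),
    lesion_load           = lesion_load(nm),
    mean_pd               = mean_lesion_intensity(nm, record$pd_volume),
    mean_t2               = mean_lesion_intensity(nm, record$t2_volume),
    mean_dist_center      = mean_distance_to_center(tm),
    central_cube          = central_cube_presence(tm),
    min_axis_dist         = min_centroid_axis_distance(tm),
    n_small               = unname(prof["n_small"]),
    n_medium              = unname(prof["n_medium"]),
    n_large               = unname(prof["n_large"])
  ), class = "lesion_feature_set")
}

#' Lesion feature table for a cohort
#'
#' @param cohort list of `patient_record`s.
#' @return `data.frame` with one row per patient and columns `id`,
#'   `lesion_count`, `lesion_load`, `mean_pd`, `mean_t2`,
#'   `mean_dist_center`, `central_cube`, `min_axis_dist`, `n_small`,
#'   `n_medium`, `n_large`.
#' @export
extract_feature_table <- function(cohort) {
  rows <- lapply(cohort, function(rec) {
    fs <- extract_features(rec)
    data.frame(id = rec$id, as.data.frame(unclass(fs)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
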