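#' Default planted class effects
#'
#' Standardized mean shifts (converters minus non-converters) for the
#' features the original cohort showed group differences on: higher lesion
#' load and count, shorter centroid distance to the vertical brain axis,
#' younger age and female predominance among converters. Magnitudes are
#' design choices of the generator (the effects' directions are the
#' domain-reported ones); 1.0 SD on lesion load is the reference effect.
#'
#' @return Named numeric vector of standardized shifts.
#' @export
default_effect_sizes <- function() {
  c(lesion_load = 1.0, lesion_count = 0.8, min_axis_dist = -0.8,
    age = -0.5, gender = -0.5)
}

#' Configuration of a synthetic CIS cohort
#'
#' Collects every knob of the generator. Defaults emulate the published
#' cohort: 22 converters / 52 non-converters at the 1-year horizon (31/39
#' at 3 years when `horizon = "3y"` and counts are left unset), a
#' truncated negative-binomial lesion count whose <=3 / 4-10 / >10 bins
#' match the reported cohort composition (14/74, 23/74, 37/74), a
#' truncated geometric lesion size populating the three size bins
#' (1-15 / 16-36 / 37+ voxels) roughly equally, a native lattice of
#' 256 x 256 x 46 voxels at 0.9375 x 0.9375 x 3 mm and a template lattice
#' of 91 x 109 x 91 voxels at 2 mm isotropic.
#'
#' @param n_converters,n_nonconverters class sizes (>= 1); when missing they
#'   default to 22/52 (`"1y"`) or 31/39 (`"3y"`).
#' @param horizon follow-up horizon the planted label refers to.
#' @param effect_sizes named standardized mean shifts, see
#'   [default_effect_sizes()]; use an all-zero vector for a null world.
#' @param lesion_count_params list `mu`, `size` of the negative binomial
#'   (truncated to >= 1 lesion, the study inclusion criterion).
#' @param lesion_size_params list `prob` (geometric on 1, 2, ...) and
#'   `max_voxels` truncation.
#' @param noise_sd intensity noise SD (> 0), arbitrary units.
#' @param contrast additive lesion hyperintensity on PD and T2 (> 0).
#' @param background_mean mean background tissue intensity.
#' @param native_dims,native_voxel_mm native-space lattice.
#' @param template_dims,template_voxel_mm template-space lattice.
#' @param seed master seed; per-patient streams are derived from it by a
#'   counter scheme, so records are reproducible independent of order.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_converters = NULL, n_nonconverters = NULL,
                          horizon = c("1y", "3y"),
                          effect_sizes = default_effect_sizes(),
                          lesion_count_params = list(mu = 13.98, size = 0.983),
                          lesion_size_params = list(prob = 0.03, max_voxels = 200),
                          noise_sd = 10, contrast = 30, background_mean = 100,
                          native_dims = c(256, 256, 46),
                          native_voxel_mm = c(0.9375, 0.9375, 3),
                          template_dims = c(91, 109, 91),
                          template_voxel_mm = c(2, 2, 2),
                          seed = 1) {
  horizon <- match.arg(horizon)
  if (is.null(n_converters))
    n_converters <- if (horizon == "1y") 22L else 31L
  if (is.null(n_nonconverters))
    n_nonconverters <- if (horizon == "1y") 52L else 39L
  if (n_converters < 1 || n_nonconverters < 1)
    stop("class counts must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("`noise_sd` must be > 0")
  p <- lesion_size_params$prob
  if (is.null(p) || p <= 0 || p >= 1 || lesion_size_params$max_voxels < 1)
    stop("lesion size distribution cannot produce >= 1 voxel")
  if (lesion_count_params$mu <= 0 || lesion_count_params$size <= 0)
    stop("invalid lesion count distribution")
  es <- default_effect_sizes() * 0
  es[names(effect_sizes)] <- effect_sizes
  structure(list(
    n_converters = as.integer(n_converters),
    n_nonconverters = as.integer(n_nonconverters),
    horizon = horizon, effect_sizes = es,
    lesion_count_params = lesion_count_params,
    lesion_size_params = lesion_size_params,
    noise_sd = noise_sd, contrast = contrast,
    background_mean = background_mean,
    native_dims = as.integer(native_dims),
    native_voxel_mm = as.numeric(native_voxel_mm),
    template_dims = as.integer(template_dims),
    template_voxel_mm = as.numeric(template_voxel_mm),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# CIS presentation-type probabilities (optic neuritis, spinal cord,
# brainstem, other), calibrated to the published composition where all 4
# spinal-cord presentations converted, with light smoothing so no
# category has probability 0.
CIS_TYPE_LEVELS <- c("optic_neuritis", "spinal_cord", "brainstem", "other")
CIS_PROBS_CONVERTER    <- c(0.74, 0.17, 0.06, 0.03)
CIS_PROBS_NONCONVERTER <- c(0.88, 0.01, 0.09, 0.02)

#' Draw planted lesion counts
#'
#' The per-patient number of lesions is negative binomial (overdispersed,
#' standard for lesion-count data), truncated to >= 1; for converters the
#' mean is shifted upward by `effect` standardized units.
#'
#' @param n number of draws.
#' @param params list `mu`, `size`.
#' @param effect standardized mean shift (0 for non-converters).
#' @param seed integer seed.
#' @return Integer vector of counts >= 1.
#' @export
draw_lesion_counts <- function(n, params, effect = 0, seed = 1) {
  with_seed(seed, {
    mu <- params$mu
    sd0 <- sqrt(mu + mu^2 / params$size)
    mu_g <- max(0.5, mu + effect * sd0)
    pmax(1L, rnbinom(n, mu = mu_g, size = params$size))
  })
}

draw_lesion_sizes <- function(n, params, effect = 0) {
  # converters get larger lesions: geometric mean size scaled up
  scale <- max(0.2, 1 + 0.5 * effect)
  p <- min(0.9, params$prob / scale)
  pmin(rgeom(n, p) + 1L, as.integer(params$max_voxels))
}

# ellipsoidal brain support: semi-axes 0.45 * field of view
brain_geometry <- function(dims, voxel_mm) {
  ci <- floor(dims / 2) + 1
  semi_mm <- 0.45 * dims * voxel_mm
  list(center_index = ci, semi_mm = semi_mm)
}

brain_support_mask <- function(dims, voxel_mm) {
  geo <- brain_geometry(dims, voxel_mm)
  ax <- lapply(1:3, function(a)
    ((seq_len(dims[a]) - geo$center_index[a]) * voxel_mm[a] / geo$semi_mm[a])^2)
  outer3 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  outer3 <= 1
}

# Draw one lesion placement centre in mm relative to the lattice centre:
# 70% from a periventricular ring (radius r0, shrunk for converters via
# the min_axis_dist effect), 30% uniform inside the brain ellipsoid.
draw_lesion_center_mm <- function(geo, radial_scale) {
  r0 <- 0.25 * min(geo$semi_mm[1:2])
  if (runif(1) < 0.7) {
    theta <- runif(1, 0, 2 * pi)
    r <- abs(rnorm(1, r0 * radial_scale, r0 * 0.25))
    p <- c(r * cos(theta), r * sin(theta), rnorm(1, 0, geo$semi_mm[3] * 0.3))
  } else {
    repeat {
      p <- runif(3, -1, 1) * geo$semi_mm
      if (sum((p / geo$semi_mm)^2) <= 1) break
    }
  }
  # pull inside the ellipsoid if noise pushed it out
  rho <- sqrt(sum((p / (0.95 * geo$semi_mm))^2))
  if (rho > 1) p <- p / rho
  p
}

# Grow a 6-connected random blob of `target` voxels from `start` (1-based
# triple); returns a matrix of voxel indices. Growth is voxel-by-voxel from
# a uniformly chosen frontier candidate, guaranteeing one 18-connected
# (indeed 6-connected) component of exactly the requested size unless the
# lattice boundary exhausts the frontier first. Compiled for speed; uses
# the R RNG stream.
grow_blob <- function(dims, start, target) {
  grow_blob_cpp(as.integer(dims), as.integer(start), as.integer(target))
}

generate_patient <- function(id, label, config, seed, support = NULL) {
  with_seed(seed, {
    conv <- identical(label, "converter")
    es <- if (conv) config$effect_sizes else config$effect_sizes * 0

    ## clinical record
    age <- min(60, max(18, rnorm(1, 34 + es[["age"]] * 7, 7)))
    p_male <- 25 / 74
    p_male <- min(0.98, max(0.02, p_male + es[["gender"]] * sqrt(p_male * (1 - p_male))))
    gender <- if (runif(1) < p_male) "male" else "female"
    cis_type <- sample(CIS_TYPE_LEVELS, 1,
                       prob = if (conv) CIS_PROBS_CONVERTER else CIS_PROBS_NONCONVERTER)
    edss <- min(8, round(2 * rgamma(1, shape = 2, scale = 0.6)) / 2)

    ## native-space lesions
    nd <- config$native_dims; nvs <- config$native_voxel_mm
    geo <- brain_geometry(nd, nvs)
    n_lesions <- draw_lesion_counts(1, config$lesion_count_params,
                                    es[["lesion_count"]],
                                    seed = sample.int(.Machine$integer.max, 1))
    sizes <- draw_lesion_sizes(n_lesions, config$lesion_size_params,
                               es[["lesion_load"]])
    radial_scale <- max(0.15, 1 + 0.35 * es[["min_axis_dist"]])

    mask <- array(0L, nd)
    centers_mm <- matrix(0, n_lesions, 3)
    # separation between placement centres limits lesion confluence; scaled
    # down on small test lattices where 8 mm would be unsatisfiable
    min_sep <- min(8, 0.3 * min(geo$semi_mm))
    for (k in seq_len(n_lesions)) {
      for (attempt in 1:10) {
        cmm <- draw_lesion_center_mm(geo, radial_scale)
        if (k == 1L) break
        prev <- centers_mm[seq_len(k - 1), , drop = FALSE]
        d2 <- (prev[, 1] - cmm[1])^2 + (prev[, 2] - cmm[2])^2 +
              (prev[, 3] - cmm[3])^2
        if (min(d2) >= min_sep^2) break
      }
      centers_mm[k, ] <- cmm
      start <- pmin(nd, pmax(1L, round(geo$center_index + cmm / nvs)))
      vox <- grow_blob(nd, start, sizes[k])
      mask[vox[, 1] + nd[1] * (vox[, 2] - 1) + nd[1] * nd[2] * (vox[, 3] - 1)] <- 1L
    }

    ## template-space mask: the same lesion voxels mapped by a fixed affine
    ## (scale about the lattice centres); deformable registration is
    ## deliberately not emulated. The affine is lesion-independent, so all
    ## mask voxels are mapped in one pass.
    td <- config$template_dims; tvs <- config$template_voxel_mm
    tgeo <- brain_geometry(td, tvs)
    affine_scale <- tgeo$semi_mm / geo$semi_mm
    tmask <- array(0L, td)
    vox <- arrayInd(which(mask == 1L), nd)
    ti <- round(t((t(vox) - geo$center_index) * nvs * affine_scale / tvs +
                  tgeo$center_index))
    ti[, 1] <- pmin(td[1], pmax(1, ti[, 1]))
    ti[, 2] <- pmin(td[2], pmax(1, ti[, 2]))
    ti[, 3] <- pmin(td[3], pmax(1, ti[, 3]))
    tmask[ti[, 1] + td[1] * (ti[, 2] - 1) + td[1] * td[2] * (ti[, 3] - 1)] <- 1L

    ## intensity volumes: hyperintense lesions on noisy background tissue
    if (is.null(support)) support <- brain_support_mask(nd, nvs)
    nvox <- prod(nd)
    make_volume <- function() {
      v <- rnorm(nvox, config$background_mean, config$noise_sd)
      v[!support] <- rnorm(sum(!support), config$background_mean * 0.15,
                           config$noise_sd * 0.5)
      v[mask == 1L] <- rnorm(sum(mask == 1L),
                             config$background_mean + config$contrast,
                             config$noise_sd)
      voxel_grid(array(pmax(v, 0), nd), nvs)
    }
    pd <- make_volume()
    t2 <- make_volume()

    ## labels at both horizons (converters at 1y remain converters at 3y;
    ## extra late conversions keep the 3-year rate near the published 44%)
    if (config$horizon == "1y") {
      label_1y <- label
      label_3y <- if (conv || runif(1) < 0.17) "converter" else "non-converter"
    } else {
      label_3y <- label
      label_1y <- if (conv && runif(1) < 22 / 31) "converter" else "non-converter"
    }

    structure(list(
      id = id,
      native_mask = voxel_grid(mask, nvs),
      template_mask = voxel_grid(tmask, tvs),
      pd_volume = pd, t2_volume = t2,
      age = age, gender = gender, cis_type = cis_type, edss = edss,
      label = label, label_1y = label_1y, label_3y = label_3y
    ), class = "patient_record")
  })
}

#' Generate a synthetic CIS cohort
#'
#' Produces `n_converters + n_nonconverters` synthetic patients: binary
#' native-space lesion masks grown as random blobs around a periventricular
#' placement ring inside an ellipsoidal brain support, matched PD/T2
#' volumes with hyperintense lesions, a template-space mask obtained by
#' mapping the same lesion voxels through a fixed affine, and a clinical
#' record. Converters receive the configured standardized shifts (more and
#' larger lesions, placement closer to the vertical axis, younger age,
#' female predominance, more spinal-cord presentations).
#'
#' The generator is bit-reproducible: per-patient RNG streams are derived
#' from `config$seed` by a counter scheme.
#'
#' @param config a [cohort_config()].
#' @return List of `patient_record`s (converters first, ids `pat001`, ...).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_converters + config$n_nonconverters
  labels <- rep(c("converter", "non-converter"),
                c(config$n_converters, config$n_nonconverters))
  ids <- sprintf("pat%03d", seq_len(n))
  seeds <- derive_seeds(config$seed, n)
  support <- brain_support_mask(config$native_dims, config$native_voxel_mm)
  mapply(generate_patient, ids, labels, seed = seeds,
         MoreArgs = list(config = config, support = support),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Generate a label-independent (null) cohort
#'
#' All planted effects are zero and the conversion label at the configured
#' horizon is an independent fair coin flip per patient, so any classifier
#' evaluated on such a cohort should perform at chance. Used for
#' calibration of the evaluation machinery.
#'
#' @param n total cohort size; must be even (the downstream balanced
#'   design needs an even split to be attainable) and >= 4.
#' @param seed master seed.
#' @param ... further arguments passed to [cohort_config()] (e.g. reduced
#'   lattice dims for fast simulation).
#' @return List of `patient_record`s with coin-flip labels.
#' @export
generate_null_cohort <- function(n, seed, ...) {
  if (n < 4 || n %% 2 != 0)
    stop("`n` must be even and >= 4 (balanced design required downstream)")
  config <- cohort_config(n_converters = 1, n_nonconverters = n - 1,
                          effect_sizes = default_effect_sizes() * 0,
                          seed = seed, ...)
  labels <- with_seed(seed + 1L,
                      ifelse(rbinom(n, 1, 0.5) == 1, "converter", "non-converter"))
  ids <- sprintf("pat%03d", seq_len(n))
  seeds <- derive_seeds(seed, n)
  support <- brain_support_mask(config$native_dims, config$native_voxel_mm)
  mapply(generate_patient, ids, labels, seed = seeds,
         MoreArgs = list(config = config, support = support),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Simulate a cohort directly in feature space
#'
#' Shortcut generator for classifier and selection studies: features are
#' independent standard normals and the named (or indexed) entries of
#' `effects` are shifted upward by that many SDs in converters. Unlike
#' [generate_cohort()] this bypasses image synthesis, so features can be
#' made exactly independent pure noise — which no image-derived feature
#' set is — making it the right tool for planted-signal and null studies
#' of the selection machinery itself.
#'
#' @param n_per_class patients per class.
#' @param n_features number of features (named `f1`, `f2`, ...).
#' @param effects named numeric vector of standardized shifts, e.g.
#'   `c(f1 = 1.5)`; empty for a null cohort.
#' @param seed integer seed.
#' @param horizon label tag.
#' @return A [cohort_matrix()].
#' @export
simulate_feature_cohort <- function(n_per_class, n_features = 6,
                                    effects = numeric(0), seed = 1,
                                    horizon = "1y") {
  stopifnot(n_per_class >= 2, n_features >= 1)
  with_seed(seed, {
    n <- 2L * n_per_class
    X <- matrix(rnorm(n * n_features), n, n_features)
    colnames(X) <- paste0("f", seq_len(n_features))
    y <- rep(c(1, -1), each = n_per_class)
    if (length(effects)) {
      if (is.null(names(effects))) names(effects) <- paste0("f", seq_along(effects))
      for (f in names(effects))
        X[y == 1, f] <- X[y == 1, f] + effects[[f]]
    }
    cohort_matrix(ids = sprintf("pat%03d", seq_len(n)), X = X, y = y,
                  horizon = horizon)
  })
}

#' Write a cohort to disk
#'
#' Writes, per patient, `<id>_pd.nii.gz`, `<id>_t2.nii.gz`,
#' `<id>_mask_native.nii.gz` and `<id>_mask_template.nii.gz`, plus one
#' `clinical.csv` with header `id,age,gender,cis_type,edss,label_1y,label_3y`.
#'
#' @param cohort list of `patient_record`s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) {
    write_nifti(rec$pd_volume, file.path(dir, paste0(rec$id, "_pd.nii.gz")),
                datatype = "float32")
    write_nifti(rec$t2_volume, file.path(dir, paste0(rec$id, "_t2.nii.gz")),
                datatype = "float32")
    write_nifti(rec$native_mask,
                file.path(dir, paste0(rec$id, "_mask_native.nii.gz")),
                datatype = "uint8")
    write_nifti(rec$template_mask,
                file.path(dir, paste0(rec$id, "_mask_template.nii.gz")),
                datatype = "uint8")
  }
  clin <- data.frame(
    id = vapply(cohort, `[[`, "", "id"),
    age = vapply(cohort, `[[`, 0, "age"),
    gender = vapply(cohort, `[[`, "", "gender"),
    cis_type = vapply(cohort, `[[`, "", "cis_type"),
    edss = vapply(cohort, `[[`, 0, "edss"),
    label_1y = vapply(cohort, `[[`, "", "label_1y"),
    label_3y = vapply(cohort, `[[`, "", "label_3y"),
    stringsAsFactors = FALSE
  )
  write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the NIfTI files and `clinical.csv`.
#' @return List of `patient_record`s in `clinical.csv` row order.
#' @export
read_cohort <- function(dir) {
  clin <- read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(clin)), function(i) {
    id <- clin$id[i]
    structure(list(
      id = id,
      native_mask = read_nifti(file.path(dir, paste0(id, "_mask_native.nii.gz"))),
      template_mask = read_nifti(file.path(dir, paste0(id, "_mask_template.nii.gz"))),
      pd_volume = read_nifti(file.path(dir, paste0(id, "_pd.nii.gz"))),
      t2_volume = read_nifti(file.path(dir, paste0(id, "_t2.nii.gz"))),
      age = clin$age[i], gender = clin$gender[i],
      cis_type = clin$cis_type[i], edss = clin$edss[i],
      label = clin$label_1y[i],
      label_1y = clin$label_1y[i], label_3y = clin$label_3y[i]
    ), class = "patient_record")
  })
}
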