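# Independent brute-force oracles for the lesion features, kept free of
# any package internals: stack-based flood fill with explicit neighbour
# loops, and per-voxel loops for every distance/intensity feature.

oracle_components <- function(vals, connectivity = 18) {
  d <- dim(vals)
  max_ord <- c(`6` = 1L, `18` = 2L, `26` = 3L)[[as.character(connectivity)]]
  lab <- array(0L, d)
  ncomp <- 0L
  sizes <- integer(0)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (vals[x, y, z] != 1 || lab[x, y, z] != 0L) next
    ncomp <- ncomp + 1L
    lab[x, y, z] <- ncomp
    stack <- list(c(x, y, z))
    sz <- 1L
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        o <- abs(dx) + abs(dy) + abs(dz)
        if (o < 1L || o > max_ord) next
        nx <- v[1] + dx; ny <- v[2] + dy; nz <- v[3] + dz
        if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
        if (vals[nx, ny, nz] == 1 && lab[nx, ny, nz] == 0L) {
          lab[nx, ny, nz] <- ncomp
          sz <- sz + 1L
          stack[[length(stack) + 1L]] <- c(nx, ny, nz)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  list(lab = lab, n = ncomp, sizes = sizes)
}

oracle_center <- function(d) floor(d / 2) + 1

oracle_mean_dist <- function(vals, vs) {
  d <- dim(vals)
  ci <- oracle_center(d)
  tot <- 0; n <- 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1]))
    if (vals[x, y, z] == 1) {
      tot <- tot + sqrt(((x - ci[1]) * vs[1])^2 + ((y - ci[2]) * vs[2])^2 +
                        ((z - ci[3]) * vs[3])^2)
      n <- n + 1
    }
  tot / n
}

oracle_cube <- function(vals, vs, side_mm = 10) {
  d <- dim(vals)
  ci <- oracle_center(d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1]))
    if (vals[x, y, z] == 1 &&
        abs((x - ci[1]) * vs[1]) <= side_mm / 2 &&
        abs((y - ci[2]) * vs[2]) <= side_mm / 2 &&
        abs((z - ci[3]) * vs[3]) <= side_mm / 2) return(1L)
  0L
}

oracle_axis_dist <- function(vals, vs) {
  cc <- oracle_components(vals, 18)
  d <- dim(vals)
  ci <- oracle_center(d)
  best <- Inf
  for (k in seq_len(cc$n)) {
    sx <- 0; sy <- 0; n <- 0
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1]))
      if (cc$lab[x, y, z] == k) { sx <- sx + x; sy <- sy + y; n <- n + 1 }
    dist <- sqrt(((sx / n - ci[1]) * vs[1])^2 + ((sy / n - ci[2]) * vs[2])^2)
    best <- min(best, dist)
  }
  best
}

oracle_profile <- function(vals) {
  sizes <- oracle_components(vals, 18)$sizes
  c(sum(sizes <= 15), sum(sizes >= 16 & sizes <= 36), sum(sizes >= 37))
}

# sparse random binary mask; caller controls the RNG state
random_mask <- function(dims, p = 0.08, voxel_mm = c(1, 1, 1)) {
  v <- array(rbinom(prod(dims), 1L, p), dims)
  if (!any(v == 1)) v[ceiling(dims[1] / 2), 1, 1] <- 1L
  voxel_grid(v, voxel_mm)
}

# KKT optimality certificate of the soft-margin dual: returns the largest
# violation of the complementarity conditions at the fitted (alpha, b).
kkt_violation <- function(K, y, alpha, b, C) {
  f <- as.vector(K %*% (alpha * y)) + b
  m <- y * f
  viol <- 0
  for (i in seq_along(y)) {
    if (alpha[i] < 1e-8)          viol <- max(viol, 1 - m[i])   # want m >= 1
    else if (alpha[i] > C - 1e-8) viol <- max(viol, m[i] - 1)   # want m <= 1
    else                          viol <- max(viol, abs(m[i] - 1))
  }
  max(viol, abs(sum(alpha * y)))
}

make_cohort <- function(X, y, ...) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  cohort_matrix(sprintf("p%03d", seq_len(nrow(X))), X, y, ...)
}
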