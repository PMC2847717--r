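#' Otsu threshold of an intensity sample
#'
#' Inter-class-variance-maximizing global threshold computed on a 256-level
#' histogram of the supplied intensities (the histogram may be restricted to a
#' region, e.g. pixels inside the nucleus).
#'
#' @param values Numeric vector/array of intensities; must not be constant.
#' @return Threshold on the original intensity scale; foreground is
#'   `intensity > threshold`.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) {
    stop_rf("no_nucleus", "cannot threshold a constant image")
  }
  vn <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(matrix(vn, ncol = 1L), range = c(0, 1), levels = 256L)
  rng[1] + thr * diff(rng)
}

# connected-component labeling; 2D via EBImage, 3D via per-slice labeling
# merged across slices with union-find (26-connectivity)
label_components <- function(mask) {
  if (length(dim(mask)) == 2L) {
    return(EBImage::bwlabel(mask * 1))
  }
  label_components_3d(mask)
}

label_components_3d <- function(mask) {
  # crop to the foreground bounding box; labeling cost then scales with the
  # object, not the field of view
  full <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(array(0L, full))
  lo <- apply(idx, 2L, min); hi <- apply(idx, 2L, max)
  sub <- mask[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  out <- array(0L, full)
  out[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- label_components_3d_core(sub)
  out
}

label_components_3d_core <- function(mask) {
  dm <- dim(mask)
  nz <- dm[3L]
  labs <- array(0L, dm)
  offset <- 0L
  for (z in seq_len(nz)) {
    sl <- EBImage::bwlabel(mask[, , z] * 1)
    mx <- as.integer(max(sl))
    pos <- sl > 0
    sl[pos] <- sl[pos] + offset
    labs[, , z] <- sl
    offset <- offset + mx
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  ny <- dm[1L]; nx <- dm[2L]
  key_base <- offset + 1L
  for (z in seq_len(nz - 1L)) {
    a <- labs[, , z]; b <- labs[, , z + 1L]
    if (max(a) == 0L || max(b) == 0L) next
    for (dy in -1:1) for (dx in -1:1) {
      ya <- max(1, 1 + dy):min(ny, ny + dy); xa <- max(1, 1 + dx):min(nx, nx + dx)
      yb <- ya - dy; xb <- xa - dx
      pa <- a[ya, xa]; pb <- b[yb, xb]
      both <- pa > 0 & pb > 0
      if (any(both)) {
        keys <- unique(as.numeric(pa[both]) * key_base + as.numeric(pb[both]))
        for (k in keys) union_(k %/% key_base, k %% key_base)
      }
    }
  }
  roots <- vapply(seq_len(offset), find, numeric(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- labs > 0
  labs[pos] <- relab[labs[pos]]
  labs
}

# component sizes with the deterministic tie-break: larger first, ties broken
# by the smaller first linear index in scan order
ranked_components <- function(labs) {
  idx <- which(labs > 0)
  if (length(idx) == 0L) return(NULL)
  lab <- labs[idx]
  size <- tabulate(lab)
  first <- vapply(split(idx, lab), min, numeric(1))
  ord <- order(-size, first)
  list(labels = as.integer(names(first))[ord], sizes = size[ord])
}

#' Segment the nucleus from a DAPI channel
#'
#' Thresholds the DAPI image with an automatic global (Otsu) threshold, fills
#' holes, and keeps the largest connected component. The resulting binary mask
#' defines the nucleus for all downstream shell and distance measurements.
#'
#' @param dapi 2D matrix or 3D array of DAPI intensities.
#' @param spacing Pixel size in μm: a scalar for 2D images, or a length-3
#'   vector `c(y, x, z)` of voxel spacings for stacks.
#' @param min_area Minimum nucleus size, in μm² (2D) or μm³ (3D). Defaults to
#'   20 μm² / 100 μm³; smaller components are treated as debris.
#'
#' @return A logical mask congruent with `dapi` containing exactly one
#'   connected foreground component.
#' @export
segment_nucleus <- function(dapi, spacing = 0.1, min_area = NULL) {
  nd <- length(dim(dapi))
  stopifnot(nd %in% c(2L, 3L), all(spacing > 0))
  if (nd == 3L && length(spacing) == 1L) spacing <- rep(spacing, 3L)
  unit <- prod(spacing[seq_len(min(length(spacing), nd))])
  if (is.null(min_area)) min_area <- if (nd == 2L) 20 else 100
  if (max(dapi) <= min(dapi)) {
    stop_rf("no_nucleus", "DAPI image is constant; no nucleus found")
  }
  thr <- otsu_threshold(dapi)
  mask <- dapi > thr
  mask <- EBImage::fillHull(mask * 1) > 0   # framewise hole filling for stacks
  labs <- label_components(mask)
  comp <- ranked_components(labs)
  if (is.null(comp) || comp$sizes[1L] * unit < min_area) {
    stop_rf("no_nucleus", sprintf(
      "no connected component of at least %g (physical units) found", min_area))
  }
  labs == comp$labels[1L]
}

#' Segment chromosome territories within the nucleus
#'
#' Thresholds the probe channel with an Otsu threshold computed only from
#' pixels inside the nucleus mask, labels connected components of the
#' suprathreshold in-nucleus pixels, and returns the `expected_count` largest.
#'
#' @param probe Probe-channel image, congruent with `nucleus`.
#' @param nucleus Logical nucleus mask from [segment_nucleus()].
#' @param expected_count Number of territories expected (1 for chromosome X in
#'   male cells, 2 for autosomes).
#'
#' @return A list of `expected_count` logical masks, each a subset of
#'   `nucleus`, ordered largest first.
#' @export
segment_territories <- function(probe, nucleus, expected_count = 1L) {
  stopifnot(identical(dim(probe), dim(nucleus)), expected_count %in% c(1L, 2L))
  inside <- probe[nucleus]
  if (length(inside) == 0L || max(inside) <= min(inside)) {
    stop_rf("territory_count", "no probe signal variation inside the nucleus")
  }
  thr <- otsu_threshold(inside)
  mask <- (probe > thr) & nucleus
  comp <- ranked_components(label_components(mask))
  if (is.null(comp) || length(comp$labels) < expected_count) {
    stop_rf("territory_count", sprintf(
      "found %d territory component(s), expected %d",
      if (is.null(comp)) 0L else length(comp$labels), expected_count))
  }
  labs <- label_components(mask)
  lapply(comp$labels[seq_len(expected_count)], function(l) labs == l)
}

#' Nuclear morphometrics from a binary mask
#'
#' Area and ellipse-equivalent axis lengths of a nucleus mask. Axes derive
#' from the second central moments of the foreground pixel coordinates: the
#' full axis length is `4 * sqrt(eigenvalue)` of the coordinate covariance,
#' which is exact for a solid ellipse. For a 3D mask the measurements are
#' taken on the largest-area z-slice (the in-plane ellipse vocabulary of
#' flattened fibroblast nuclei).
#'
#' @param nucleus Logical mask (2D or 3D).
#' @param spacing Pixel size in μm (scalar, 2D) or voxel spacing `c(y, x, z)`.
#'
#' @return A one-row tibble: `area` (μm²), `major_axis` (μm), `minor_axis`
#'   (μm), `aspect_ratio`.
#' @export
measure_morphometrics <- function(nucleus, spacing = 0.1) {
  nd <- length(dim(nucleus))
  if (nd == 3L) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    slice_areas <- apply(nucleus, 3L, sum)
    nucleus <- nucleus[, , which.max(slice_areas)]
    spacing <- spacing[1:2]
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  idx <- which(nucleus, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_rf("empty_mask", "mask has no foreground pixels")
  coords <- cbind(idx[, 1L] * spacing[1L], idx[, 2L] * spacing[2L])
  n <- nrow(coords)
  area <- n * prod(spacing)
  if (n == 1L) {
    axes <- c(0, 0)
  } else {
    cv <- stats::cov(coords) * (n - 1) / n
    axes <- 4 * sqrt(pmax(sort(eigen(cv, symmetric = TRUE)$values, decreasing = TRUE), 0))
  }
  tibble(
    area = area,
    major_axis = axes[1L],
    minor_axis = axes[2L],
    aspect_ratio = if (axes[2L] > 0) axes[1L] / axes[2L] else NA_real_
  )
}

#' Compare nuclear morphometrics between two groups
#'
#' Welch's unequal-variance two-tailed t-test per measure (area, major axis,
#' minor axis, aspect ratio), as used to check that nuclear shape and size do
#' not differ between conditions.
#'
#' @param group_a,group_b Tibbles of per-nucleus morphometrics, one row per
#'   nucleus (from [measure_morphometrics()], row-bound).
#' @param alpha Significance level.
#'
#' @return A tibble with one row per measure: `measure`, `t_stat`, `df`,
#'   `p_value`, `significant`.
#' @export
compare_morphometrics <- function(group_a, group_b, alpha = 0.05) {
  measures <- c("area", "major_axis", "minor_axis", "aspect_ratio")
  if (nrow(group_a) < 2L || nrow(group_b) < 2L) {
    stop_rf("sample_size", "each group needs at least 2 nuclei")
  }
  purrr::map_dfr(measures, function(m) {
    welch_row(group_a[[m]], group_b[[m]], alpha) |>
      dplyr::mutate(measure = m, .before = 1L)
  })
}

# single Welch test returned as a one-row tibble; identical samples get the
# degenerate p = 1 rather than an error
welch_row <- function(x, y, alpha = 0.05) {
  if (isTRUE(all.equal(sd(x), 0)) && isTRUE(all.equal(sd(y), 0)) &&
      isTRUE(all.equal(mean(x), mean(y)))) {
    return(tibble(t_stat = 0, df = NA_real_, p_value = 1, significant = FALSE))
  }
  ht <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  tibble(
    t_stat = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    significant = ht$p.value < alpha
  )
}
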