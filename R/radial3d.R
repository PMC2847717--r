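#' Geometric center of a territory mask
#'
#' Unweighted mean of the physical coordinates of the foreground voxel
#' centers. The voxel at (1-based) index `i` along an axis has physical
#' coordinate `(i - 1) * spacing` along that axis.
#'
#' @param territory Logical 3D mask.
#' @param spacing Voxel spacing in μm, `c(y, x, z)`.
#'
#' @return Named numeric vector `c(y, x, z)` in μm.
#' @export
territory_centroid <- function(territory, spacing = c(0.15, 0.15, 0.2)) {
  stopifnot(length(dim(territory)) == 3L, length(spacing) == 3L, all(spacing > 0))
  idx <- which(territory, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_rf("empty_mask", "territory mask is empty")
  setNames(colMeans((idx - 1) %*% diag(spacing)), c("y", "x", "z"))
}

# periphery voxels: foreground with a background 6-neighbor or on the border
periphery_voxels <- function(nucleus) {
  dm <- dim(nucleus)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- nucleus
  core <- function(dy, dx, dz) {
    pad[2:(dm[1] + 1L) + dy, 2:(dm[2] + 1L) + dx, 2:(dm[3] + 1L) + dz]
  }
  interior <- nucleus &
    core(-1, 0, 0) & core(1, 0, 0) &
    core(0, -1, 0) & core(0, 1, 0) &
    core(0, 0, -1) & core(0, 0, 1)
  nucleus & !interior
}

#' Distance from a point to the nearest nuclear periphery
#'
#' The periphery is the set of nucleus voxels having at least one background
#' 6-neighbor (voxels on the grid border count as peripheral). The returned
#' value is the minimum anisotropic Euclidean distance from the point to a
#' periphery voxel center, so it matches an exhaustive search exactly. The
#' discretization error against the continuum surface is about half a voxel
#' on average but can reach one full voxel dimension in the worst case,
#' because the minimum favors periphery voxels whose outward neighbor only
#' just crosses the boundary.
#'
#' @param point Physical coordinates `c(y, x, z)` in μm, inside the nucleus.
#' @param nucleus Logical 3D nucleus mask.
#' @param spacing Voxel spacing in μm, `c(y, x, z)`.
#'
#' @return Distance in μm.
#' @export
distance_to_periphery <- function(point, nucleus, spacing = c(0.15, 0.15, 0.2)) {
  stopifnot(length(point) == 3L, length(dim(nucleus)) == 3L,
            length(spacing) == 3L, all(spacing > 0))
  vox <- round(point / spacing) + 1
  if (any(vox < 1) || any(vox > dim(nucleus)) ||
      !nucleus[vox[1L], vox[2L], vox[3L]]) {
    stop_rf("point_outside", "point does not lie inside the nucleus mask")
  }
  per <- which(periphery_voxels(nucleus), arr.ind = TRUE)
  coords <- (per - 1) %*% diag(spacing)
  sqrt(min(colSums((t(coords) - as.numeric(point))^2)))
}

#' Normalize a periphery distance by nuclear axis length
#'
#' @param d Distance in μm (>= 0).
#' @param major_axis,minor_axis Nuclear axis lengths in μm.
#' @param mode `"avg_axes"` divides by `(major + minor) / 2`; `"major_axis"`
#'   divides by the major axis alone.
#'
#' @return Dimensionless normalized distance.
#' @export
normalize_distance <- function(d, major_axis, minor_axis = NULL,
                               mode = c("avg_axes", "major_axis")) {
  mode <- match.arg(mode)
  if (any(d < 0)) stop_rf("value", "distances must be non-negative")
  if (any(major_axis <= 0) || (mode == "avg_axes" && any(minor_axis <= 0))) {
    stop_rf("value", "axis lengths must be positive")
  }
  switch(mode,
    avg_axes = d / ((major_axis + minor_axis) / 2),
    major_axis = d / major_axis
  )
}

#' Frequency distribution of periphery distances
#'
#' Half-open bins `[k * w, (k + 1) * w)` starting at 0.
#'
#' @param distances Numeric vector of distances (μm), non-empty.
#' @param bin_width Bin width in μm (default 0.5).
#'
#' @return An object of class `frequency_distribution`: tibble with
#'   `bin_start`, `bin_end`, `count`; attribute `n` is the total count.
#' @export
frequency_distribution <- function(distances, bin_width = 0.5) {
  if (length(distances) == 0L) stop_rf("empty_input", "no distances supplied")
  stopifnot(bin_width > 0, all(distances >= 0))
  bin <- floor(distances / bin_width)
  nb <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = nb)
  out <- tibble(
    bin_start = (seq_len(nb) - 1L) * bin_width,
    bin_end = seq_len(nb) * bin_width,
    count = counts
  )
  structure(out, n = length(distances),
            class = c("frequency_distribution", class(out)))
}

#' Check that cohort ordering is invariant to distance normalization
#'
#' Orders the cohorts by median distance under (i) raw μm, (ii) distances
#' normalized per nucleus by the average of major and minor axis, and (iii)
#' by the major axis alone, and reports whether the three orderings agree —
#' the robustness property that relative chromosome positions do not depend
#' on the normalization chosen.
#'
#' @param measurements A tibble with columns `cohort`, `distance_um`,
#'   `major_axis`, `minor_axis` (axes of the nucleus each distance was
#'   measured in).
#'
#' @return `TRUE` if the median ordering is identical under all three
#'   scalings (vacuously `TRUE` for a single cohort).
#' @export
rank_invariance_check <- function(measurements) {
  need <- c("cohort", "distance_um", "major_axis", "minor_axis")
  stopifnot(all(need %in% names(measurements)))
  med <- measurements |>
    dplyr::mutate(
      norm_avg = normalize_distance(.data$distance_um, .data$major_axis,
                                    .data$minor_axis, mode = "avg_axes"),
      norm_major = normalize_distance(.data$distance_um, .data$major_axis,
                                      mode = "major_axis")
    ) |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      raw = median(.data$distance_um),
      avg = median(.data$norm_avg),
      major = median(.data$norm_major),
      .groups = "drop"
    )
  identical(order(med$raw), order(med$avg)) &&
    identical(order(med$raw), order(med$major))
}
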