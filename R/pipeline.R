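#' Erosion analysis of a single 2D nucleus
#'
#' Runs the full 2D measurement for one two-channel image: segment the nucleus
#' from DAPI, partition it into equal-area shells, and measure the per-shell
#' raw and DAPI-normalized probe proportions.
#'
#' @param dapi,probe 2D intensity matrices (same shape).
#' @param pixel_size Pixel size, μm.
#' @param n_shells Number of shells (default 5).
#' @param min_area Minimum nucleus area, μm² (default 20).
#'
#' @return A tibble as [measure_shell_profile()].
#' @export
analyze_nucleus_2d <- function(dapi, probe, pixel_size = 0.2, n_shells = 5L,
                               min_area = 20) {
  nucleus <- segment_nucleus(dapi, spacing = pixel_size, min_area = min_area)
  part <- compute_shell_partition(nucleus, n_shells = n_shells)
  measure_shell_profile(part, dapi, probe)
}

#' Erosion analysis of a cohort of 2D nuclei
#'
#' Accepts either a [generate_cohort()] object or the path to a manifest CSV
#' with columns `nucleus_id`, `dapi`, `probe` (TIFF paths). Results do not
#' depend on the listing order of the nuclei.
#'
#' @param x A 2D `sim_cohort` or a manifest CSV path.
#' @param condition Condition label for the resulting cohort profile.
#' @param pixel_size,n_shells,min_area Passed to [analyze_nucleus_2d()].
#'
#' @return A [cohort_profile()] retaining per-nucleus normalized and raw DAPI
#'   values.
#' @export
analyze_cohort_2d <- function(x, condition, pixel_size = 0.2, n_shells = 5L,
                              min_area = 20) {
  if (inherits(x, "sim_cohort")) {
    stopifnot(x$spec$kind == "2d")
    pixel_size <- x$spec$pixel_size
    profiles <- purrr::imap(x$nuclei, function(nuc, i) {
      analyze_nucleus_2d(nuc$dapi, nuc$probe, pixel_size, n_shells, min_area) |>
        dplyr::mutate(nucleus_id = i - 1L, .before = 1L)
    })
  } else {
    manifest <- read_results(x)
    stopifnot(all(c("nucleus_id", "dapi", "probe") %in% names(manifest)))
    profiles <- purrr::pmap(
      manifest[c("nucleus_id", "dapi", "probe")],
      function(nucleus_id, dapi, probe) {
        analyze_nucleus_2d(read_image(dapi, "2d"), read_image(probe, "2d"),
                           pixel_size, n_shells, min_area) |>
          dplyr::mutate(nucleus_id = nucleus_id, .before = 1L)
      })
  }
  cohort_profile(dplyr::bind_rows(profiles), condition)
}

#' @rdname cohort_profile
#' @param profiles,condition As [cohort_profile()].
#' @export
aggregate_cohort <- function(profiles, condition) {
  cohort_profile(profiles, condition)
}

#' 3D center-to-periphery measurement of one nucleus stack
#'
#' Segments the nucleus and its territories from a two-channel confocal
#' stack, then measures, for each territory, the anisotropic Euclidean
#' distance from its geometric center to the nearest nuclear periphery, plus
#' the axis-normalized variants (nuclear axes taken on the largest-area
#' z-slice of the nucleus mask).
#'
#' @param dapi,probe 3D intensity arrays `[y, x, z]` (same shape).
#' @param spacing Voxel spacing `c(y, x, z)`, μm.
#' @param expected_count Territories expected (1 or 2).
#' @param min_volume Minimum nucleus volume, μm³ (default 100).
#'
#' @return A tibble with one row per territory: `territory_id`, centroid
#'   `y/x/z` (μm), `distance_um`, `norm_avg_axes`, `norm_major_axis`,
#'   `major_axis`, `minor_axis`.
#' @export
analyze_stack_3d <- function(dapi, probe, spacing = c(0.15, 0.15, 0.2),
                             expected_count = 1L, min_volume = 100) {
  nucleus <- segment_nucleus(dapi, spacing = spacing, min_area = min_volume)
  morpho <- measure_morphometrics(nucleus, spacing = spacing)
  terrs <- segment_territories(probe, nucleus, expected_count)
  purrr::imap_dfr(terrs, function(tm, i) {
    ctr <- territory_centroid(tm, spacing)
    d <- distance_to_periphery(ctr, nucleus, spacing)
    tibble(
      territory_id = i,
      y = ctr[["y"]], x = ctr[["x"]], z = ctr[["z"]],
      distance_um = d,
      norm_avg_axes = normalize_distance(d, morpho$major_axis,
                                         morpho$minor_axis, "avg_axes"),
      norm_major_axis = normalize_distance(d, morpho$major_axis,
                                           mode = "major_axis"),
      major_axis = morpho$major_axis,
      minor_axis = morpho$minor_axis
    )
  })
}

#' 3D measurement over a cohort of stacks
#'
#' @param x A 3D `sim_cohort`.
#' @param condition Condition/chromosome label attached to every row.
#' @param expected_count,min_volume Passed to [analyze_stack_3d()].
#'
#' @return A tibble with one row per territory per nucleus, including
#'   `condition` and `nucleus_id`.
#' @export
analyze_cohort_3d <- function(x, condition, expected_count = 1L,
                              min_volume = 100) {
  stopifnot(inherits(x, "sim_cohort"), x$spec$kind == "3d")
  purrr::imap_dfr(x$nuclei, function(nuc, i) {
    analyze_stack_3d(nuc$dapi, nuc$probe, x$spec$spacing,
                     expected_count, min_volume) |>
      dplyr::mutate(condition = condition, nucleus_id = i - 1L, .before = 1L)
  })
}
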