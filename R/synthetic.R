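#' Specification for synthetic nucleus images
#'
#' Parameters of the seeded generator that emulates two-channel FISH imaging
#' of flattened fibroblast nuclei: an elliptical (2D) or flattened ellipsoidal
#' (3D) nucleus filled with DAPI counterstain, and one or two chromosome
#' territories rendered as Gaussian blobs placed at a controlled radial
#' fraction between the nucleus center (`radial_fraction = 0`) and the
#' boundary (`radial_fraction = 1`) along a random direction. The fraction is
#' expressed in the equal-area metric the erosion analysis itself uses: the
#' territory center lies on the homothetic contour enclosing `radial_fraction`
#' of the nuclear area (2D) or volume (3D), so the expected shell index of a
#' point territory is linear in the fraction.
#'
#' Defaults mirror the study-scale conditions: cohorts of 60 nuclei in 2D
#' (50-70 per chromosome is typical) and 20 in 3D; 0.2 μm optical-section
#' spacing in z; nucleus semi-axes 10 × 6.5 μm (and 2 μm axially in 3D), with
#' per-nucleus log-normal axis jitter and a uniformly random in-plane
#' orientation.
#'
#' @param kind `"2d"` or `"3d"`.
#' @param semi_axes Nucleus semi-axes in μm: `c(major, minor)` in-plane, plus
#'   an axial semi-axis for 3D.
#' @param pixel_size In-plane pixel size in μm (2D).
#' @param spacing Voxel spacing `c(y, x, z)` in μm (3D).
#' @param radial_fraction Territory position in `[0, 1]`: the area/volume
#'   quantile of the homothetic contour the center is placed on (0 = nucleus
#'   center, 1 = boundary), along a uniformly random direction.
#' @param territory_sigma Gaussian sd of the territory blob, μm.
#' @param n_territories 1 or 2.
#' @param dapi_level Mean DAPI intensity inside the nucleus.
#' @param probe_peak Peak probe intensity at the blob center.
#' @param noise_sd Additive Gaussian noise sd on both channels (clipped at 0).
#' @param dapi_gradient Fractional center-to-edge DAPI attenuation in
#'   `[0, 1)`; 0 keeps DAPI uniform inside the nucleus.
#' @param axis_jitter_sd Log-scale sd of per-nucleus axis jitter.
#' @param n_nuclei Cohort size.
#' @param seed Master seed; nucleus `i` uses substream `seed + i`, so cohorts
#'   are order-independent and reproducible.
#'
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(kind = c("2d", "3d"),
                     semi_axes = NULL,
                     pixel_size = 0.2,
                     spacing = c(0.15, 0.15, 0.2),
                     radial_fraction = 0.5,
                     territory_sigma = 1.0,
                     n_territories = 1L,
                     dapi_level = 100,
                     probe_peak = 150,
                     noise_sd = 5,
                     dapi_gradient = 0,
                     axis_jitter_sd = 0.05,
                     n_nuclei = NULL,
                     seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(semi_axes)) {
    semi_axes <- if (kind == "2d") c(10, 6.5) else c(10, 6.5, 2)
  }
  if (is.null(n_nuclei)) n_nuclei <- if (kind == "2d") 60L else 20L
  stopifnot(
    length(semi_axes) == if (kind == "2d") 2L else 3L,
    all(semi_axes > 0), pixel_size > 0, all(spacing > 0),
    radial_fraction >= 0, radial_fraction <= 1,
    territory_sigma > 0, n_territories %in% c(1L, 2L),
    dapi_level > 0, probe_peak > 0, noise_sd >= 0,
    dapi_gradient >= 0, dapi_gradient < 1,
    n_nuclei >= 1L, seed == round(seed)
  )
  structure(
    list(kind = kind, semi_axes = semi_axes, pixel_size = pixel_size,
         spacing = spacing, radial_fraction = radial_fraction,
         territory_sigma = territory_sigma,
         n_territories = as.integer(n_territories),
         dapi_level = dapi_level, probe_peak = probe_peak,
         noise_sd = noise_sd, dapi_gradient = dapi_gradient,
         axis_jitter_sd = axis_jitter_sd,
         n_nuclei = as.integer(n_nuclei), seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec %s: n=%d, r=%.2f, seed=%d>\n",
              x$kind, x$n_nuclei, x$radial_fraction, x$seed))
  invisible(x)
}

clip_round <- function(x) pmin(round(pmax(x, 0)), 65535)

# radial fraction -> blob center offset (μm) for an axis-aligned ellipse/
# ellipsoid; u is a unit direction in the nucleus frame. r is an area (2D) /
# volume (3D) quantile: the center lies on the homothetic contour enclosing
# fraction r of the nucleus, so r maps linearly onto equal-area shell depth
# (ray fraction sqrt(r) in 2D, r^(1/3) in 3D; 0 = center, 1 = boundary).
ray_offset <- function(r, u, axes) {
  rho <- r^(1 / length(axes))
  t_boundary <- 1 / sqrt(sum((u / axes)^2))
  rho * t_boundary * u
}

#' Generate one synthetic 2D nucleus
#'
#' Deterministic given `(spec$seed, index)`. The DAPI channel is the nucleus
#' ellipse at `dapi_level` (optionally attenuated radially) plus clipped
#' Gaussian noise; the probe channel holds one Gaussian blob per territory,
#' centered at `radial_fraction` of the way from the nucleus center to the
#' boundary along a uniformly random direction.
#'
#' @param spec A 2D [sim_spec()].
#' @param index Nucleus index (0-based substream offset).
#'
#' @return List with integer matrices `dapi` and `probe` and a `truth` tibble
#'   (territory centers in μm, radial fraction, true axes in μm).
#' @export
generate_nucleus_2d <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "sim_spec"), spec$kind == "2d")
  withr::with_seed(spec$seed + index, {
    a <- spec$semi_axes[1L] * exp(rnorm(1, 0, spec$axis_jitter_sd))
    b <- spec$semi_axes[2L] * exp(rnorm(1, 0, spec$axis_jitter_sd))
    phi <- runif(1, 0, pi)
    half_um <- max(spec$semi_axes) * 1.3
    n_px <- 2L * ceiling(half_um / spec$pixel_size) + 1L
    ctr <- (n_px - 1) / 2 * spec$pixel_size
    yy <- ((seq_len(n_px) - 1) * spec$pixel_size) - ctr
    xx <- yy
    # nucleus-frame coordinates of every pixel
    Y <- matrix(yy, n_px, n_px)
    X <- matrix(xx, n_px, n_px, byrow = TRUE)
    Yr <- cos(phi) * Y + sin(phi) * X
    Xr <- -sin(phi) * Y + cos(phi) * X
    rho2 <- (Yr / a)^2 + (Xr / b)^2
    inside <- rho2 <= 1
    dapi <- ifelse(inside, spec$dapi_level * (1 - spec$dapi_gradient * rho2), 0)
    probe <- matrix(0, n_px, n_px)
    truth <- vector("list", spec$n_territories)
    for (t_id in seq_len(spec$n_territories)) {
      theta <- runif(1, 0, 2 * pi)
      u <- c(cos(theta), sin(theta))                    # nucleus frame (y', x')
      off <- ray_offset(spec$radial_fraction, u, c(a, b))
      # rotate back to lab frame
      cy <- cos(phi) * off[1L] - sin(phi) * off[2L]
      cx <- sin(phi) * off[1L] + cos(phi) * off[2L]
      if (sum((off / c(a, b))^2) > 1 + 1e-9) {
        stop_rf("generation", "territory center falls outside the nucleus")
      }
      d2 <- (Y - cy)^2 + (X - cx)^2
      probe <- probe + spec$probe_peak * exp(-d2 / (2 * spec$territory_sigma^2))
      truth[[t_id]] <- tibble(
        nucleus_id = index, territory_id = t_id,
        center_y_um = cy + ctr, center_x_um = cx + ctr,
        radial_fraction = spec$radial_fraction,
        major_axis = 2 * a, minor_axis = 2 * b, orientation = phi
      )
    }
    if (spec$noise_sd > 0) {
      dapi <- dapi + rnorm(length(dapi), 0, spec$noise_sd)
      probe <- probe + rnorm(length(probe), 0, spec$noise_sd)
    }
    list(dapi = clip_round(dapi), probe = clip_round(probe),
         truth = dplyr::bind_rows(truth))
  })
}

#' Generate one synthetic 3D confocal stack
#'
#' Flattened ellipsoidal nucleus with anisotropic voxels; territories are
#' isotropic 3D Gaussian blobs at the requested radial fraction along a
#' uniformly random 3D direction. Deterministic given `(spec$seed, index)`.
#'
#' @param spec A 3D [sim_spec()].
#' @param index Nucleus index.
#'
#' @return List with integer arrays `dapi` and `probe` (`[y, x, z]`) and a
#'   `truth` tibble (centers in μm, radial fraction, true in-plane axes).
#' @export
generate_stack_3d <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "sim_spec"), spec$kind == "3d")
  withr::with_seed(spec$seed + index, {
    ax <- spec$semi_axes * exp(rnorm(3, 0, spec$axis_jitter_sd))  # (a, b, c_z)
    margin <- 1.25
    dims <- c(
      2L * ceiling(ax[1L] * margin / spec$spacing[1L]) + 1L,
      2L * ceiling(ax[1L] * margin / spec$spacing[2L]) + 1L,
      2L * ceiling(ax[3L] * margin * 1.4 / spec$spacing[3L]) + 1L
    )
    ctr <- (dims - 1) / 2 * spec$spacing
    yy <- (seq_len(dims[1L]) - 1) * spec$spacing[1L] - ctr[1L]
    xx <- (seq_len(dims[2L]) - 1) * spec$spacing[2L] - ctr[2L]
    zz <- (seq_len(dims[3L]) - 1) * spec$spacing[3L] - ctr[3L]
    phi <- runif(1, 0, pi)
    Y <- array(yy, dims)
    X <- aperm(array(xx, dims[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
    Z <- aperm(array(zz, dims[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
    Yr <- cos(phi) * Y + sin(phi) * X
    Xr <- -sin(phi) * Y + cos(phi) * X
    rho2 <- (Yr / ax[1L])^2 + (Xr / ax[2L])^2 + (Z / ax[3L])^2
    dapi <- spec$dapi_level * (1 - spec$dapi_gradient * rho2)
    dapi[rho2 > 1] <- 0
    probe <- array(0, dims)
    truth <- vector("list", spec$n_territories)
    for (t_id in seq_len(spec$n_territories)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))           # nucleus frame (y', x', z)
      off <- ray_offset(spec$radial_fraction, u, ax)
      cy <- cos(phi) * off[1L] - sin(phi) * off[2L]
      cx <- sin(phi) * off[1L] + cos(phi) * off[2L]
      cz <- off[3L]
      if (sum((off / ax)^2) > 1 + 1e-9) {
        stop_rf("generation", "territory center falls outside the nucleus")
      }
      # blob support is negligible beyond 4 sigma; render only that box
      reach <- 4 * spec$territory_sigma
      iy <- which(abs(yy - cy) <= reach)
      ix <- which(abs(xx - cx) <= reach)
      iz <- which(abs(zz - cz) <= reach)
      d2 <- outer(outer((yy[iy] - cy)^2, (xx[ix] - cx)^2, `+`), (zz[iz] - cz)^2, `+`)
      probe[iy, ix, iz] <- probe[iy, ix, iz] +
        spec$probe_peak * exp(-d2 / (2 * spec$territory_sigma^2))
      truth[[t_id]] <- tibble(
        nucleus_id = index, territory_id = t_id,
        center_y_um = cy + ctr[1L], center_x_um = cx + ctr[2L],
        center_z_um = cz + ctr[3L],
        radial_fraction = spec$radial_fraction,
        major_axis = 2 * ax[1L], minor_axis = 2 * ax[2L],
        axial_axis = 2 * ax[3L], orientation = phi
      )
    }
    if (spec$noise_sd > 0) {
      dapi <- dapi + rnorm(length(dapi), 0, spec$noise_sd)
      probe <- probe + rnorm(length(probe), 0, spec$noise_sd)
    }
    list(dapi = clip_round(dapi), probe = clip_round(probe),
         truth = dplyr::bind_rows(truth))
  })
}

#' Generate a seeded cohort of synthetic nuclei
#'
#' @param spec A [sim_spec()].
#'
#' @return An object of class `sim_cohort`: list with `spec`, `nuclei` (list
#'   of per-nucleus `dapi`/`probe`/`truth`), and `truth` (row-bound ground
#'   truth for all nuclei).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  gen <- if (spec$kind == "2d") generate_nucleus_2d else generate_stack_3d
  nuclei <- lapply(seq_len(spec$n_nuclei) - 1L, function(i) gen(spec, i))
  structure(
    list(spec = spec, nuclei = nuclei,
         truth = dplyr::bind_rows(lapply(nuclei, `[[`, "truth"))),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort %s: %d nuclei, r=%.2f, seed=%d>\n",
              x$spec$kind, x$spec$n_nuclei, x$spec$radial_fraction, x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk as TIFFs with a manifest
#'
#' Emits `nucleus_<i>_dapi.tif` / `nucleus_<i>_probe.tif` per nucleus plus
#' `manifest.csv` (nucleus_id, dapi, probe paths) and `truth.csv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::imap(cohort$nuclei, function(nuc, i) {
    id <- i - 1L
    dp <- file.path(dir, sprintf("nucleus_%03d_dapi.tif", id))
    pp <- file.path(dir, sprintf("nucleus_%03d_probe.tif", id))
    write_image(nuc$dapi, dp)
    write_image(nuc$probe, pp)
    tibble(nucleus_id = id, dapi = dp, probe = pp)
  })
  write_results(dplyr::bind_rows(rows), file.path(dir, "manifest.csv"))
  write_results(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
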