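test_that("disk shells reproduce the analytic equal-area annulus radii", {
  R <- 50
  mask <- disk_mask(R)
  part <- compute_shell_partition(mask)
  expect_identical(sort(unique(as.vector(part$labels[mask]))), 1:5)

  n <- nrow(mask); c0 <- (n + 1) / 2
  rho <- sqrt((row(mask) - c0)^2 + (col(mask) - c0)^2)
  # inner radius of shell k estimates the analytic cut R * sqrt(1 - k/5)
  for (k in 1:4) {
    inner <- min(rho[part$labels == k])
    expect_lt(abs(inner - R * sqrt(1 - k / 5)), 1)
  }
})

test_that("shells tile the nucleus with equal areas up to tie granularity", {
  withr::with_seed(11, {
    for (i in 1:8) {
      mask <- ellipse_mask(runif(1, 35, 60), runif(1, 25, 35), runif(1, 0, pi))
      part <- compute_shell_partition(mask)
      # union of shells is the mask, shells disjoint by construction of labels
      expect_identical(part$labels > 0, mask)
      expect_identical(sum(part$areas), sum(mask))
      tol <- max(0.02 * sum(mask) / 5, max_tie_group(mask))
      expect_true(all(abs(part$areas - sum(mask) / 5) <= tol))
    }
  })
})

test_that("masks too small to erode are refused", {
  tiny <- matrix(FALSE, 10, 10); tiny[4:5, 4:5] <- TRUE
  expect_error(compute_shell_partition(tiny), class = "radialfish_error_mask_too_small")
})

test_that("profile percentages conserve signal and self-normalize", {
  mask <- ellipse_mask(45, 30, 0.3)
  part <- compute_shell_partition(mask)
  dapi <- mask * 80 + 1  # nonzero background is ignored by the partition
  for (c_scale in c(0.5, 1, 3)) {
    prof <- measure_shell_profile(part, dapi, dapi * c_scale)
    expect_equal(sum(prof$raw_probe_pct), 100, tolerance = 1e-6)
    expect_equal(sum(prof$raw_dapi_pct), 100, tolerance = 1e-6)
    expect_equal(prof$normalized, rep(1, 5), tolerance = 1e-9)
  }
})

test_that("probe confined to shell 1 yields the analytic enrichment", {
  mask <- disk_mask(50)
  part <- compute_shell_partition(mask)
  dapi <- mask * 100
  probe <- matrix(0, nrow(mask), ncol(mask))
  probe[part$labels == 1] <- 60
  prof <- measure_shell_profile(part, dapi, probe)
  expect_equal(prof$raw_probe_pct, c(100, 0, 0, 0, 0))
  # normalized shell 1 = 100 / dapi% in shell 1, computed from actual areas
  dapi_pct1 <- 100 * part$areas[1] / sum(part$areas)
  expect_equal(prof$normalized[1], 100 / dapi_pct1)
})

test_that("degenerate channels raise classed errors", {
  mask <- disk_mask(30)
  part <- compute_shell_partition(mask)
  expect_error(measure_shell_profile(part, mask * 10, mask * 0),
               class = "radialfish_error_zero_signal")
  dapi_hole <- mask * 10
  dapi_hole[part$labels == 3] <- 0
  expect_error(measure_shell_profile(part, dapi_hole, mask * 10),
               class = "radialfish_error_degenerate_dapi")
})

test_that("profiles are exactly invariant under 90-degree rotation", {
  spec <- sim_spec("2d", radial_fraction = 0.75, n_nuclei = 1, seed = 21)
  nuc <- generate_nucleus_2d(spec, 0)
  rot <- function(m) t(m)[ncol(m):1, ]
  before <- analyze_nucleus_2d(nuc$dapi, nuc$probe, spec$pixel_size)
  after <- analyze_nucleus_2d(rot(nuc$dapi), rot(nuc$probe), spec$pixel_size)
  expect_equal(after$normalized, before$normalized, tolerance = 1e-12)
  expect_equal(after$raw_dapi_pct, before$raw_dapi_pct, tolerance = 1e-12)
})

test_that("cohort aggregation computes SEM with the n-1 denominator", {
  one <- tibble::tibble(nucleus_id = 1L, shell = 1:5,
                        normalized = c(2, 1, 1, 0.5, 0.5),
                        raw_dapi_pct = rep(20, 5))
  trio <- dplyr::bind_rows(one, dplyr::mutate(one, nucleus_id = 2L),
                           dplyr::mutate(one, nucleus_id = 3L))
  cp <- aggregate_cohort(trio, "flat")
  expect_equal(tidy(cp)$mean, one$normalized)
  expect_equal(tidy(cp)$sem, rep(0, 5))

  a <- 1.4; b <- 0.6
  pair <- dplyr::bind_rows(
    dplyr::mutate(one, normalized = replace(normalized, shell == 1, a)),
    dplyr::mutate(one, nucleus_id = 2L,
                  normalized = replace(normalized, shell == 1, b)))
  cp2 <- aggregate_cohort(pair, "pair")
  expect_equal(tidy(cp2)$sem[1], abs(a - b) / 2)

  expect_error(aggregate_cohort(one, "solo"), class = "radialfish_error_sample_size")
})

test_that("a full synthetic cohort records its size and five shells", {
  spec <- sim_spec("2d", radial_fraction = 0.85, n_nuclei = 10, seed = 31)
  cp <- analyze_cohort_2d(generate_cohort(spec), "peripheral")
  expect_identical(cp$n, 10L)
  expect_identical(nrow(tidy(cp)), 5L)
})

test_that("shell-1 signal rises and shell-5 falls as territories move outward", {
  rs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  means <- vapply(seq_along(rs), function(i) {
    spec <- sim_spec("2d", radial_fraction = rs[i], n_nuclei = 25,
                     seed = 400 + i)
    m <- tidy(analyze_cohort_2d(generate_cohort(spec), "c"))$mean
    c(m[1], m[5])
  }, numeric(2))
  expect_true(all(diff(means[1, ]) > 0))  # shell 1 strictly increasing in r
  # endpoint displacement: periphery (0.9) vs interior (0.1)
  expect_lt(means[1, 1], means[1, 5])
  expect_gt(means[2, 1], means[2, 5])
})
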