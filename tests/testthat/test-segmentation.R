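test_that("nucleus segmentation recovers a clean ellipse exactly", {
  mask <- ellipse_mask(40, 25, phi = 0.4)
  img <- mask * 100
  got <- segment_nucleus(img, spacing = 0.2)
  expect_identical(got, mask)
})

test_that("degenerate DAPI images raise NoNucleusFound-class errors", {
  expect_error(segment_nucleus(matrix(0, 32, 32)), class = "radialfish_error_no_nucleus")
  expect_error(segment_nucleus(matrix(7, 32, 32)), class = "radialfish_error_no_nucleus")
  # bright but tiny object: below min_area
  tiny <- matrix(0, 32, 32); tiny[16, 16] <- 200
  expect_error(segment_nucleus(tiny, spacing = 0.2, min_area = 20),
               class = "radialfish_error_no_nucleus")
})

test_that("only the largest connected component is kept", {
  img <- matrix(0, 140, 260)
  big <- disk_mask(25)    # ~1963 px
  small <- disk_mask(12)  # ~452 px
  img[40 + seq_len(nrow(big)), 10 + seq_len(ncol(big))] <- big * 100
  img[40 + seq_len(nrow(small)), 180 + seq_len(ncol(small))] <- small * 100
  got <- segment_nucleus(img, spacing = 0.2)
  expect_identical(sum(got), sum(big))
  expect_lt(max(which(got, arr.ind = TRUE)[, 2]), 100)  # the big (left) disk
})

test_that("segmentation is idempotent on its own mask", {
  spec <- sim_spec("2d", radial_fraction = 0.5, n_nuclei = 1, seed = 2)
  nuc <- generate_nucleus_2d(spec, 0)
  m1 <- segment_nucleus(nuc$dapi, spacing = spec$pixel_size)
  m2 <- segment_nucleus(m1 * 255, spacing = spec$pixel_size)
  expect_identical(m2, m1)
})

test_that("territory segmentation finds the expected number of blobs", {
  spec <- sim_spec("2d", radial_fraction = 0.6, n_nuclei = 1, seed = 8,
                   noise_sd = 0)
  nuc <- generate_nucleus_2d(spec, 0)
  nucleus <- segment_nucleus(nuc$dapi, spacing = spec$pixel_size)
  terr <- segment_territories(nuc$probe, nucleus, 1L)
  expect_length(terr, 1L)
  # the blob's peak pixel is inside the returned mask
  expect_true(terr[[1]][which.max(nuc$probe * nucleus)])
  # masks are subsets of the nucleus
  expect_true(all(nucleus[terr[[1]]]))
  expect_error(segment_territories(nuc$probe, nucleus, 2L),
               class = "radialfish_error_territory_count")

  spec2 <- sim_spec("2d", radial_fraction = 0.6, n_territories = 2L,
                    n_nuclei = 1, seed = 8, noise_sd = 0)
  nuc2 <- generate_nucleus_2d(spec2, 0)
  nucleus2 <- segment_nucleus(nuc2$dapi, spacing = spec2$pixel_size)
  terr2 <- segment_territories(nuc2$probe, nucleus2, 2L)
  expect_length(terr2, 2L)
  expect_identical(sum(terr2[[1]] & terr2[[2]]), 0L)
})

test_that("moment-based axes match known disk and ellipse geometry", {
  m <- measure_morphometrics(disk_mask(50), spacing = 0.1)
  expect_equal(m$major_axis, 10, tolerance = 0.02)
  expect_equal(m$minor_axis, 10, tolerance = 0.02)

  e <- measure_morphometrics(ellipse_mask(60, 30), spacing = 0.1)
  expect_equal(e$aspect_ratio, 2.0, tolerance = 0.02)
  expect_equal(e$major_axis, 12, tolerance = 0.02)

  hundred <- matrix(FALSE, 20, 20); hundred[1:10, 1:10] <- TRUE
  expect_equal(measure_morphometrics(hundred, spacing = 0.2)$area, 4.0)

  expect_error(measure_morphometrics(matrix(FALSE, 5, 5)),
               class = "radialfish_error_empty_mask")
})

test_that("morphometric axes are invariant to 90-degree rotation", {
  mask <- ellipse_mask(45, 28, phi = 0.7)
  a <- measure_morphometrics(mask, spacing = 0.1)
  b <- measure_morphometrics(t(mask)[ncol(mask):1, ], spacing = 0.1)
  expect_equal(b$major_axis, a$major_axis, tolerance = 0.02)
  expect_equal(b$minor_axis, a$minor_axis, tolerance = 0.02)
})

test_that("morphometric comparison behaves under null and alternative", {
  base <- tibble::tibble(area = rep(200, 10), major_axis = 20,
                         minor_axis = 13, aspect_ratio = 20 / 13)
  same <- compare_morphometrics(base, base)
  expect_true(all(same$p_value == 1))
  expect_true(!any(same$significant))
  expect_error(compare_morphometrics(base[1, ], base),
               class = "radialfish_error_sample_size")

  withr::with_seed(99, {
    a <- tibble::tibble(area = rnorm(20, 200, 5), major_axis = rnorm(20, 20, 0.5),
                        minor_axis = rnorm(20, 13, 0.5))
    a$aspect_ratio <- a$major_axis / a$minor_axis
    b <- dplyr::mutate(a, area = area * 2)
    res <- compare_morphometrics(a, b)
    expect_true(res$significant[res$measure == "area"])
    expect_false(res$significant[res$measure == "aspect_ratio"])
  })
})

test_that("same-distribution morphometrics are flagged at about the alpha rate", {
  hits <- withr::with_seed(123, {
    replicate(200, {
      a <- tibble::tibble(area = rnorm(15, 200, 20), major_axis = rnorm(15, 20, 1),
                          minor_axis = rnorm(15, 13, 1))
      a$aspect_ratio <- a$major_axis / a$minor_axis
      b <- tibble::tibble(area = rnorm(15, 200, 20), major_axis = rnorm(15, 20, 1),
                          minor_axis = rnorm(15, 13, 1))
      b$aspect_ratio <- b$major_axis / b$minor_axis
      compare_morphometrics(a, b)$significant
    })
  })
  rates <- rowMeans(hits)  # one rate per measure over 200 replicates
  ci_hi <- qbinom(0.975, 200, 0.05) / 200
  expect_true(all(rates <= ci_hi))
})
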