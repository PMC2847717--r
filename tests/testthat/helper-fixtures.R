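# geometric fixtures built in code, plus independent oracles

# solid disk mask of radius R px, centered in a (2R + 2*pad + 1)^2 grid
disk_mask <- function(R, pad = 3L) {
  n <- 2L * (R + pad) + 1L
  c0 <- R + pad + 1L
  y <- matrix(seq_len(n) - c0, n, n)
  x <- t(y)
  y^2 + x^2 <= R^2
}

# solid ellipse mask, semi-axes (a, b) px, rotated by phi
ellipse_mask <- function(a, b, phi = 0, pad = 3L) {
  n <- 2L * (ceiling(max(a, b)) + pad) + 1L
  c0 <- (n + 1L) / 2
  y <- matrix(seq_len(n) - c0, n, n)
  x <- t(y)
  yr <- cos(phi) * y + sin(phi) * x
  xr <- -sin(phi) * y + cos(phi) * x
  (yr / a)^2 + (xr / b)^2 <= 1
}

# digitized sphere/ellipsoid: voxel centers at (i-1)*spacing, center given in μm
ellipsoid_mask <- function(semi_axes, spacing, center) {
  dims <- ceiling(2 * (semi_axes + 1) / spacing)
  yy <- (seq_len(dims[1]) - 1) * spacing[1] - center[1]
  xx <- (seq_len(dims[2]) - 1) * spacing[2] - center[2]
  zz <- (seq_len(dims[3]) - 1) * spacing[3] - center[3]
  r2 <- outer(outer((yy / semi_axes[1])^2, (xx / semi_axes[2])^2, `+`),
              (zz / semi_axes[3])^2, `+`)
  r2 <= 1
}

# random lumpy 3D mask: union of a few random ellipsoids around a base one
random_blob_mask <- function(seed, dims = c(14L, 13L, 9L)) {
  withr::with_seed(seed, {
    mask <- array(FALSE, dims)
    ctr <- dims / 2
    n_lumps <- sample(2:4, 1)
    centers <- rbind(ctr, ctr + matrix(rnorm(3 * n_lumps, 0, 2), ncol = 3))
    for (i in seq_len(nrow(centers))) {
      ax <- runif(3, 2, 4.5)
      idx <- which(array(TRUE, dims), arr.ind = TRUE)
      r2 <- ((idx[, 1] - centers[i, 1]) / ax[1])^2 +
            ((idx[, 2] - centers[i, 2]) / ax[2])^2 +
            ((idx[, 3] - centers[i, 3]) / ax[3])^2
      mask[idx[r2 <= 1, , drop = FALSE]] <- TRUE
    }
    mask
  })
}

# independent brute-force oracle for the periphery distance: explicit loops,
# no shared code with the package implementation
brute_force_periphery_distance <- function(point, mask, spacing) {
  dm <- dim(mask)
  best <- Inf
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!mask[i, j, k]) next
    on_border <- i == 1 || i == dm[1] || j == 1 || j == dm[2] ||
      k == 1 || k == dm[3]
    has_bg <- on_border ||
      !mask[i - 1, j, k] || !mask[i + 1, j, k] ||
      !mask[i, j - 1, k] || !mask[i, j + 1, k] ||
      !mask[i, j, k - 1] || !mask[i, j, k + 1]
    if (!has_bg) next
    v <- c(i - 1, j - 1, k - 1) * spacing
    d <- sqrt(sum((v - point)^2))
    if (d < best) best <- d
  }
  best
}

# textbook Welch t statistic / Welch-Satterthwaite df / two-sided p
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# render a logical mask as a two-channel image pair with uniform DAPI
mask_as_channels <- function(mask, level = 100) {
  list(dapi = mask * level, probe = mask * level)
}

# largest tie-group size in the distance transform of a mask (the partition's
# granularity bound), computed independently of the partition code
max_tie_group <- function(mask) {
  padded <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  dm <- EBImage::distmap(padded)[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  max(table(dm[mask]))
}
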