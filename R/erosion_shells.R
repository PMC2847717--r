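#' Partition a nucleus into concentric equal-area shells
#'
#' The erosion-analysis geometry: the Euclidean distance transform of the
#' nucleus mask (distance of every nucleus pixel to the nearest background
#' pixel) is cut at its area quantiles, producing `n_shells` nested shells of
#' equal pixel count. Shell 1 is the most peripheral, shell `n_shells` the
#' most interior. Pixels sharing a distance value that straddles a cut are
#' assigned as a block to the shell holding the majority of the tie group
#' (lower shell on a split vote), which makes the partition deterministic.
#'
#' @param nucleus Logical 2D nucleus mask.
#' @param n_shells Number of shells (default 5, the convention used for all
#'   reported profiles).
#'
#' @return An object of class `shell_partition`: list with `labels` (integer
#'   matrix, 0 background, 1..n_shells inside), `n_shells`, and `areas`
#'   (pixel count per shell).
#' @export
compute_shell_partition <- function(nucleus, n_shells = 5L) {
  stopifnot(length(dim(nucleus)) == 2L, n_shells >= 2L)
  n_shells <- as.integer(n_shells)
  fg <- which(nucleus)
  npx <- length(fg)
  if (npx < 20L * n_shells) {
    stop_rf("mask_too_small", sprintf(
      "nucleus has %d pixels; need at least %d for %d shells",
      npx, 20L * n_shells, n_shells))
  }
  # EBImage::distmap does not treat the array border as background: pad first
  padded <- matrix(0, nrow(nucleus) + 2L, ncol(nucleus) + 2L)
  padded[2:(nrow(nucleus) + 1L), 2:(ncol(nucleus) + 1L)] <- nucleus
  dm <- EBImage::distmap(padded)[2:(nrow(nucleus) + 1L), 2:(ncol(nucleus) + 1L)]
  d <- dm[fg]
  ord <- order(d)
  prelim <- as.integer(floor((seq_len(npx) - 1L) * n_shells / npx)) + 1L
  # tie-group majority rule: only groups of equal distance that straddle a
  # quantile cut need reassigning (at most n_shells - 1 of them)
  runs <- rle(d[ord])
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (g in which(prelim[starts] != prelim[ends])) {
    grp <- starts[g]:ends[g]
    prelim[grp] <- which.max(tabulate(prelim[grp], nbins = n_shells))
  }
  shell <- integer(npx)
  shell[ord] <- prelim
  labels <- matrix(0L, nrow(nucleus), ncol(nucleus))
  labels[fg] <- shell
  structure(
    list(labels = labels, n_shells = n_shells,
         areas = tabulate(shell, nbins = n_shells)),
    class = "shell_partition"
  )
}

#' @export
print.shell_partition <- function(x, ...) {
  cat(sprintf("<shell_partition: %d shells, %d px nucleus>\n",
              x$n_shells, sum(x$areas)))
  cat("areas:", paste(x$areas, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy shell_partition
#' @export
tidy.shell_partition <- function(x, ...) {
  tibble(shell = seq_len(x$n_shells), area_px = x$areas)
}

#' Per-shell signal proportions for one nucleus
#'
#' Sums the pixel intensity of the DAPI and probe channels over each shell and
#' expresses them as percentages of the in-nucleus total; the normalized value
#' is the probe percentage divided by the DAPI percentage in the same shell.
#' Values above 1 mean the probe is enriched in that shell relative to DNA.
#'
#' @param partition A [compute_shell_partition()] result.
#' @param dapi,probe Intensity images congruent with the partition.
#'
#' @return A tibble with one row per shell: `shell`, `raw_probe_pct`,
#'   `raw_dapi_pct` (each summing to 100), `normalized`.
#' @export
measure_shell_profile <- function(partition, dapi, probe) {
  stopifnot(inherits(partition, "shell_partition"),
            identical(dim(dapi), dim(partition$labels)),
            identical(dim(probe), dim(partition$labels)))
  lab <- partition$labels
  inside <- lab > 0L
  f <- factor(lab[inside], levels = seq_len(partition$n_shells))
  probe_sum <- tapply(probe[inside], f, sum, default = 0)
  dapi_sum <- tapply(dapi[inside], f, sum, default = 0)
  if (sum(probe_sum) <= 0) {
    stop_rf("zero_signal", "no probe signal inside the nucleus")
  }
  if (any(dapi_sum <= 0)) {
    stop_rf("degenerate_dapi", "a shell has zero total DAPI signal")
  }
  raw_probe <- 100 * as.numeric(probe_sum) / sum(probe_sum)
  raw_dapi <- 100 * as.numeric(dapi_sum) / sum(dapi_sum)
  tibble(
    shell = seq_len(partition$n_shells),
    raw_probe_pct = raw_probe,
    raw_dapi_pct = raw_dapi,
    normalized = raw_probe / raw_dapi
  )
}

#' Aggregate per-nucleus shell profiles into a cohort profile
#'
#' @param profiles A tibble of per-nucleus profiles: columns `nucleus_id`,
#'   `shell`, `normalized`, and (optionally, for the DAPI control)
#'   `raw_dapi_pct`. Typically built by row-binding [measure_shell_profile()]
#'   results with a `nucleus_id` column added.
#' @param condition Condition label for the cohort (non-empty string).
#'
#' @return An object of class `cohort_profile` retaining the per-nucleus data;
#'   [tidy()] gives the per-shell mean ± SEM, [glance()] the cohort summary
#'   including its radial position call.
#' @export
cohort_profile <- function(profiles, condition) {
  stopifnot(is.character(condition), nzchar(condition))
  need <- c("nucleus_id", "shell", "normalized")
  if (!all(need %in% names(profiles))) {
    stop_rf("value", paste0("profiles must have columns: ", paste(need, collapse = ", ")))
  }
  n <- dplyr::n_distinct(profiles$nucleus_id)
  if (n < 2L) stop_rf("sample_size", "a cohort needs at least 2 nuclei")
  n_shells <- dplyr::n_distinct(profiles$shell)
  counts <- dplyr::count(profiles, .data$nucleus_id)
  if (any(counts$n != n_shells)) {
    stop_rf("value", "every nucleus must contribute one row per shell")
  }
  structure(
    list(condition = condition, n = n, n_shells = n_shells,
         data = as_tibble(profiles)),
    class = "cohort_profile"
  )
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("<cohort_profile '%s': %d nuclei, %d shells>\n",
              x$condition, x$n, x$n_shells))
  print(tidy(x))
  invisible(x)
}

#' @describeIn cohort_profile Per-shell mean and standard error of the mean of
#'   the normalized signal across nuclei (sample sd, n - 1 denominator).
#' @param x A `cohort_profile`.
#' @param ... Unused.
#' @method tidy cohort_profile
#' @export
tidy.cohort_profile <- function(x, ...) {
  x$data |>
    dplyr::group_by(.data$shell) |>
    dplyr::summarise(
      mean = mean(.data$normalized),
      sem = sd(.data$normalized) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(condition = x$condition, .before = 1L)
}

#' @describeIn cohort_profile One-row summary: condition, n, center-of-mass
#'   index and radial position call.
#' @method glance cohort_profile
#' @export
glance.cohort_profile <- function(x, ...) {
  pos <- classify_position(x)
  tibble(condition = x$condition, n = x$n, n_shells = x$n_shells,
         com_index = pos$com_index, position = pos$position)
}
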