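# Volumetric features: whole-volume and per-class 100-bin histograms plus
# the gray/white contrast t-score. High-contrast volumes show separated
# gray- and white-matter profiles; artifacts blur them together.

#' 100-bin histogram container
#'
#' Bin n covers the half-open interval ((n-1) * delta, n * delta], with the
#' first bin's lower edge closed so that exact zeros are counted and the
#' counts always sum to the voxel total.
#'
#' @param counts integer vector of length 100.
#' @param bin_width bin width delta (intensity or probability units).
#' @param domain_max upper end of the binned domain (`I_max` or 1).
#' @return An object of class `histogram100`.
#' @export
histogram100 <- function(counts, bin_width, domain_max) {
  if (length(counts) != 100L || any(counts < 0))
    stop_t1qc("counts must be 100 non-negative integers", "histogram")
  structure(list(counts = as.integer(counts), bin_width = bin_width,
                 domain_max = domain_max), class = "histogram100")
}

#' @export
print.histogram100 <- function(x, ...) {
  cat(sprintf("<histogram100> %d voxels over [0, %g], bin width %g\n",
              sum(x$counts), x$domain_max, x$bin_width))
  invisible(x)
}

# Shared binning: values into 100 bins over [0, domain_max] with the edge
# convention above. `edges` must have length 101 starting at 0.
.bin100 <- function(v, edges) {
  idx <- findInterval(v, edges, left.open = TRUE)
  idx[idx < 1L] <- 1L     # closed lower edge: exact zeros land in bin 1
  idx[idx > 100L] <- 100L
  tabulate(idx, nbins = 100L)
}

#' Whole-volume intensity histogram (VF1)
#'
#' Divides the observed intensity range `[0, I_max]` into 100 equal bins
#' and counts voxels per bin. All voxels are counted, including background
#' air, so the counts sum to the voxel total.
#'
#' @param vol [volume_grid()] or 3D array with at least one positive voxel.
#' @return A [histogram100()] with `domain_max = I_max`.
#' @export
#' @examples
#' v <- array(runif(8^3), dim = c(8, 8, 8))
#' sum(vf1_histogram(v)$counts) == length(v)
vf1_histogram <- function(vol) {
  v <- as.vector(vg_data(vol))
  imax <- max(v)
  if (imax <= 0)
    stop_t1qc("all-zero volume: intensity histogram undefined",
              "degenerate_input")
  edges <- imax * (0:100) / 100
  histogram100(.bin100(v, edges), bin_width = imax / 100, domain_max = imax)
}

#' Tissue-probability histogram (VF2)
#'
#' As [vf1_histogram()] but over the fixed probability domain \[0, 1\]
#' (100 bins of width 0.01), regardless of the observed maximum. Computed
#' per class (GM, WM, CSF) by the caller.
#'
#' @param map [volume_grid()] or 3D array with values in \[0, 1\].
#' @return A [histogram100()] with `domain_max = 1`.
#' @export
vf2_class_histogram <- function(map) {
  v <- as.vector(vg_data(map))
  if (any(v < 0) || any(v > 1))
    stop_t1qc("probability map values must lie in [0, 1]", "map_range")
  edges <- (0:100) / 100
  histogram100(.bin100(v, edges), bin_width = 0.01, domain_max = 1)
}

#' Gray/white contrast t-score (VF3)
#'
#' Thresholds the gray- and white-matter probability maps at 0.5 into
#' binary masks, multiplies them into the intensity volume and contrasts
#' the two masked intensity distributions:
#' `gw_t_score = (mu_WM - mu_GM) / sqrt(var_GM + var_WM)`.
#'
#' Two estimation modes are provided. `"intensity"` (default) takes the
#' mean and variance of the masked non-zero voxel intensities, the reading
#' under which the score measures tissue contrast. `"literal"` computes
#' mean and variance over the 100 histogram bin counts of each masked
#' intensity histogram (population variance over bins); under this reading
#' the mean difference reduces to a voxel-count difference and is
#' independent of contrast, so the mode exists to make that discrepancy
#' explicit and testable.
#'
#' @param vol [volume_grid()] or 3D array.
#' @param maps a [tissue_map_set()] with `gm` and `wm` maps.
#' @param mode `"intensity"` or `"literal"`.
#' @return An object of class `contrast_stats` with fields `mu_gm`,
#'   `mu_wm`, `var_gm`, `var_wm`, `x1` and `gw_t_score`.
#' @export
gw_t_score <- function(vol, maps, mode = c("intensity", "literal")) {
  mode <- match.arg(mode)
  v <- vg_data(vol)
  stats_for <- function(class) {
    m <- maps[[class]] >= 0.5
    if (!any(m))
      stop_t1qc(sprintf("empty %s mask at threshold 0.5", toupper(class)),
                "empty_mask")
    vals <- v[m]
    vals <- vals[vals > 0]        # zeros are mask artifacts, not tissue
    if (length(vals) < 2L)
      stop_t1qc(sprintf("fewer than two non-zero %s voxels", toupper(class)),
                "empty_mask")
    if (mode == "intensity") {
      c(mu = mean(vals), v = stats::var(vals))
    } else {
      counts <- vf1_histogram(array(vals, dim = c(length(vals), 1, 1)))$counts
      mu <- mean(counts)
      c(mu = mu, v = mean((counts - mu)^2))
    }
  }
  g <- stats_for("gm"); w <- stats_for("wm")
  denom <- sqrt(g[["v"]] + w[["v"]])
  if (denom == 0)
    stop_t1qc("zero pooled variance: contrast score undefined",
              "zero_variance")
  x1 <- w[["mu"]] - g[["mu"]]
  structure(list(mu_gm = g[["mu"]], mu_wm = w[["mu"]],
                 var_gm = g[["v"]], var_wm = w[["v"]],
                 x1 = x1, gw_t_score = x1 / denom, mode = mode),
            class = "contrast_stats")
}

#' @export
print.contrast_stats <- function(x, ...) {
  cat(sprintf(
    "<contrast_stats> (%s mode) mu_GM = %.4g, mu_WM = %.4g, gw_t_score = %.4g\n",
    x$mode, x$mu_gm, x$mu_wm, x$gw_t_score))
  invisible(x)
}
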