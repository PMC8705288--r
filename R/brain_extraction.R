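#' Otsu threshold of an intensity histogram
#'
#' Selects the threshold maximizing the between-class variance
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2} over all candidate thresholds, where the
#' background class collects the histogram levels at or below the threshold
#' and the foreground class the levels strictly above it. Ties are broken
#' toward the smallest threshold. Candidate thresholds are the histogram
#' levels themselves (the largest level can never be a valid threshold under
#' the strict-greater foreground convention).
#'
#' @param values Numeric vector of histogram levels (bin values), strictly
#'   increasing or in any order (sorted internally).
#' @param counts Non-negative counts per level, same length as `values`.
#' @return The selected threshold, one of `values`; foreground voxels are
#'   those with intensity strictly greater than it.
#' @export
#' @examples
#' otsu_threshold(c(0, 10), c(50, 50))   # -> 0: split 0 | 10
otsu_threshold <- function(values, counts) {
  if (length(values) != length(counts) || length(values) < 1L) {
    stop("ostvol_histogram_error: values and counts must be equal-length, non-empty",
         call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("ostvol_histogram_error: negative counts", call. = FALSE)
  }
  keep <- counts > 0
  values <- values[keep]; counts <- counts[keep]
  if (length(values) < 2L) {
    stop("ostvol_degenerate_histogram: need at least two populated levels",
         call. = FALSE)
  }
  o <- order(values)
  values <- values[o]; counts <- as.numeric(counts[o])
  n <- sum(counts)
  # cumulative weight and mean below-or-equal each candidate level
  cw <- cumsum(counts)
  cm <- cumsum(counts * values)
  total_mean <- cm[length(cm)] / n
  k <- length(values) - 1L           # last level cannot be a threshold
  w0 <- cw[seq_len(k)] / n
  mu0 <- cm[seq_len(k)] / cw[seq_len(k)]
  w1 <- 1 - w0
  mu1 <- (total_mean - w0 * mu0) / w1
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  # smallest threshold among (numerically) tied maxima
  values[min(which(sigma_b >= max(sigma_b) * (1 - 1e-9)))]
}

#' Histogram of an intensity grid
#'
#' Builds the fixed-bin histogram the brain-extraction step thresholds:
#' `n_bins` equal-width bins spanning the observed intensity range, every
#' voxel included (zero background voxels form their own class in BraTS-style
#' data). Bin levels are bin midpoints.
#'
#' @param intensity Numeric array.
#' @param n_bins Number of bins (default 256).
#' @return List with `values` (bin midpoints), `counts`, and `breaks`.
#' @export
intensity_histogram <- function(intensity, n_bins = 256L) {
  v <- as.vector(intensity)
  if (anyNA(v)) stop("ostvol_histogram_error: NA intensities", call. = FALSE)
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    return(list(values = rng[1L], counts = length(v), breaks = rng))
  }
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  list(values = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
       counts = counts, breaks = breaks)
}

#' Extract the brain mask of a labeled volume
#'
#' Applies Otsu thresholding to the volume's intensity grid and takes as
#' brain every voxel strictly brighter than the threshold, unioned with all
#' tumor-labeled voxels (labels 1, 2, 4): necrotic cores can fall below the
#' global threshold, and the whole tumor must by construction lie inside the
#' brain region whose voxel count defines the Vb feature.
#'
#' @param volume A [labeled_volume] with an intensity grid.
#' @param n_bins Histogram bins for the Otsu step (default 256).
#' @return List of class `brain_mask`: `mask` (logical 3D array),
#'   `voxel_count`, and `threshold` (intensity scale).
#' @export
brain_mask <- function(volume, n_bins = 256L) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (is.null(volume$intensity)) {
    stop("ostvol_missing_intensity: volume carries no intensity grid",
         call. = FALSE)
  }
  h <- intensity_histogram(volume$intensity, n_bins)
  thr <- otsu_threshold(h$values, h$counts)
  mask <- volume$intensity > thr | volume$labels != 0L
  structure(list(mask = mask, voxel_count = sum(mask), threshold = thr),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("Brain mask: %d voxels above threshold %.4g (union with tumor labels)\n",
              x$voxel_count, x$threshold))
  invisible(x)
}
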