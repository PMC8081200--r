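# Slot 1 (image smoothing) and slot 2 (contrast enhancement) of the workflow.

#' Gaussian low-pass smoothing
#'
#' Linear shift-invariant smoothing with a normalized 2D Gaussian kernel on a
#' 5x5 support, the classic first step for suppressing high-frequency speckle
#' before binarisation.
#'
#' @param img numeric intensity matrix in \[0, 1\].
#' @param sigma kernel standard deviation in pixels (> 0); default 1.5.
#' @return smoothed matrix of the same shape, values in \[0, 1\].
#' @export
gaussian_smooth <- function(img, sigma = 1.5) {
  stopifnot(is.matrix(img), sigma > 0)
  k <- gaussian_kernel(sigma, half = 2L)
  out <- EBImage::filter2(img, k, boundary = "replicate")
  pmin(pmax(as.matrix(out), 0), 1)
}

# normalized 2D Gaussian on a (2*half+1)^2 support
gaussian_kernel <- function(sigma, half = 2L) {
  d <- (-half):half
  g <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Fit k-means contrast-stretch thresholds
#'
#' Clusters pixel intensities into three classes (background, weak signal,
#' strong signal) with 1D k-means, then derives the low and high stretch
#' thresholds from the intensity histogram: `th_low` is the smallest intensity
#' above the class-1 centroid at which the 256-bin histogram first drops below
#' half its value at that centroid; `th_high` is the symmetric rule below the
#' class-3 centroid. Centroids are initialised at the 10th/50th/90th intensity
#' percentiles so the fit is deterministic.
#'
#' @param img intensity matrix in \[0, 1\] with at least `k` distinct values.
#' @param k number of intensity classes (default 3).
#' @param max_points at most this many pixels (regularly subsampled) enter the
#'   k-means iterations; the histogram rules always use the full image.
#' @return a `contrast_thresholds` list with fields `th_low`, `th_high`, `mu`
#'   (sorted centroids).
#' @export
fit_contrast_thresholds <- function(img, k = 3L, max_points = 50000L) {
  stopifnot(is.matrix(img))
  v <- as.vector(img)
  init <- unique(stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE))
  if (length(unique(round(v, 6))) < k || length(init) < k)
    stop("contrast slot: image has fewer than ", k, " distinct intensities")
  if (length(v) > max_points) {
    idx <- round(seq(1L, length(v), length.out = max_points))
    vv <- v[idx]
  } else vv <- v
  km <- stats::kmeans(vv, centers = matrix(init, ncol = 1), iter.max = 50L)
  mu <- sort(km$centers[, 1])
  h <- intensity_histogram(v)
  centers <- (seq_len(256L) - 0.5) / 256
  b1 <- bin_of(mu[1]); b3 <- bin_of(mu[k])
  th_low <- threshold_half_drop(h, centers, from = b1, direction = 1L)
  th_high <- threshold_half_drop(h, centers, from = b3, direction = -1L)
  if (is.na(th_low)) th_low <- (mu[1] + mu[2]) / 2
  if (is.na(th_high)) th_high <- (mu[k - 1] + mu[k]) / 2
  if (th_low >= th_high) {
    th_low <- (mu[1] + mu[2]) / 2
    th_high <- (mu[k - 1] + mu[k]) / 2
  }
  if (th_low >= th_high)
    stop("contrast slot: degenerate thresholds (th_low >= th_high)")
  structure(list(th_low = th_low, th_high = th_high, mu = mu),
            class = "contrast_thresholds")
}

intensity_histogram <- function(v) {
  tabulate(bin_of(v), nbins = 256L)
}

bin_of <- function(x) pmin(pmax(floor(x * 256) + 1L, 1L), 256L)

# first bin past `from` (walking in `direction`) whose count drops below half
# the count at `from`; returns the bin-centre intensity or NA
threshold_half_drop <- function(h, centers, from, direction) {
  target <- h[from] / 2
  if (from + direction < 1L || from + direction > 256L) return(NA_real_)
  idx <- if (direction > 0) seq(from + 1L, 256L) else seq(from - 1L, 1L)
  hit <- idx[which(h[idx] < target)[1]]
  if (is.na(hit)) NA_real_ else centers[hit]
}

#' Contrast stretch between two thresholds
#'
#' Maps intensities below `th_low` to 0, above `th_high` to 1, and linearly in
#' between: `g(s) = (s - th_low) / (th_high - th_low)`. Monotone
#' non-decreasing and continuous at both knees.
#'
#' @param img intensity matrix.
#' @param th a `contrast_thresholds` object from [fit_contrast_thresholds()].
#' @return stretched matrix in \[0, 1\].
#' @export
contrast_stretch <- function(img, th) {
  stopifnot(inherits(th, "contrast_thresholds"), th$th_low < th$th_high)
  out <- (img - th$th_low) / (th$th_high - th$th_low)
  pmin(pmax(out, 0), 1)
}

#' Intensity adjustment by morphological top-hat
#'
#' Subtracts a grayscale opening with a disk structuring element from the
#' image (white top-hat). The opening captures the slowly varying background,
#' so the subtraction keeps structures smaller than the disk while removing
#' uneven illumination; the result is invariant to a constant offset.
#'
#' @param img intensity matrix in \[0, 1\].
#' @param disk_radius structuring-element radius in pixels (>= 1), default 5.
#' @return adjusted matrix in \[0, 1\].
#' @export
intensity_adjust <- function(img, disk_radius = 5L) {
  stopifnot(is.matrix(img), disk_radius >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(disk_radius) + 1L, shape = "disc")
  opened <- as.matrix(EBImage::opening(img, brush))
  pmin(pmax(img - opened, 0), 1)
}
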