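# Slot-3 options: the seven binarisation methods. Foreground convention is
# signal = TRUE = white everywhere.

#' Construct a binary mask
#'
#' @param bits logical matrix, same shape as the source strip.
#' @param baseline_row inherited zero-velocity row index.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(bits, baseline_row) {
  stopifnot(is.matrix(bits))
  storage.mode(bits) <- "logical"
  structure(list(bits = bits, baseline_row = as.integer(baseline_row)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px (%.1f%%), baseline %d\n",
              nrow(x$bits), ncol(x$bits), sum(x$bits),
              100 * mean(x$bits), x$baseline_row))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$bits)

# shift a matrix by (dr, dc) with replicated borders
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Non-linear Laplace (NLLAP) response
#'
#' For every pixel, `grandmax` is the largest and `grandmin` the smallest of
#' the four intensity differences between the 4-neighbours and the centre;
#' the response is their sum. Border pixels use replicated edges. The response
#' is positive on the dark side of an edge, negative on the bright side, and
#' zero in flat regions, with a zero-crossing at the boundary.
#'
#' @param img intensity matrix.
#' @return signed response matrix of the same shape.
#' @export
nllap_response <- function(img) {
  d <- nllap_diffs(img)
  d$gmax + d$gmin
}

nllap_diffs <- function(img) {
  up    <- shift_replicate(img, -1L, 0L) - img
  down  <- shift_replicate(img,  1L, 0L) - img
  left  <- shift_replicate(img, 0L, -1L) - img
  right <- shift_replicate(img, 0L,  1L) - img
  list(gmax = pmax(up, down, left, right),
       gmin = pmin(up, down, left, right))
}

#' NLLAP configuration
#'
#' Holds the edge-strength thresholds `l1 > l2 > 0` and the background
#' statistics thresholds used by the adaptive rule of [binarize_nllap()]. All
#' constants were described only as "empirically determined" in the source
#' methods, so by default they are derived from the image itself:
#' `n_samples` probe patches of `patch_size` pixels are placed along the
#' baseline; `m_th` is the 25th percentile of the patch means, `sigma_th` the
#' 75th percentile of the patch standard deviations, and `l2`/`l1` sit at 25%
#' and 50% of the observed edge-strength range.
#'
#' @param l1,l2 edge-strength thresholds (`l1 > l2 > 0`), or `NA` to derive.
#' @param m_th,sigma_th background mean / sd thresholds, or `NA` to derive.
#' @param n_samples number of probe patches (default 10).
#' @param patch_size probe patch side in pixels (default 8).
#' @return an `nllap_config` list.
#' @export
nllap_config <- function(l1 = NA_real_, l2 = NA_real_, m_th = NA_real_,
                         sigma_th = NA_real_, n_samples = 10L,
                         patch_size = 8L) {
  if (!is.na(l1) && !is.na(l2) && !(l1 > l2 && l2 > 0))
    stop("nllap_config requires l1 > l2 > 0")
  structure(list(l1 = l1, l2 = l2, m_th = m_th, sigma_th = sigma_th,
                 n_samples = as.integer(n_samples),
                 patch_size = as.integer(patch_size)),
            class = "nllap_config")
}

# probe patch statistics near the baseline row
nllap_probe_stats <- function(img, baseline_row, cfg) {
  nr <- nrow(img); nc <- ncol(img)
  ps <- min(cfg$patch_size, nr, nc)
  r0 <- min(max(baseline_row - ps %/% 2L, 1L), nr - ps + 1L)
  starts <- unique(round(seq(1L, nc - ps + 1L, length.out = cfg$n_samples)))
  mns <- sds <- numeric(length(starts))
  for (i in seq_along(starts)) {
    patch <- img[r0:(r0 + ps - 1L), starts[i]:(starts[i] + ps - 1L)]
    mns[i] <- mean(patch); sds[i] <- stats::sd(patch)
  }
  lowest <- which.min(mns)
  list(m_b = mns[lowest], sigma_b = sds[lowest], means = mns, sds = sds)
}

#' Binarisation by the NLLAP edge detector
#'
#' Computes the signed NLLAP response, assigns zero-response pixels to their
#' nearest signed region, and places edges at the zero-crossings between
#' positive and negative regions. The strength of an edge pixel is the
#' weakest-link reading of the crossing: the minimum of
#' `grandmax - grandmin` over the pixel and its opposite-sign neighbours.
#' The binarisation threshold is chosen adaptively: probe patches near the
#' baseline give the background mean `m_b` and sd `sigma_b` of the quietest
#' patch, and the stricter threshold `l1` is used when `m_b < m_th` or
#' `sigma_b > sigma_th` (noisy or very dark background), `l2` otherwise.
#'
#' @param img intensity matrix.
#' @param cfg an [nllap_config()]; `NA` fields are derived from the image.
#' @param baseline_row row index used to place the probe patches; defaults to
#'   the middle row.
#' @return a [binary_mask()] marking retained edge pixels.
#' @export
binarize_nllap <- function(img, cfg = nllap_config(),
                           baseline_row = nrow(img) %/% 2L) {
  d <- nllap_diffs(img)
  resp <- d$gmax + d$gmin
  strength_all <- d$gmax - d$gmin
  s <- sign(resp)
  # propagate signs into the zero band (nearest signed region, 4-connected)
  for (iter in seq_len(64L)) {
    zero <- s == 0
    if (!any(zero)) break
    nb <- shift_replicate(s, -1L, 0L) + shift_replicate(s, 1L, 0L) +
      shift_replicate(s, 0L, -1L) + shift_replicate(s, 0L, 1L)
    newsign <- sign(nb)
    changed <- zero & newsign != 0
    if (!any(changed)) break
    s[changed] <- newsign[changed]
  }
  if (all(s == 0))
    return(binary_mask(matrix(FALSE, nrow(img), ncol(img)), baseline_row))
  # zero-crossings: pixel with an opposite-signed 4-neighbour
  opp_min <- matrix(Inf, nrow(img), ncol(img))
  edge <- matrix(FALSE, nrow(img), ncol(img))
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    s_n <- shift_replicate(s, off[1], off[2])
    d_n <- shift_replicate(strength_all, off[1], off[2])
    cross <- s != 0 & s_n != 0 & s != s_n
    edge <- edge | cross
    opp_min[cross] <- pmin(opp_min[cross], d_n[cross])
  }
  if (!any(edge))
    return(binary_mask(matrix(FALSE, nrow(img), ncol(img)), baseline_row))
  strength <- pmin(strength_all, opp_min)
  es <- strength[edge]
  rng <- range(es)
  l2 <- if (is.na(cfg$l2)) rng[1] + 0.25 * diff(rng) else cfg$l2
  l1 <- if (is.na(cfg$l1)) rng[1] + 0.50 * diff(rng) else cfg$l1
  ps <- nllap_probe_stats(img, baseline_row, cfg)
  m_th <- if (is.na(cfg$m_th)) stats::quantile(ps$means, 0.25, names = FALSE)
          else cfg$m_th
  sigma_th <- if (is.na(cfg$sigma_th))
    stats::quantile(ps$sds, 0.75, names = FALSE) else cfg$sigma_th
  t_sel <- if (ps$m_b < m_th || ps$sigma_b > sigma_th) l1 else l2
  bits <- edge & strength >= t_sel
  binary_mask(bits, baseline_row)
}

#' Binarisation by combined Sobel and NLLAP edge detectors
#'
#' The 3x3 Sobel gradient magnitude is thresholded with Otsu's rule on the
#' magnitude image and OR-combined with the [binarize_nllap()] mask, so the
#' result always contains the NLLAP edges.
#'
#' @inheritParams binarize_nllap
#' @return a [binary_mask()].
#' @export
binarize_nllap_sobel <- function(img, cfg = nllap_config(),
                                 baseline_row = nrow(img) %/% 2L) {
  mag <- sobel_magnitude(img)
  mx <- max(mag)
  sob <- if (mx > 1e-9) {
    magn <- mag / mx
    thr <- otsu_threshold(intensity_histogram(as.vector(magn)))
    if (is.na(thr)) matrix(FALSE, nrow(img), ncol(img)) else magn > thr
  } else matrix(FALSE, nrow(img), ncol(img))
  nll <- binarize_nllap(img, cfg, baseline_row)
  binary_mask(sob | nll$bits, baseline_row)
}

sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- as.matrix(EBImage::filter2(img, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(img, t(kx), boundary = "replicate"))
  sqrt(gx^2 + gy^2)
}

#' Binarisation by the Canny edge detector
#'
#' Gaussian-derivative gradients, non-maximum suppression along the quantised
#' gradient direction, and dual-threshold hysteresis: weak edge segments are
#' kept only when 8-connected to a strong pixel. The hysteresis thresholds
#' are set from percentiles of the non-zero gradient magnitudes (the source
#' methods state only `sigma`).
#'
#' @param img intensity matrix.
#' @param sigma Gaussian standard deviation (default 0.5).
#' @param low_pct,high_pct magnitude percentiles for the weak / strong
#'   hysteresis thresholds (defaults 0.70 and 0.90).
#' @param baseline_row inherited baseline row.
#' @return a [binary_mask()] of thin (about one pixel wide) edge curves.
#' @export
binarize_canny <- function(img, sigma = 0.5, low_pct = 0.70, high_pct = 0.90,
                           baseline_row = nrow(img) %/% 2L) {
  stopifnot(sigma > 0)
  half <- max(2L, ceiling(3 * sigma))
  sm <- as.matrix(EBImage::filter2(img, gaussian_kernel(sigma, half),
                                   boundary = "replicate"))
  gx <- (shift_replicate(sm, 0L, 1L) - shift_replicate(sm, 0L, -1L)) / 2
  gy <- (shift_replicate(sm, 1L, 0L) - shift_replicate(sm, -1L, 0L)) / 2
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) < 1e-9)   # flat image (allowing for filter round-off)
    return(binary_mask(matrix(FALSE, nrow(img), ncol(img)), baseline_row))
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  bin <- (round(ang / 45) %% 4)
  offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L),
               `3` = c(1L, -1L))
  nms <- matrix(FALSE, nrow(img), ncol(img))
  for (b in 0:3) {
    o <- offs[[as.character(b)]]
    fwd <- shift_replicate(mag, o[1], o[2])
    bwd <- shift_replicate(mag, -o[1], -o[2])
    sel <- bin == b & mag >= fwd & mag > bwd   # strict on one side: 1-px lines
    nms <- nms | sel
  }
  nz <- mag[mag > 0]
  lo <- stats::quantile(nz, low_pct, names = FALSE)
  hi <- stats::quantile(nz, high_pct, names = FALSE)
  weak <- nms & mag >= lo
  strong <- nms & mag >= hi
  if (!any(strong))
    return(binary_mask(matrix(FALSE, nrow(img), ncol(img)), baseline_row))
  lab <- label_components(weak, connectivity = 8L)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  binary_mask(matrix(lab %in% keep, nrow(img), ncol(img)), baseline_row)
}

#' Global Otsu binarisation
#'
#' Single global threshold on a 256-bin intensity histogram minimising the
#' within-class (equivalently maximising the between-class) variance.
#' Foreground is every pixel strictly above the threshold. A single-valued
#' image yields an empty mask.
#'
#' @param img intensity matrix.
#' @param baseline_row inherited baseline row.
#' @return a [binary_mask()].
#' @export
binarize_otsu <- function(img, baseline_row = nrow(img) %/% 2L) {
  thr <- otsu_threshold(intensity_histogram(as.vector(img)))
  bits <- if (is.na(thr)) matrix(FALSE, nrow(img), ncol(img)) else img > thr
  binary_mask(bits, baseline_row)
}

# Otsu threshold on a 256-bin histogram; returns the intensity at the upper
# edge of the split bin, or NA for a degenerate (single-bin) histogram.
otsu_threshold <- function(h) {
  n <- sum(h)
  if (n == 0 || sum(h > 0) < 2) return(NA_real_)
  p <- h / n
  lev <- (seq_len(256L) - 0.5) / 256      # bin-centre intensities
  w0 <- cumsum(p)
  m0 <- cumsum(p * lev)
  mt <- m0[256]
  k <- seq_len(255L)
  valid <- w0[k] > 0 & w0[k] < 1
  crit <- rep(-Inf, 255L)
  crit[valid] <- (mt * w0[k][valid] - m0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  if (!any(is.finite(crit))) return(NA_real_)
  which.max(crit) / 256
}

#' 2D Otsu binarisation on the gray/median histogram
#'
#' Builds a two-dimensional histogram of (pixel gray level, median of its
#' k x k neighbourhood) and selects the threshold pair maximising the
#' between-class scatter of the two diagonal classes (background: both
#' coordinates at or below the pair; foreground: both above). Using the
#' neighbourhood median instead of the mean keeps isolated noise pixels out
#' of the foreground class, which is why this is the reference binarizer of
#' the main work chain.
#'
#' @param img intensity matrix.
#' @param neighborhood odd neighbourhood side (>= 3), default 3.
#' @param baseline_row inherited baseline row.
#' @return a [binary_mask()].
#' @export
binarize_otsu2d <- function(img, neighborhood = 3L,
                            baseline_row = nrow(img) %/% 2L) {
  stopifnot(neighborhood >= 3L, neighborhood %% 2L == 1L)
  med <- neighborhood_median(img, neighborhood)
  g <- bin_of(as.vector(img)) - 1L       # 0..255
  m <- bin_of(as.vector(med)) - 1L
  if (length(unique(g)) < 2L)
    return(binary_mask(matrix(FALSE, nrow(img), ncol(img)), baseline_row))
  counts <- tabulate(g * 256L + m + 1L, nbins = 65536L)
  P <- matrix(counts / length(g), 256L, 256L, byrow = TRUE)  # [g+1, m+1]
  lev <- (seq_len(256L) - 0.5) / 256
  W <- apply(apply(P, 2, cumsum), 1, cumsum)         # W[t, s] after transpose
  W <- t(W)                                          # W[s, t] = P(g<=s-1, m<=t-1)
  Gm <- t(apply(apply(P * lev, 2, cumsum), 1, cumsum))
  Mm <- t(apply(apply(sweep(P, 2, lev, `*`), 2, cumsum), 1, cumsum))
  w0 <- W
  w1 <- 1 - outer(W[, 256L], rep(1, 256L)) - outer(rep(1, 256L), W[256L, ]) + W
  mg_t <- Gm[256L, 256L]; mm_t <- Mm[256L, 256L]
  sg1 <- mg_t - outer(Gm[, 256L], rep(1, 256L)) -
    outer(rep(1, 256L), Gm[256L, ]) + Gm
  sm1 <- mm_t - outer(Mm[, 256L], rep(1, 256L)) -
    outer(rep(1, 256L), Mm[256L, ]) + Mm
  ok <- w0 > 0 & w1 > 0
  crit <- matrix(-Inf, 256L, 256L)
  dg0 <- Gm / pmax(w0, 1e-300) - mg_t
  dm0 <- Mm / pmax(w0, 1e-300) - mm_t
  dg1 <- sg1 / pmax(w1, 1e-300) - mg_t
  dm1 <- sm1 / pmax(w1, 1e-300) - mm_t
  crit[ok] <- (w0 * (dg0^2 + dm0^2) + w1 * (dg1^2 + dm1^2))[ok]
  if (!any(is.finite(crit)))
    return(binary_mask(matrix(FALSE, nrow(img), ncol(img)), baseline_row))
  best <- arrayInd(which.max(crit), dim(crit))
  s <- best[1] - 1L; t_ <- best[2] - 1L                # levels 0..255
  bits <- matrix(g > s & m > t_, nrow(img), ncol(img))
  binary_mask(bits, baseline_row)
}

# k x k neighbourhood median with replicated borders; fast 3x3 network path
neighborhood_median <- function(img, k = 3L) {
  if (k == 3L) return(median3x3(img))
  half <- (k - 1L) %/% 2L
  offs <- expand.grid(dr = -half:half, dc = -half:half)
  stack <- vapply(seq_len(nrow(offs)),
                  function(i) shift_replicate(img, offs$dr[i], offs$dc[i]),
                  numeric(length(img)))
  matrix(apply(stack, 1, stats::median), nrow(img), ncol(img))
}

# median of 9 via a pmin/pmax sorting network (Paeth's 19-comparison scheme)
median3x3 <- function(img) {
  p <- list()
  i <- 1L
  for (dr in -1:1) for (dc in -1:1) {
    p[[i]] <- shift_replicate(img, dr, dc); i <- i + 1L
  }
  swap <- function(a, b) list(lo = pmin(p[[a]], p[[b]]),
                              hi = pmax(p[[a]], p[[b]]))
  op <- function(a, b) { s <- swap(a, b); p[[a]] <<- s$lo; p[[b]] <<- s$hi }
  op(2L, 3L); op(5L, 6L); op(8L, 9L); op(1L, 2L); op(4L, 5L); op(7L, 8L)
  op(2L, 3L); op(5L, 6L); op(8L, 9L); op(1L, 4L); op(6L, 9L); op(5L, 8L)
  op(4L, 7L); op(2L, 5L); op(3L, 6L); op(5L, 8L); op(3L, 5L); op(6L, 8L)
  op(5L, 6L)
  p[[5L]]
}

#' Binarisation by the steepest histogram-gradient threshold
#'
#' Smooths the 256-bin intensity histogram with a 5-bin moving average and
#' places the threshold where the first difference of the histogram is most
#' negative on the falling flank of the background peak -- i.e. just past the
#' dominant dark-background mode of a Doppler image. Foreground is every
#' pixel strictly above the threshold.
#'
#' @param img intensity matrix.
#' @param baseline_row inherited baseline row.
#' @return a [binary_mask()].
#' @export
binarize_steepest_gradient <- function(img, baseline_row = nrow(img) %/% 2L) {
  v <- as.vector(img)
  if (length(unique(bin_of(v))) < 2L)
    return(binary_mask(matrix(FALSE, nrow(img), ncol(img)), baseline_row))
  h <- intensity_histogram(v)
  hp <- c(h[1], h[1], h, h[256], h[256])
  hs <- stats::filter(hp, rep(1 / 5, 5), sides = 2)[3:258]
  peak <- which.max(hs)
  if (peak >= 256L) peak <- 255L
  d <- diff(hs)                     # d[i] = hs[i+1] - hs[i]
  flank <- peak:255L
  i <- flank[which.max(abs(d[flank]))]
  thr <- i / 256
  binary_mask(matrix(v > thr, nrow(img), ncol(img)), baseline_row)
}

#' Local adaptive percentile binarisation
#'
#' Splits the image column-wise into `n_regions` equal-width rectangles with
#' 50% overlap. Each region's threshold is the intensity above which the
#' brightest `pct`% of its pixels lie; in overlap areas the thresholds of the
#' adjacent regions are averaged, giving a per-column threshold profile.
#' Foreground is every pixel strictly above its local threshold.
#'
#' @param img intensity matrix.
#' @param n_regions number of rectangles (>= 2... the classic choice is 3).
#' @param pct percentage of brightest pixels per region (default 25).
#' @param baseline_row inherited baseline row.
#' @return a [binary_mask()].
#' @export
binarize_adaptive <- function(img, n_regions = 3L, pct = 25,
                              baseline_row = nrow(img) %/% 2L) {
  stopifnot(n_regions >= 2L)
  nc <- ncol(img)
  w <- min(nc, ceiling(2 * nc / (n_regions + 1)))
  starts <- round(seq(1, nc - w + 1, length.out = n_regions))
  thr_sum <- numeric(nc); thr_n <- numeric(nc)
  for (s in starts) {
    cols <- s:(s + w - 1L)
    thr <- stats::quantile(img[, cols], 1 - pct / 100, names = FALSE)
    thr_sum[cols] <- thr_sum[cols] + thr
    thr_n[cols] <- thr_n[cols] + 1
  }
  thr_col <- thr_sum / pmax(thr_n, 1)
  bits <- sweep(img, 2, thr_col, `>`)
  binary_mask(bits, baseline_row)
}
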