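#' Construct a pulsed-wave Doppler strip
#'
#' A `doppler_strip` is the carrier object for all image operations in the
#' tracing workflow: a grayscale raster in which columns are time, rows are
#' velocity, and a known baseline row marks zero velocity. Row 1 is the top of
#' the image; "above the baseline" means a smaller row index and corresponds to
#' positive velocity (flow toward the transducer).
#'
#' @param pixels numeric matrix of intensities in \[0, 1\], rows x columns.
#' @param baseline_row integer row index of the zero-velocity axis line.
#' @param column_rate columns per second of the strip, i.e. the envelope
#'   sampling rate in Hz (a 75 mm/s sweep on a typical scanner yields a few
#'   hundred columns per second).
#' @param subject_id opaque identifier of the subject the recording belongs to.
#' @param source provenance string, e.g. a file path or `"synthetic"`.
#'
#' @return an object of class `doppler_strip`.
#' @export
doppler_strip <- function(pixels, baseline_row, column_rate,
                          subject_id = NA_character_, source = "memory") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (anyNA(pixels)) stop("strip pixels contain NA")
  if (min(pixels) < -1e-8 || max(pixels) > 1 + 1e-8)
    stop("strip intensities must lie in [0, 1]")
  pixels <- pmin(pmax(pixels, 0), 1)
  baseline_row <- as.integer(baseline_row)
  if (length(baseline_row) != 1L || is.na(baseline_row) ||
      baseline_row < 1L || baseline_row > nrow(pixels))
    stop("baseline_row outside image: ", baseline_row)
  if (!is.numeric(column_rate) || column_rate <= 0)
    stop("column_rate must be > 0")
  structure(
    list(pixels = pixels, baseline_row = baseline_row,
         column_rate = as.numeric(column_rate),
         subject_id = as.character(subject_id),
         polarity = "unknown", source = source),
    class = "doppler_strip")
}

#' @export
print.doppler_strip <- function(x, ...) {
  cat(sprintf("<doppler_strip> %d rows x %d cols, baseline row %d, %.1f col/s",
              nrow(x$pixels), ncol(x$pixels), x$baseline_row, x$column_rate))
  cat(sprintf("\n  subject: %s | polarity: %s | source: %s\n",
              x$subject_id, x$polarity, x$source))
  invisible(x)
}

#' @export
dim.doppler_strip <- function(x) dim(x$pixels)

#' Load a PWD strip image from disk
#'
#' Reads an 8- or 16-bit grayscale or RGB PNG/TIFF and rescales intensities to
#' \[0, 1\]. RGB images are converted to luminance with the ITU-R 601 weights
#' (0.299, 0.587, 0.114). If no baseline row is supplied it is located with
#' [detect_baseline()].
#'
#' @param path path to a PNG or TIFF raster.
#' @param column_rate columns per second (Hz).
#' @param baseline_row optional integer row index; detected when `NULL`.
#' @param subject_id optional subject identifier.
#' @return a [doppler_strip()].
#' @export
load_strip <- function(path, column_rate, baseline_row = NULL,
                       subject_id = NA_character_) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3]
    w <- if (nch >= 3) c(0.299, 0.587, 0.114) else rep(1 / nch, nch)
    gray <- matrix(0, dim(dat)[1], dim(dat)[2])
    for (k in seq_len(min(nch, 3L))) gray <- gray + w[k] * dat[, , k]
    dat <- gray
  }
  # EBImage stores [x = column, y = row]; transpose to rows x cols raster order
  pixels <- t(dat)
  pixels <- pmin(pmax(pixels, 0), 1)
  if (is.null(baseline_row)) {
    baseline_row <- detect_baseline(
      doppler_strip(pixels, nrow(pixels) %/% 2L, column_rate))
  }
  if (baseline_row < 1 || baseline_row > nrow(pixels))
    stop("baseline_row outside image: ", baseline_row)
  doppler_strip(pixels, baseline_row, column_rate,
                subject_id = subject_id, source = path)
}

#' Write a strip raster to disk
#'
#' @param strip a [doppler_strip()].
#' @param path output path; format follows the extension (.png or .tiff).
#' @return `path`, invisibly.
#' @export
write_strip <- function(strip, path) {
  EBImage::writeImage(EBImage::Image(t(strip$pixels)), path)
  invisible(path)
}

#' Locate the zero-velocity baseline row
#'
#' The baseline on a PWD display is a horizontal axis line running the full
#' width of the strip. It is located as the row maximising the row-mean
#' intensity, restricted to the middle 80% of rows (the axis never hugs the
#' image border on a clinical display). This is a fallback: synthetic strips
#' and the CLI pass the baseline explicitly.
#'
#' @param strip a [doppler_strip()]; its current `baseline_row` is ignored.
#' @return integer row index, with attribute `confidence` equal to `"high"` or
#'   `"low"` (`"low"` when no row stands out, in which case the middle row is
#'   returned).
#' @export
detect_baseline <- function(strip) {
  px <- strip$pixels
  nr <- nrow(px)
  lo <- max(1L, ceiling(nr * 0.1))
  hi <- min(nr, floor(nr * 0.9))
  score <- rowMeans(px)[lo:hi]
  if (diff(range(score)) < 1e-9) {
    out <- nr %/% 2L
    attr(out, "confidence") <- "low"
    return(out)
  }
  out <- lo + which.max(score) - 1L
  # a genuine axis line clearly exceeds the typical row brightness
  conf <- if (max(score) > mean(score) + 2 * stats::sd(score)) "high" else "low"
  attr(out, "confidence") <- conf
  out
}

#' Enforce positive E/A balance
#'
#' Depending on the fetal position the mitral inflow can move toward or away
#' from the transducer, so the E/A wave may appear above (positive balance) or
#' below the baseline. All downstream processing assumes positive balance;
#' strips whose summed intensity above the baseline is smaller than below are
#' flipped upside-down and the baseline row remapped. The operation is
#' idempotent.
#'
#' @param strip a [doppler_strip()].
#' @return the strip, flipped if required, with `polarity` set.
#' @export
ensure_positive_balance <- function(strip) {
  px <- strip$pixels
  yb <- strip$baseline_row
  nr <- nrow(px)
  above <- if (yb > 1L) sum(px[seq_len(yb - 1L), , drop = FALSE]) else 0
  below <- if (yb < nr) sum(px[(yb + 1L):nr, , drop = FALSE]) else 0
  if (above < below) {
    strip$pixels <- px[nr:1L, , drop = FALSE]
    strip$baseline_row <- nr + 1L - yb
    strip$polarity <- "positive"
    strip$source <- strip$source
  } else {
    strip$polarity <- "positive"
  }
  strip
}

#' @rdname autoplot-pwdtrace
#' @export
autoplot.doppler_strip <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$intensity <- as.vector(t(object$pixels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_hline(yintercept = object$baseline_row,
                        colour = "orange", linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "time (columns)", y = "velocity (rows)",
                  title = sprintf("PWD strip (%s)", object$subject_id)) +
    ggplot2::theme_minimal()
}
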