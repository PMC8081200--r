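# Slot-5 options: from binary mask to upper/lower velocity envelopes.

#' Construct an envelope pair
#'
#' Per-column upper (`G_u`) and lower (`G_l`) velocity envelopes relative to
#' the baseline, in row units: `value = baseline_row - row`, so positive
#' values lie above the baseline. Columns with no foreground carry 0 in both
#' envelopes. Stored as a tibble with columns `x`, `upper`, `lower` so it
#' pipes straight into dplyr/ggplot2; the column rate and baseline travel as
#' attributes.
#'
#' @param upper,lower numeric vectors of equal length, `upper >= lower`.
#' @param column_rate columns per second (Hz).
#' @param baseline_row originating baseline row index.
#' @return a tibble of class `envelope_pair`.
#' @export
envelope_pair <- function(upper, lower, column_rate = NA_real_,
                          baseline_row = NA_integer_) {
  stopifnot(length(upper) == length(lower))
  if (any(upper < lower)) stop("upper envelope below lower envelope")
  out <- tibble::tibble(x = seq_along(upper), upper = as.numeric(upper),
                        lower = as.numeric(lower))
  attr(out, "column_rate") <- as.numeric(column_rate)
  attr(out, "baseline_row") <- as.integer(baseline_row)
  class(out) <- c("envelope_pair", class(out))
  out
}

env_column_rate <- function(env) attr(env, "column_rate")

#' White-region contour envelope extraction
#'
#' Traces the outermost boundary of the white regions: for every column the
#' upper envelope is the largest and the lower envelope the smallest signed
#' distance `baseline_row - row` over foreground pixels, and 0 where the
#' column holds no foreground.
#'
#' @param mask a [binary_mask()] with its baseline row set.
#' @param column_rate columns per second, attached to the result.
#' @return an [envelope_pair()].
#' @export
extract_contour <- function(mask, column_rate = NA_real_) {
  stopifnot(inherits(mask, "binary_mask"))
  bits <- mask$bits
  yb <- mask$baseline_row
  nr <- nrow(bits)
  # topmost/bottommost foreground row per column, vectorised
  rowidx <- matrix(seq_len(nr), nr, ncol(bits))
  top <- suppressWarnings(apply(ifelse(bits, rowidx, NA_integer_), 2,
                                min, na.rm = TRUE))
  bot <- suppressWarnings(apply(ifelse(bits, rowidx, NA_integer_), 2,
                                max, na.rm = TRUE))
  empty <- !is.finite(top)
  upper <- ifelse(empty, 0, yb - top)
  lower <- ifelse(empty, 0, yb - bot)
  envelope_pair(upper, lower, column_rate, yb)
}

#' Biggest-gap envelope extraction
#'
#' Works on each column separately and on each side of the baseline
#' separately. Runs of background pixels ("gaps") are scored by a triangular
#' weight profile peaking at the centre of the half, so a gap in the central
#' area of the search space outweighs gaps hugging the baseline or the image
#' border. In the upper half the winning gap's signal-side boundary -- the
#' white pixel immediately below the gap's lowest black pixel -- defines the
#' upper envelope; the mirrored rule below the baseline defines the lower
#' envelope. A half with no foreground contributes 0. Ties are broken toward
#' the gap farther from the baseline.
#'
#' @inheritParams extract_contour
#' @return an [envelope_pair()].
#' @export
extract_biggest_gap <- function(mask, column_rate = NA_real_) {
  stopifnot(inherits(mask, "binary_mask"))
  bits <- mask$bits
  yb <- mask$baseline_row
  nr <- nrow(bits); nc <- ncol(bits)
  up_rows <- if (yb > 1L) seq_len(yb - 1L) else integer(0)
  lo_rows <- if (yb < nr) (yb + 1L):nr else integer(0)
  w_up <- triangular_weights(length(up_rows))
  w_lo <- triangular_weights(length(lo_rows))
  upper <- numeric(nc); lower <- numeric(nc)
  for (x in seq_len(nc)) {
    if (length(up_rows)) {
      colv <- bits[up_rows, x]
      # boundary index = signal pixel adjacent (below) the winning gap;
      # "farther from baseline" = gap starting nearer row 1
      bi <- gap_boundary(colv, w_up, from_baseline = FALSE)
      upper[x] <- if (is.na(bi)) 0 else yb - up_rows[bi]
    }
    if (length(lo_rows)) {
      colv <- bits[lo_rows, x]
      bi <- gap_boundary(rev(colv), rev(w_lo), from_baseline = FALSE)
      lower[x] <- if (is.na(bi)) 0 else
        yb - lo_rows[length(lo_rows) + 1L - bi]
    }
  }
  envelope_pair(upper, lower, column_rate, yb)
}

# triangular weight profile over a half of height L, peaking at its centre
triangular_weights <- function(L) {
  if (L == 0L) return(numeric(0))
  d <- seq_len(L) - 0.5
  1 - abs(d - L / 2) / (L / 2)
}

# One half-column, oriented so index 1 is the far side (away from baseline)
# and index L is adjacent to the baseline. Returns the index of the signal
# pixel adjacent to the baseline side of the heaviest gap, or NA when the
# half holds no signal. Ties favour the earlier (farther-from-baseline) gap.
gap_boundary <- function(colv, w, from_baseline = FALSE) {
  if (!any(colv)) return(NA_integer_)
  r <- rle(colv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gaps <- which(!r$values)
  if (length(gaps) == 0L) {
    # solid signal: envelope at the far end of the run
    return(starts[which(r$values)[1]])
  }
  score <- vapply(gaps, function(i) sum(w[starts[i]:ends[i]]), numeric(1))
  best <- gaps[which.max(score)]              # which.max takes first on ties
  # signal pixel just past the gap, toward the baseline
  cand <- ends[best] + 1L
  if (cand <= length(colv) && colv[cand]) return(cand)
  # gap touches the baseline end: fall back to the signal pixel preceding it
  if (starts[best] > 1L && colv[starts[best] - 1L]) return(starts[best] - 1L)
  # otherwise the nearest signal pixel past the gap
  nxt <- which(colv & seq_along(colv) > ends[best])
  if (length(nxt)) return(nxt[1])
  prv <- which(colv & seq_along(colv) < starts[best])
  prv[length(prv)]
}

#' @rdname autoplot-pwdtrace
#' @export
autoplot.envelope_pair <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("upper", "lower"),
                            names_to = "envelope", values_to = "velocity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$velocity,
                                   colour = .data$envelope)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(upper = "firebrick",
                                            lower = "steelblue")) +
    ggplot2::labs(x = "time (columns)", y = "velocity (rows from baseline)") +
    ggplot2::theme_minimal()
}
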