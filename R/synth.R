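# Synthetic PWD-strip generator: wide strips with an E/A biphasic wave above
# the baseline and a V wave below it per heartbeat, speckle-like noise,
# malformed segments, and ground-truth envelopes and beat labels.

#' Synthetic cohort parameters
#'
#' Defaults emulate the clinical acquisition conditions the toolbox targets:
#' 25 subjects, fetal heart rates between 110 and 160 bpm, an E peak smaller
#' than the A peak (as before birth), a V wave of opposite polarity, a column
#' rate of 230 Hz so even the slowest beat fits a 128-column window, and
#' moderate multiplicative speckle plus additive background noise and salt
#' pixels. About 30% of beats are malformed (dropout, missing A, fused E/A,
#' clipped V) and excluded from the complete-beat labels, mirroring the
#' incomplete/malformed class a cardiologist would skip.
#'
#' @param n_subjects number of subjects (default 25).
#' @param beats_per_subject beats rendered per strip (default 20).
#' @param fhr_range fetal heart-rate range in bpm (default 110-160).
#' @param column_rate strip columns per second (Hz, default 230).
#' @param rows image height in pixels (default 200).
#' @param baseline_row zero-velocity row (default 100).
#' @param ea_ratio E-peak / A-peak amplitude ratio, < 1 (default 0.75).
#' @param a_amp A-peak amplitude in rows (default 75).
#' @param v_depth V-wave depth in rows (default 55).
#' @param fill_low,fill_high intensity of the spectral fill at the envelope
#'   edge and at the baseline.
#' @param speckle_sd multiplicative speckle sd (default 0.15).
#' @param bg_noise_sd additive background noise sd (default 0.08).
#' @param salt_frac fraction of salt pixels (default 0.005).
#' @param blur_sigma light rendering blur in pixels (default 0.8).
#' @param malform_rate fraction of beats corrupted (default 0.3).
#' @param shift positive-window shift radius for labelling (default 15).
#' @param seed master seed.
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_subjects = 25L, beats_per_subject = 20L,
                         fhr_range = c(110, 160), column_rate = 230,
                         rows = 200L, baseline_row = 100L, ea_ratio = 0.75,
                         a_amp = 75, v_depth = 55, fill_low = 0.55,
                         fill_high = 0.9, speckle_sd = 0.15,
                         bg_noise_sd = 0.08, salt_frac = 0.005,
                         blur_sigma = 0.8, malform_rate = 0.3, shift = 15L,
                         seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects),
            beats_per_subject = as.integer(beats_per_subject),
            fhr_range = fhr_range, column_rate = column_rate,
            rows = as.integer(rows), baseline_row = as.integer(baseline_row),
            ea_ratio = ea_ratio, a_amp = a_amp, v_depth = v_depth,
            fill_low = fill_low, fill_high = fill_high,
            speckle_sd = speckle_sd, bg_noise_sd = bg_noise_sd,
            salt_frac = salt_frac, blur_sigma = blur_sigma,
            malform_rate = malform_rate, shift = as.integer(shift),
            seed = as.integer(seed))
  if (p$ea_ratio >= 1) stop("ea_ratio must be < 1 (fetal E smaller than A)")
  if (round(60 / min(p$fhr_range) * p$column_rate) > WINDOW_WIDTH)
    stop("slowest beat does not fit a ", WINDOW_WIDTH, "-column window")
  if (p$a_amp >= p$baseline_row || p$v_depth >= p$rows - p$baseline_row)
    stop("wave amplitudes exceed the image half-heights")
  structure(p, class = "synth_params")
}

#' Ideal single-beat envelope template
#'
#' One cardiac cycle of the ideal five-chamber PWD morphology: the upper
#' envelope holds two successive positive raised-cosine humps (E then A,
#' amplitudes in ratio `ea_ratio` so E < A) over the diastolic fraction of
#' the beat, and the lower envelope one negative hump (V, the aortic
#' outflow) of depth `v_depth` over the systolic fraction. Elsewhere both
#' envelopes are zero, and the two are never simultaneously non-zero.
#'
#' @param fhr_bpm heart rate of this beat.
#' @param ea_ratio E/A amplitude ratio (< 1).
#' @param v_depth V depth in rows.
#' @param column_rate columns per second.
#' @param a_amp A-peak amplitude in rows.
#' @return list with `upper`, `lower` (length = beat columns), `length`, and
#'   the hump support intervals (`e_span`, `a_span`, `v_span`, in columns).
#' @export
beat_template <- function(fhr_bpm, ea_ratio = 0.75, v_depth = 55,
                          column_rate = 230, a_amp = 75) {
  L <- round(60 / fhr_bpm * column_rate)
  if (L > WINDOW_WIDTH)
    stop("beat of ", L, " columns exceeds the ", WINDOW_WIDTH,
         "-column window")
  xs <- seq_len(L)
  hump <- function(lo, hi, amp) {
    sel <- xs >= lo & xs <= hi
    out <- numeric(L)
    t <- (xs[sel] - lo) / (hi - lo)
    out[sel] <- amp * 0.5 * (1 - cos(2 * pi * t))
    out
  }
  e_span <- round(c(0.02, 0.26) * L)
  a_span <- round(c(0.30, 0.56) * L)
  v_span <- round(c(0.64, 0.96) * L)
  upper <- hump(e_span[1], e_span[2], ea_ratio * a_amp) +
    hump(a_span[1], a_span[2], a_amp)
  lower <- -hump(v_span[1], v_span[2], v_depth)
  list(upper = upper, lower = lower, length = L,
       e_span = e_span, a_span = a_span, v_span = v_span)
}

MALFORM_TYPES <- c("dropout", "missing_a", "fused_ea", "clipped_v")

# corrupt one beat template in place
malform_beat <- function(tpl, type, a_amp, ea_ratio, v_depth) {
  L <- tpl$length
  xs <- seq_len(L)
  switch(type,
    dropout = {
      sel <- xs >= round(0.25 * L) & xs <= round(0.75 * L)
      tpl$upper[sel] <- 0; tpl$lower[sel] <- 0
    },
    missing_a = {
      sel <- xs >= tpl$a_span[1] & xs <= tpl$a_span[2]
      tpl$upper[sel] <- 0
    },
    fused_ea = {
      lo <- tpl$e_span[1]; hi <- tpl$a_span[2]
      sel <- xs >= lo & xs <= hi
      t <- (xs[sel] - lo) / (hi - lo)
      tpl$upper <- numeric(L)
      tpl$upper[sel] <- a_amp * 0.5 * (1 - cos(2 * pi * t))
    },
    clipped_v = {
      tpl$lower <- tpl$lower * 0.3
    })
  tpl
}

#' Render one synthetic PWD strip with ground truth
#'
#' Concatenates beats with heart-rate jitter around the subject's base rate,
#' fills the pixels between the baseline and the envelopes with an intensity
#' profile that decays toward the envelope edge, draws the bright axis line,
#' then adds multiplicative speckle, additive background noise and salt
#' pixels and applies a light blur. A `malform_rate` fraction of beats is
#' corrupted and excluded from the complete-beat centres.
#'
#' @param params a [synth_params()].
#' @param subject_seed seed for this subject's randomness.
#' @param subject_id identifier stored on the strip.
#' @return list with `strip` (a [doppler_strip()]) and `truth` (list:
#'   `upper_true`, `lower_true`, `beat_centers`, `beats` tibble,
#'   `malformed_spans`).
#' @export
render_strip <- function(params, subject_seed = params$seed,
                         subject_id = "S1") {
  p <- params
  with_local_seed(subject_seed, {
    base_fhr <- stats::runif(1, p$fhr_range[1], p$fhr_range[2])
    upper <- lower <- numeric(0)
    beats <- list()
    cursor <- 0L
    for (b in seq_len(p$beats_per_subject)) {
      fhr <- min(max(base_fhr + stats::rnorm(1, 0, 3), p$fhr_range[1]),
                 p$fhr_range[2])
      tpl <- beat_template(fhr, p$ea_ratio, p$v_depth, p$column_rate, p$a_amp)
      type <- NA_character_
      if (stats::runif(1) < p$malform_rate) {
        type <- sample(MALFORM_TYPES, 1)
        tpl <- malform_beat(tpl, type, p$a_amp, p$ea_ratio, p$v_depth)
      }
      beats[[b]] <- tibble::tibble(
        start = cursor + 1L, end = cursor + tpl$length,
        center = cursor + round(tpl$length / 2),
        complete = is.na(type), type = type)
      upper <- c(upper, tpl$upper)
      lower <- c(lower, tpl$lower)
      cursor <- cursor + tpl$length
    }
    beats <- dplyr::bind_rows(beats)
    W <- length(upper)
    img <- matrix(0, p$rows, W)
    yb <- p$baseline_row
    for (x in seq_len(W)) {
      u <- round(upper[x])
      if (u > 0) {
        d <- seq_len(u)
        img[yb - d, x] <- p$fill_high -
          (p$fill_high - p$fill_low) * (d - 1) / max(u - 1, 1)
      }
      v <- round(-lower[x])
      if (v > 0) {
        d <- seq_len(v)
        img[yb + d, x] <- p$fill_high -
          (p$fill_high - p$fill_low) * (d - 1) / max(v - 1, 1)
      }
    }
    img[yb, ] <- 0.95
    if (p$speckle_sd > 0)
      img <- img * (1 + matrix(stats::rnorm(length(img), 0, p$speckle_sd),
                               nrow(img)))
    if (p$bg_noise_sd > 0)
      img <- img + abs(matrix(stats::rnorm(length(img), 0, p$bg_noise_sd),
                              nrow(img)))
    if (p$salt_frac > 0) {
      ns <- round(p$salt_frac * length(img))
      if (ns > 0) img[sample(length(img), ns)] <- stats::runif(ns, 0.7, 1)
    }
    img <- pmin(pmax(img, 0), 1)
    if (p$blur_sigma > 0) img <- gaussian_smooth(img, p$blur_sigma)
    strip <- doppler_strip(img, yb, p$column_rate, subject_id = subject_id,
                           source = "synthetic")
    strip$polarity <- "positive"
    truth <- list(
      upper_true = upper, lower_true = lower,
      beat_centers = beats$center[beats$complete],
      beats = beats,
      malformed_spans = beats[!beats$complete, c("start", "end", "type")])
    list(strip = strip, truth = truth)
  })
}

#' Generate a synthetic cohort with labelled windows
#'
#' Renders `n_subjects` independent strips (subject seeds derived from the
#' master seed), traces nothing -- the windows carry positions and labels
#' only, so any chain can be evaluated on the same labelled positions, as in
#' the clinical labelling protocol where the cardiologist's windows are fixed
#' before any tracing.
#'
#' @param params a [synth_params()].
#' @return a `pwd_cohort`: list of subjects (each with `strip`, `truth`,
#'   `windows`), the parameters, and a reproducible `manifest_hash`.
#' @export
generate_cohort <- function(params = synth_params()) {
  p <- params
  subjects <- lapply(seq_len(p$n_subjects), function(i) {
    sid <- sprintf("S%02d", i)
    seed_i <- (p$seed %% 1000000L) * 1000L + i
    rs <- render_strip(p, subject_seed = seed_i, subject_id = sid)
    windows <- slide_windows(
      envelope_pair(rs$truth$upper_true, rs$truth$lower_true,
                    p$column_rate, p$baseline_row),
      rs$strip, rs$truth$beat_centers, shift = p$shift,
      seed = seed_i + 500000L)
    c(rs, list(windows = windows))
  })
  manifest <- lapply(subjects, function(su)
    list(id = su$strip$subject_id, cols = ncol(su$strip$pixels),
         centers = su$truth$beat_centers,
         n_windows = nrow(su$windows),
         strip_hash = rlang::hash(su$strip$pixels)))
  structure(list(subjects = subjects, params = p,
                 manifest = manifest, manifest_hash = rlang::hash(manifest)),
            class = "pwd_cohort")
}

#' @export
print.pwd_cohort <- function(x, ...) {
  nw <- sum(vapply(x$subjects, function(s) nrow(s$windows), integer(1)))
  cat(sprintf("<pwd_cohort> %d subjects, %d beats each, %d labelled windows\n",
              x$params$n_subjects, x$params$beats_per_subject, nw))
  cat("  manifest:", x$manifest_hash, "\n")
  invisible(x)
}
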