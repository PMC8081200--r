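# Slot-6 options: 1D smoothing of the traced envelopes.

apply_env_filter <- function(env, fn) {
  stopifnot(inherits(env, "envelope_pair"))
  up <- fn(env$upper); lo <- fn(env$lower)
  # smoothing can transiently cross the two curves; keep the pair ordered
  envelope_pair(pmax(up, lo), pmin(up, lo),
                attr(env, "column_rate"), attr(env, "baseline_row"))
}

pad_replicate <- function(x, k) {
  h <- (k - 1L) %/% 2L
  if (h == 0L) return(x)
  c(rep(x[1], h), x, rep(x[length(x)], h))
}

#' Sliding-window median smoothing
#'
#' Applies a running median of `taps` samples independently to the upper and
#' lower envelopes, with replicated edges. A 3-tap median removes isolated
#' single-sample spikes exactly; the 15-tap variant smooths far more
#' aggressively.
#'
#' @param env an [envelope_pair()].
#' @param taps odd window length (3, 5 and 15 are the literature choices).
#' @return the smoothed [envelope_pair()].
#' @export
median_smooth <- function(env, taps = 3L) {
  taps <- as.integer(taps)
  stopifnot(taps %% 2L == 1L, taps >= 1L)
  apply_env_filter(env, function(x) {
    if (length(x) < taps) return(x)
    xp <- pad_replicate(x, taps)
    as.numeric(stats::runmed(xp, taps,
                             endrule = "keep"))[(1 + (taps - 1L) %/% 2L):
                                                  (length(xp) - (taps - 1L) %/% 2L)]
  })
}

#' Centered moving-average smoothing
#'
#' A `taps`-point averaging filter with replicated edges; the five-point
#' variant is the literature's choice.
#'
#' @param env an [envelope_pair()].
#' @param taps window length (>= 1).
#' @return the smoothed [envelope_pair()].
#' @export
moving_average_smooth <- function(env, taps = 5L) {
  taps <- as.integer(taps)
  stopifnot(taps >= 1L)
  apply_env_filter(env, function(x) {
    if (length(x) < taps) return(x)
    xp <- pad_replicate(x, taps)
    y <- stats::filter(xp, rep(1 / taps, taps), sides = 2)
    h <- (taps - 1L) %/% 2L
    as.numeric(y)[(1 + h):(length(xp) - h)]
  })
}

#' First-order Butterworth low-pass smoothing
#'
#' A causal (single-pass) first-order Butterworth digital filter, bilinear
#' design, applied to each envelope. The default 70 Hz cut-off, roughly ten
#' times the fetal heart's fundamental frequency, suppresses high-amplitude
#' outliers while keeping the beat morphology intact. A zero-phase variant
#' (forward-backward pass) is available behind `zero_phase`.
#'
#' @param env an [envelope_pair()] whose `column_rate` attribute is set.
#' @param cutoff_hz cut-off frequency in Hz; must be below the Nyquist rate
#'   `column_rate / 2`.
#' @param zero_phase use a forward-backward pass instead of the causal one.
#' @return the smoothed [envelope_pair()].
#' @export
butterworth_smooth <- function(env, cutoff_hz = 70, zero_phase = FALSE) {
  fs <- env_column_rate(env)
  if (is.na(fs)) stop("envelope has no column_rate; cannot design the filter")
  if (cutoff_hz >= fs / 2)
    stop(sprintf("cutoff %.1f Hz is at or above Nyquist for column_rate %.1f Hz",
                 cutoff_hz, fs))
  bw <- signal::butter(1, cutoff_hz / (fs / 2), type = "low")
  apply_env_filter(env, function(x) {
    if (zero_phase) as.numeric(signal::filtfilt(bw, x))
    else as.numeric(signal::filter(bw, x))
  })
}

#' Identity envelope post-processing
#'
#' @param env an [envelope_pair()].
#' @return `env`, unchanged.
#' @export
identity_envpost <- function(env) {
  stopifnot(inherits(env, "envelope_pair"))
  env
}
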