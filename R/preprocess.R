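#' Resample a waveform
#'
#' Polyphase anti-aliased resampling to a new rate. The output length is
#' `round(length(w) * target_rate / rate)`, so total duration is preserved to
#' within one sample period.
#'
#' @param w A `waveform`.
#' @param target_rate Target sampling rate in Hz.
#' @return A `waveform` at `target_rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 100 * (0:66149) / 22050), 22050)
#' length(resample_wave(w, 4000)$samples)  # 12000
#' @export
resample_wave <- function(w, target_rate) {
  stopifnot(inherits(w, "waveform"))
  if (!is.numeric(target_rate) || target_rate <= 0) {
    stop("target_rate must be positive", call. = FALSE)
  }
  if (target_rate == w$rate) return(w)
  # rational rate ratio for the polyphase filter (rates in practice integral)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  p <- round(target_rate * 100)
  q <- round(w$rate * 100)
  g <- gcd(p, q)
  y <- signal::resample(w$samples, p / g, q / g)
  n_out <- round(length(w$samples) * target_rate / w$rate)
  if (length(y) >= n_out) y <- y[seq_len(n_out)]
  else y <- c(y, rep(y[length(y)], n_out - length(y)))
  waveform(y, target_rate)
}

#' Fix waveform duration by truncation or tiling
#'
#' Long clips keep only their first `target_s` seconds; shorter clips are
#' tiled end-to-end until they reach or exceed `target_s`, then truncated, so
#' every output has exactly `round(target_s * rate)` samples.
#'
#' @param w A `waveform`.
#' @param target_s Target duration in seconds (default 3, one full cardiac
#'   cycle plus margin at resting heart rates).
#' @return A `waveform` of exactly `target_s` seconds at the input rate.
#' @export
fix_duration <- function(w, target_s = 3) {
  stopifnot(inherits(w, "waveform"))
  if (target_s <= 0) stop("target_s must be positive", call. = FALSE)
  n_target <- round(target_s * w$rate)
  x <- w$samples
  if (length(x) < n_target) {
    x <- rep(x, times = ceiling(n_target / length(x)))
  }
  out <- waveform(x[seq_len(n_target)], w$rate)
  attributes(out) <- c(attributes(out),
                       attributes(w)[setdiff(names(attributes(w)), c("names", "class"))])
  out
}

# Shannon energy envelope of the 25-150 Hz band, 20 ms frames.
# Returns the per-frame envelope normalized to unit maximum.
energy_envelope <- function(w, frame_s = 0.02) {
  ny <- w$rate / 2
  b <- signal::butter(4, c(25, min(150, 0.9 * ny)) / ny, type = "pass")
  x <- signal::filtfilt(b, w$samples)
  peak <- max(abs(x))
  if (peak == 0) return(rep(0, max(1L, floor(length(x) / (frame_s * w$rate)))))
  x <- x / peak
  frame_n <- max(1L, round(frame_s * w$rate))
  n_frames <- floor(length(x) / frame_n)
  idx <- matrix(x[seq_len(n_frames * frame_n)]^2, nrow = frame_n)
  # Shannon energy emphasises medium-intensity components over spikes
  se <- -colMeans(idx * log(pmax(idx, 1e-12)))
  se / max(se)
}

# Reference "lub-dub" envelope at 72 beats/min used by verify_heartbeat():
# one cycle of the same Shannon-energy envelope computed from a clean
# synthetic normal beat.
lubdub_reference <- function(rate = 4000) {
  w <- synthesize_clip(heart_label("normal"),
                       pcg_params(heart_rate = 72, noise_sd = 0, seed = 1L,
                                  rate = rate, duration = 3))
  energy_envelope(w)
}

#' Verify that a clip looks like a heartbeat
#'
#' Gate for non-heartbeat recordings. Computes a smoothed Shannon-energy
#' envelope of the 25-150 Hz band (20 ms frames) and requires both (a)
#' envelope periodicity inside the physiological 40-180 beats/min range,
#' scored by the peak normalized autocorrelation over the corresponding lag
#' window, and (b) a minimum normalized cross-correlation against a stored
#' reference "lub-dub" envelope. The clip passes only when both scores reach
#' `threshold`. The check is invariant to positive rescaling of the samples.
#'
#' @param w A `waveform` of at least 1 s.
#' @param threshold Score threshold in `[0, 1]` applied to both checks.
#' @return A `verification_result`: `passed`, `correlation_score` (the lower
#'   of the two scores), `estimated_rate` (beats/min, `NA` when silent) and
#'   `reason`.
#' @export
verify_heartbeat <- function(w, threshold = 0.6) {
  stopifnot(inherits(w, "waveform"))
  if (wave_duration(w) < 1) stop("verification needs at least 1 s of audio",
                                 call. = FALSE)
  res <- function(passed, score, rate_bpm, reason) {
    structure(list(passed = passed, correlation_score = score,
                   estimated_rate = rate_bpm, reason = reason),
              class = "verification_result")
  }
  if (all(w$samples == 0)) return(res(FALSE, 0, NA_real_, "silence"))
  env <- energy_envelope(w)
  frame_rate <- 1 / 0.02
  # (a) periodicity: autocorrelation peak across lags spanning 40-180 bpm
  lag_min <- max(2L, floor(frame_rate * 60 / 180))
  lag_max <- min(length(env) - 2L, ceiling(frame_rate * 60 / 40))
  if (lag_max <= lag_min) return(res(FALSE, 0, NA_real_, "too short"))
  e <- env - mean(env)
  denom <- sum(e^2)
  if (denom == 0) return(res(FALSE, 0, NA_real_, "flat envelope"))
  ac <- vapply(lag_min:lag_max, function(l) {
    sum(e[seq_len(length(e) - l)] * e[-seq_len(l)]) / denom
  }, numeric(1))
  period_score <- max(ac)
  best_lag <- (lag_min:lag_max)[which.max(ac)]
  bpm <- 60 * frame_rate / best_lag
  # (b) shape: best normalized cross-correlation with the reference envelope
  ref <- lubdub_reference(w$rate)
  m <- min(length(ref), length(env))
  r1 <- env[seq_len(m)] - mean(env[seq_len(m)])
  r2 <- ref[seq_len(m)] - mean(ref[seq_len(m)])
  shape_score <- if (sum(r1^2) == 0 || sum(r2^2) == 0) 0 else
    max(stats::ccf(r1, r2, lag.max = m %/% 2, plot = FALSE)$acf)
  score <- min(period_score, shape_score)
  passed <- period_score >= threshold && shape_score >= threshold
  reason <- if (passed) "lub-dub pattern detected"
            else if (period_score < threshold) "no periodic envelope in 40-180 bpm"
            else "envelope does not match lub-dub reference"
  res(passed, score, bpm, reason)
}

#' @export
print.verification_result <- function(x, ...) {
  cat(sprintf("<verification: %s (score %.3f, est. %s bpm) - %s>\n",
              if (x$passed) "PASS" else "FAIL", x$correlation_score,
              if (is.na(x$estimated_rate)) "?" else sprintf("%.0f", x$estimated_rate),
              x$reason))
  invisible(x)
}

#' Standard preprocessing for one clip
#'
#' Resamples to `rate`, fixes duration to `seconds`, and peak-normalizes —
#' the fixed-shape input contract shared by the encoder and the networks.
#'
#' @param w A `waveform`.
#' @param rate Target rate in Hz (default 4000).
#' @param seconds Target duration (default 3).
#' @return A preprocessed `waveform` of exactly `rate * seconds` samples.
#' @export
preprocess_clip <- function(w, rate = 4000, seconds = 3) {
  normalize_peak(fix_duration(resample_wave(w, rate), seconds))
}
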