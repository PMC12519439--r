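# Fixed, ordered feature-name contract shared by the feature matrix, the
# aggregated vector, the explainer and serialized tables.
pcg_feature_names <- function() {
  c(paste0("mfcc", 1:13), "chroma_stft", "spectral_centroid",
    "spectral_bandwidth", "rolloff", "rmse", "zero_crossing_rate")
}

# Mel scale (HTK-style) helpers.
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_mels x n_bins matrix over FFT bin centers.
mel_filterbank <- function(n_mels, n_fft, rate) {
  freqs <- (0:(n_fft / 2)) * rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(rate / 2),
                         length.out = n_mels + 2))
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; c0 <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (c0 - lo)
    down <- (hi - freqs) / (hi - c0)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  m <- outer(0:(n_out - 1), 0:(n_in - 1), function(k, n) {
    cos(pi * k * (2 * n + 1) / (2 * n_in))
  })
  m <- m * sqrt(2 / n_in)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Extract the named per-frame audio features
#'
#' Short-time analysis of a clip into the fixed 19-feature space used by the
#' augmentation and explanation paths: 13 MFCCs (mel filterbank log-power
#' spectrum followed by an orthonormal DCT), a scalar chroma summary (mean of
#' the max-normalized 12 pitch-class energies), spectral centroid, bandwidth
#' and 85% rolloff (Hz, from the magnitude spectrum), per-frame RMS energy,
#' and the zero-crossing rate. The STFT uses a Hann window with a 512-point
#' FFT.
#'
#' @param w A `waveform`.
#' @param frame_length Analysis frame in samples (default 25 ms at the
#'   waveform rate).
#' @param hop Hop in samples (default 10 ms).
#' @param n_fft FFT size (default 512).
#' @param rolloff_pct Cumulative-energy fraction defining rolloff
#'   (default 0.85).
#' @return A `feature_matrix`: numeric matrix `frames x 19` with the fixed
#'   column order of `pcg_feature_names()`.
#' @export
extract_features <- function(w, frame_length = round(0.025 * w$rate),
                             hop = round(0.010 * w$rate), n_fft = 512,
                             rolloff_pct = 0.85) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  if (frame_length > length(x)) stop("frame_length exceeds signal length",
                                     call. = FALSE)
  n_frames <- 1L + (length(x) - frame_length) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- vapply(starts, function(s) x[s + seq_len(frame_length)],
                   numeric(frame_length))           # frame_length x n_frames
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(frame_length) - 1) / (frame_length - 1))
  padded <- matrix(0, n_fft, n_frames)
  padded[seq_len(frame_length), ] <- frames * win
  spec <- stats::mvfft(padded)[seq_len(n_fft / 2 + 1), , drop = FALSE]
  mag <- Mod(spec)
  pow <- mag^2
  freqs <- (0:(n_fft / 2)) * w$rate / n_fft

  fb <- mel_filterbank(26, n_fft, w$rate)
  mel_log <- log(pmax(fb %*% pow, 1e-10))
  mfcc <- t(dct_matrix(13, 26) %*% mel_log)        # n_frames x 13

  # chroma: fold bin power onto 12 pitch classes (A440 reference), normalize
  # each frame to unit maximum, summarize as the mean of the 12 classes
  pc <- rep(NA_integer_, length(freqs))
  nz <- freqs > 0
  pc[nz] <- (round(12 * log2(freqs[nz] / 440)) %% 12) + 1L
  chroma <- vapply(seq_len(n_frames), function(f) {
    cls <- vapply(1:12, function(k) sum(pow[which(pc == k), f]), numeric(1))
    mx <- max(cls)
    if (mx == 0) 0 else mean(cls / mx)
  }, numeric(1))

  mag_sum <- colSums(mag)
  centroid <- ifelse(mag_sum > 0, colSums(freqs * mag) / mag_sum, 0)
  bandwidth <- vapply(seq_len(n_frames), function(f) {
    if (mag_sum[f] == 0) return(0)
    sqrt(sum(mag[, f] * (freqs - centroid[f])^2) / mag_sum[f])
  }, numeric(1))
  rolloff <- vapply(seq_len(n_frames), function(f) {
    if (mag_sum[f] == 0) return(0)
    cs <- cumsum(mag[, f])
    freqs[which(cs >= rolloff_pct * cs[length(cs)])[1]]
  }, numeric(1))

  rmse <- sqrt(colMeans(frames^2))
  zcr <- vapply(seq_len(n_frames), function(f) {
    fr <- frames[, f]
    mean(fr[-length(fr)] * fr[-1] < 0)
  }, numeric(1))

  out <- cbind(mfcc, chroma, centroid, bandwidth, rolloff, rmse, zcr)
  colnames(out) <- pcg_feature_names()
  structure(out, class = c("feature_matrix", class(out)))
}

#' Aggregate a feature matrix to one vector per clip
#'
#' Per-feature arithmetic mean across frames, preserving the fixed feature
#' order — the per-clip representation used by the feature-space classifiers
#' and the attribution plots.
#'
#' @param fm A `feature_matrix` with at least one frame.
#' @return Named numeric vector of length 19.
#' @export
aggregate_features <- function(fm) {
  if (!is.matrix(fm) || nrow(fm) < 1) {
    stop("feature matrix must have at least one frame", call. = FALSE)
  }
  colMeans(fm)
}
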