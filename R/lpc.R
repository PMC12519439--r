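#' Raw (biased) autocorrelation of a frame
#'
#' Computes `r[l] = sum_t frame[t] * frame[t + l]` for lags `0..max_lag`,
#' the autocorrelation sequence the Levinson-Durbin recursion consumes.
#'
#' @param frame Numeric amplitude vector.
#' @param max_lag Largest lag, strictly less than `length(frame)`.
#' @return Numeric vector `r[0..max_lag]` (length `max_lag + 1`).
#' @examples
#' frame_autocorrelation(c(1, 1, 1), 1)  # c(3, 2)
#' @export
frame_autocorrelation <- function(frame, max_lag) {
  n <- length(frame)
  if (max_lag >= n) stop("max_lag must be smaller than the frame length",
                         call. = FALSE)
  vapply(0:max_lag, function(l) {
    sum(frame[seq_len(n - l)] * frame[seq_len(n - l) + l])
  }, numeric(1))
}

#' Levinson-Durbin recursion
#'
#' Solves the order-`p` Toeplitz normal equations of linear prediction in
#' O(p^2), returning the forward prediction coefficients `a_1..a_p` (in the
#' convention `x[t] ~ sum_i a_i x[t-i]`), the final prediction-error energy
#' (gain), and the reflection coefficients `k_1..k_p`.
#'
#' @param r Autocorrelation sequence `r[0..]` with `length(r) >= p + 1` and
#'   `r[1] > 0`.
#' @param p Prediction order.
#' @return An `lpc_model`: list with `order`, `coefficients`, `gain`,
#'   `reflection`, and `gain_trace` (error energy after each order).
#' @examples
#' levinson_durbin(c(1, 0.5), 1)  # a_1 = 0.5, gain = 0.75
#' @export
levinson_durbin <- function(r, p) {
  if (length(r) < p + 1) stop("need at least p + 1 autocorrelation lags",
                              call. = FALSE)
  if (r[1] <= 0) stop("zero-lag autocorrelation must be positive", call. = FALSE)
  a <- numeric(p)
  k <- numeric(p)
  e <- r[1]
  trace <- numeric(p)
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[seq_len(i - 1)] * r[i:2])
    ki <- acc / e
    if (!is.finite(ki) || abs(ki) >= 1) {
      stop(sprintf("numerically singular recursion at order %d (|k| = %g)",
                   i, abs(ki)), call. = FALSE)
    }
    k[i] <- ki
    a_new <- a
    a_new[i] <- ki
    if (i > 1) {
      a_new[seq_len(i - 1)] <- a[seq_len(i - 1)] - ki * rev(a[seq_len(i - 1)])
    }
    a <- a_new
    e <- e * (1 - ki^2)
    trace[i] <- e
  }
  structure(list(order = p, coefficients = a, gain = e, reflection = k,
                 gain_trace = trace),
            class = "lpc_model")
}

#' @export
print.lpc_model <- function(x, ...) {
  cat(sprintf("<lpc_model: order %d, gain %.4g>\n", x$order, x$gain))
  invisible(x)
}

#' Residual energy of a frame under a prediction model
#'
#' Energy of the prediction error `e[t] = x[t] - sum_i a_i x[t-i]` (zero
#' prehistory). For a model fitted to the same windowed frame this is close
#' to the model's `gain`.
#'
#' @param frame Numeric amplitude vector.
#' @param model An `lpc_model` with `order < length(frame)`.
#' @return Scalar residual energy.
#' @export
residual_energy <- function(frame, model) {
  stopifnot(inherits(model, "lpc_model"))
  p <- model$order
  if (p >= length(frame)) stop("model order must be below frame length",
                               call. = FALSE)
  pred <- signal::filter(signal::Arma(b = c(0, model$coefficients), a = 1),
                         frame)
  sum((frame - pred)^2)
}

#' Encode a waveform with per-frame LPC
#'
#' Splits the waveform into Hamming-windowed frames and fits an order-`p`
#' linear predictor to each by the Levinson-Durbin recursion. The resulting
#' `frames x (p + 1)` table (coefficients then gain) is the compressed
#' representation fed to the classifiers: for the defaults (3 s at 4 kHz,
#' 120 ms frames, 50% hop, p = 12) that is 49 x 13 = 637 values in place of
#' 12,000 raw samples.
#'
#' @param w A `waveform`.
#' @param order Prediction order (default 12, ~ rate/1000 + 8 at 4 kHz).
#' @param frame_length Frame length in samples (default 480 = 120 ms at
#'   4 kHz, long enough to contain an S1 transient).
#' @param hop Hop in samples (default `frame_length / 2`).
#' @return An `lpc_encoding`: list with `coef` (frames x (order + 1) matrix,
#'   last column the gain), `order`, `frame_length`, `hop`, `rate`.
#' @export
lpc_encode <- function(w, order = 12, frame_length = 480, hop = frame_length %/% 2) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  if (frame_length > n) stop("frame_length exceeds signal length", call. = FALSE)
  if (order >= frame_length) stop("order must be below frame_length", call. = FALSE)
  n_frames <- 1L + (n - frame_length) %/% hop
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_length) - 1) / (frame_length - 1))
  coef <- matrix(0, n_frames, order + 1L)
  for (f in seq_len(n_frames)) {
    start <- (f - 1L) * hop
    frame <- w$samples[start + seq_len(frame_length)] * win
    r <- frame_autocorrelation(frame, order)
    if (r[1] <= 0) {
      coef[f, ] <- c(numeric(order), 0)  # silent frame: trivial predictor
      next
    }
    m <- tryCatch(levinson_durbin(r, order), error = function(e) {
      stop(sprintf("frame %d: %s", f, conditionMessage(e)), call. = FALSE)
    })
    coef[f, ] <- c(m$coefficients, m$gain)
  }
  colnames(coef) <- c(paste0("a", seq_len(order)), "gain")
  structure(list(coef = coef, order = order, frame_length = frame_length,
                 hop = hop, rate = w$rate),
            class = "lpc_encoding")
}

#' @export
print.lpc_encoding <- function(x, ...) {
  cat(sprintf("<lpc_encoding: %d frames x %d values (order %d, frame %d, hop %d)>\n",
              nrow(x$coef), ncol(x$coef), x$order, x$frame_length, x$hop))
  invisible(x)
}

#' Flatten an LPC encoding to one numeric vector
#'
#' Concatenates per-frame (coefficients, gain) rows in frame order — the
#' "audio vector" consumed by the augmentation and classification stages.
#'
#' @param enc An `lpc_encoding`.
#' @return Numeric vector of length `frames * (order + 1)`.
#' @export
lpc_flatten <- function(enc) {
  stopifnot(inherits(enc, "lpc_encoding"))
  as.numeric(t(enc$coef))
}
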