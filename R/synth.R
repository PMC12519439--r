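#' Three-level heart-sound label
#'
#' Labels follow the screening taxonomy: level 1 separates normal beats from
#' murmurs, level 2 places a murmur in systole or diastole, and level 3
#' splits systolic murmurs into ejection-systolic (ESM, crescendo-decrescendo
#' "diamond" intensity) and pansystolic (PSM, constant "rectangular"
#' intensity). Diastolic murmurs are not subdivided.
#'
#' @param leaf One of `"normal"`, `"diastolic"`, `"ESM"`, `"PSM"`.
#' @return A `heart_label` with fields `level1`, `level2`, `level3`.
#' @examples
#' heart_label("ESM")
#' @export
heart_label <- function(leaf = c("normal", "diastolic", "ESM", "PSM")) {
  leaf <- match.arg(leaf)
  lab <- switch(leaf,
    normal    = list(level1 = "normal", level2 = "none",      level3 = "none"),
    diastolic = list(level1 = "murmur", level2 = "diastolic", level3 = "none"),
    ESM       = list(level1 = "murmur", level2 = "systolic",  level3 = "ESM"),
    PSM       = list(level1 = "murmur", level2 = "systolic",  level3 = "PSM"))
  lab$leaf <- leaf
  structure(lab, class = "heart_label")
}

#' @export
print.heart_label <- function(x, ...) {
  cat(sprintf("<heart_label %s/%s/%s>\n", x$level1, x$level2, x$level3))
  invisible(x)
}

#' Synthesis parameters for one phonocardiogram clip
#'
#' @param heart_rate Beats per minute, in (40, 180].
#' @param s1_s2_interval Systole length as a fraction of the cardiac cycle.
#' @param s1_amplitude,s2_amplitude Peak amplitudes of the S1/S2 bursts.
#' @param s1_freq,s2_freq Center frequencies (Hz) of the S1/S2 tone bursts.
#' @param s1_dur,s2_dur Burst durations in seconds.
#' @param murmur_shape `"none"`, `"ESM"`, `"PSM"` or `"diastolic"`.
#' @param murmur_amplitude Murmur amplitude relative to full scale.
#' @param noise_sd Standard deviation of the additive ambient noise.
#' @param breathing_depth Depth in `[0, 1)` of a slow (0.25 Hz) amplitude
#'   modulation of the noise floor imitating breathing; 0 disables it.
#' @param duration Clip length in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Integer RNG seed for the clip.
#' @return A `pcg_params` list.
#' @export
pcg_params <- function(heart_rate = 72, s1_s2_interval = 0.35,
                       s1_amplitude = 0.9, s2_amplitude = 0.7,
                       s1_freq = 40, s2_freq = 60,
                       s1_dur = 0.09, s2_dur = 0.065,
                       murmur_shape = "none", murmur_amplitude = 0.45,
                       noise_sd = 0.05, breathing_depth = 0,
                       duration = 3, rate = 4000, seed = 1L) {
  if (heart_rate <= 40 || heart_rate > 180) {
    stop("heart_rate must lie in (40, 180] beats/min", call. = FALSE)
  }
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!murmur_shape %in% c("none", "ESM", "PSM", "diastolic")) {
    stop("unknown murmur_shape: ", murmur_shape, call. = FALSE)
  }
  structure(list(heart_rate = heart_rate, s1_s2_interval = s1_s2_interval,
                 s1_amplitude = s1_amplitude, s2_amplitude = s2_amplitude,
                 s1_freq = s1_freq, s2_freq = s2_freq,
                 s1_dur = s1_dur, s2_dur = s2_dur,
                 murmur_shape = murmur_shape,
                 murmur_amplitude = murmur_amplitude,
                 noise_sd = noise_sd, breathing_depth = breathing_depth,
                 duration = duration, rate = rate, seed = as.integer(seed)),
            class = "pcg_params")
}

#' Murmur intensity envelope
#'
#' Unit-peak intensity envelope of a murmur across its time window.
#' ESM is a diamond: intensity rises monotonically from zero to a single
#' interior peak and falls back to zero. PSM is rectangular: constant
#' intensity (optionally with short linear on/off ramps). The diastolic
#' default is an early-diastolic decrescendo.
#'
#' @param shape `"ESM"`, `"PSM"` or `"diastolic"`.
#' @param n_points Number of envelope samples (>= 3).
#' @param ramp Fraction of `n_points` used for linear on/off ramps of the
#'   PSM envelope; 0 (default) gives a pure rectangle.
#' @return Numeric vector of length `n_points` with maximum 1.
#' @examples
#' murmur_envelope("ESM", 101)
#' murmur_envelope("PSM", 50)
#' @export
murmur_envelope <- function(shape, n_points, ramp = 0) {
  if (n_points < 3) stop("n_points must be at least 3", call. = FALSE)
  n <- as.integer(n_points)
  if (identical(shape, "ESM")) {
    p <- n %/% 2L + 1L  # unique interior peak
    up <- (seq_len(p) - 1) / (p - 1)
    down <- (n - seq((p + 1L), n)) / (n - p)
    return(c(up, down))
  }
  if (identical(shape, "PSM")) {
    env <- rep(1, n)
    k <- floor(ramp * n)
    if (k > 0) {
      env[seq_len(k)] <- seq_len(k) / (k + 1)
      env[seq(n - k + 1L, n)] <- rev(seq_len(k)) / (k + 1)
    }
    return(env)
  }
  if (identical(shape, "diastolic")) {
    t <- (seq_len(n) - 1) / (n - 1)
    return(exp(-4 * t))
  }
  stop("unknown murmur shape: ", shape, call. = FALSE)
}

# Gaussian-windowed tone burst of `n` samples at `freq` Hz.
tone_burst <- function(n, freq, rate, phase = 0) {
  t <- (seq_len(n) - 1) / rate
  c_t <- (n - 1) / (2 * rate)
  sd_t <- (n / rate) / 6
  exp(-0.5 * ((t - c_t) / sd_t)^2) * sin(2 * pi * freq * t + phase)
}

# Band-limited (120-400 Hz) unit-RMS noise used as the murmur carrier.
murmur_carrier <- function(n, rate) {
  x <- stats::rnorm(n + 400L)
  ny <- rate / 2
  b <- signal::butter(4, c(120, 400) / ny, type = "pass")
  y <- signal::filtfilt(b, x)[201:(200L + n)]
  y / sqrt(mean(y^2))
}

#' Synthesize one labelled phonocardiogram clip
#'
#' Builds a quasi-periodic heart-sound clip: one S1 and one S2
#' Gaussian-windowed tone burst per cardiac cycle (S1 before S2), an optional
#' murmur as band-limited (120-400 Hz) noise shaped by [murmur_envelope()],
#' and additive ambient noise. Systolic murmur energy is placed strictly
#' between each S1 onset and the following S2 onset; diastolic murmur energy
#' begins at/after S2 and ends at/before the next S1. The ground-truth event
#' windows are attached as attribute `"events"` for downstream verification.
#'
#' @param label A `heart_label` (or a leaf name accepted by [heart_label()]).
#' @param params A `pcg_params`; its `murmur_shape` must be consistent with
#'   the label (`"none"` for normal clips, the leaf's shape otherwise, with
#'   `"diastolic"` for diastolic murmurs).
#' @return A `waveform` with attributes `"label"` (the `heart_label`) and
#'   `"events"` (data frame of typed time windows in seconds).
#' @examples
#' w <- synthesize_clip(heart_label("ESM"),
#'                      pcg_params(murmur_shape = "ESM", seed = 7))
#' head(attr(w, "events"))
#' @export
synthesize_clip <- function(label, params = NULL) {
  if (is.character(label)) label <- heart_label(label)
  stopifnot(inherits(label, "heart_label"))
  want_shape <- if (label$level1 == "normal") "none"
                else if (label$level2 == "diastolic") "diastolic"
                else label$level3
  if (is.null(params)) params <- pcg_params(murmur_shape = want_shape)
  stopifnot(inherits(params, "pcg_params"))
  if (!identical(params$murmur_shape, want_shape)) {
    stop(sprintf("murmur_shape '%s' inconsistent with label leaf '%s'",
                 params$murmur_shape, label$leaf), call. = FALSE)
  }
  with_seed(params$seed, {
    n <- round(params$duration * params$rate)
    x <- numeric(n)
    period <- 60 / params$heart_rate
    s1_n <- round(params$s1_dur * params$rate)
    s2_n <- round(params$s2_dur * params$rate)
    events <- list()
    k <- 0L
    repeat {
      s1_on <- k * period
      s2_on <- s1_on + params$s1_s2_interval * period
      i1 <- round(s1_on * params$rate) + 1L
      if (i1 > n) break
      j1 <- min(i1 + s1_n - 1L, n)
      x[i1:j1] <- x[i1:j1] +
        params$s1_amplitude * tone_burst(s1_n, params$s1_freq,
                                         params$rate)[seq_len(j1 - i1 + 1L)]
      events[[length(events) + 1L]] <-
        data.frame(type = "S1", start = s1_on, end = s1_on + params$s1_dur)
      i2 <- round(s2_on * params$rate) + 1L
      if (i2 <= n) {
        j2 <- min(i2 + s2_n - 1L, n)
        x[i2:j2] <- x[i2:j2] +
          params$s2_amplitude * tone_burst(s2_n, params$s2_freq,
                                           params$rate)[seq_len(j2 - i2 + 1L)]
        events[[length(events) + 1L]] <-
          data.frame(type = "S2", start = s2_on, end = s2_on + params$s2_dur)
      }
      if (params$murmur_shape != "none") {
        win <- switch(params$murmur_shape,
          ESM = ,
          PSM = c(s1_on + params$s1_dur, s2_on),
          diastolic = c(s2_on + params$s2_dur, (k + 1) * period))
        a <- round(win[1] * params$rate) + 2L   # strictly after window start
        b <- min(round(win[2] * params$rate), n)  # strictly before window end
        # skip windows truncated below an expressible envelope (clip edge)
        if (b - a + 1L >= 3L && a <= n) {
          env <- murmur_envelope(params$murmur_shape, b - a + 1L)
          carrier <- murmur_carrier(b - a + 1L, params$rate)
          x[a:b] <- x[a:b] + params$murmur_amplitude * env * carrier
          events[[length(events) + 1L]] <-
            data.frame(type = "murmur", start = (a - 1) / params$rate,
                       end = (b - 1) / params$rate)
        }
      }
      k <- k + 1L
    }
    if (params$noise_sd > 0) {
      noise <- stats::rnorm(n, sd = params$noise_sd)
      if (params$breathing_depth > 0) {
        t <- (seq_len(n) - 1) / params$rate
        noise <- noise * (1 + params$breathing_depth * sin(2 * pi * 0.25 * t))
      }
      x <- x + noise
    }
    w <- waveform(x, params$rate)
    attr(w, "label") <- label
    attr(w, "events") <- do.call(rbind, events)
    attr(w, "params") <- params
    w
  })
}

#' Specification of a synthetic clip corpus
#'
#' @param counts Named integer vector of per-leaf clip counts; names among
#'   `normal`, `ESM`, `PSM`, `diastolic`.
#' @param ranges Named list of `c(lo, hi)` ranges overriding the default
#'   per-clip parameter draws (fields of [pcg_params()]).
#' @param duration,rate Clip duration (s) and sampling rate (Hz).
#' @param seed Master seed; per-clip seeds are derived from it.
#' @return A `corpus_spec`.
#' @export
corpus_spec <- function(counts, ranges = list(), duration = 3, rate = 4000,
                        seed = 1L) {
  counts <- counts[counts >= 0 | is.na(counts)]
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("corpus counts must be non-negative", call. = FALSE)
  }
  bad <- setdiff(names(counts), c("normal", "ESM", "PSM", "diastolic"))
  if (length(bad)) stop("unknown leaf labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  defaults <- list(heart_rate = c(60, 100), s1_s2_interval = c(0.30, 0.40),
                   s1_amplitude = c(0.70, 0.90), s2_frac = c(0.65, 0.85),
                   s1_freq = c(30, 45), s2_freq = c(50, 70),
                   s1_dur = c(0.07, 0.10), s2_dur = c(0.05, 0.08),
                   murmur_amplitude = c(0.35, 0.55),
                   noise_sd = c(0.02, 0.08), breathing_depth = c(0, 0))
  for (nm in names(ranges)) defaults[[nm]] <- ranges[[nm]]
  structure(list(counts = counts, ranges = defaults, duration = duration,
                 rate = rate, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a labelled synthetic corpus
#'
#' Draws per-clip parameters uniformly from the ranges in the spec and
#' synthesizes exactly the requested number of clips per leaf label,
#' reproducibly under the master seed. When `dir` is given each clip is
#' written as 16-bit mono WAV and the manifest as `manifest.csv`.
#'
#' @param spec A [corpus_spec()].
#' @param dir Optional output directory for WAV files and the manifest.
#' @return A `pcg_corpus`: list with `waves` (list of labelled waveforms) and
#'   `manifest` (one row per clip: `clip_id`, `path`, `level1`, `level2`,
#'   `level3`, `seed`, `params_json`).
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (!is.null(dir) && !dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  leaves <- rep(names(spec$counts), times = spec$counts)
  n <- length(leaves)
  draws <- with_seed(spec$seed, {
    seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer()
    list(seeds = seeds,
         u = matrix(stats::runif(n * length(spec$ranges)), nrow = max(n, 1L)))
  })
  waves <- vector("list", n)
  rows <- vector("list", n)
  rg <- spec$ranges
  for (i in seq_len(n)) {
    pick <- function(nm, j) {
      r <- rg[[nm]]
      r[1] + (r[2] - r[1]) * draws$u[i, j]
    }
    s1a <- pick("s1_amplitude", 3)
    lab <- heart_label(leaves[i])
    shape <- if (lab$level1 == "normal") "none"
             else if (lab$level2 == "diastolic") "diastolic" else lab$level3
    p <- pcg_params(
      heart_rate = pick("heart_rate", 1), s1_s2_interval = pick("s1_s2_interval", 2),
      s1_amplitude = s1a, s2_amplitude = s1a * pick("s2_frac", 4),
      s1_freq = pick("s1_freq", 5), s2_freq = pick("s2_freq", 6),
      s1_dur = pick("s1_dur", 7), s2_dur = pick("s2_dur", 8),
      murmur_shape = shape, murmur_amplitude = pick("murmur_amplitude", 9),
      noise_sd = pick("noise_sd", 10), breathing_depth = pick("breathing_depth", 11),
      duration = spec$duration, rate = spec$rate, seed = draws$seeds[i])
    w <- synthesize_clip(lab, p)
    clip_id <- sprintf("clip_%04d_%s", i, leaves[i])
    path <- if (!is.null(dir)) file.path(dir, paste0(clip_id, ".wav")) else NA_character_
    if (!is.null(dir)) write_wav(w, path)
    waves[[i]] <- w
    rows[[i]] <- data.frame(
      clip_id = clip_id, path = path,
      level1 = lab$level1, level2 = lab$level2, level3 = lab$level3,
      seed = draws$seeds[i],
      params_json = jsonlite::toJSON(unclass(p), auto_unbox = TRUE),
      stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0) do.call(rbind, rows) else
    data.frame(clip_id = character(), path = character(), level1 = character(),
               level2 = character(), level3 = character(), seed = integer(),
               params_json = character(), stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(waves = waves, manifest = manifest, spec = spec),
            class = "pcg_corpus")
}

#' @export
print.pcg_corpus <- function(x, ...) {
  tab <- table(factor(x$manifest$level1, levels = c("normal", "murmur")))
  cat(sprintf("<pcg_corpus: %d clips (%d normal, %d murmur) @ %g Hz>\n",
              nrow(x$manifest), tab[["normal"]], tab[["murmur"]],
              x$spec$rate))
  invisible(x)
}
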