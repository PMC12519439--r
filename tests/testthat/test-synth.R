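test_that("murmur envelopes have the prescribed shapes for all sizes", {
  for (n in c(3, 4, 5, 10, 50, 101)) {
    esm <- murmur_envelope("ESM", n)
    expect_length(esm, n)
    expect_equal(esm[1], 0)
    expect_equal(esm[n], 0)
    expect_equal(max(esm), 1)
    peak <- which.max(esm)
    expect_gt(peak, 1)
    expect_lt(peak, n)
    # strictly unimodal: rises to the peak, falls after it
    expect_true(all(diff(esm[1:peak]) > 0))
    expect_true(all(diff(esm[peak:n]) < 0))

    psm <- murmur_envelope("PSM", n)
    expect_true(all(psm == 1))

    dia <- murmur_envelope("diastolic", n)
    expect_equal(max(dia), 1)
    expect_true(all(diff(dia) < 0))  # decrescendo
  }
  expect_identical(murmur_envelope("PSM", 3), c(1, 1, 1))
  # with ramps the interior plateau still sits at 1
  ramped <- murmur_envelope("PSM", 50, ramp = 0.1)
  expect_equal(max(ramped), 1)
  expect_true(all(ramped[10:40] == 1))
  expect_error(murmur_envelope("square", 10), "unknown")
  expect_error(murmur_envelope("ESM", 2), "at least 3")
})

test_that("synthesized clips respect the murmur timing rules", {
  for (leaf in c("ESM", "PSM", "diastolic")) {
    shape <- if (leaf == "diastolic") "diastolic" else leaf
    w <- synthesize_clip(leaf, pcg_params(murmur_shape = shape, seed = 11))
    ev <- attr(w, "events")
    s1 <- ev[ev$type == "S1", ]
    s2 <- ev[ev$type == "S2", ]
    mm <- ev[ev$type == "murmur", ]
    expect_gt(nrow(mm), 0)
    for (i in seq_len(nrow(mm))) {
      if (leaf %in% c("ESM", "PSM")) {
        # systolic: strictly between an S1 onset and the following S2 onset
        prev_s1 <- max(s1$start[s1$start < mm$start[i]])
        next_s2 <- min(s2$start[s2$start >= mm$end[i]])
        expect_gt(mm$start[i], prev_s1)
        expect_lte(mm$end[i], next_s2)
      } else {
        # diastolic: begins at/after S2, ends at/before the next S1
        prev_s2 <- max(s2$start[s2$start <= mm$start[i]])
        expect_gte(mm$start[i], prev_s2)
        next_s1 <- s1$start[s1$start >= mm$end[i] - 1e-9]
        if (length(next_s1)) expect_lte(mm$end[i], min(next_s1) + 1e-9)
      }
    }
  }
})

test_that("a noiseless normal clip is silent outside the S1/S2 windows", {
  p <- pcg_params(noise_sd = 0, seed = 5)
  w <- synthesize_clip("normal", p)
  ev <- attr(w, "events")
  t <- (seq_along(w$samples) - 1) / w$rate
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(ev))) {
    inside <- inside | (t >= ev$start[i] - 1e-9 & t <= ev$end[i] + 1e-9)
  }
  expect_equal(sum(w$samples[!inside]^2), 0)
})

test_that("ESM systolic-window energy dominates the diastolic window", {
  # oracle: RMS over the generator's own ground-truth event windows
  p <- pcg_params(murmur_shape = "ESM", murmur_amplitude = 0.9,
                  s1_amplitude = 0.9, seed = 21)
  w <- synthesize_clip("ESM", p)
  ev <- attr(w, "events")
  rms_window <- function(a, b) {
    idx <- which((seq_along(w$samples) - 1) / w$rate >= a &
                   (seq_along(w$samples) - 1) / w$rate <= b)
    sqrt(mean(w$samples[idx]^2))
  }
  mm <- ev[ev$type == "murmur", ][1, ]
  s2 <- ev[ev$type == "S2", ]
  s1 <- ev[ev$type == "S1", ]
  sys_rms <- rms_window(mm$start, mm$end)
  # diastolic window of the same cycle: S2 end to next S1 onset
  s2_end <- min(s2$end[s2$end > mm$end])
  next_s1 <- min(s1$start[s1$start > s2_end])
  dia_rms <- rms_window(s2_end, next_s1)
  expect_gte(sys_rms / dia_rms, 3)
})

test_that("synthesis is bit-deterministic under the clip seed", {
  p <- pcg_params(murmur_shape = "PSM", seed = 77)
  w1 <- synthesize_clip("PSM", p)
  w2 <- synthesize_clip("PSM", p)
  expect_identical(w1$samples, w2$samples)
})

test_that("label/shape inconsistency and bad parameters are rejected", {
  expect_error(synthesize_clip("normal", pcg_params(murmur_shape = "ESM")),
               "inconsistent")
  expect_error(synthesize_clip("ESM", pcg_params(murmur_shape = "diastolic")),
               "inconsistent")
  expect_error(pcg_params(duration = 0), "duration")
  expect_error(pcg_params(rate = -1), "rate")
  expect_error(pcg_params(murmur_shape = "sinusoid"), "unknown")
})

test_that("generate_corpus emits exactly the requested labelled counts", {
  dir <- withr::local_tempdir()
  spec <- corpus_spec(c(normal = 4, ESM = 2, PSM = 2, diastolic = 2), seed = 3)
  corpus <- generate_corpus(spec, dir = dir)
  m <- corpus$manifest
  expect_equal(nrow(m), 10)
  expect_equal(sum(m$level1 == "normal"), 4)
  expect_equal(sum(m$level3 == "ESM"), 2)
  expect_equal(sum(m$level3 == "PSM"), 2)
  expect_equal(sum(m$level2 == "diastolic"), 2)
  expect_true(all(file.exists(m$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # WAV round trip preserves the signal to 16-bit quantization
  w0 <- corpus$waves[[1]]
  w1 <- read_wav(m$path[1])
  expect_equal(w1$rate, w0$rate)
  expect_lt(max(abs(w1$samples - pmax(pmin(w0$samples, 1), -1))), 1e-4)

  empty <- generate_corpus(corpus_spec(c(normal = 0, ESM = 0), seed = 1))
  expect_equal(nrow(empty$manifest), 0)
  expect_length(empty$waves, 0)

  # reproducibility under the master seed
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$waves[[5]]$samples, c2$waves[[5]]$samples)
  expect_identical(c1$manifest$seed, c2$manifest$seed)
})
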