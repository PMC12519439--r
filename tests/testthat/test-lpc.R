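test_that("autocorrelation matches hand values and the brute-force oracle", {
  expect_equal(frame_autocorrelation(c(1, 0, 0, 0), 2), c(1, 0, 0))
  expect_equal(frame_autocorrelation(c(1, 1, 1), 1), c(3, 2))
  set.seed(4)
  frame <- rnorm(40)
  got <- frame_autocorrelation(frame, 10)
  brute <- sapply(0:10, function(l) {
    s <- 0
    for (t in seq_len(40 - l)) s <- s + frame[t] * frame[t + l]
    s
  })
  expect_equal(got, brute, tolerance = 1e-12)
  expect_true(all(got[1] >= abs(got[-1])))
  expect_error(frame_autocorrelation(1:3, 3), "smaller")
})

test_that("Levinson-Durbin reproduces closed forms", {
  m <- levinson_durbin(c(1, 0.5), 1)
  expect_equal(m$coefficients, 0.5)
  expect_equal(m$gain, 0.75)
  white <- levinson_durbin(c(1, 0, 0), 2)
  expect_equal(white$coefficients, c(0, 0))
  expect_equal(white$gain, 1)
  expect_error(levinson_durbin(c(0, 0.5), 1), "positive")
  expect_error(levinson_durbin(c(1, 0.5), 3), "lags")
})

test_that("Levinson-Durbin equals the direct Toeplitz solve across orders", {
  # AR(2) synthetic frame and random frames, orders 1..16
  set.seed(12)
  x <- numeric(400)
  e <- rnorm(400)
  for (t in 3:400) x[t] <- 1.2 * x[t - 1] - 0.5 * x[t - 2] + e[t]
  r <- frame_autocorrelation(x, 16)
  for (p in 1:16) {
    m <- levinson_durbin(r, p)
    oracle <- toeplitz_lpc(r, p)
    expect_lt(max(abs(m$coefficients - oracle$coefficients)), 1e-8)
    expect_lt(abs(m$gain - oracle$gain), 1e-8)
  }
})

test_that("gain is non-increasing in order and reflections are stable", {
  set.seed(8)
  for (rep in 1:10) {
    r <- random_autocorr(80, 16)
    m <- levinson_durbin(r, 16)
    expect_true(all(diff(c(r[1], m$gain_trace)) <= 1e-12))
    expect_true(all(abs(m$reflection) < 1))
    expect_gte(m$gain, 0)
  }
})

test_that("encoding has the contracted frame count and is deterministic", {
  w <- waveform(rnorm(12000), 4000)
  enc <- lpc_encode(w, order = 12, frame_length = 480, hop = 240)
  expect_equal(dim(enc$coef), c(49, 13))
  expect_length(lpc_flatten(enc), 637)
  enc2 <- lpc_encode(w, order = 12, frame_length = 480, hop = 240)
  expect_identical(enc$coef, enc2$coef)
  expect_error(lpc_encode(waveform(rnorm(100), 4000), frame_length = 480),
               "exceeds")
})

test_that("residual energy behaves like a prediction error", {
  set.seed(19)
  # a sinusoid is an exact AR(2) process: x[t] = 2cos(w) x[t-1] - x[t-2];
  # the matched predictor leaves only the two zero-prehistory boundary terms
  w0 <- 0.3
  x <- cos(w0 * (1:300))
  a <- c(2 * cos(w0), -1)
  model <- structure(list(order = 2, coefficients = a, gain = 0,
                          reflection = c(NA, NA)), class = "lpc_model")
  boundary <- x[1]^2 + (x[2] - a[1] * x[1])^2
  expect_equal(residual_energy(x, model), boundary, tolerance = 1e-10)

  frame <- rnorm(200)
  zero_model <- structure(list(order = 2, coefficients = c(0, 0), gain = NA,
                               reflection = c(0, 0)), class = "lpc_model")
  expect_equal(residual_energy(frame, zero_model), sum(frame^2))

  # fitted model beats a coefficient grid search at p = 2 (oracle)
  r <- frame_autocorrelation(frame, 2)
  fit <- levinson_durbin(r, 2)
  fit_res <- residual_energy(frame, fit)
  grid <- seq(-1.5, 1.5, by = 0.05)
  best <- Inf
  for (a1 in grid) for (a2 in grid) {
    cand <- structure(list(order = 2, coefficients = c(a1, a2), gain = NA,
                           reflection = NULL), class = "lpc_model")
    best <- min(best, residual_energy(frame, cand))
  }
  expect_lte(fit_res, best + 0.05 * abs(best))

  # per-frame residual energy never exceeds frame energy for fitted models
  w <- waveform(rnorm(2000), 4000)
  enc <- lpc_encode(w, order = 8, frame_length = 200, hop = 100)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:199) / 199)
  for (f in seq_len(nrow(enc$coef))) {
    fr <- w$samples[(f - 1) * 100 + 1:200] * win
    m <- structure(list(order = 8, coefficients = enc$coef[f, 1:8], gain = NA,
                        reflection = NULL), class = "lpc_model")
    expect_lte(residual_energy(fr, m), sum(fr^2) + 1e-9)
  }
})
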