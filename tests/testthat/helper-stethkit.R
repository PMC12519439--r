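# Shared fixtures, all generated in code. Expensive objects are cached per
# test run in this environment.
.fixtures <- new.env(parent = emptyenv())

# Small labelled corpus (8 clips/leaf) plus preprocessed clips and LPC
# vectors, cached.
tiny_corpus <- function() {
  if (is.null(.fixtures$tiny)) {
    spec <- corpus_spec(c(normal = 8, ESM = 8, PSM = 8, diastolic = 8),
                        seed = 42)
    corpus <- generate_corpus(spec)
    clips <- lapply(corpus$waves, preprocess_clip)
    vectors <- t(vapply(clips, function(w) lpc_flatten(lpc_encode(w)),
                        numeric(49 * 13)))
    .fixtures$tiny <- list(corpus = corpus, clips = clips, vectors = vectors,
                           input_shape = c(49L, 13L))
  }
  .fixtures$tiny
}

# Linearly separable two-class sequence dataset: class-dependent mean shift
# on a short noisy sequence.
separable_seqs <- function(n = 200, T_ = 12, C = 4, seed = 7) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    y <- factor(rep(c("a", "b"), length.out = n), levels = c("a", "b"))
    X <- array(rnorm(n * T_ * C, sd = 0.3), c(n, T_, C))
    shift <- array(rep(ifelse(y == "a", 1, -1), T_ * C), c(n, T_, C))
    X <- X + shift
    list(X = X, y = y)
  })
}

# Per-epoch reproducible pseudo-random positive-definite autocorrelation:
# autocorrelations of random frames are positive semi-definite by
# construction.
random_autocorr <- function(len = 64, max_lag = 16) {
  frame <- rnorm(len)
  frame_autocorrelation(frame, max_lag)
}

# Direct Toeplitz normal-equations solve: the independent oracle for
# Levinson-Durbin.
toeplitz_lpc <- function(r, p) {
  R <- stats::toeplitz(r[1:p])
  a <- solve(R, r[2:(p + 1)])
  gain <- r[1] - sum(a * r[2:(p + 1)])
  list(coefficients = as.numeric(a), gain = gain)
}
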