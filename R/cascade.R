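# Reshape rows of frame-major flattened vectors (frame1 values, frame2
# values, ...) into a (n, T, C) sequence array.
vec_to_seq <- function(M, T_, C) {
  M <- as.matrix(M)
  X <- array(0, c(nrow(M), T_, C))
  for (c in seq_len(C)) X[, , c] <- M[, (seq_len(T_) - 1L) * C + c]
  X
}

# Encode one preprocessed waveform to the flattened audio vector the stage
# classifiers consume.
clip_vector <- function(w, lpc_order = 12, frame_length = 480,
                        hop = frame_length %/% 2) {
  lpc_flatten(lpc_encode(w, order = lpc_order, frame_length = frame_length,
                         hop = hop))
}

#' Bundle three trained stage models into a cascade
#'
#' @param stage1 `trained_classifier` for normal vs murmur (classes must be
#'   `normal`/`murmur`).
#' @param stage2 `trained_classifier` for systolic vs diastolic.
#' @param stage3 `trained_classifier` for ESM vs PSM.
#' @param rate,seconds Preprocessing contract (default 4 kHz, 3 s).
#' @param lpc_order,frame_length Encoder settings shared by all stages.
#' @param verify_threshold Threshold for [verify_heartbeat()].
#' @param on_verify_fail `"classify"` (classify anyway, flag the result) or
#'   `"re-record"` (skip classification).
#' @return A `cascade_model`.
#' @export
cascade_model <- function(stage1, stage2, stage3, rate = 4000, seconds = 3,
                          lpc_order = 12, frame_length = 480,
                          verify_threshold = 0.6,
                          on_verify_fail = c("classify", "re-record")) {
  for (m in list(stage1, stage2, stage3)) stopifnot(inherits(m, "trained_classifier"))
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 rate = rate, seconds = seconds, lpc_order = lpc_order,
                 frame_length = frame_length,
                 verify_threshold = verify_threshold,
                 on_verify_fail = match.arg(on_verify_fail)),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model: %s -> %s -> %s @ %g Hz / %g s>\n",
              x$stage1$family, x$stage2$family, x$stage3$family,
              x$rate, x$seconds))
  invisible(x)
}

# Argmax with ties broken toward the pathological branch (screening should
# rather re-examine a normal heart than miss a murmur).
vote <- function(probs, pathological) {
  stopifnot(length(probs) == 2L)
  if (probs[[pathological]] >= probs[[setdiff(names(probs), pathological)]]) {
    pathological
  } else {
    setdiff(names(probs), pathological)
  }
}

#' Route one clip through the classification cascade
#'
#' Preprocesses the clip (resample, fix duration, peak-normalize), verifies
#' the lub-dub pattern, LPC-encodes it, then runs the three stage models in
#' order: normal vs murmur; if murmur wins, systolic vs diastolic; if
#' systolic wins, ESM vs PSM. Stages after a "normal" or "diastolic" vote
#' are never executed. Ties vote toward the pathological branch.
#'
#' @param w A `waveform` (any rate/duration).
#' @param cascade A [cascade_model()].
#' @return A `cascade_result`: `stage1_probs`, `stage2_probs` (or `NULL`),
#'   `stage3_probs` (or `NULL`), `leaf` in
#'   `{normal, diastolic, ESM, PSM, re-record}`, `verification`.
#' @export
classify_clip <- function(w, cascade) {
  stopifnot(inherits(w, "waveform"), inherits(cascade, "cascade_model"))
  clip <- preprocess_clip(w, cascade$rate, cascade$seconds)
  ver <- verify_heartbeat(clip, cascade$verify_threshold)
  result <- function(leaf, p1 = NULL, p2 = NULL, p3 = NULL) {
    structure(list(stage1_probs = p1, stage2_probs = p2, stage3_probs = p3,
                   leaf = leaf, verification = ver),
              class = "cascade_result")
  }
  if (!ver$passed && cascade$on_verify_fail == "re-record") {
    return(result("re-record"))
  }
  x <- clip_vector(clip, cascade$lpc_order, cascade$frame_length)
  shape <- cascade$stage1$input_shape
  X <- vec_to_seq(matrix(x, 1), shape[1], shape[2])
  p1 <- predict_proba(cascade$stage1, X)[1, ]
  if (vote(p1, "murmur") == "normal") return(result("normal", p1))
  p2 <- predict_proba(cascade$stage2, X)[1, ]
  if (vote(p2, "systolic") == "diastolic") return(result("diastolic", p1, p2))
  p3 <- predict_proba(cascade$stage3, X)[1, ]
  leaf <- vote(p3, "PSM")
  result(leaf, p1, p2, p3)
}

#' @export
print.cascade_result <- function(x, ...) {
  fmt <- function(p) if (is.null(p)) "-" else
    paste(sprintf("%s %.2f", names(p), p), collapse = ", ")
  cat(sprintf("<cascade_result: leaf %s | s1: %s | s2: %s | s3: %s | verify %s>\n",
              x$leaf, fmt(x$stage1_probs), fmt(x$stage2_probs),
              fmt(x$stage3_probs),
              if (x$verification$passed) "pass" else "FAIL"))
  invisible(x)
}

#' Batched cascade routing over precomputed audio vectors
#'
#' Vector-level equivalent of [classify_clip()] for evaluation at scale:
#' runs stage 1 on every row, stage 2 only on rows voted "murmur", stage 3
#' only on rows voted "systolic", with the same tie-breaking. Routing each
#' row independently equals per-clip classification (no cross-clip state).
#'
#' @param stages List with `stage1`, `stage2`, `stage3` classifiers.
#' @param vectors Matrix of flattened LPC encodings.
#' @param input_shape `c(frames, order + 1)`.
#' @return Character vector of leaf labels
#'   (`normal`/`diastolic`/`ESM`/`PSM`), one per row.
#' @export
classify_vectors <- function(stages, vectors, input_shape) {
  vectors <- as.matrix(vectors)
  X <- vec_to_seq(vectors, input_shape[1], input_shape[2])
  n <- nrow(vectors)
  leaf <- rep("normal", n)
  p1 <- predict_proba(stages$stage1, X)
  murmur <- p1[, "murmur"] >= p1[, "normal"]
  if (any(murmur)) {
    idx2 <- which(murmur)
    p2 <- predict_proba(stages$stage2, X[idx2, , , drop = FALSE])
    leaf[idx2] <- "diastolic"
    systolic <- p2[, "systolic"] >= p2[, "diastolic"]
    if (any(systolic)) {
      idx3 <- idx2[systolic]
      p3 <- predict_proba(stages$stage3, X[idx3, , , drop = FALSE])
      leaf[idx3] <- ifelse(p3[, "PSM"] >= p3[, "ESM"], "PSM", "ESM")
    }
  }
  leaf
}

#' Train the three-stage cascade from labelled audio vectors
#'
#' Builds the three stage datasets from the label hierarchy — all clips for
#' normal vs murmur, murmur clips for systolic vs diastolic, systolic clips
#' for ESM vs PSM — and trains one classifier per stage.
#'
#' @param vectors Matrix of flattened LPC encodings, one row per clip.
#' @param manifest Data frame with columns `level1`, `level2`, `level3`.
#' @param input_shape `c(frames, order + 1)` of the encoding.
#' @param families Length-3 character vector of per-stage families
#'   (default CNN_LSTM for stages 1-2 and CNN for stage 3).
#' @param cfg A [train_config()] shared by the stages (per-stage seeds are
#'   derived from its seed).
#' @return List of three `trained_classifier`s named `stage1..stage3`.
#' @export
train_cascade_stages <- function(vectors, manifest, input_shape,
                                 families = c("CNN_LSTM", "CNN_LSTM", "CNN"),
                                 cfg = train_config()) {
  vectors <- as.matrix(vectors)
  stopifnot(nrow(vectors) == nrow(manifest))
  to_X <- function(rows) {
    vec_to_seq(vectors[rows, , drop = FALSE], input_shape[1], input_shape[2])
  }
  stage_cfg <- function(k) {
    c2 <- cfg
    c2$seed <- cfg$seed + k
    c2
  }
  s1_rows <- seq_len(nrow(manifest))
  y1 <- factor(manifest$level1, levels = c("normal", "murmur"))
  stage1 <- train_classifier(families[1], to_X(s1_rows), y1, stage_cfg(1L))
  s2_rows <- which(manifest$level1 == "murmur")
  y2 <- factor(manifest$level2[s2_rows], levels = c("systolic", "diastolic"))
  stage2 <- train_classifier(families[2], to_X(s2_rows), y2, stage_cfg(2L))
  s3_rows <- which(manifest$level2 == "systolic")
  y3 <- factor(manifest$level3[s3_rows], levels = c("ESM", "PSM"))
  stage3 <- train_classifier(families[3], to_X(s3_rows), y3, stage_cfg(3L))
  list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
       stage_rows = list(s1_rows, s2_rows, s3_rows))
}
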