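leaf_to_levels <- function(leaf) {
  lab <- heart_label(leaf)
  c(level1 = lab$level1, level2 = lab$level2, level3 = lab$level3)
}

#' Full-pipeline configuration
#'
#' Bundles every knob of the end-to-end run. The defaults are the study
#' conditions: a 480-clip source corpus (351 normal / 129 murmur),
#' augmentation to 10,000 vectors of which 3,600 are murmurs and 730
#' systolic, a separate boost of the systolic class to 5,000 vectors, a
#' 70-30 split, and the CNN_LSTM / CNN_LSTM / CNN stage families.
#'
#' @param corpus_counts Named per-leaf clip counts of the source corpus.
#' @param allocation Named per-leaf totals of the stage-1/2 augmented set.
#' @param systolic_boost Named per-leaf totals (ESM/PSM) of the boosted
#'   stage-3 set.
#' @param rate,seconds Preprocessing contract.
#' @param lpc_order,frame_length LPC encoder settings.
#' @param families Per-stage model families.
#' @param gmm_k Mixture components per class.
#' @param split,epochs,batch_size,lr,patience Training settings.
#' @param n_background,n_explained Explainer settings.
#' @param seeds Named integer seeds: `corpus`, `gmm`, `train`, `shap`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(
    corpus_counts = c(normal = 351, ESM = 26, PSM = 26, diastolic = 77),
    allocation = c(normal = 6400, ESM = 365, PSM = 365, diastolic = 2870),
    systolic_boost = c(ESM = 2500, PSM = 2500),
    rate = 4000, seconds = 3, lpc_order = 12, frame_length = 480,
    families = c("CNN_LSTM", "CNN_LSTM", "CNN"),
    gmm_k = 3, split = 0.7, epochs = 100, batch_size = 32, lr = 1e-3,
    patience = 10, n_background = 100, n_explained = 10,
    seeds = c(corpus = 11L, gmm = 22L, train = 33L, shap = 44L)) {
  structure(list(corpus_counts = corpus_counts, allocation = allocation,
                 systolic_boost = systolic_boost, rate = rate,
                 seconds = seconds, lpc_order = lpc_order,
                 frame_length = frame_length, families = families,
                 gmm_k = gmm_k, split = split, epochs = epochs,
                 batch_size = batch_size, lr = lr, patience = patience,
                 n_background = n_background, n_explained = n_explained,
                 seeds = seeds),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Executes synthesis -> preprocessing -> LPC encoding -> feature
#' extraction -> GMM augmentation -> stage training -> evaluation ->
#' explanation in order, and (optionally) writes every artifact to a run
#' directory: `manifest.csv`, `features.csv`, `augmentation.csv` (per-label
#' counts and origins), per-stage `metrics.json`, `shap_values.csv` and
#' `feature_ranking.csv`. Identical configs reproduce identical metrics.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional run directory.
#' @return A `pipeline_run` (invisible components: corpus, vectors,
#'   augmented sets, stage classifiers, metrics, attribution report).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## 1. synthetic labelled corpus
  corpus <- generate_corpus(corpus_spec(config$corpus_counts,
                                        duration = config$seconds,
                                        rate = config$rate,
                                        seed = config$seeds[["corpus"]]))
  manifest <- corpus$manifest

  ## 2-3. preprocess + encode + featurize
  clips <- lapply(corpus$waves, preprocess_clip, rate = config$rate,
                  seconds = config$seconds)
  vectors <- t(vapply(clips, clip_vector, numeric(
    (1L + (config$rate * config$seconds - config$frame_length) %/%
       (config$frame_length %/% 2L)) * (config$lpc_order + 1L)),
    lpc_order = config$lpc_order, frame_length = config$frame_length))
  feats <- t(vapply(clips, function(w) aggregate_features(extract_features(w)),
                    numeric(19)))
  n_frames <- nrow(lpc_encode(clips[[1]], config$lpc_order,
                              config$frame_length)$coef)
  input_shape <- c(n_frames, config$lpc_order + 1L)

  leaf <- ifelse(manifest$level1 == "normal", "normal",
                 ifelse(manifest$level2 == "diastolic", "diastolic",
                        manifest$level3))

  ## 4. class-stratified GMM augmentation
  aug1 <- augment_dataset(vectors, leaf, config$allocation, K = config$gmm_k,
                          seed = config$seeds[["gmm"]])
  aug3 <- augment_dataset(vectors, leaf, config$systolic_boost,
                          K = config$gmm_k,
                          seed = config$seeds[["gmm"]] + 1L)
  lv1 <- t(vapply(aug1$labels, leaf_to_levels, character(3)))
  aug1_manifest <- data.frame(level1 = lv1[, 1], level2 = lv1[, 2],
                              level3 = lv1[, 3], origin = aug1$origin,
                              stringsAsFactors = FALSE)
  lv3 <- t(vapply(aug3$labels, leaf_to_levels, character(3)))
  aug3_manifest <- data.frame(level1 = lv3[, 1], level2 = lv3[, 2],
                              level3 = lv3[, 3], origin = aug3$origin,
                              stringsAsFactors = FALSE)

  ## 5. per-stage training (stages 1-2 on the 10k set, stage 3 on the boost)
  cfg <- train_config(split = config$split, epochs = config$epochs,
                      batch_size = config$batch_size, lr = config$lr,
                      patience = config$patience,
                      seed = config$seeds[["train"]])
  to_X <- function(M) vec_to_seq(M, input_shape[1], input_shape[2])
  y1 <- factor(aug1_manifest$level1, levels = c("normal", "murmur"))
  stage1 <- train_classifier(config$families[1], to_X(aug1$vectors), y1, {
    c1 <- cfg; c1$seed <- cfg$seed + 1L; c1
  })
  m_rows <- which(aug1_manifest$level1 == "murmur")
  y2 <- factor(aug1_manifest$level2[m_rows], levels = c("systolic", "diastolic"))
  stage2 <- train_classifier(config$families[2],
                             to_X(aug1$vectors[m_rows, , drop = FALSE]), y2, {
    c2 <- cfg; c2$seed <- cfg$seed + 2L; c2
  })
  y3 <- factor(aug3_manifest$level3, levels = c("ESM", "PSM"))
  stage3 <- train_classifier(config$families[3], to_X(aug3$vectors), y3, {
    c3 <- cfg; c3$seed <- cfg$seed + 3L; c3
  })

  ## 6. held-out evaluation per stage
  eval_stage <- function(clf, X, y, positive) {
    p <- predict_proba(clf, X[clf$test_idx, , , drop = FALSE])
    pred <- clf$classes[max.col(p, ties.method = "first")]
    compute_metrics(as.character(y[clf$test_idx]), pred,
                    y_score = p[, positive], positive = positive)
  }
  metrics <- list(
    stage1 = eval_stage(stage1, to_X(aug1$vectors), y1, "murmur"),
    stage2 = eval_stage(stage2, to_X(aug1$vectors[m_rows, , drop = FALSE]),
                        y2, "systolic"),
    stage3 = eval_stage(stage3, to_X(aug3$vectors), y3, "ESM"))

  ## 7. feature-space surrogate + Shapley attribution
  colnames(feats) <- pcg_feature_names()
  ysur <- factor(manifest$level1, levels = c("normal", "murmur"))
  sur_cfg <- cfg
  sur_cfg$seed <- cfg$seed + 4L
  surrogate <- train_classifier(config$families[1], feats, ysur, sur_cfg)
  bg_n <- min(config$n_background, length(surrogate$train_idx))
  ex_n <- min(config$n_explained, length(surrogate$test_idx))
  picks <- with_seed(config$seeds[["shap"]], list(
    bg = sample(surrogate$train_idx, bg_n),
    ex = sample(surrogate$test_idx, ex_n)))
  report <- shap_values(surrogate, feats[picks$bg, , drop = FALSE],
                        feats[picks$ex, , drop = FALSE],
                        class_of_interest = "murmur",
                        seed = config$seeds[["shap"]])
  ranking <- rank_features(report)

  metrics_json <- lapply(metrics, function(m) {
    list(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
         f1 = m$f1, roc_auc = m$roc_auc, positive = m$positive,
         confusion = m$confusion)
  })
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(clip_id = manifest$clip_id, as.data.frame(feats)),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(rbind(cbind(set = "stage12", aug1_manifest),
                           cbind(set = "stage3", aug3_manifest)),
                     file.path(out_dir, "augmentation.csv"), row.names = FALSE)
    jsonlite::write_json(metrics_json, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(report$values),
                     file.path(out_dir, "shap_values.csv"), row.names = FALSE)
    utils::write.csv(ranking, file.path(out_dir, "feature_ranking.csv"),
                     row.names = FALSE)
  }
  invisible(structure(list(
    corpus = corpus, vectors = vectors, features = feats,
    aug1 = aug1, aug1_manifest = aug1_manifest,
    aug3 = aug3, aug3_manifest = aug3_manifest,
    stages = list(stage1 = stage1, stage2 = stage2, stage3 = stage3),
    surrogate = surrogate, metrics = metrics, metrics_json = metrics_json,
    attribution = report, ranking = ranking, input_shape = input_shape,
    config = config), class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %s (%s): accuracy %.3f, F1 %.3f, AUC %.3f [test n = %d]\n",
                nm, x$stages[[nm]]$family, m$accuracy, m$f1, m$roc_auc,
                sum(m$confusion)))
  }
  cat(sprintf("  top features: %s\n",
              paste(utils::head(x$ranking$feature, 4), collapse = ", ")))
  invisible(x)
}
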