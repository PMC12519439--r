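test_that("linear models get their closed-form attributions exactly", {
  set.seed(1)
  M <- 5
  w <- c(2, -1, 0.5, 0, 3)
  f <- function(X) as.numeric(as.matrix(X) %*% w + 1.5)
  bg <- matrix(rnorm(40 * M), 40, M)
  xs <- matrix(rnorm(3 * M), 3, M)
  rep_ <- shap_values(f, bg, xs, seed = 2)
  expect_true(rep_$exact)
  for (i in 1:3) {
    closed <- w * (xs[i, ] - colMeans(bg))
    expect_equal(unname(rep_$values[i, ]), closed, tolerance = 1e-8)
  }
})

test_that("constant models receive zero attribution everywhere", {
  f <- function(X) rep(3.7, nrow(as.matrix(X)))
  rep_ <- shap_values(f, matrix(rnorm(20), 10, 2), matrix(rnorm(6), 3, 2))
  expect_equal(max(abs(rep_$values)), 0, tolerance = 1e-10)
})

test_that("additivity holds on every explained sample", {
  set.seed(3)
  M <- 8
  f <- function(X) { X <- as.matrix(X); sin(X[, 1]) * X[, 2] + exp(0.3 * X[, 5]) }
  bg <- matrix(rnorm(30 * M), 30, M)
  xs <- matrix(rnorm(5 * M), 5, M)
  rep_ <- shap_values(f, bg, xs, seed = 4)
  recon <- rep_$base + rowSums(rep_$values)
  expect_equal(recon, rep_$fx, tolerance = 1e-3)
  expect_error(shap_values(f, bg[0, , drop = FALSE], xs), "non-empty")
})

test_that("a single-feature model concentrates attribution on it", {
  # 19 features forces the sampled-coalition path
  set.seed(5)
  M <- 19
  j <- 7
  f <- function(X) tanh(as.matrix(X)[, j])
  bg <- matrix(rnorm(25 * M), 25, M)
  xs <- matrix(rnorm(4 * M, sd = 2), 4, M)
  rep_ <- shap_values(f, bg, xs, seed = 6)
  expect_false(rep_$exact)
  for (i in 1:4) {
    mass <- abs(rep_$values[i, ])
    expect_gte(mass[j] / sum(mass), 0.95)
  }
  # additivity also holds on the sampled path
  expect_equal(rep_$base + rowSums(rep_$values), rep_$fx, tolerance = 1e-3)
})

test_that("duplicated identical features share attribution symmetrically", {
  set.seed(7)
  M <- 6
  f <- function(X) { X <- as.matrix(X); 2 * X[, 1] + 2 * X[, 2] }
  bg0 <- matrix(rnorm(30), 30, 1)
  bg <- cbind(bg0, bg0, matrix(rnorm(30 * 4), 30, 4))
  x0 <- rnorm(1)
  xs <- matrix(c(x0, x0, rnorm(4)), 1, M)
  rep_ <- shap_values(f, bg, xs, seed = 8)
  expect_equal(unname(rep_$values[1, 1]), unname(rep_$values[1, 2]),
               tolerance = 1e-6)
})

test_that("feature ranking sorts by mean absolute attribution", {
  mk <- function(values, names) {
    structure(list(values = matrix(values, nrow = 1,
                                   dimnames = list(NULL, names)),
                   base = 0, fx = 0, feature_names = names,
                   class_explained = NULL, exact = TRUE),
              class = "attribution_report")
  }
  zero <- mk(c(0, 0, 0), c("c", "a", "b"))
  expect_identical(rank_features(zero)$feature, c("a", "b", "c"))
  dom <- mk(c(0.1, -5, 0.2), c("x", "y", "z"))
  expect_identical(rank_features(dom)$feature[1], "y")
  # loop oracle on a random report
  set.seed(9)
  vals <- matrix(rnorm(4 * 6), 4, 6,
                 dimnames = list(NULL, paste0("f", 1:6)))
  rep_ <- structure(list(values = vals, base = 0, fx = numeric(4),
                         feature_names = colnames(vals),
                         class_explained = NULL, exact = TRUE),
                    class = "attribution_report")
  got <- rank_features(rep_)
  oracle_imp <- sapply(1:6, function(j) {
    s <- 0; for (i in 1:4) s <- s + abs(vals[i, j]); s / 4
  })
  expect_identical(got$feature, colnames(vals)[order(-oracle_imp)])
  expect_equal(got$mean_abs_attribution,
               unname(sort(oracle_imp, decreasing = TRUE)))
})

test_that("classifier explanations run over the named feature space", {
  x <- tiny_corpus()
  feats <- t(vapply(x$clips,
                    function(w) aggregate_features(extract_features(w)),
                    numeric(19)))
  colnames(feats) <- stethkit:::pcg_feature_names()
  y <- factor(x$corpus$manifest$level1, levels = c("normal", "murmur"))
  clf <- train_classifier("CNN", feats, y,
                          train_config(epochs = 8, seed = 23))
  rep_ <- shap_values(clf, feats[clf$train_idx[1:10], ],
                      feats[clf$test_idx[1:2], ],
                      class_of_interest = "murmur", nsamples = 300, seed = 10)
  expect_identical(rep_$feature_names, stethkit:::pcg_feature_names())
  expect_equal(rep_$base + rowSums(rep_$values), rep_$fx, tolerance = 1e-3)
  expect_identical(nrow(rank_features(rep_)), 19L)
})
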