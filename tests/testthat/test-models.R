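# Finite-difference gradient verification of the layer stack: analytic
# backprop gradients must match central differences on every layer type.
test_that("backpropagation matches finite differences on all layer types", {
  ns <- asNamespace("stethkit")
  # fixed seed; rejection-checked so no sampled ReLU pre-activation sits on
  # the kink where a central difference is invalid
  set.seed(43)
  check_net <- function(layers, T_, C) {
    net <- structure(list(family = "test", layers = layers,
                          input_shape = c(T_, C)), class = "network")
    B <- 3
    X <- array(rnorm(B * T_ * C), c(B, T_, C))
    Y <- matrix(0, B, 2); Y[cbind(1:B, sample(1:2, B, TRUE))] <- 1
    lossfn <- function(nn) {
      r <- ns$nn_forward(nn, X, train = TRUE)
      ns$softmax_ce(r$logits, Y)$loss
    }
    r <- ns$nn_forward(net, X, train = TRUE)
    ce <- ns$softmax_ce(r$logits, Y)
    net_g <- ns$nn_backward(r$net, ce$dLogits)
    worst <- 0
    for (li in seq_along(net_g$layers)) {
      g <- net_g$layers[[li]]$grads
      if (is.null(g)) next
      for (nm in names(g)) {
        p <- net_g$layers[[li]]$params[[nm]]
        for (ii in sample(length(p), min(3, length(p)))) {
          h <- 1e-5
          up <- net; up$layers[[li]]$params[[nm]][ii] <- p[ii] + h
          dn <- net; dn$layers[[li]]$params[[nm]][ii] <- p[ii] - h
          fd <- (lossfn(up) - lossfn(dn)) / (2 * h)
          an <- g[[nm]][ii]
          worst <- max(worst, abs(fd - an) / max(1e-8, abs(fd) + abs(an)))
        }
      }
    }
    worst
  }
  expect_lt(check_net(list(ns$layer_conv1d(3, 5, 3), ns$layer_batchnorm(5),
                           ns$layer_rnn("lstm", 5, 4, TRUE),
                           ns$layer_rnn("lstm", 4, 3, FALSE),
                           ns$layer_dense(3, 2)), 7, 3), 1e-5)
  expect_lt(check_net(list(ns$layer_rnn("lstm", 3, 5, TRUE, bidirectional = TRUE),
                           ns$layer_rnn("lstm", 10, 4, FALSE, bidirectional = TRUE),
                           ns$layer_dense(8, 5, act = "relu"),
                           ns$layer_dense(5, 2)), 7, 3), 1e-5)
  expect_lt(check_net(list(ns$layer_rnn("gru", 3, 5, TRUE, bidirectional = TRUE),
                           ns$layer_rnn("gru", 10, 4, FALSE, bidirectional = TRUE),
                           ns$layer_dense(8, 2)), 7, 3), 1e-5)
  expect_lt(check_net(list(ns$layer_conv1d(3, 4, 3), ns$layer_batchnorm(4),
                           ns$layer_gap(), ns$layer_dense(4, 2)), 7, 3), 1e-5)
})

test_that("network families follow their architecture contracts", {
  net <- build_network("CNN_LSTM", c(49, 13))
  types <- vapply(net$layers, `[[`, "", "type")
  expect_equal(sum(types == "conv1d"), 3)
  expect_equal(sum(types == "rnn"), 2)
  # recurrent layers come after the last convolution, before the dense head
  expect_true(max(which(types == "conv1d")) < min(which(types == "rnn")))
  expect_identical(types[length(types)], "dense")
  expect_equal(net$layers[[7]]$H, 8L)
  expect_equal(net$layers[[8]]$H, 4L)
  expect_equal(net$layers[[8]]$dropout, 0.2)

  bl <- build_network("BiLSTM", c(19, 1))
  expect_true(all(vapply(bl$layers[1:2], `[[`, TRUE, "bidirectional")))
  expect_equal(bl$layers[[1]]$H, 128L)
  cnn <- build_network("CNN", c(49, 13))
  expect_true("gap" %in% vapply(cnn$layers, `[[`, "", "type"))
  expect_error(build_network("MLP", c(10, 1)), "unknown")
})

test_that("untrained networks emit normalized two-class softmax outputs", {
  ns <- asNamespace("stethkit")
  set.seed(3)
  X <- array(rnorm(5 * 20 * 2), c(5, 20, 2))
  for (fam in c("CNN_LSTM", "BiLSTM", "CNN", "BiGRU")) {
    net <- build_network(fam, c(20, 2), seed = 4)
    p <- ns$softmax_rows(ns$nn_forward(net, X)$logits)
    expect_equal(dim(p), c(5L, 2L))
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }
  # zero-initialized head gives symmetric logits: both probabilities 0.5
  net <- build_network("CNN_LSTM", c(20, 2), seed = 4)
  k <- length(net$layers)
  net$layers[[k]]$params$W[] <- 0
  net$layers[[k]]$params$b[] <- 0
  p <- ns$softmax_rows(ns$nn_forward(net, X)$logits)
  expect_true(all(p == 0.5))
})

test_that("training splits are stratified, 70-30 sized, and seeded", {
  d <- separable_seqs(n = 100)
  cfg <- train_config(epochs = 2, seed = 21)
  clf1 <- train_classifier("CNN", d$X, d$y, cfg)
  clf2 <- train_classifier("CNN", d$X, d$y, cfg)
  expect_identical(clf1$test_idx, clf2$test_idx)
  expect_equal(length(clf1$train_idx), 70)   # floor(50 * 0.7) per class
  expect_equal(length(clf1$test_idx), 30)
  split_y <- table(d$y[clf1$train_idx])
  expect_equal(as.numeric(split_y), c(35, 35))
  expect_error(train_classifier("CNN", d$X, rep("a", 100), cfg), "two classes")
  expect_error(train_classifier(build_network("CNN", c(5, 2)), d$X, d$y, cfg),
               "shape")
})

test_that("every family overfits a small separable problem", {
  d <- separable_seqs(n = 200, T_ = 12, C = 4)
  for (fam in c("CNN_LSTM", "BiLSTM", "CNN", "BiGRU")) {
    clf <- train_classifier(fam, d$X, d$y,
                            train_config(epochs = 40, patience = 40,
                                         seed = 5))
    p <- predict_proba(clf, d$X[clf$train_idx, , , drop = FALSE])
    pred <- clf$classes[max.col(p, ties.method = "first")]
    acc <- mean(pred == as.character(d$y[clf$train_idx]))
    expect_gte(acc, 0.95)
    expect_equal(rowSums(p), rep(1, length(clf$train_idx)), tolerance = 1e-6)
  }
})

test_that("prediction is row-wise deterministic and shape-checked", {
  d <- separable_seqs(n = 60)
  clf <- train_classifier("CNN", d$X, d$y, train_config(epochs = 3, seed = 2))
  one <- d$X[1, , , drop = FALSE]
  rep5 <- d$X[rep(1, 5), , , drop = FALSE]
  p <- predict_proba(clf, rep5)
  expect_equal(p, p[rep(1, 5), ], tolerance = 1e-12)
  expect_equal(predict_proba(clf, one)[1, ], p[1, ], tolerance = 1e-12)
  expect_error(predict_proba(clf, array(0, c(2, 5, 4))), "shape")
})
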