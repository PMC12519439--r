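test_that("a point mass fits to its location with floored variance", {
  v <- matrix(rep(c(2, -1, 0.5), each = 20), 20, 3)
  expect_warning(m <- fit_class_gmm(v, K = 1, seed = 1), "regularized")
  expect_equal(as.numeric(m$means), c(2, -1, 0.5))
  expect_true(all(m$vars == m$var_floor))
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
})

test_that("two separated clusters are recovered near the true centers", {
  set.seed(2)
  a <- matrix(rnorm(120, mean = 0, sd = 0.3), 60, 2)
  b <- matrix(rnorm(120, mean = 5, sd = 0.3), 60, 2)
  m <- fit_class_gmm(rbind(a, b), K = 2, seed = 3)
  centers <- m$means[order(m$means[, 1]), ]
  sep <- sqrt(sum((c(5, 5) - c(0, 0))^2))
  expect_lt(sqrt(sum((centers[1, ] - c(0, 0))^2)), 0.1 * sep)
  expect_lt(sqrt(sum((centers[2, ] - c(5, 5))^2)), 0.1 * sep)
  # independent cross-check: mclust's diagonal-covariance fit reaches an
  # equivalent log-likelihood on the same data
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  mc <- mclust::Mclust(rbind(a, b), G = 2, modelNames = "VVI",
                       verbose = FALSE)
  ours <- m$loglik_trace[length(m$loglik_trace)]
  expect_lt(abs(ours - mc$loglik) / abs(mc$loglik), 0.02)
})

test_that("the EM log-likelihood trace is non-decreasing", {
  set.seed(9)
  v <- matrix(rnorm(300), 100, 3) + rep(c(0, 3), each = 50)
  m <- fit_class_gmm(v, K = 2, seed = 5)
  expect_true(all(diff(m$loglik_trace) >= -1e-7))
  expect_error(fit_class_gmm(v[1:2, ], K = 3), "at least")
})

test_that("sampling is exact in count, seeded, and matches mixture moments", {
  set.seed(10)
  v <- matrix(rnorm(400), 200, 2) + rep(c(0, 4), each = 100)
  m <- fit_class_gmm(v, K = 2, seed = 6)
  expect_equal(nrow(sample_class(m, 0, seed = 1)), 0)
  s1 <- sample_class(m, 50, seed = 7)
  s2 <- sample_class(m, 50, seed = 7)
  expect_identical(s1, s2)
  # closed-form mixture mean oracle at large n
  big <- sample_class(m, 20000, seed = 8)
  mu <- gmm_mean(m)
  sigma2 <- as.numeric(m$weights %*% (m$vars + m$means^2)) - mu^2
  se <- sqrt(sigma2 / 20000)
  expect_true(all(abs(colMeans(big) - mu) <= 3 * se))
  # zero-variance component collapses to its mean
  point <- structure(list(weights = 1, means = matrix(c(1, 2), 1),
                          vars = matrix(0, 1, 2), K = 1L,
                          loglik_trace = 0, label = NULL, seed = 1L,
                          var_floor = 0), class = "gmm_model")
  drawn <- sample_class(point, 5, seed = 9)
  expect_true(all(drawn == matrix(c(1, 2), 5, 2, byrow = TRUE)))
})

test_that("augmentation matches the allocation exactly and tags origins", {
  set.seed(11)
  v <- rbind(matrix(rnorm(60), 20, 3), matrix(rnorm(60, 5), 20, 3))
  labs <- rep(c("normal", "murmur"), each = 20)
  out <- augment_dataset(v, labs, c(normal = 45, murmur = 30), K = 2, seed = 12)
  expect_equal(sum(out$labels == "normal"), 45)
  expect_equal(sum(out$labels == "murmur"), 30)
  expect_equal(sum(out$origin == "real"), 40)
  expect_equal(sum(out$origin == "synthetic"), 35)
  expect_equal(nrow(out$vectors), 75)
  # allocation equal to the source counts adds nothing
  same <- augment_dataset(v, labs, c(normal = 20, murmur = 20), K = 2, seed = 1)
  expect_equal(nrow(same$vectors), 40)
  expect_true(all(same$origin == "real"))
  # determinism
  out2 <- augment_dataset(v, labs, c(normal = 45, murmur = 30), K = 2, seed = 12)
  expect_identical(out$vectors, out2$vectors)
  expect_error(augment_dataset(v, labs, c(systolic = 10), K = 2),
               "systolic")
})
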