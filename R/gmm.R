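#' Fit a diagonal-covariance Gaussian mixture to one class
#'
#' EM fit of a `K`-component Gaussian mixture with diagonal covariances,
#' used to model the per-class distribution of audio vectors before
#' sampling synthetic ones. Means are initialized by seeded k-means;
#' variances are floored at `var_floor` (default 1e-6) for small-sample
#' stability, and the per-iteration log-likelihood trace is retained (EM
#' guarantees it is non-decreasing).
#'
#' @param vectors Numeric matrix, one row per vector; `nrow >= K`.
#' @param K Number of mixture components (default 3).
#' @param seed Integer seed controlling initialization.
#' @param label Optional class label stored with the model.
#' @param var_floor Lower bound applied to every variance.
#' @param max_iter,tol EM stopping rule (iterations / absolute
#'   log-likelihood change).
#' @return A `gmm_model`: `weights`, `means` (K x d), `vars` (K x d),
#'   `loglik_trace`, `label`, `seed`.
#' @export
fit_class_gmm <- function(vectors, K = 3, seed = 1L, label = NULL,
                          var_floor = 1e-6, max_iter = 200, tol = 1e-8) {
  vectors <- as.matrix(vectors)
  if (!all(is.finite(vectors))) stop("vectors must be finite", call. = FALSE)
  n <- nrow(vectors); d <- ncol(vectors)
  if (n < K) stop(sprintf("need at least K = %d vectors, got %d", K, n),
                  call. = FALSE)
  with_seed(seed, {
    if (K == 1L) {
      cl <- rep(1L, n)
    } else {
      km <- suppressWarnings(stats::kmeans(vectors, centers = K, nstart = 5,
                                           iter.max = 50))
      cl <- km$cluster
    }
    w <- tabulate(cl, K) / n
    mu <- matrix(0, K, d)
    v <- matrix(0, K, d)
    for (k in seq_len(K)) {
      xk <- vectors[cl == k, , drop = FALSE]
      mu[k, ] <- colMeans(xk)
      v[k, ] <- pmax(apply(xk, 2, function(col) mean((col - mean(col))^2)),
                     var_floor)
    }
    degenerate <- FALSE
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      # E step in log space
      logp <- vapply(seq_len(K), function(k) {
        -0.5 * (d * log(2 * pi) + sum(log(v[k, ])) +
                  colSums((t(vectors) - mu[k, ])^2 / v[k, ])) + log(w[k])
      }, numeric(n))
      logp <- matrix(logp, nrow = n)
      m <- apply(logp, 1, max)
      lse <- m + log(rowSums(exp(logp - m)))
      trace <- c(trace, sum(lse))
      resp <- exp(logp - lse)
      # M step
      nk <- colSums(resp)
      w <- nk / n
      for (k in seq_len(K)) {
        mu[k, ] <- colSums(resp[, k] * vectors) / nk[k]
        vk <- colSums(resp[, k] * (vectors - matrix(mu[k, ], n, d, byrow = TRUE))^2) / nk[k]
        if (any(vk < var_floor)) degenerate <- TRUE
        v[k, ] <- pmax(vk, var_floor)
      }
      if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) break
    }
    if (degenerate) {
      warning("degenerate covariance regularized to the variance floor",
              call. = FALSE)
    }
    structure(list(weights = w, means = mu, vars = v, K = K,
                   loglik_trace = trace, label = label, seed = as.integer(seed),
                   var_floor = var_floor),
              class = "gmm_model")
  })
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model: K = %d, d = %d%s, loglik %.2f>\n", x$K,
              ncol(x$means),
              if (is.null(x$label)) "" else paste0(", class '", x$label, "'"),
              x$loglik_trace[length(x$loglik_trace)]))
  invisible(x)
}

#' Closed-form mean of a fitted mixture
#' @param model A `gmm_model`.
#' @return Numeric vector: the weighted average of component means.
#' @export
gmm_mean <- function(model) {
  stopifnot(inherits(model, "gmm_model"))
  as.numeric(model$weights %*% model$means)
}

#' Sample vectors from a fitted class mixture
#'
#' @param model A `gmm_model`.
#' @param n Number of vectors to draw (>= 0).
#' @param seed Integer seed; draws are reproducible.
#' @return Numeric matrix `n x d`.
#' @export
sample_class <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "gmm_model"))
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  d <- ncol(model$means)
  if (n == 0) return(matrix(numeric(0), 0, d))
  with_seed(seed, {
    comp <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
    noise <- matrix(stats::rnorm(n * d), n, d)
    model$means[comp, , drop = FALSE] +
      noise * sqrt(model$vars[comp, , drop = FALSE])
  })
}

#' Augment a labelled vector set with GMM samples
#'
#' Fits one mixture per label present in the allocation and samples each
#' class up to its allocated total, so the output per-label counts equal the
#' allocation exactly (original rows are kept and marked `origin = "real"`,
#' sampled rows `origin = "synthetic"`). This is how a small recorded corpus
#' is grown to training size while preserving per-class structure.
#'
#' @param vectors Numeric matrix of audio vectors, one row per clip.
#' @param labels Character vector of class labels, one per row.
#' @param allocation Named numeric vector: target total count per label.
#'   Every allocated label needs at least `K` source vectors.
#' @param K Components per class mixture (default 3).
#' @param seed Master seed; per-class fit/sample seeds derive from it.
#' @return List with `vectors` (matrix), `labels`, `origin`
#'   (`"real"`/`"synthetic"`), and `models` (per-label `gmm_model`s).
#' @export
augment_dataset <- function(vectors, labels, allocation, K = 3, seed = 1L) {
  vectors <- as.matrix(vectors)
  stopifnot(length(labels) == nrow(vectors))
  if (any(allocation < 0)) stop("allocation counts must be >= 0", call. = FALSE)
  miss <- setdiff(names(allocation), unique(labels))
  if (length(miss)) {
    stop("label(s) missing from the corpus: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  class_seeds <- with_seed(seed,
                           sample.int(.Machine$integer.max - 1L,
                                      2L * length(allocation)))
  out_v <- list(); out_l <- character(0); out_o <- character(0)
  models <- list()
  for (i in seq_along(allocation)) {
    lab <- names(allocation)[i]
    target <- allocation[[i]]
    rows <- vectors[labels == lab, , drop = FALSE]
    if (nrow(rows) > target) {
      stop(sprintf("allocation for '%s' (%d) is below its source count (%d)",
                   lab, target, nrow(rows)), call. = FALSE)
    }
    n_new <- target - nrow(rows)
    model <- fit_class_gmm(rows, K = K, seed = class_seeds[2 * i - 1], label = lab)
    models[[lab]] <- model
    synth <- sample_class(model, n_new, seed = class_seeds[2 * i])
    out_v[[length(out_v) + 1L]] <- rows
    out_v[[length(out_v) + 1L]] <- synth
    out_l <- c(out_l, rep(lab, target))
    out_o <- c(out_o, rep("real", nrow(rows)), rep("synthetic", n_new))
  }
  list(vectors = do.call(rbind, out_v), labels = out_l, origin = out_o,
       models = models)
}
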