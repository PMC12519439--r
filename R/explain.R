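# Shapley kernel weight for a coalition of size s out of M players.
shapley_kernel_weight <- function(M, s) {
  (M - 1) / (choose(M, s) * s * (M - s))
}

#' Shapley-value feature attributions (kernel estimator)
#'
#' Estimates additive per-feature attributions for each explained sample by
#' the kernel method: model evaluations on coalitions of "present" features
#' (absent features imputed from a background set) are combined by weighted
#' least squares under the additivity constraint, so for every sample
#' `base + sum(attributions) == model(sample)` up to solver precision. When
#' the full coalition space is within budget it is enumerated and the
#' estimate is exact; otherwise complete coalition sizes are enumerated in
#' decreasing weight order and the remainder sampled under the seed.
#'
#' @param model Either a function mapping an `n x M` matrix to a numeric
#'   output vector, or a `trained_classifier` (then `class_of_interest`
#'   selects the probability column explained).
#' @param background Non-empty `n_b x M` matrix of background vectors used
#'   to impute absent features.
#' @param samples `n x M` matrix of samples to explain.
#' @param class_of_interest Class name, required when `model` is a
#'   `trained_classifier`.
#' @param nsamples Coalition budget (default: full enumeration up to 2046,
#'   else `2 * M + 1024`).
#' @param seed Seed for coalition sampling.
#' @return An `attribution_report`: `values` (`n x M` matrix of per-feature
#'   attributions), `base` (mean model output on the background), `fx`
#'   (model outputs of the explained samples), `feature_names`,
#'   `class_explained`, `exact` (whether the coalition space was enumerated).
#' @export
shap_values <- function(model, background, samples, class_of_interest = NULL,
                        nsamples = NULL, seed = 1L) {
  background <- as.matrix(background)
  samples <- as.matrix(samples)
  if (nrow(background) < 1) stop("background set must be non-empty", call. = FALSE)
  M <- ncol(samples)
  stopifnot(ncol(background) == M)
  f <- if (inherits(model, "trained_classifier")) {
    if (is.null(class_of_interest)) {
      stop("class_of_interest is required for a trained_classifier", call. = FALSE)
    }
    function(X) predict_proba(model, X)[, class_of_interest]
  } else if (is.function(model)) {
    model
  } else {
    stop("model must be a function or a trained_classifier", call. = FALSE)
  }
  feature_names <- colnames(samples) %||% paste0("x", seq_len(M))
  total <- 2^M - 2
  if (is.null(nsamples)) nsamples <- if (total <= 2046) total else 2 * M + 1024
  exact <- total <= nsamples

  coal <- with_seed(seed, build_coalitions(M, nsamples, exact))
  Z <- coal$Z
  wz <- coal$w

  base <- mean(f(background))
  fx <- as.numeric(f(samples))
  nb <- nrow(background)
  nc <- nrow(Z)
  values <- matrix(0, nrow(samples), M)
  for (i in seq_len(nrow(samples))) {
    x <- samples[i, ]
    # evaluate v(S) = E_b f(x_S, b_{-S}) for every coalition
    big <- background[rep(seq_len(nb), times = nc), , drop = FALSE]
    zrep <- Z[rep(seq_len(nc), each = nb), , drop = FALSE]
    big[zrep == 1] <- matrix(x, nb * nc, M, byrow = TRUE)[zrep == 1]
    v <- colMeans(matrix(f(big), nb, nc))
    # constrained WLS: eliminate the last feature via the additivity identity
    y <- v - base - Z[, M] * (fx[i] - base)
    A <- Z[, -M, drop = FALSE] - Z[, M]
    AtW <- t(A * wz)
    beta <- solve(AtW %*% A + diag(1e-10, M - 1L), AtW %*% y)
    phi <- c(beta, fx[i] - base - sum(beta))
    values[i, ] <- phi
  }
  colnames(values) <- feature_names
  structure(list(values = values, base = base, fx = fx,
                 feature_names = feature_names,
                 class_explained = class_of_interest, exact = exact),
            class = "attribution_report")
}

# Coalition design: all subsets when exact, else complete sizes in
# decreasing kernel-weight order plus sampled coalitions for the remainder.
build_coalitions <- function(M, budget, exact) {
  if (exact) {
    sizes <- 1:(M - 1)
    Z <- do.call(rbind, lapply(sizes, function(s) {
      combs <- utils::combn(M, s)
      out <- matrix(0L, ncol(combs), M)
      out[cbind(rep(seq_len(ncol(combs)), each = s), as.integer(combs))] <- 1L
      out
    }))
    w <- shapley_kernel_weight(M, rowSums(Z))
    return(list(Z = Z, w = w))
  }
  size_weight <- vapply(1:(M - 1), function(s) {
    choose(M, s) * shapley_kernel_weight(M, s)
  }, numeric(1))
  ord <- order(size_weight / choose(M, 1:(M - 1)), decreasing = TRUE)
  # pair sizes s and M-s so both ends of each order are covered together
  Zs <- list(); ws <- list()
  remaining <- budget
  done <- logical(M - 1)
  for (s in 1:floor((M - 1) / 2)) {
    szs <- unique(c(s, M - s))
    need <- sum(choose(M, szs))
    if (need <= remaining) {
      for (sz in szs) {
        combs <- utils::combn(M, sz)
        Zblk <- matrix(0L, ncol(combs), M)
        Zblk[cbind(rep(seq_len(ncol(combs)), each = sz), as.integer(combs))] <- 1L
        Zs[[length(Zs) + 1L]] <- Zblk
        ws[[length(ws) + 1L]] <- rep(shapley_kernel_weight(M, sz), nrow(Zblk))
        done[sz] <- TRUE
      }
      remaining <- remaining - need
    } else break
  }
  open_sizes <- which(!done)
  if (length(open_sizes) && remaining > 0) {
    p <- size_weight[open_sizes] / sum(size_weight[open_sizes])
    draw_s <- sample(open_sizes, remaining, replace = TRUE, prob = p)
    Zblk <- t(vapply(draw_s, function(s) {
      z <- integer(M); z[sample.int(M, s)] <- 1L; z
    }, integer(M)))
    # sampled coalitions share their size's aggregate weight
    wblk <- size_weight[draw_s] / as.numeric(table(factor(draw_s, levels = open_sizes))[as.character(draw_s)])
    Zs[[length(Zs) + 1L]] <- Zblk
    ws[[length(ws) + 1L]] <- wblk
  }
  list(Z = do.call(rbind, Zs), w = unlist(ws))
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report: %d sample(s) x %d features, base %.4f%s%s>\n",
              nrow(x$values), ncol(x$values), x$base,
              if (is.null(x$class_explained)) "" else
                paste0(", class '", x$class_explained, "'"),
              if (x$exact) ", exact" else ""))
  invisible(x)
}

#' Rank features by attribution impact
#'
#' Orders features by mean absolute attribution across explained samples,
#' descending, with alphabetical name tie-breaking.
#'
#' @param report An `attribution_report` with at least one sample.
#' @return Data frame with columns `feature` and `mean_abs_attribution`,
#'   most impactful first.
#' @export
rank_features <- function(report) {
  stopifnot(inherits(report, "attribution_report"))
  if (nrow(report$values) < 1) stop("report has no samples", call. = FALSE)
  imp <- colMeans(abs(report$values))
  ord <- order(-imp, report$feature_names)
  data.frame(feature = report$feature_names[ord],
             mean_abs_attribution = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
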