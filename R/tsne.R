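# Exact (non-Barnes-Hut) t-distributed stochastic neighbour embedding.
# At the cohort scales this pipeline targets (tens to a few hundred
# samples) the O(n^2) exact gradient is cheap and keeps the package free of
# compiled dependencies.  The implementation follows the standard recipe:
# perplexity calibration by per-point binary search on the Gaussian kernel
# bandwidth, symmetrized input affinities, early exaggeration, and
# momentum/gain-adapted gradient descent on the Student-t low-dimensional
# affinities.

# P(j|i) rows with entropy matched to log(perplexity)
tsne_input_probs <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- log(sw) + beta * sum(di * w) / sw
      }
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

tsne_exact <- function(X, dims = 2L, perplexity = 10, max_iter = 1000L,
                       initial_dims = 50L, eta = 200,
                       exaggeration = 12, stop_lying_iter = 250L,
                       momentum = 0.5, final_momentum = 0.8,
                       mom_switch_iter = 250L) {
  n <- nrow(X)
  if (n - 1 < 3 * perplexity) {
    pw_stop(sprintf(
      "perplexity %g too large for %d samples (need n - 1 >= 3 * perplexity); try <= %g",
      perplexity, n, (n - 1) / 3), "pairedEWAS_contract_error")
  }
  if (ncol(X) > initial_dims) {
    X <- prcomp(X, rank. = initial_dims, center = TRUE)$x
  }
  D2 <- as.matrix(dist(X))^2
  P <- tsne_input_probs(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  P <- P * exaggeration

  Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  for (iter in seq_len(max_iter)) {
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (P - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    gains <- pmax(0.01, ifelse(sign(grad) != sign(dY), gains + 0.2,
                               gains * 0.8))
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
    if (iter == stop_lying_iter) P <- P / exaggeration
    if (iter == mom_switch_iter) momentum <- final_momentum
  }
  Y
}

#' Embed global methylome profiles in two dimensions with t-SNE
#'
#' Embeds each sample's methylome (all probes) into 2-D with exact t-SNE so
#' that work and vacation samples of the same subject can be connected and
#' recovery groups compared visually.  Deterministic given `seed`.  The
#' defaults (perplexity 10 for a 64-sample cohort, 10,000 iterations) suit
#' the paired-cohort scale; reduce `iterations` for quick looks.
#'
#' @param matrix Probes x samples M-value matrix.
#' @param sheet Sample sheet aligned with the matrix columns.
#' @param perplexity Gaussian-kernel perplexity; requires
#'   `n_samples - 1 >= 3 * perplexity`.
#' @param iterations Gradient-descent iterations.
#' @param seed Integer seed for the random initialization.
#' @return `data.frame`: `sample_id`, `subject`, `group`, `period`, `x`,
#'   `y` (one row per sample).
#' @export
embed_global_profiles <- function(matrix, sheet, perplexity = 10,
                                  iterations = 10000L, seed = 1L) {
  check_sheet(sheet)
  if (!all(sheet$sample_id %in% colnames(matrix))) {
    pw_stop("matrix columns do not cover the sample sheet",
            "pairedEWAS_alignment_error")
  }
  X <- t(matrix[, sheet$sample_id, drop = FALSE])
  Y <- with_seed(sub_seed(seed, 5L),
                 tsne_exact(X, perplexity = perplexity,
                            max_iter = as.integer(iterations)))
  data.frame(
    sample_id = sheet$sample_id,
    subject = sheet$subject,
    group = sheet$group,
    period = sheet$period,
    x = Y[, 1], y = Y[, 2],
    stringsAsFactors = FALSE, row.names = NULL)
}
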