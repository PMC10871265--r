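#' t-SNE embedding from an arbitrary distance measure
#'
#' Exact (non-tree) t-SNE for visualization of the learned representations:
#' conditional probabilities from the supplied distance measure with
#' per-point bandwidths calibrated to the target perplexity, gradient
#' descent with momentum and early exaggeration. Quadratic in `n`; intended
#' for the dataset sizes this package targets (hundreds of images).
#'
#' @param emb embedding matrix.
#' @param measure distance measure name (see [distance_measures()]).
#' @param perplexity target perplexity; defaults to `min(30, (n - 1) / 3)`.
#' @param seed integer seed.
#' @param n_iter gradient-descent iterations.
#' @return `n x 2` matrix of coordinates.
#' @export
tsne_embed <- function(emb, measure = "euclidean", perplexity = NULL,
                       seed = 0, n_iter = 300) {
  X <- unclass(as.matrix(emb))
  n <- nrow(X)
  if (n < 5) stop("need at least 5 points for t-SNE")
  perplexity <- perplexity %||% min(30, (n - 1) / 3)
  D2 <- pairwise_distances(X, measure)^2

  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:50) {
      w <- exp(-d * beta)
      s <- sum(w)
      if (s == 0) { beta <- beta / 10; next }
      p <- w / s
      h <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- w / s
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  G <- matrix(0, n, 2)
  lr <- 200
  for (it in seq_len(n_iter)) {
    mom <- if (it < 100) 0.5 else 0.8
    Pe <- if (it <= 50) P * 4 else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    G <- mom * G - lr * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
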