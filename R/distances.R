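#' Distance measures for embedding clustering
#'
#' The 22 candidate measures used for distance selection, in their
#' canonical order: Bray-Curtis, Canberra, Chebyshev, city-block, Pearson
#' correlation, cosine, Dice, Euclidean, Hamming, Jaccard, Jensen-Shannon,
#' Kulsinski, Mahalanobis, matching, Minkowski, Rogers-Tanimoto,
#' Russell-Rao, standardized Euclidean, Sokal-Michener, Sokal-Sneath,
#' squared Euclidean, and Yule. Similarity measures (correlation, cosine)
#' are converted to dissimilarities as `1 - s`. Binary measures operate on
#' the nonzero-indicator pattern of the vectors. Measures undefined on a
#' given matrix (singular covariance for Mahalanobis, zero-variance columns
#' for standardized Euclidean, zero-mass rows for Jensen-Shannon) raise an
#' error, which distance selection treats as a skip.
#'
#' @name distances
NULL

#' @rdname distances
#' @export
distance_measures <- function() {
  c("braycurtis", "canberra", "chebyshev", "cityblock", "correlation",
    "cosine", "dice", "euclidean", "hamming", "jaccard", "jensenshannon",
    "kulsinski", "mahalanobis", "matching", "minkowski", "rogerstanimoto",
    "russellrao", "seuclidean", "sokalmichener", "sokalsneath",
    "sqeuclidean", "yule")
}

.binary_measures <- c("dice", "jaccard", "kulsinski", "matching",
                      "rogerstanimoto", "russellrao", "sokalmichener",
                      "sokalsneath", "yule", "hamming")

#' Pairwise distance matrix under a named measure
#'
#' @param X numeric matrix, one observation per row.
#' @param measure one of [distance_measures()].
#' @param minkowski_p order of the Minkowski measure (default 3; 2 would
#'   duplicate Euclidean).
#' @return `n x n` symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(X, measure, minkowski_p = 3) {
  X <- unclass(as.matrix(X))
  n <- nrow(X)
  full <- function(d) as.matrix(d)

  if (measure %in% .binary_measures) {
    B <- (X != 0) * 1
    a <- tcrossprod(B)               # both TRUE
    b <- tcrossprod(B, 1 - B)        # TRUE in u, FALSE in v
    cc <- t(b)
    m <- ncol(B)
    d0 <- m - a - b - cc             # both FALSE
    R <- b + cc
    D <- switch(measure,
      hamming = R / m,
      matching = R / m,
      dice = safe_div(R, 2 * a + R),
      jaccard = safe_div(R, a + R),
      kulsinski = safe_div(R - a + m, R + m),
      rogerstanimoto = safe_div(2 * R, m + R),
      sokalmichener = safe_div(2 * R, m + R),
      russellrao = (m - a) / m,
      sokalsneath = safe_div(2 * R, a + 2 * R),
      yule = safe_div(2 * b * cc, a * d0 + b * cc))
    diag(D) <- 0
    return(D)
  }

  switch(measure,
    cityblock = full(dist(X, "manhattan")),
    chebyshev = full(dist(X, "maximum")),
    canberra = full(dist(X, "canberra")),
    euclidean = full(dist(X, "euclidean")),
    sqeuclidean = full(dist(X, "euclidean"))^2,
    minkowski = full(dist(X, "minkowski", p = minkowski_p)),
    braycurtis = {
      num <- full(dist(X, "manhattan"))
      den <- matrix(0, n, n)
      for (i in seq_len(n))
        den[i, ] <- colSums(abs(t(X) + X[i, ]))
      safe_div(num, den)
    },
    cosine = {
      nr <- sqrt(rowSums(X^2))
      if (any(nr == 0)) stop("cosine: zero-norm row")
      S <- tcrossprod(X / nr)
      D <- 1 - S; D[D < 0] <- 0; diag(D) <- 0; D
    },
    correlation = {
      Xc <- X - rowMeans(X)
      nr <- sqrt(rowSums(Xc^2))
      if (any(nr == 0)) stop("correlation: zero-variance row")
      S <- tcrossprod(Xc / nr)
      D <- 1 - S; D[D < 0] <- 0; diag(D) <- 0; D
    },
    seuclidean = {
      v <- apply(X, 2, var)
      if (any(v == 0)) stop("seuclidean: zero-variance column")
      full(dist(sweep(X, 2, sqrt(v), "/"), "euclidean"))
    },
    mahalanobis = {
      S <- cov(X)
      Si <- tryCatch(solve(S), error = function(e)
        stop("mahalanobis: singular covariance"))
      D <- matrix(0, n, n)
      for (i in seq_len(n)) {
        di <- sweep(X, 2, X[i, ])
        D[i, ] <- sqrt(pmax(rowSums((di %*% Si) * di), 0))
      }
      (D + t(D)) / 2
    },
    jensenshannon = {
      P <- X - apply(X, 1, min)
      mass <- rowSums(P)
      if (any(mass <= 0)) stop("jensenshannon: zero-mass row")
      P <- P / mass
      D <- matrix(0, n, n)
      for (i in seq_len(n)) {
        p <- P[i, ]
        M <- (P + rep(p, each = n)) / 2
        kl1 <- rowSums(ifelse(P > 0, P * log(P / M), 0))
        kl2 <- colSums(ifelse(p > 0, p * log(p / t(M)), 0))
        D[i, ] <- sqrt(pmax((kl1 + kl2) / 2, 0))
      }
      diag(D) <- 0
      (D + t(D)) / 2
    },
    stop("unknown measure: ", measure))
}

safe_div <- function(a, b) {
  out <- a / b
  out[b == 0] <- 0
  out
}

#' Mean silhouette width from a precomputed distance matrix
#'
#' @param dmat `n x n` distance matrix.
#' @param labels cluster labels (any atomic type); must contain at least 2
#'   distinct values and no more than `n - 1`.
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(dmat, labels) {
  li <- as.integer(factor(labels))
  if (length(unique(li)) < 2 || length(unique(li)) >= length(li))
    stop("silhouette needs 2..n-1 clusters")
  if (max(dmat) == 0)
    stop("silhouette undefined: all pairwise distances are zero")
  mean(cluster::silhouette(li, dmatrix = as.matrix(dmat))[, "sil_width"])
}
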