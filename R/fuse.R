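#' Fusing image and node embeddings
#'
#' Image and graph-node representations are concatenated and reduced: PCA
#' for dense matrices, truncated (uncentered) SVD for sparse ones (fraction
#' of exact zeros above `sparsity_cutoff`), keeping every component whose
#' explained-variance ratio is at least `var_threshold` (2% by default),
#' with a floor of two components. Reduction can instead be applied to each
#' block before concatenation.
#'
#' @name fuse
NULL

#' Fusion configuration
#'
#' @param mode `"concat_then_reduce"`, `"reduce_then_concat"`,
#'   `"image_only"` or `"node_only"`.
#' @param var_threshold minimum explained-variance ratio per kept component.
#' @param sparsity_cutoff zero-fraction above which the SVD branch is used.
#' @param standardize column-standardize each block (zero mean, unit
#'   variance; zero-variance columns dropped) before concatenation so large
#'   scale blocks do not dominate.
#' @export
fusion_config <- function(mode = c("concat_then_reduce",
                                   "reduce_then_concat",
                                   "image_only", "node_only"),
                          var_threshold = 0.02, sparsity_cutoff = 0.5,
                          standardize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(var_threshold > 0, var_threshold < 1)
  structure(list(mode = mode, var_threshold = var_threshold,
                 sparsity_cutoff = sparsity_cutoff,
                 standardize = standardize), class = "fusion_config")
}

#' Variance-thresholded dimensionality reduction
#'
#' @param emb embedding matrix (`n >= 2` rows).
#' @param var_threshold keep components with explained-variance ratio at
#'   least this (subject to the 2-component floor).
#' @param sparsity_cutoff zero-entry fraction routing to uncentered
#'   truncated SVD instead of centered PCA.
#' @return Reduced `embedding_matrix` (scores). Component signs are fixed
#'   (largest-magnitude loading positive) for reproducibility.
#' @export
reduce <- function(emb, var_threshold = 0.02, sparsity_cutoff = 0.5) {
  X <- unclass(as.matrix(emb))
  if (nrow(X) < 2) stop("need at least 2 rows")
  sparsity <- mean(X == 0)
  if (all(apply(X, 2, var) == 0)) stop("zero-variance matrix")

  if (sparsity > sparsity_cutoff) {
    sv <- svd(X)
    ratios <- sv$d^2 / sum(sv$d^2)
    V <- sv$v
    scores <- sv$u %*% diag(sv$d, length(sv$d))
    branch <- "svd"
  } else {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    ratios <- pc$sdev^2 / sum(pc$sdev^2)
    V <- pc$rotation
    scores <- pc$x
    branch <- "pca"
  }
  keep <- which(ratios >= var_threshold)
  n_keep <- max(length(keep), min(2, ncol(scores)))
  idx <- seq_len(n_keep)
  scores <- scores[, idx, drop = FALSE]
  # fixed sign convention: largest |loading| positive
  for (j in idx) {
    lj <- V[, j]
    if (lj[which.max(abs(lj))] < 0) scores[, j] <- -scores[, j]
  }
  out <- embedding_matrix(scores,
                          method = sprintf("%s(%s)", branch,
                                           attr(emb, "method") %||% "?"))
  attr(out, "explained_variance_ratio") <- ratios[idx]
  attr(out, "branch") <- branch
  out
}

.standardize_block <- function(X) {
  X <- unclass(as.matrix(X))
  v <- apply(X, 2, var)
  X <- X[, v > 0, drop = FALSE]
  scale(X)
}

#' Combine image and node embeddings
#'
#' @param img_emb,node_emb `n x a` and `n x b` embedding matrices with
#'   aligned rows.
#' @param cfg a [fusion_config()].
#' @return Fused `embedding_matrix`, rows index-aligned with the inputs.
#' @export
combine <- function(img_emb, node_emb, cfg = fusion_config()) {
  if (cfg$mode %in% c("concat_then_reduce", "reduce_then_concat") &&
      (is.null(img_emb) || is.null(node_emb)))
    stop("both embeddings are required for mode ", cfg$mode)
  if (!is.null(img_emb) && !is.null(node_emb) &&
      nrow(img_emb) != nrow(node_emb))
    stop("row counts differ between image and node embeddings")

  prep <- function(X) if (cfg$standardize) .standardize_block(X) else
    unclass(as.matrix(X))

  out <- switch(cfg$mode,
    image_only = reduce(img_emb, cfg$var_threshold, cfg$sparsity_cutoff),
    node_only = reduce(node_emb, cfg$var_threshold, cfg$sparsity_cutoff),
    concat_then_reduce = reduce(
      embedding_matrix(cbind(prep(img_emb), prep(node_emb))),
      cfg$var_threshold, cfg$sparsity_cutoff),
    reduce_then_concat = {
      ri <- reduce(img_emb, cfg$var_threshold, cfg$sparsity_cutoff)
      rn <- reduce(node_emb, cfg$var_threshold, cfg$sparsity_cutoff)
      embedding_matrix(cbind(prep(ri), prep(rn)))
    })
  attr(out, "method") <- sprintf("fused:%s", cfg$mode)
  out
}
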