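#' Cluster-comparison metrics
#'
#' Supervised scores comparing a predicted partition with ground truth:
#' the F-similarity-based Maximal Matching F-score (FMMF; maximum-weight
#' one-to-one matching between predicted and true clusters on pairwise
#' F-similarities), the Community-wise Maximum F-similarity F-score (CMMF;
#' per-cluster best matches without the one-to-one constraint), the Qi et
#' al. overlap-threshold F-score, and the Unbiased Sn-PPV Accuracy (UnSPA).
#' Unsupervised indices: silhouette, Calinski-Harabasz, Davies-Bouldin.
#'
#' @name evalmetrics
NULL

#' Harmonic-mean combination of precision and recall
#'
#' The F-score combination rule shared by all supervised metrics:
#' `2PR / (P + R)`, 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F-score.
#' @export
harmonic_f <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' F-similarity between two item sets
#'
#' With overlap `O = |P intersect T|`: precision `O/|P|`, recall `O/|T|`,
#' `F = 2pr/(p+r)` (0 when the overlap is empty).
#'
#' @param P,T nonempty vectors of item identifiers.
#' @return Scalar in `[0, 1]`.
#' @export
f_similarity <- function(P, T) {
  if (!length(P) || !length(T)) stop("empty cluster")
  o <- length(intersect(P, T))
  if (o == 0) return(0)
  harmonic_f(o / length(P), o / length(T))
}

# pairwise F-similarity matrix between two partitions (lists of sets)
f_similarity_matrix <- function(pred, true) {
  outer(seq_along(pred), seq_along(true),
        Vectorize(function(i, j) f_similarity(pred[[i]], true[[j]])))
}

# maximum-weight bipartite matching weight on a nonnegative matrix,
# via igraph's weighted bipartite matcher
max_weight_matching <- function(W) {
  nr <- nrow(W); nc <- ncol(W)
  el <- which(W > 0, arr.ind = TRUE)
  if (!nrow(el)) return(0)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nr), rep(TRUE, nc)),
                                    edges = as.vector(t(cbind(el[, 1],
                                                              nr + el[, 2]))))
  igraph::E(g)$weight <- W[el]
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  m$matching_weight
}

#' Maximal Matching F-score (FMMF)
#'
#' Maximum-weight one-to-one matching between predicted and true clusters
#' on the pairwise F-similarity matrix; precision divides the matched
#' weight by the number of predicted clusters, recall by the number of
#' true clusters; F is their harmonic mean.
#'
#' @param pred,true partitions: lists of item-id vectors.
#' @return Named numeric `c(precision, recall, F)`.
#' @export
#' @examples
#' fmmf(list(1:2, 3), list(1:3))
fmmf <- function(pred, true) {
  if (!length(pred) || !length(true)) stop("empty partition")
  W <- f_similarity_matrix(pred, true)
  mw <- max_weight_matching(W)
  p <- mw / length(pred); r <- mw / length(true)
  c(precision = p, recall = r, F = harmonic_f(p, r))
}

#' Community-wise Maximum F-similarity F-score (CMMF)
#'
#' Precision: mean over predicted clusters of the best F-similarity to any
#' true cluster; recall: the same with roles swapped; F: harmonic mean.
#' Always at least FMMF.
#'
#' @inheritParams fmmf
#' @return Named numeric `c(precision, recall, F)`.
#' @export
cmmf <- function(pred, true) {
  if (!length(pred) || !length(true)) stop("empty partition")
  W <- f_similarity_matrix(pred, true)
  p <- mean(apply(W, 1, max)); r <- mean(apply(W, 2, max))
  c(precision = p, recall = r, F = harmonic_f(p, r))
}

#' Overlap-threshold F-score (Qi et al.)
#'
#' A predicted cluster matches a true one when
#' `|P intersect T|^2 / (|P| |T|)` reaches `omega_threshold`; precision and
#' recall are the matched fractions on each side.
#'
#' @inheritParams fmmf
#' @param omega_threshold overlap threshold (default 0.25).
#' @return Named numeric `c(precision, recall, F)`.
#' @export
qi_fscore <- function(pred, true, omega_threshold = 0.25) {
  if (!length(pred) || !length(true)) stop("empty partition")
  omega <- outer(seq_along(pred), seq_along(true),
                 Vectorize(function(i, j) {
                   o <- length(intersect(pred[[i]], true[[j]]))
                   o^2 / (length(pred[[i]]) * length(true[[j]]))
                 }))
  hit <- omega >= omega_threshold
  p <- mean(apply(hit, 1, any)); r <- mean(apply(hit, 2, any))
  c(precision = p, recall = r, F = harmonic_f(p, r))
}

#' Unbiased Sn-PPV Accuracy (UnSPA)
#'
#' Sensitivity `Sn = sum_T max_P |T ^ P| / sum_T |T|`; unbiased positive
#' predictive value `PPV = sum_P max_T |T ^ P| / sum_P |P|`; UnSPA is
#' their geometric mean.
#'
#' @inheritParams fmmf
#' @return Scalar in `[0, 1]`.
#' @export
unspa <- function(pred, true) {
  if (!length(pred) || !length(true)) stop("empty partition")
  O <- outer(seq_along(pred), seq_along(true),
             Vectorize(function(i, j)
               length(intersect(pred[[i]], true[[j]]))))
  sn <- sum(apply(O, 2, max)) / sum(lengths(true))
  ppv <- sum(apply(O, 1, max)) / sum(lengths(pred))
  sqrt(sn * ppv)
}

#' Convert label vectors to partitions
#'
#' @param labels per-item labels; `0` or `NA` marks noise.
#' @param drop_noise drop noise items entirely instead of making each a
#'   singleton cluster.
#' @return List of item-index vectors.
#' @export
labels_to_partition <- function(labels, drop_noise = FALSE) {
  idx <- seq_along(labels)
  noise <- is.na(labels) | labels == 0
  out <- unname(split(idx[!noise], labels[!noise]))
  if (!drop_noise && any(noise))
    out <- c(out, as.list(idx[noise]))
  out
}

#' Unsupervised clustering indices
#'
#' Silhouette (under the supplied distance measure), Calinski-Harabasz and
#' Davies-Bouldin (both Euclidean, per their definitions). Noise points are
#' removed first; with fewer than two remaining clusters the scores are
#' returned as `NA` markers.
#'
#' @param emb embedding matrix.
#' @param assignment `cluster_assignment` or label vector.
#' @param measure distance measure for the silhouette.
#' @return Named numeric `c(silhouette, calinski_harabasz, davies_bouldin)`.
#' @export
unsupervised_scores <- function(emb, assignment, measure = "euclidean") {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  X <- unclass(as.matrix(emb))
  keep <- labels > 0
  X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  k <- length(unique(labels)); n <- nrow(X)
  if (k < 2 || k >= n)
    return(c(silhouette = NA_real_, calinski_harabasz = NA_real_,
             davies_bouldin = NA_real_))

  sil <- silhouette_score(pairwise_distances(X, measure), labels)

  ci <- as.integer(factor(labels))
  sizes <- as.vector(table(ci))
  centm <- rowsum(X, ci) / sizes
  gmean <- colMeans(X)
  bss <- sum(sizes * rowSums(sweep(centm, 2, gmean)^2))
  wss <- sum((X - centm[ci, , drop = FALSE])^2)
  ch <- (bss / (k - 1)) / (wss / (n - k))

  # Davies-Bouldin: mean over clusters of the worst (Si + Sj) / Mij
  S <- vapply(seq_len(k), function(i) {
    pts <- X[ci == i, , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, centm[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(dist(centm))
  db <- mean(vapply(seq_len(k), function(i) {
    r <- (S[i] + S[-i]) / M[i, -i]
    max(r)
  }, numeric(1)))

  c(silhouette = sil, calinski_harabasz = ch, davies_bouldin = db)
}

#' Full evaluation report for a predicted clustering
#'
#' @param pred `cluster_assignment` or label vector (0 = noise).
#' @param truth ground-truth label vector; `NA` marks junk/unannotated
#'   items. When junk is present the supervised metrics are reported twice:
#'   with junk as its own pseudo-complex and with junk excluded.
#' @param emb optional embedding matrix for the unsupervised indices.
#' @param measure distance measure for the silhouette.
#' @param drop_noise exclude predicted noise instead of singleton clusters.
#' @return An `eval_report` list of named metric values and cluster counts.
#' @export
evaluate_clustering <- function(pred, truth, emb = NULL,
                                measure = "euclidean", drop_noise = FALSE) {
  labels <- if (inherits(pred, "cluster_assignment")) pred$labels
            else as.integer(pred)
  stopifnot(length(labels) == length(truth))

  supervised <- function(keep, truth_lab) {
    pp <- labels_to_partition(labels[keep], drop_noise = drop_noise)
    tp <- labels_to_partition(truth_lab)
    f1 <- fmmf(pp, tp); c1 <- cmmf(pp, tp); q1 <- qi_fscore(pp, tp)
    list(fmm_precision = unname(f1["precision"]),
         fmm_recall = unname(f1["recall"]), fmmf = unname(f1["F"]),
         cmmf_precision = unname(c1["precision"]),
         cmmf_recall = unname(c1["recall"]), cmmf = unname(c1["F"]),
         qi_precision = unname(q1["precision"]),
         qi_recall = unname(q1["recall"]), qi_f = unname(q1["F"]),
         unspa = unspa(pp, tp),
         n_pred_clusters = length(pp), n_true_clusters = length(tp))
  }

  junk <- is.na(truth)
  rep_all <- supervised(rep(TRUE, length(labels)),
                        ifelse(junk, "junk", as.character(truth)))
  out <- rep_all
  if (any(junk)) {
    # indices must stay aligned after junk removal
    keep <- !junk
    sub_labels <- labels[keep]
    out$excluding_junk <- {
      pp <- labels_to_partition(sub_labels, drop_noise = drop_noise)
      tp <- labels_to_partition(as.character(truth[keep]))
      f1 <- fmmf(pp, tp)
      list(fmm_precision = unname(f1["precision"]),
           fmm_recall = unname(f1["recall"]), fmmf = unname(f1["F"]),
           cmmf = unname(cmmf(pp, tp)["F"]),
           qi_f = unname(qi_fscore(pp, tp)["F"]),
           unspa = unspa(pp, tp))
    }
  }
  if (!is.null(emb)) {
    us <- unsupervised_scores(emb, labels, measure)
    out$silhouette <- unname(us["silhouette"])
    out$calinski_harabasz <- unname(us["calinski_harabasz"])
    out$davies_bouldin <- unname(us["davies_bouldin"])
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: FMMF %.3f (P %.3f / R %.3f) | CMMF %.3f | Qi F %.3f | UnSPA %.3f\n",
    x$fmmf, x$fmm_precision, x$fmm_recall, x$cmmf, x$qi_f, x$unspa))
  cat(sprintf("  clusters: %d predicted vs %d true\n",
              x$n_pred_clusters, x$n_true_clusters))
  invisible(x)
}

#' Write an evaluation report as TSV or JSON
#'
#' @param report an `eval_report`.
#' @param path output path; format chosen by extension (`.json` or TSV
#'   otherwise).
#' @export
write_eval_report <- function(report, path) {
  flat <- unlist(report)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(flat), path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(data.frame(metric = names(flat), value = unname(flat)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
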