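#' Common-line similarity graphs
#'
#' By the projection slice theorem, two 2D projections of the same 3D object
#' share a common 1D line projection. Each image is reduced to its stack of
#' 1D line projections over a fixed angle grid; every image pair is scored
#' by the best-matching line pair under a chosen measure; per-node Z-scored
#' scores define a directed k-nearest-neighbor similarity graph.
#'
#' @name commonline
NULL

.distance_measures <- c("L1", "L2", "wasserstein")
.similarity_measures <- c("cosine", "correlation")

# cache of sparse column-sum-of-rotated-image operators, keyed by size/angle
.rot_op_cache <- new.env(parent = emptyenv())

# sparse operator S (L x H*W): S %*% vec(img) = column sums of the image
# rotated by -theta about its center (bilinear interpolation, zero padding)
rotation_colsum_operator <- function(h, w, theta_deg) {
  key <- sprintf("%d_%d_%.6f", h, w, theta_deg)
  if (!is.null(.rot_op_cache[[key]])) return(.rot_op_cache[[key]])
  th <- theta_deg * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  # output pixel (i,j) of the rotated image samples the input at the
  # back-rotated coordinate
  ij <- expand.grid(i = seq_len(h), j = seq_len(w))
  u <- ij$i - cr; v <- ij$j - cc
  us <- cos(th) * u - sin(th) * v
  vs <- sin(th) * u + cos(th) * v
  si <- us + cr; sj <- vs + cc
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (di in 0:1) for (dj in 0:1) {
    wt <- (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj)
    ii <- i0 + di; jj <- j0 + dj
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w & wt > 0
    rows <- c(rows, ij$j[ok])                 # output column index
    cols <- c(cols, ii[ok] + (jj[ok] - 1) * h) # input linear index
    vals <- c(vals, wt[ok])
  }
  op <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                             dims = c(w, h * w))
  .rot_op_cache[[key]] <- op
  op
}

#' 1D line projections of an image
#'
#' For each angle theta on the grid `[0, 180)` at `angle_step_deg` steps,
#' the signal is the vector of column sums of the image rotated by `-theta`
#' about its center (bilinear interpolation, zero padding); one row of the
#' Radon transform per angle.
#'
#' @param image square numeric matrix (pad non-square images first).
#' @param angle_step_deg angle step in degrees; must divide 180.
#' @return `A x L` matrix (A = 180 / step angles, L = image width), with
#'   attribute `angles` (degrees).
#' @export
#' @examples
#' line_projections(matrix(1:4, 2, byrow = TRUE), 90)
line_projections <- function(image, angle_step_deg = 5) {
  if (nrow(image) != ncol(image))
    stop("image must be square; pad it first")
  if (abs(180 / angle_step_deg - round(180 / angle_step_deg)) > 1e-9)
    stop("angle_step_deg must divide 180")
  angles <- seq(0, 180 - angle_step_deg, by = angle_step_deg)
  out <- matrix(0, length(angles), ncol(image))
  for (a in seq_along(angles)) {
    op <- rotation_colsum_operator(nrow(image), ncol(image), angles[a])
    out[a, ] <- as.numeric(op %*% as.vector(image))
  }
  attr(out, "angles") <- angles
  out
}

#' Line-projection stacks for a whole projection set
#'
#' @param ps a `projection_set`.
#' @param angle_step_deg angle grid step (degrees).
#' @return A `line_projection_stack`: list with `signals` (array
#'   `A x L x n`) and `angles`.
#' @export
line_projection_stack <- function(ps, angle_step_deg = 5) {
  d <- dim(ps$images)
  n <- d[1]; h <- d[2]; w <- d[3]
  if (h != w) stop("images must be square; pad them first")
  angles <- seq(0, 180 - angle_step_deg, by = angle_step_deg)
  A <- length(angles)
  imat <- matrix(ps$images, n, h * w)  # row i = vec(image i)
  sig <- array(0, dim = c(A, w, n))
  for (a in seq_len(A)) {
    op <- rotation_colsum_operator(h, w, angles[a])
    sig[a, , ] <- as.matrix(op %*% t(imat))
  }
  structure(list(signals = sig, angles = angles), class = "line_projection_stack")
}

#' Best common-line score for one image pair
#'
#' Evaluates the measure on all `A x A` pairs of line projections and
#' returns the optimum: minimum for distance measures (`L1`, `L2`,
#' `wasserstein`), maximum for similarity measures (`cosine`,
#' `correlation`). Ties are broken by the lexicographically smallest
#' `(angle_i, angle_j)`. Zero-variance signals under `correlation` (or
#' zero-norm under `cosine`) score similarity 0 and are skipped for the
#' argmax.
#'
#' @param lp_i,lp_j `A x L` line-projection matrices (equal `L`).
#' @param measure one of `"L1"`, `"L2"`, `"cosine"`, `"correlation"`,
#'   `"wasserstein"`.
#' @return list `(score, angle_i, angle_j)` with angles in degrees (taken
#'   from the `angles` attribute when present, else a 5-degree grid).
#' @export
pair_score <- function(lp_i, lp_j, measure = "L2") {
  measure <- match.arg(measure, c(.distance_measures, .similarity_measures))
  stopifnot(ncol(lp_i) == ncol(lp_j))
  A1 <- nrow(lp_i); A2 <- nrow(lp_j)
  angs_i <- attr(lp_i, "angles") %||% ((seq_len(A1) - 1) * 5)
  angs_j <- attr(lp_j, "angles") %||% ((seq_len(A2) - 1) * 5)
  is_dist <- measure %in% .distance_measures

  prep <- function(m) {
    switch(measure,
      correlation = t(scale(t(m), center = TRUE, scale = FALSE)),
      wasserstein = t(apply(m, 1, function(s) {
        s <- s - min(s)
        if (sum(s) <= 0) stop("wasserstein: zero-mass signal")
        cumsum(s / sum(s))
      })),
      m)
  }
  pi_ <- prep(lp_i); pj_ <- prep(lp_j)

  best <- if (is_dist) Inf else -Inf
  bi <- bj <- NA_integer_
  n_deg <- 0L
  for (a in seq_len(A1)) {
    si <- pi_[a, ]
    for (b in seq_len(A2)) {
      sj <- pj_[b, ]
      v <- switch(measure,
        L1 = sum(abs(si - sj)),
        L2 = sqrt(sum((si - sj)^2)),
        wasserstein = sum(abs(si - sj)),
        cosine = {
          ni <- sqrt(sum(si^2)); nj <- sqrt(sum(sj^2))
          if (ni == 0 || nj == 0) NA_real_ else sum(si * sj) / (ni * nj)
        },
        correlation = {
          ni <- sqrt(sum(si^2)); nj <- sqrt(sum(sj^2))
          if (ni == 0 || nj == 0) NA_real_ else sum(si * sj) / (ni * nj)
        })
      if (is.na(v)) { n_deg <- n_deg + 1L; next }  # degenerate: skip argmax
      if (if (is_dist) v < best else v > best) {
        best <- v; bi <- a; bj <- b
      }
    }
  }
  if (n_deg > 0)
    pc_log(sprintf("pair_score: %d degenerate signal pairs scored 0", n_deg))
  if (is.na(bi)) { best <- 0; bi <- 1L; bj <- 1L }
  list(score = best, angle_i = angs_i[bi], angle_j = angs_j[bj])
}

#' All-pairs best common-line scores
#'
#' Native-code evaluation of [pair_score()] over every image pair.
#'
#' @param lps a `line_projection_stack`.
#' @inheritParams pair_score
#' @return A `score_matrix`: list with `score`, `angle_i`, `angle_j`
#'   (`n x n` matrices, `NA` diagonal), `measure`, `angles`.
#' @export
score_matrix <- function(lps, measure = "L2") {
  measure <- match.arg(measure, c(.distance_measures, .similarity_measures))
  sig <- aperm(lps$signals, c(2, 1, 3))   # (L, A, n)
  res <- pair_scores_cpp(sig, measure)
  if (res$n_degenerate > 0)
    pc_log(sprintf("score_matrix: %d degenerate signals under %s",
                   res$n_degenerate, measure))
  ai <- matrix(lps$angles[res$ai + 1], nrow(res$ai))
  aj <- matrix(lps$angles[res$aj + 1], nrow(res$aj))
  structure(list(score = res$score, angle_i = ai, angle_j = aj,
                 measure = measure, angles = lps$angles),
            class = "score_matrix")
}

#' Build the Z-scored similarity graph
#'
#' For each source node the candidate scores against the other `n - 1`
#' nodes are Z-scored; for distance measures the stored edge weight is the
#' negated Z-score, so that larger weights always mean more similar. In
#' `top_k` mode the `k` largest-weight out-edges per node are kept
#' (directed); in `top_m_edges` mode the `m` largest-weight edges overall.
#'
#' @param sm a `score_matrix`.
#' @param mode `"top_k"` (default) or `"top_m_edges"`.
#' @param k neighbors per node (default 5).
#' @param m global edge budget for `top_m_edges` (default 3000).
#' @param global_zscore Z-score over all off-diagonal scores at once instead
#'   of per source node.
#' @return A `similarity_graph`: list with `n_nodes`, `edges` (data.frame
#'   `src, dst, raw_score, weight, angle_src, angle_dst`; 1-based indices),
#'   `directed`, `measure`, `mode`.
#' @export
build_similarity_graph <- function(sm, mode = c("top_k", "top_m_edges"),
                                   k = 5, m = 3000, global_zscore = FALSE) {
  mode <- match.arg(mode)
  s <- sm$score
  n <- nrow(s)
  is_dist <- sm$measure %in% .distance_measures

  w <- matrix(NA_real_, n, n)
  if (global_zscore) {
    off <- !diag(n)
    mu <- mean(s[off]); sg <- sd(s[off])
    if (!is.finite(sg) || sg == 0) {
      warning("zero variance of scores; weights set to 0")
      w[off] <- 0
    } else w[off] <- (s[off] - mu) / sg
  } else {
    for (i in seq_len(n)) {
      cand <- s[i, -i]
      mu <- mean(cand); sg <- sd(cand)
      if (!is.finite(sg) || sg == 0) {
        warning(sprintf("node %d: zero score variance; weights set to 0", i))
        w[i, -i] <- 0
      } else w[i, -i] <- (s[i, -i] - mu) / sg
    }
  }
  if (is_dist) w <- -w

  edges <- NULL
  if (mode == "top_k") {
    if (k >= n) {
      warning("k >= n - 1: keeping all edges")
      k <- n - 1
    }
    rows <- lapply(seq_len(n), function(i) {
      ord <- order(-w[i, ], seq_len(n))
      ord <- ord[ord != i][seq_len(k)]
      data.frame(src = i, dst = ord, raw_score = s[i, ord],
                 weight = w[i, ord], angle_src = sm$angle_i[i, ord],
                 angle_dst = sm$angle_j[i, ord])
    })
    edges <- do.call(rbind, rows)
  } else {
    idx <- which(!diag(n))
    ord <- idx[order(-w[idx])]
    ord <- ord[seq_len(min(m, length(ord)))]
    src <- ((ord - 1) %% n) + 1
    dst <- ((ord - 1) %/% n) + 1
    edges <- data.frame(src = src, dst = dst, raw_score = s[ord],
                        weight = w[ord],
                        angle_src = sm$angle_i[ord], angle_dst = sm$angle_j[ord])
  }
  rownames(edges) <- NULL
  structure(list(n_nodes = n, edges = edges, directed = TRUE,
                 measure = sm$measure, mode = mode),
            class = "similarity_graph")
}

#' Symmetrize a directed similarity graph
#'
#' The undirected edge `{u, v}` exists iff either directed edge exists; its
#' weight (and carried attributes) come from the larger-weight direction.
#' Idempotent.
#'
#' @param g a `similarity_graph`.
#' @return Undirected `similarity_graph`.
#' @export
symmetrize <- function(g) {
  e <- g$edges
  lo <- pmin(e$src, e$dst); hi <- pmax(e$src, e$dst)
  key <- paste(lo, hi)
  keep <- unlist(lapply(split(seq_len(nrow(e)), key), function(ix) {
    ix[which.max(e$weight[ix])]
  }), use.names = FALSE)
  out <- e[sort(keep), ]
  sw <- out$src > out$dst
  if (any(sw)) {
    tmp <- out$src[sw]; out$src[sw] <- out$dst[sw]; out$dst[sw] <- tmp
    tmp <- out$angle_src[sw]; out$angle_src[sw] <- out$angle_dst[sw]
    out$angle_dst[sw] <- tmp
  }
  rownames(out) <- NULL
  structure(list(n_nodes = g$n_nodes, edges = out, directed = FALSE,
                 measure = g$measure, mode = g$mode),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d nodes, %d %s edges (%s, %s)\n",
              x$n_nodes, nrow(x$edges),
              if (x$directed) "directed" else "undirected",
              x$measure, x$mode))
  invisible(x)
}

#' Convert a similarity graph to igraph
#'
#' @param g a `similarity_graph`.
#' @return An igraph object with a `weight` edge attribute.
#' @export
graph_to_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$edges[, c("src", "dst", "weight", "raw_score")],
    directed = g$directed,
    vertices = data.frame(name = seq_len(g$n_nodes)))
}

#' Export / import similarity graphs
#'
#' TSV edge lists carry `src dst raw_score weight angle_src angle_dst`
#' (0-based node indices on disk); GraphML export goes through igraph.
#'
#' @param g a `similarity_graph`.
#' @param path output file.
#' @export
write_graph_tsv <- function(g, path) {
  e <- g$edges
  e$src <- e$src - 1L; e$dst <- e$dst - 1L
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @param n_nodes node count (defaults to `max(index) + 1`).
#' @param measure,directed metadata for the imported graph (e.g. a
#'   precomputed common-line edge list from another tool).
#' @export
read_graph_tsv <- function(path, n_nodes = NULL, measure = "L2",
                           directed = TRUE) {
  e <- read.delim(path)
  need <- c("src", "dst", "raw_score", "weight")
  if (!all(need %in% names(e)))
    stop("graph TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(e$angle_src)) e$angle_src <- NA_real_
  if (is.null(e$angle_dst)) e$angle_dst <- NA_real_
  e$src <- e$src + 1L; e$dst <- e$dst + 1L
  n <- n_nodes %||% max(e$src, e$dst)
  structure(list(n_nodes = n,
                 edges = e[, c("src", "dst", "raw_score", "weight",
                               "angle_src", "angle_dst")],
                 directed = directed, measure = measure, mode = "imported"),
            class = "similarity_graph")
}

#' @rdname write_graph_tsv
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(graph_to_igraph(g), path, format = "graphml")
  invisible(path)
}
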