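#' Clustering embeddings and similarity graphs
#'
#' Four spatial clusterers over a selectable distance measure — all chosen
#' so the number of clusters need not be known in advance — plus eight graph
#' community methods over the similarity graph. Hyperparameters are tuned
#' by exhaustive grid search maximizing the matching-based F-score on the
#' training complexes; the distance measure is chosen by the best silhouette
#' of the ground-truth training classes.
#'
#' @name clustering
NULL

#' Hyperparameter grids for the spatial clusterers
#'
#' DBSCAN: eps 0.25–3 by 0.25, min_samples 2–10; OPTICS: max_eps 0.25–3 by
#' 0.25, min_samples 2–10; BIRCH: threshold 0.1–1 by 0.1, branching_factor
#' 10–100 by 10; Affinity Propagation: damping 0.5–1 by 0.1.
#'
#' @return Named list of per-algorithm parameter grids (data frames, rows
#'   in search order).
#' @export
default_search_space <- function() {
  list(
    dbscan = expand.grid(min_samples = 2:10,
                         eps = seq(0.25, 3, by = 0.25))[, c("eps", "min_samples")],
    optics = expand.grid(min_samples = 2:10,
                         max_eps = seq(0.25, 3, by = 0.25))[, c("max_eps", "min_samples")],
    birch = expand.grid(branching_factor = seq(10, 100, by = 10),
                        threshold = seq(0.1, 1, by = 0.1))[, c("threshold", "branching_factor")],
    affinity = data.frame(damping = seq(0.5, 1, by = 0.1)))
}

#' Cluster assignment constructor
#'
#' @param labels integer labels, `0` marking noise/unassigned; cluster ids
#'   are renumbered to be contiguous.
#' @param algorithm,params,measure provenance.
#' @export
cluster_assignment <- function(labels, algorithm = "unknown",
                               params = list(), measure = NULL) {
  labels <- as.integer(labels)
  pos <- labels > 0
  labels[pos] <- as.integer(factor(labels[pos]))
  structure(list(labels = labels, algorithm = algorithm, params = params,
                 measure = measure,
                 n_clusters = length(unique(labels[pos]))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %s, %d clusters, %d noise point(s)\n",
              x$algorithm, x$n_clusters, sum(x$labels == 0)))
  invisible(x)
}

# ---- spatial clusterers (distance-matrix based) ---------------------------

#' DBSCAN over a precomputed distance matrix
#'
#' A point is core if at least `min_samples` points (itself included) lie
#' within `eps`; clusters are the connected components of core points under
#' eps-reachability, border points join the first cluster that claims them,
#' the rest are noise (label 0).
#'
#' @param dmat distance matrix.
#' @param eps neighborhood radius.
#' @param min_samples density threshold.
#' @return `cluster_assignment`.
#' @export
dbscan_fit <- function(dmat, eps, min_samples) {
  d <- as.matrix(dmat)
  n <- nrow(d)
  nb <- d <= eps
  core <- rowSums(nb) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      if (!core[p]) next
      reach <- which(nb[p, ] & labels == 0L)
      labels[reach] <- cl
      queue <- c(queue, reach[core[reach]])
    }
  }
  cluster_assignment(labels, "dbscan",
                     list(eps = eps, min_samples = min_samples))
}

#' OPTICS over a precomputed distance matrix
#'
#' Computes the reachability ordering (core distance = distance to the
#' `min_samples`-th nearest neighbor, the point itself included) and
#' extracts clusters at the `max_eps` threshold (DBSCAN-equivalent
#' extraction): a point whose reachability exceeds `max_eps` starts a new
#' cluster if its own core distance is within `max_eps`, else it is noise.
#'
#' @param dmat distance matrix.
#' @param max_eps maximum neighborhood radius.
#' @param min_samples density threshold.
#' @return `cluster_assignment`; the visit `order` and `reachability`
#'   values are attached as attributes.
#' @export
optics_fit <- function(dmat, max_eps, min_samples) {
  d <- as.matrix(dmat)
  n <- nrow(d)
  core_dist <- apply(d, 1, function(r) sort(r)[min_samples])
  core_dist[core_dist > max_eps] <- Inf
  reach <- rep(Inf, n)
  processed <- rep(FALSE, n)
  ordering <- integer(0)

  for (start in seq_len(n)) {
    if (processed[start]) next
    seeds <- start
    seed_r <- Inf
    while (length(seeds)) {
      j <- which.min(seed_r)
      p <- seeds[j]
      seeds <- seeds[-j]; seed_r <- seed_r[-j]
      if (processed[p]) next
      processed[p] <- TRUE
      ordering <- c(ordering, p)
      if (is.finite(core_dist[p])) {
        nbrs <- which(d[p, ] <= max_eps & !processed)
        if (length(nbrs)) {
          newr <- pmax(core_dist[p], d[p, nbrs])
          upd <- newr < reach[nbrs]
          reach[nbrs[upd]] <- newr[upd]
          seeds <- c(seeds, nbrs[upd])
          seed_r <- c(seed_r, reach[nbrs[upd]])
          keep <- !duplicated(seeds, fromLast = TRUE)
          seed_r <- reach[seeds][keep]
          seeds <- seeds[keep]
        }
      }
    }
  }

  labels <- integer(n)
  cl <- 0L
  for (p in ordering) {
    if (reach[p] > max_eps) {
      if (is.finite(core_dist[p])) {
        cl <- cl + 1L
        labels[p] <- cl
      }                                  # else noise
    } else {
      if (cl == 0L) cl <- 1L
      labels[p] <- cl
    }
  }
  out <- cluster_assignment(labels, "optics",
                            list(max_eps = max_eps,
                                 min_samples = min_samples))
  attr(out, "order") <- ordering
  attr(out, "reachability") <- reach
  out
}

#' Compact CF-subcluster clustering (BIRCH-style)
#'
#' Single-pass clustering-feature variant: each point joins the nearest
#' subcluster if the merged subcluster's radius stays within `threshold`,
#' otherwise starts a new one; when the number of subclusters exceeds
#' `branching_factor` the subclusters are rebuilt at a 1.5x larger
#' threshold. Points are finally assigned to the nearest subcluster
#' centroid (no global clustering step).
#'
#' @param X embedding matrix (rows = points).
#' @param threshold subcluster radius limit.
#' @param branching_factor maximum number of subclusters before a rebuild.
#' @return `cluster_assignment`.
#' @export
birch_fit <- function(X, threshold, branching_factor) {
  X <- unclass(as.matrix(X))
  n <- nrow(X)
  cf <- list()  # each: list(n, ls, ss)

  merged_radius <- function(a, x) {
    nn <- a$n + 1
    ls <- a$ls + x
    ss <- a$ss + sum(x^2)
    sqrt(max(ss / nn - sum((ls / nn)^2), 0))
  }
  merge_cf <- function(a, b) list(n = a$n + b$n, ls = a$ls + b$ls,
                                  ss = a$ss + b$ss)
  cf_radius <- function(a) sqrt(max(a$ss / a$n - sum((a$ls / a$n)^2), 0))

  rebuild <- function(cf, thr) {
    out <- list()
    for (a in cf) {
      placed <- FALSE
      if (length(out)) {
        cents <- t(vapply(out, function(b) b$ls / b$n, numeric(ncol(X))))
        dd <- sqrt(colSums((t(cents) - a$ls / a$n)^2))
        j <- which.min(dd)
        cand <- merge_cf(out[[j]], a)
        if (cf_radius(cand) <= thr) {
          out[[j]] <- cand
          placed <- TRUE
        }
      }
      if (!placed) out[[length(out) + 1]] <- a
    }
    out
  }

  thr <- threshold
  for (i in seq_len(n)) {
    x <- X[i, ]
    placed <- FALSE
    if (length(cf)) {
      cents <- t(vapply(cf, function(b) b$ls / b$n, numeric(ncol(X))))
      dd <- sqrt(colSums((t(cents) - x)^2))
      j <- which.min(dd)
      if (merged_radius(cf[[j]], x) <= thr) {
        cf[[j]] <- list(n = cf[[j]]$n + 1, ls = cf[[j]]$ls + x,
                        ss = cf[[j]]$ss + sum(x^2))
        placed <- TRUE
      }
    }
    if (!placed) cf[[length(cf) + 1]] <- list(n = 1, ls = x, ss = sum(x^2))
    while (length(cf) > branching_factor) {
      thr <- thr * 1.5
      cf <- rebuild(cf, thr)
    }
  }

  cents <- t(vapply(cf, function(b) b$ls / b$n, numeric(ncol(X))))
  labels <- apply(X, 1, function(x) which.min(colSums((t(cents) - x)^2)))
  cluster_assignment(labels, "birch",
                     list(threshold = threshold,
                          branching_factor = branching_factor))
}

#' Affinity propagation over a precomputed distance matrix
#'
#' Standard responsibility/availability message passing on the similarity
#' `S = -d^2` with the median off-diagonal similarity as preference.
#' Converges when the exemplar set is stable for `convergence_iter` sweeps;
#' non-convergence is flagged via the `converged` attribute (tuning treats
#' it as a failed grid point).
#'
#' @param dmat distance matrix.
#' @param damping damping factor in `[0.5, 1)`.
#' @param max_iter,convergence_iter iteration controls.
#' @return `cluster_assignment` with attribute `converged`.
#' @export
affinity_fit <- function(dmat, damping, max_iter = 200,
                         convergence_iter = 15) {
  d <- as.matrix(dmat)
  n <- nrow(d)
  S <- -d^2
  diag(S) <- NA
  pref <- median(S, na.rm = TRUE)
  diag(S) <- pref
  if (damping >= 1) {
    out <- cluster_assignment(integer(n), "affinity",
                              list(damping = damping))
    attr(out, "converged") <- FALSE
    return(out)
  }

  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L
  last_ex <- integer(0)
  for (it in seq_len(max_iter)) {
    AS <- A + S
    m1 <- apply(AS, 1, max)
    i1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), i1)] <- -Inf
    m2 <- apply(AS2, 1, max)
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), i1)] <- S[cbind(seq_len(n), i1)] - m2
    R <- damping * R + (1 - damping) * Rnew

    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(pmin(0, rep(colsum, each = n) - Rp), n, n)
    diag(Anew) <- colSums(pmax(R, 0)) - pmax(diag(R), 0)  # sum_{i'!=k} max(0,R)
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(A + R) > 0)
    if (identical(ex, last_ex) && length(ex)) stable <- stable + 1L
    else stable <- 0L
    last_ex <- ex
    if (stable >= convergence_iter) break
  }
  converged <- stable >= convergence_iter && length(last_ex) > 0

  labels <- integer(n)
  if (length(last_ex)) {
    labels <- last_ex[max.col(S[, last_ex, drop = FALSE],
                              ties.method = "first")]
    labels[last_ex] <- last_ex
    labels <- as.integer(factor(labels))
  }
  out <- cluster_assignment(labels, "affinity", list(damping = damping))
  attr(out, "converged") <- converged
  out
}

# ---- model selection -------------------------------------------------------

#' Choose the best distance measure by training-class silhouette
#'
#' Evaluates each candidate on the training rows: the silhouette of the
#' ground-truth training classes under that measure. Candidates that are
#' undefined on the data are skipped with a log entry; ties keep the first
#' candidate in canonical order.
#'
#' @param emb embedding matrix.
#' @param train_idx row indices of the training images.
#' @param truth per-image ground-truth labels (full length).
#' @param candidates measure names (default all 22).
#' @return The winning measure name; per-candidate silhouettes in attribute
#'   `scores`.
#' @export
select_distance <- function(emb, train_idx, truth,
                            candidates = distance_measures()) {
  Xt <- unclass(as.matrix(emb))[train_idx, , drop = FALSE]
  yt <- truth[train_idx]
  if (length(unique(yt)) < 2) stop("need >= 2 training classes")
  scores <- setNames(rep(NA_real_, length(candidates)), candidates)
  for (ms in candidates) {
    scores[ms] <- tryCatch(
      silhouette_score(pairwise_distances(Xt, ms), yt),
      error = function(e) {
        pc_log(sprintf("select_distance: %s skipped (%s)", ms,
                       conditionMessage(e)))
        NA_real_
      })
  }
  if (all(is.na(scores))) stop("no distance measure is defined on the data")
  best <- candidates[which.max(scores)]
  attr(best, "scores") <- scores
  best
}

#' Grid-search a clusterer against training-complex F-score
#'
#' Exhaustively evaluates the algorithm's hyperparameter grid: each fit
#' runs on all points; the matching-based F-score (FMMF) restricted to the
#' training images picks the winner. Ties prefer higher silhouette, then
#' fewer clusters, then the earlier grid point. Noise points count as
#' singleton clusters during scoring (set `drop_noise = TRUE` to exclude
#' them instead).
#'
#' @param emb embedding matrix.
#' @param algo `"dbscan"`, `"optics"`, `"birch"` or `"affinity"`.
#' @param space grid list from [default_search_space()].
#' @param measure distance measure name.
#' @param train_idx training row indices.
#' @param train_truth ground-truth labels for `train_idx` (same length).
#' @param drop_noise exclude noise points from evaluation instead of
#'   treating them as singletons.
#' @return The winning `cluster_assignment`, with the tuning table in
#'   attribute `tuning`.
#' @export
tune_and_fit <- function(emb, algo = c("dbscan", "optics", "birch",
                                       "affinity"),
                         space = default_search_space(), measure = "euclidean",
                         train_idx, train_truth, drop_noise = FALSE) {
  algo <- match.arg(algo)
  grid <- space[[algo]]
  X <- unclass(as.matrix(emb))
  dmat <- if (algo != "birch") pairwise_distances(X, measure) else NULL

  best <- NULL; best_key <- c(-Inf, -Inf, Inf)
  rows <- list()
  for (gi in seq_len(nrow(grid))) {
    prm <- as.list(grid[gi, , drop = FALSE])
    fit <- tryCatch(switch(algo,
      dbscan = dbscan_fit(dmat, prm$eps, prm$min_samples),
      optics = optics_fit(dmat, prm$max_eps, prm$min_samples),
      birch = birch_fit(X, prm$threshold, prm$branching_factor),
      affinity = affinity_fit(dmat, prm$damping)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (algo == "affinity" && !isTRUE(attr(fit, "converged"))) next

    sc <- fmmf(labels_to_partition(fit$labels[train_idx],
                                   drop_noise = drop_noise),
               labels_to_partition(train_truth))["F"]
    sil <- tryCatch(silhouette_score(
      if (is.null(dmat)) pairwise_distances(X, measure) else dmat,
      ifelse(fit$labels == 0, paste0("n", seq_along(fit$labels)),
             fit$labels)),
      error = function(e) -Inf)
    rows[[length(rows) + 1]] <-
      cbind(as.data.frame(prm), fmmf_train = unname(sc),
            silhouette = sil, n_clusters = fit$n_clusters)
    key <- c(sc, sil, -fit$n_clusters)
    if (is.null(best) ||
        key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] &&
         key[3] > best_key[3])) {
      best <- fit; best_key <- key
    }
  }
  if (is.null(best)) {
    warning("no grid point produced a usable clustering; returning all-noise")
    best <- cluster_assignment(integer(nrow(X)), algo, list())
  }
  if (best$n_clusters <= 1)
    warning("tuned model yields <= 1 cluster")
  best$measure <- measure
  attr(best, "tuning") <- do.call(rbind, rows)
  best
}

# ---- graph clustering ------------------------------------------------------

.graph_methods <- c("scc", "wcc", "walktrap", "edge_betweenness",
                    "greedy_modularity", "k_clique", "label_prop_semisync",
                    "label_prop_async")

#' Cluster the similarity graph directly
#'
#' Eight community methods: strongly/weakly connected components, walktrap
#' (4 steps), edge betweenness, greedy modularity, k-clique percolation,
#' and semi-synchronous / asynchronous label propagation. Methods defined
#' only for undirected graphs symmetrize the input first (logged). Edge
#' weights are shifted positive for weight-using methods; edge betweenness
#' receives them converted to distances (`max(w) - w + eps`).
#'
#' @param g a `similarity_graph`.
#' @param method one of the eight method names.
#' @param params method parameters (`k` for `k_clique`, default 3;
#'   `steps` for walktrap, default 4).
#' @param seed seed for the stochastic label-propagation methods.
#' @return `cluster_assignment`.
#' @export
graph_cluster <- function(g, method = .graph_methods, params = list(),
                          seed = 0) {
  method <- match.arg(method)
  n <- g$n_nodes

  undirected_ig <- function() {
    gu <- if (g$directed) {
      pc_log(sprintf("graph_cluster(%s): symmetrizing directed graph",
                     method))
      symmetrize(g)
    } else g
    ig <- graph_to_igraph(gu)
    w <- igraph::E(ig)$weight
    if (length(w) && min(w) <= 0)
      igraph::E(ig)$weight <- w - min(w) + 1e-6
    ig
  }

  labels <- switch(method,
    scc = igraph::components(graph_to_igraph(g), mode = "strong")$membership,
    wcc = igraph::components(graph_to_igraph(g), mode = "weak")$membership,
    walktrap = igraph::membership(igraph::cluster_walktrap(
      undirected_ig(), steps = params$steps %||% 4)),
    edge_betweenness = {
      ig <- undirected_ig()
      w <- igraph::E(ig)$weight
      igraph::E(ig)$weight <- max(w) - w + 1e-6  # similarities -> distances
      igraph::membership(igraph::cluster_edge_betweenness(ig))
    },
    greedy_modularity = igraph::membership(igraph::cluster_fast_greedy(
      igraph::simplify(undirected_ig(),
                       edge.attr.comb = list(weight = "max", "ignore")))),
    k_clique = {
      ig <- igraph::simplify(undirected_ig())
      k <- params$k %||% 3
      cl <- igraph::cliques(ig, min = k)
      memb <- integer(n)
      if (length(cl)) {
        cl <- lapply(cl, as.integer)
        nc <- length(cl)
        # percolation: cliques sharing k-1 nodes are in one community
        adj <- matrix(FALSE, nc, nc)
        for (i in seq_len(nc)) for (j in seq_len(nc)) {
          if (i < j &&
              length(intersect(cl[[i]], cl[[j]])) >= k - 1)
            adj[i, j] <- adj[j, i] <- TRUE
        }
        cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
        comp <- igraph::components(cg)$membership
        for (i in order(comp)) {
          for (v in cl[[i]]) if (memb[v] == 0) memb[v] <- comp[i]
        }
      }
      # non-members become singleton clusters
      nxt <- max(memb, 0)
      for (v in which(memb == 0)) { nxt <- nxt + 1; memb[v] <- nxt }
      memb
    },
    label_prop_async = with_seed(seed, igraph::membership(
      igraph::cluster_label_prop(undirected_ig()))),
    label_prop_semisync = {
      ig <- undirected_ig()
      semisync_label_prop(ig, seed)
    })

  cluster_assignment(as.integer(labels), paste0("graph:", method),
                     params = params)
}

# semi-synchronous label propagation: nodes are greedily colored; color
# classes (independent sets) update their labels synchronously, so no
# node updates simultaneously with a neighbor
semisync_label_prop <- function(ig, seed = 0, max_sweeps = 100) {
  n <- igraph::vcount(ig)
  adj <- igraph::as_adj_list(ig)
  w <- igraph::E(ig)$weight %||% rep(1, igraph::ecount(ig))
  inc <- igraph::as_adj_edge_list(ig)
  coloring <- integer(n)
  for (v in seq_len(n)) {
    used <- coloring[as.integer(adj[[v]])]
    coloring[v] <- min(setdiff(seq_len(n), used))
  }
  labels <- seq_len(n)
  with_seed(seed, {
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      for (col in sort(unique(coloring))) {
        newlab <- labels
        for (v in which(coloring == col)) {
          nb <- as.integer(adj[[v]])
          if (!length(nb)) next
          ew <- w[as.integer(inc[[v]])]
          tab <- tapply(ew, labels[nb], sum)
          mx <- names(tab)[tab == max(tab)]
          pick <- if (as.character(labels[v]) %in% mx) labels[v]
                  else as.integer(sample(mx, 1))
          if (pick != labels[v]) changed <- TRUE
          newlab[v] <- pick
        }
        labels <- newlab
      }
      if (!changed) break
    }
  })
  labels
}

# ---- cluster file IO -------------------------------------------------------

#' Write / read cluster files
#'
#' One line per cluster: space-separated 0-based image indices; noise
#' points, if any, go under a reserved `#NOISE` header line.
#'
#' @param assignment a `cluster_assignment` (or bare label vector).
#' @param path file path.
#' @export
write_clusters <- function(assignment, path) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  con <- file(path, "w"); on.exit(close(con))
  for (cl in sort(unique(labels[labels > 0])))
    writeLines(paste(which(labels == cl) - 1, collapse = " "), con)
  if (any(labels == 0)) {
    writeLines("#NOISE", con)
    writeLines(paste(which(labels == 0) - 1, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_clusters
#' @param n total number of items (defaults to the largest index + 1).
#' @export
read_clusters <- function(path, n = NULL) {
  lines <- readLines(path)
  labels <- integer(0)
  cl <- 0L; noise_mode <- FALSE
  for (ln in lines) {
    if (grepl("^#NOISE", ln)) { noise_mode <- TRUE; next }
    if (!nzchar(trimws(ln))) next
    idx <- as.integer(strsplit(trimws(ln), "\\s+")[[1]]) + 1L
    if (noise_mode) labels[idx] <- 0L
    else { cl <- cl + 1L; labels[idx] <- cl }
  }
  n <- n %||% length(labels)
  labels[is.na(labels)] <- 0L
  length(labels) <- n
  labels[is.na(labels)] <- 0L
  cluster_assignment(labels, "file")
}
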