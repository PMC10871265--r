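blobs3 <- function(n_per = 15, sep = 8, d = 3, sd = 0.3, seed = 2) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per),
             matrix(rnorm(n_per * d, sep, sd), n_per),
             matrix(rnorm(n_per * d, -sep, sd), n_per))
  list(X = X, y = rep(1:3, each = n_per))
}

test_that("search grids match their printed ranges", {
  sp <- default_search_space()
  expect_equal(nrow(sp$dbscan), 12 * 9)  # eps 0.25..3 x min_samples 2..10
  expect_setequal(unique(sp$dbscan$eps), seq(0.25, 3, 0.25))
  expect_setequal(unique(sp$dbscan$min_samples), 2:10)
  expect_equal(nrow(sp$optics), 12 * 9)
  expect_equal(nrow(sp$birch), 10 * 10)
  expect_setequal(unique(sp$birch$threshold), seq(0.1, 1, 0.1))
  expect_setequal(unique(sp$birch$branching_factor), seq(10, 100, 10))
  expect_equal(sp$affinity$damping, seq(0.5, 1, 0.1))
})

test_that("distance selection maximizes training-class silhouette", {
  b <- blobs3()
  sel <- select_distance(b$X, seq_len(45), b$y)
  scores <- attr(sel, "scores")
  expect_gt(max(scores, na.rm = TRUE), 0.5)
  expect_equal(as.character(sel),
               names(scores)[which.max(scores)])
  # deterministic
  expect_equal(as.character(select_distance(b$X, seq_len(45), b$y)),
               as.character(sel))
  # undefined measures are skipped, not fatal (e.g. mahalanobis on n < d)
  set.seed(1)
  wide <- matrix(rnorm(8 * 20), 8, 20)
  sel2 <- select_distance(wide, 1:8, rep(1:2, each = 4))
  expect_true(is.na(attr(sel2, "scores")["mahalanobis"]))

  expect_error(select_distance(matrix(1, 10, 3), 1:10,
                               rep(1:2, each = 5)), "no distance measure")
})

test_that("spatial clusterers recover three separated blobs", {
  b <- blobs3()
  d <- pairwise_distances(b$X, "euclidean")
  for (fit in list(dbscan_fit(d, 2, 3), optics_fit(d, 2, 3),
                   birch_fit(b$X, 0.9, 50), affinity_fit(d, 0.7))) {
    expect_equal(fit$n_clusters, 3)
    agree <- fmmf(labels_to_partition(fit$labels),
                  labels_to_partition(b$y))["F"]
    expect_equal(unname(agree), 1)
  }
  # DBSCAN marks far-away points as noise
  Xo <- rbind(b$X, c(50, 50, 50))
  do <- pairwise_distances(Xo, "euclidean")
  fo <- dbscan_fit(do, 2, 3)
  expect_equal(fo$labels[46], 0L)

  # non-converged affinity propagation is flagged
  af1 <- affinity_fit(d, 1)
  expect_false(attr(af1, "converged"))
})

test_that("tuning finds a perfect grid point on separable data", {
  b <- blobs3()
  tr <- seq_len(45)  # all points; training truth known
  fit <- tune_and_fit(b$X, "dbscan", measure = "euclidean",
                      train_idx = tr, train_truth = b$y)
  tab <- attr(fit, "tuning")
  expect_equal(max(tab$fmmf_train), 1)
  # returned parameters come from the printed grid
  sp <- default_search_space()$dbscan
  expect_true(any(sp$eps == fit$params$eps &
                  sp$min_samples == fit$params$min_samples))
  expect_equal(unname(fmmf(labels_to_partition(fit$labels),
                           labels_to_partition(b$y))["F"]), 1)

  fitb <- tune_and_fit(b$X, "birch", measure = "euclidean",
                       train_idx = tr, train_truth = b$y)
  expect_true(fitb$params$threshold %in% seq(0.1, 1, 0.1))
})

test_that("graph clustering covers every node exactly once", {
  tri2 <- manual_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                             c(4, 5), c(5, 6), c(4, 6)), 6)
  fit <- graph_cluster(tri2, "wcc")
  expect_equal(fit$n_clusters, 2)
  expect_length(fit$labels, 6)
  expect_true(all(fit$labels > 0))

  # walktrap and edge betweenness recover disjoint cliques exactly
  g2 <- clique_graph(c(5, 5))
  truth <- labels_to_partition(rep(1:2, each = 5))
  for (m in c("walktrap", "edge_betweenness", "greedy_modularity")) {
    fit <- suppressWarnings(graph_cluster(g2, m))
    expect_equal(unname(fmmf(labels_to_partition(fit$labels), truth)["F"]),
                 1, info = m)
  }

  # two 5-cliques joined by one bridge: label propagation is stable
  bridged <- manual_graph(rbind(do.call(rbind, lapply(list(0, 5), function(o)
    t(combn(o + 1:5, 2)))), c(5, 6)), 10)
  for (s in 1:10) {
    fit <- graph_cluster(bridged, "label_prop_async", seed = s)
    expect_equal(fit$n_clusters, 2)
  }
  fit_ss <- graph_cluster(bridged, "label_prop_semisync", seed = 1)
  expect_equal(fit_ss$n_clusters, 2)

  # SCC equals a brute-force reachability oracle on a directed graph
  gd <- manual_graph(rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 4)),
                     5, directed = TRUE)
  fit <- graph_cluster(gd, "scc")
  reach <- function(a, b, E) {
    seen <- a; frontier <- a
    while (length(frontier)) {
      nxt <- setdiff(E$dst[E$src %in% frontier], seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    b %in% seen
  }
  for (i in 1:5) for (j in 1:5) {
    same <- fit$labels[i] == fit$labels[j]
    oracle <- reach(i, j, gd$edges) && reach(j, i, gd$edges)
    expect_equal(same, oracle)
  }

  # k-clique percolation: triangles found, stragglers become singletons
  kc <- graph_cluster(manual_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                                         c(3, 4)), 4), "k_clique",
                      params = list(k = 3))
  expect_equal(kc$labels[1], kc$labels[2])
  expect_false(kc$labels[4] == kc$labels[1])

  expect_error(graph_cluster(tri2, "louvain"), "arg")
})

test_that("cluster files round-trip including the noise section", {
  ca <- cluster_assignment(c(1, 1, 2, 2, 0, 2, 3))
  f <- tempfile()
  write_clusters(ca, f)
  back <- read_clusters(f, n = 7)
  expect_equal(back$labels[5], 0L)
  expect_equal(unname(fmmf(labels_to_partition(back$labels),
                           labels_to_partition(ca$labels))["F"]), 1)
})
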