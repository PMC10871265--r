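test_that("node2vec embeds cliques coherently and is seeded", {
  g <- clique_graph(c(6, 6))
  prm <- node_embedding_params("node2vec", dim = 16, walks_per_node = 8,
                               walk_length = 20, window = 5, seed = 1)
  emb <- node2vec_embed(g, prm)
  expect_equal(dim(unclass(emb)), c(12, 16))
  expect_true(all(is.finite(emb)))

  emb2 <- node2vec_embed(g, prm)
  expect_identical(unclass(emb), unclass(emb2))

  E <- unclass(emb)
  En <- E / sqrt(rowSums(E^2))
  S <- En %*% t(En)
  within <- c(S[1:6, 1:6][upper.tri(S[1:6, 1:6])],
              S[7:12, 7:12][upper.tri(S[7:12, 7:12])])
  across <- S[1:6, 7:12]
  expect_gt(mean(within), mean(across))

  # isolated node: zero vector with a warning
  gi <- manual_graph(rbind(c(1, 2), c(2, 1)), 3, directed = TRUE)
  expect_warning(e3 <- node2vec_embed(gi, prm), "isolated")
  expect_true(all(e3[3, ] == 0))
})

test_that("graphwave respects graph automorphisms", {
  prm <- node_embedding_params("graphwave", n_sample_points = 50,
                               scales = c(5, 10))
  # vertex-transitive ring: all rows identical
  gw <- graphwave_embed(ring_graph(8), prm)
  expect_equal(ncol(gw), 2 * 50 * 2)  # dimension formula
  expect_lt(max(abs(sweep(unclass(gw), 2, gw[1, ]))), 1e-8)

  # star: all leaves identical, hub distinct
  gs <- graphwave_embed(star_graph(5), prm)
  leaves <- unclass(gs)[2:6, ]
  expect_lt(max(abs(sweep(leaves, 2, leaves[1, ]))), 1e-8)
  expect_gt(max(abs(gs[1, ] - gs[2, ])), 1e-6)

  # disconnected graphs are allowed
  gd <- manual_graph(rbind(c(1, 2), c(3, 4)), 4)
  expect_true(all(is.finite(graphwave_embed(gd, prm))))
})

test_that("DGI separates attribute-distinct cliques and is seeded", {
  g <- clique_graph(c(6, 6))
  set.seed(1)
  attrs <- rbind(matrix(rnorm(6 * 4, 2), 6), matrix(rnorm(6 * 4, -2), 6))
  prm <- node_embedding_params("dgi-gcn", dim = 16, dgi_epochs = 60, seed = 1)
  emb <- dgi_gcn_embed(g, attrs, prm)
  expect_equal(dim(unclass(emb)), c(12, 16))
  expect_true(all(is.finite(emb)))
  expect_identical(unclass(dgi_gcn_embed(g, attrs, prm)), unclass(emb))

  E <- unclass(emb)
  En <- E / sqrt(rowSums(E^2))
  S <- En %*% t(En)
  within <- c(S[1:6, 1:6][upper.tri(S[1:6, 1:6])],
              S[7:12, 7:12][upper.tri(S[7:12, 7:12])])
  expect_gt(mean(within), mean(S[1:6, 7:12]))

  expect_error(dgi_gcn_embed(g, attrs[1:5, ], prm), "row per graph node")
})

test_that("the embedding interface accepts user plug-ins", {
  g <- clique_graph(c(3, 3))
  custom <- function(g, params) embedding_matrix(
    matrix(seq_len(g$n_nodes * 2), g$n_nodes, 2), method = "node:custom")
  prm <- node_embedding_params("node2vec", dim = 4, seed = 1)
  prm$method <- custom
  out <- node_embed(g, prm)
  expect_equal(dim(unclass(out)), c(6, 2))
  expect_equal(attr(out, "method"), "node:custom")
})
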