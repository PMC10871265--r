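test_that("line projections are Radon rows: base cases and mass", {
  m <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  lp <- line_projections(m, 90)
  expect_equal(lp[1, ], c(4, 6))  # theta = 0: plain column sums

  expect_error(line_projections(matrix(0, 2, 3)), "square")
  expect_error(line_projections(matrix(0, 4, 4), 7), "divide")

  # centered particle images conserve mass at every angle
  ps <- fixture_ps()
  for (i in c(1, 9, 20)) {
    img <- ps$images[i, , ]
    lp <- line_projections(img)
    expect_lt(max(abs(rowSums(lp) - sum(img))) / sum(img), 1e-2)
  }
})

test_that("line projections match the naive per-pixel rotation oracle", {
  set.seed(3)
  img <- matrix(runif(64), 8)
  lp <- line_projections(img)
  naive <- naive_line_projections(img)
  expect_lt(max(abs(lp - naive)), 1e-9)

  # quarter-turn: signal of rot90(img) at theta is the signal of img at
  # theta + 90 (mod 180); wrapped angles come back axis-reversed
  r90 <- t(img)[, nrow(img):1]
  lp2 <- line_projections(r90)
  for (a in seq_len(36)) {
    b <- ((a - 1 + 18) %% 36) + 1
    expected <- if (a <= 18) lp[b, ] else rev(lp[b, ])
    expect_lt(max(abs(lp2[a, ] - expected)), 1e-9)
  }
})

test_that("pair_score finds the best common line and matches brute force", {
  lps <- fixture_lps()
  lp1 <- lps$signals[, , 1]
  attr(lp1, "angles") <- lps$angles
  same <- pair_score(lp1, lp1, "L2")
  expect_equal(same$score, 0)
  expect_equal(same$angle_i, same$angle_j)

  # constant images, single angle: closed-form L1
  c1 <- matrix(3, 4, 4); c2 <- matrix(5, 4, 4)
  l1 <- line_projections(c1, 180)  # single angle 0
  l2 <- line_projections(c2, 180)
  r <- pair_score(l1, l2, "L1")
  expect_equal(r$score, 16 * abs(3 - 5))

  # native all-pairs scores equal the naive double-loop oracle
  set.seed(11)
  imgs <- lapply(1:8, function(i) matrix(runif(64), 8))
  ps <- projection_set(imgs)
  stack <- line_projection_stack(ps)
  for (ms in c("L1", "L2", "cosine")) {
    sm <- score_matrix(stack, ms)
    for (i in 1:4) for (j in 5:8) {
      oracle <- naive_pair_score(stack$signals[, , i],
                                 stack$signals[, , j], ms)
      expect_lt(abs(sm$score[i, j] - oracle), 1e-9)
    }
  }

  # degenerate signals under correlation are scored 0, not an optimum
  lpz <- line_projections(matrix(1, 4, 4), 90)
  rz <- pair_score(lpz, lpz, "correlation")
  expect_equal(rz$score, 0)

  # wasserstein rejects zero-mass signals
  expect_error(pair_score(line_projections(matrix(0, 4, 4), 180),
                          line_projections(matrix(1, 4, 4), 180),
                          "wasserstein"), "zero-mass")
})

test_that("similarity graph: Z-scores, top-k selection, symmetrization", {
  # hand-built 3-node distance case: k = 1 keeps the nearest neighbor
  sm <- structure(list(
    score = matrix(c(NA, 1, 9, 1, NA, 4, 9, 4, NA), 3),
    angle_i = matrix(0, 3, 3), angle_j = matrix(0, 3, 3),
    measure = "L2", angles = 0), class = "score_matrix")
  g1 <- build_similarity_graph(sm, k = 1)
  e0 <- g1$edges[g1$edges$src == 1, ]
  expect_equal(e0$dst, 2)

  # k = n - 1 gives the complete directed graph (with a warning at k >= n)
  expect_warning(gc_ <- build_similarity_graph(sm, k = 5), "all edges")
  expect_equal(nrow(gc_$edges), 3 * 2)

  smr <- memo("sm4x6", function() score_matrix(fixture_lps(), "L2"))
  g <- build_similarity_graph(smr, k = 5)
  n <- g$n_nodes
  # out-degree bound
  expect_true(all(table(g$edges$src) <= 5))
  expect_true(all(g$edges$src != g$edges$dst))
  expect_true(all(is.finite(g$edges$weight)))

  # per-node Z-scores of the full candidate set: mean 0, sd 1
  for (i in c(1, 7, 24)) {
    cand <- smr$score[i, -i]
    z <- (cand - mean(cand)) / sd(cand)
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }

  # distance measures store the negated Z-score: nearest neighbor first
  i <- 1
  nn <- which.min(smr$score[i, -i])
  nn <- (seq_len(n)[-i])[nn]
  top <- g$edges[g$edges$src == i, ]
  expect_equal(top$dst[which.max(top$weight)], nn)

  # top-k neighbor sets equal an independent sort-based oracle
  set.seed(5)
  dm <- matrix(runif(36, 1, 9), 6); dm <- (dm + t(dm)) / 2; diag(dm) <- NA
  sm6 <- structure(list(score = dm, angle_i = matrix(0, 6, 6),
                        angle_j = matrix(0, 6, 6), measure = "L2",
                        angles = 0), class = "score_matrix")
  g6 <- build_similarity_graph(sm6, k = 2)
  for (i in 1:6) {
    mine <- sort(g6$edges$dst[g6$edges$src == i])
    oracle <- setdiff(order(dm[i, ]), i)[1:2]
    expect_equal(mine, sort(oracle))
  }

  # top-m global mode keeps exactly the m largest weights
  gm <- build_similarity_graph(smr, mode = "top_m_edges", m = 40)
  expect_equal(nrow(gm$edges), 40)
  wmat <- t(apply(smr$score, 1, function(r)
    -(r - mean(r, na.rm = TRUE)) / sd(r, na.rm = TRUE)))
  off <- wmat[!is.na(smr$score)]
  expect_equal(sort(gm$edges$weight, decreasing = TRUE),
               sort(off, decreasing = TRUE)[1:40], tolerance = 1e-9)

  # symmetrize: max rule, idempotence
  gd <- manual_graph(rbind(c(1, 2), c(2, 1), c(2, 3)), 3,
                     weight = c(0.2, 0.7, 0.5), directed = TRUE)
  gu <- symmetrize(gd)
  expect_false(gu$directed)
  expect_equal(nrow(gu$edges), 2)
  e12 <- gu$edges[gu$edges$src == 1 & gu$edges$dst == 2, ]
  expect_equal(e12$weight, 0.7)
  expect_identical(symmetrize(gu)$edges, gu$edges)
})

test_that("duplicated images are mutual nearest neighbors under L2", {
  ps <- fixture_ps()
  imgs <- list(ps$images[1, , ], ps$images[5, , ], ps$images[9, , ],
               ps$images[13, , ], ps$images[17, , ], ps$images[1, , ])
  dup <- projection_set(imgs)
  sm <- score_matrix(line_projection_stack(dup), "L2")
  expect_equal(which.min(sm$score[1, -1]) + 1, 6)
  expect_equal(which.min(sm$score[6, -6]), 1)
  expect_lt(sm$score[1, 6], 1e-9)
})

test_that("graph TSV and GraphML exports round-trip", {
  g <- fixture_graph()
  f <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, f)
  back <- read_graph_tsv(f, n_nodes = g$n_nodes)
  expect_equal(back$edges$src, g$edges$src)
  expect_equal(back$edges$weight, g$edges$weight, tolerance = 1e-9)

  fg <- tempfile(fileext = ".graphml")
  write_graphml(g, fg)
  ig <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::ecount(ig), nrow(g$edges))
})
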