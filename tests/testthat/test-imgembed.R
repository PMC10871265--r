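test_that("backbone embeddings are deterministic with fixed-size output", {
  ps <- fixture_ps()
  imgs <- list(ps$images[1, , ], ps$images[2, , ], ps$images[1, , ])
  dup <- projection_set(imgs)
  e1 <- pretrained_embed(dup, "tiny-cnn", seed = 1)
  expect_equal(nrow(e1), 3)
  expect_identical(e1[1, ], e1[3, ])  # duplicated image, identical rows

  e2 <- pretrained_embed(dup, "tiny-cnn", seed = 1)
  expect_identical(unclass(e1), unclass(e2))
  e3 <- pretrained_embed(dup, "tiny-cnn", seed = 2)
  expect_false(identical(unclass(e1), unclass(e3)))

  expect_error(pretrained_embed(dup, "resnet18"), "tiny-cnn")
})

test_that("triple generation respects labels, counts and modes", {
  tr <- generate_triples(c("a", "a", "b"), n_negatives = 10, seed = 1)
  expect_equal(nrow(tr), 10)
  expect_true(all(tr[, "negative"] == 3))

  labs <- rep(c("x", "y"), each = 3)
  tr2 <- generate_triples(labs, n_negatives = 10, seed = 1)
  expect_equal(nrow(tr2), (3 + 3) * 10)  # C(3,2) pairs per class x 10

  labs4 <- rep(letters[1:4], each = 2)
  tr3 <- generate_triples(labs4, mode = "per_class", seed = 1)
  expect_equal(nrow(tr3), 4 * 1 * 3)  # each pair gets 3 negatives

  # validity: label(A) = label(P) != label(N), A != P
  set.seed(2)
  labs5 <- sample(letters[1:5], 40, replace = TRUE)
  tr4 <- generate_triples(labs5, n_negatives = 4, seed = 3)
  expect_true(all(labs5[tr4[, 1]] == labs5[tr4[, 2]]))
  expect_true(all(labs5[tr4[, 1]] != labs5[tr4[, 3]]))
  expect_true(all(tr4[, 1] != tr4[, 2]))

  expect_error(generate_triples(rep("a", 5)), "2 classes")
})

test_that("triplet loss follows the margin contract", {
  eA <- c(0, 0); eP <- c(1, 0); eN <- c(1, 0)
  expect_equal(triplet_loss(eA, eP, eN, margin = 0.5), 0.5)

  # clamped at zero when the negative is far enough
  eP <- c(sqrt(0.2), 0); eN <- c(1, 0)
  expect_equal(triplet_loss(eA, eP, eN, margin = 0.5), 0)

  # default margin is 0.5: d(A,P) = d(A,N) + 0.1 gives loss 0.6
  eP <- c(sqrt(1.1), 0); eN <- c(1, 0)
  expect_equal(triplet_loss(eA, eP, eN), 0.6)

  # invariants: nonnegative; zero whenever d(A,N) >= d(A,P) + margin
  set.seed(4)
  for (i in 1:50) {
    a <- rnorm(8); p <- rnorm(8); n <- rnorm(8)
    l <- triplet_loss(a, p, n)
    expect_gte(l, 0)
    if (sum((a - n)^2) >= sum((a - p)^2) + 0.5) expect_equal(l, 0)
  }
})

test_that("complex splits are disjoint, complete and deterministic", {
  labs <- rep(letters[1:10], each = 2)
  sp <- split_complexes(labs, seed = 1)
  expect_equal(length(sp$train), 7)
  expect_equal(length(sp$test), 3)
  expect_setequal(c(sp$train, sp$test), letters[1:10])
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_complexes(labs, seed = 1))
  expect_error(split_complexes(rep("a", 4)), "2 classes")
  # both sides stay nonempty even at extreme fractions
  sp2 <- split_complexes(rep(c("a", "b"), 3), train_frac = 0.99, seed = 1)
  expect_length(sp2$test, 1)
})

test_that("Siamese training reduces loss and tightens classes", {
  ps <- toy_stripes()
  tr <- generate_triples(ps$labels, n_negatives = 5, seed = 1)
  cfg <- siamese_config(epochs = 10, batch_size = 2, seed = 1)
  enc <- train_siamese(ps, tr, cfg)

  h <- enc$history
  expect_equal(nrow(h), 10)
  expect_lt(h$train_loss[10], h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))

  # frozen backbone: filters identical to their seeded initialization
  expect_identical(enc$backbone$kerns,
                   projclust:::tiny_cnn_params(cfg$seed)$kerns)

  emb <- siamese_embed(enc, ps)
  expect_equal(ncol(emb), 256)
  d <- as.matrix(dist(unclass(emb)))
  same <- outer(ps$labels, ps$labels, "==")
  diag(same) <- NA
  expect_lt(mean(d[which(same)]), mean(d[which(!same)]))

  # inference is deterministic; duplicated images embed identically
  emb2 <- siamese_embed(enc, ps)
  expect_identical(unclass(emb), unclass(emb2))

  expect_error(train_siamese(ps, tr[0, , drop = FALSE], cfg), "nonempty")
  small <- projection_set(ps$images[1:3, 1:14, 1:14, drop = FALSE])
  expect_error(siamese_embed(enc, small), "size")
})

test_that("encoder checkpoints round-trip through JSON", {
  ps <- toy_stripes(n_per = 3)
  tr <- generate_triples(ps$labels, n_negatives = 2, seed = 1)
  enc <- train_siamese(ps, tr, siamese_config(epochs = 2, seed = 1))
  f <- tempfile(fileext = ".json")
  save_encoder(enc, f)
  enc2 <- load_encoder(f)
  e1 <- siamese_embed(enc, ps)
  e2 <- siamese_embed(enc2, ps)
  expect_lt(max(abs(unclass(e1) - unclass(e2))), 1e-10)
})

test_that("embedding TSV export round-trips", {
  ps <- fixture_ps()
  emb <- pretrained_embed(projection_set(list(ps$images[1, , ],
                                              ps$images[2, , ])), seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_embedding_tsv(emb, f)
  back <- read_embedding_tsv(f)
  expect_equal(unclass(back), unclass(emb), ignore_attr = TRUE,
               tolerance = 1e-12)
})
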