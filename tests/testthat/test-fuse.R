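test_that("reduce applies the variance rule with a 2-component floor", {
  set.seed(1)
  # essentially 1-D data: the floor keeps 2 components
  line <- outer(rnorm(50), seq_len(10)) +
    matrix(rnorm(500, sd = 1e-6), 50, 10)
  r <- reduce(line)
  expect_equal(ncol(r), 2)
  expect_equal(attr(r, "branch"), "pca")

  # isotropic 5-D Gaussian: every ratio ~ 0.2 >= 0.02, all kept
  iso <- matrix(rnorm(1000), 200, 5)
  r5 <- reduce(iso)
  expect_equal(ncol(r5), 5)
  expect_true(all(attr(r5, "explained_variance_ratio") >= 0.02))

  # every retained component above the floor explains >= 2% variance
  set.seed(2)
  X <- matrix(rnorm(600), 60, 10) %*% diag(c(8, 6, 4, 2, 1, rep(0.05, 5)))
  rX <- reduce(X)
  if (ncol(rX) > 2)
    expect_true(all(attr(rX, "explained_variance_ratio") >= 0.02))

  # sparsity > 0.5 routes to the (uncentered) SVD branch
  Xs <- matrix(rnorm(500), 50, 10)
  Xs[sample(500, 300)] <- 0
  expect_equal(attr(reduce(Xs), "branch"), "svd")

  # deterministic across runs
  expect_identical(unclass(reduce(X)), unclass(reduce(X)))

  expect_error(reduce(matrix(1, 10, 3)), "zero-variance")
  expect_error(reduce(matrix(1:3, 1, 3)), "2 rows")
})

test_that("combine concatenates with aligned rows in every mode", {
  set.seed(3)
  img <- matrix(rnorm(40 * 6), 40, 6)
  node <- matrix(rnorm(40 * 4), 40, 4)

  out <- combine(img, node, fusion_config("concat_then_reduce"))
  expect_equal(nrow(out), 40)
  expect_lte(ncol(out), 10)

  out2 <- combine(img, node, fusion_config("reduce_then_concat"))
  expect_equal(nrow(out2), 40)

  # image_only is reduce passthrough
  only <- combine(img, NULL, fusion_config("image_only"))
  expect_equal(unclass(only), unclass(reduce(img)), ignore_attr = TRUE)

  # permutation equivariance of rows
  perm <- sample(40)
  o1 <- combine(img, node, fusion_config("concat_then_reduce"))
  o2 <- combine(img[perm, ], node[perm, ],
                fusion_config("concat_then_reduce"))
  expect_equal(unclass(o2), unclass(o1)[perm, ], tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(combine(img, node[1:10, ], fusion_config()), "row counts")
  expect_error(combine(img, NULL, fusion_config("concat_then_reduce")),
               "required")
})
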