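test_that("F-similarity closed forms", {
  expect_equal(f_similarity(1:3, 1:3), 1)
  expect_equal(f_similarity(1:3, 4:6), 0)
  expect_equal(f_similarity(1:3, 2:6), 0.5)  # p = 2/3, r = 2/5
  expect_error(f_similarity(integer(0), 1:3), "empty")
})

test_that("worked partition examples score as derived by hand", {
  pred <- list(c(1, 2), 3)
  true <- list(1:3)
  f <- fmmf(pred, true)
  expect_equal(unname(f["precision"]), 0.4, tolerance = 1e-4)
  expect_equal(unname(f["recall"]), 0.8, tolerance = 1e-4)
  expect_equal(unname(f["F"]), 0.5333, tolerance = 1e-4)

  cm <- cmmf(pred, true)
  expect_equal(unname(cm["precision"]), 0.65, tolerance = 1e-4)
  expect_equal(unname(cm["recall"]), 0.8, tolerance = 1e-4)
  expect_equal(unname(cm["F"]), 0.7172, tolerance = 1e-4)

  expect_equal(unspa(pred, true), 0.8165, tolerance = 1e-4)

  # Qi: omega = 4 / 8 = 0.5 >= 0.25 in both directions
  expect_equal(unname(qi_fscore(list(1:4), list(1:2))["F"]), 1)
  expect_equal(unname(qi_fscore(list(1:2), list(3:4))["F"]), 0)

  # single catch-all cluster: Sn = 1, PPV = m/(km)
  k <- 4; m <- 5
  pred1 <- list(1:(k * m))
  true_k <- split(1:(k * m), rep(1:k, each = m))
  expect_equal(unspa(pred1, true_k), sqrt(1 * (m / (k * m))))
})

test_that("identity partitions score 1 on every supervised metric", {
  for (seed in 1:5) {
    part <- random_partition(40, 7, seed)
    expect_equal(unname(fmmf(part, part)["F"]), 1)
    expect_equal(unname(cmmf(part, part)["F"]), 1)
    expect_equal(unname(qi_fscore(part, part)["F"]), 1)
    expect_equal(unspa(part, part), 1)
  }
  # relabeling (reordering clusters) changes nothing; perturbation does
  part <- random_partition(12, 4, 1)
  shuf <- part[c(3, 1, 4, 2)]
  expect_equal(unname(fmmf(shuf, part)["F"]), 1)
  moved <- part
  moved[[1]] <- c(moved[[1]], moved[[2]][1])
  moved[[2]] <- moved[[2]][-1]
  moved <- moved[lengths(moved) > 0]
  expect_lt(unname(fmmf(moved, part)["F"]), 1)
})

test_that("FMMF swap symmetry and brute-force matching equivalence", {
  for (seed in 1:8) {
    pred <- random_partition(14, sample(2:5, 1), seed)
    true <- random_partition(14, sample(2:6, 1), seed + 100)
    a <- fmmf(pred, true); b <- fmmf(true, pred)
    expect_equal(unname(a["precision"]), unname(b["recall"]))
    expect_equal(unname(a["recall"]), unname(b["precision"]))
    expect_equal(unname(a["F"]), unname(b["F"]))

    W <- projclust:::f_similarity_matrix(pred, true)
    expect_equal(projclust:::max_weight_matching(W),
                 brute_force_matching(W), tolerance = 1e-12)
  }
})

test_that("CMMF dominates FMMF over random partition pairs", {
  for (seed in 1:100) {
    pred <- random_partition(16, sample(2:6, 1), seed)
    true <- random_partition(16, sample(2:6, 1), seed + 1000)
    expect_gte(unname(cmmf(pred, true)["F"]) + 1e-12,
               unname(fmmf(pred, true)["F"]))
  }
})

test_that("label/partition conversion handles noise both ways", {
  labs <- c(1, 1, 2, 0, 2, NA)
  p1 <- labels_to_partition(labs)
  expect_equal(length(p1), 4)  # 2 clusters + 2 singleton noise points
  expect_equal(sort(unlist(p1)), 1:6)
  p2 <- labels_to_partition(labs, drop_noise = TRUE)
  expect_equal(length(p2), 2)
  expect_equal(sort(unlist(p2)), c(1, 2, 3, 5))
})

test_that("unsupervised indices behave on blobs and degenerate input", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, 0, 0.2), 20), matrix(rnorm(40, 10, 0.2), 20))
  y <- rep(1:2, each = 20)
  us <- unsupervised_scores(X, y)
  expect_gt(us["silhouette"], 0.9)
  expect_gt(us["calinski_harabasz"], 100)
  expect_lt(us["davies_bouldin"], 0.5)
  expect_identical(us, unsupervised_scores(X, y))

  one <- unsupervised_scores(X, rep(1, 40))
  expect_true(all(is.na(one)))
})

test_that("evaluation reports cover junk dual-reporting and IO", {
  pred <- c(1, 1, 1, 2, 2, 2)  # junk item swallowed by cluster 2
  truth <- c("a", "a", "a", "b", "b", NA)  # last item is junk
  rep <- evaluate_clustering(pred, truth)
  expect_s3_class(rep, "eval_report")
  expect_true(!is.null(rep$excluding_junk))
  expect_equal(rep$excluding_junk$fmmf, 1)
  expect_lt(rep$fmmf, 1)  # junk-as-pseudo-complex penalizes the match

  f <- tempfile(fileext = ".json")
  write_eval_report(rep, f)
  expect_true(jsonlite::validate(readChar(f, file.size(f))))
  f2 <- tempfile(fileext = ".tsv")
  write_eval_report(rep, f2)
  expect_gt(nrow(read.delim(f2)), 5)
})
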