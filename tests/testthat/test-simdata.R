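test_that("make_volume is deterministic and shapes are distinct", {
  v1 <- make_volume("cube", 32, 0)
  v2 <- make_volume("cube", 32, 0)
  expect_identical(v1$grid, v2$grid)
  expect_true(sum(v1$grid) > 0)
  expect_true(all(v1$grid >= 0))

  sph <- make_volume("sphere", 32, 0)
  dmb <- make_volume("dumbbell", 32, 0)
  ncc <- sum(sph$grid * dmb$grid) /
    sqrt(sum(sph$grid^2) * sum(dmb$grid^2))
  expect_lt(ncc, 0.95)

  # all shape pairs are distinguishable
  vols <- lapply(c("sphere", "dumbbell", "cube", "torus", "rod", "lshape"),
                 make_volume, grid_size = 24)
  for (i in 1:5) for (j in (i + 1):6) {
    ncc <- sum(vols[[i]]$grid * vols[[j]]$grid) /
      sqrt(sum(vols[[i]]$grid^2) * sum(vols[[j]]$grid^2))
    expect_lt(ncc, 0.95)
  }

  expect_error(make_volume("pyramid", 32), "arg")
  expect_error(make_volume("sphere", 8), "grid_size")
})

test_that("projection integrates mass and respects symmetry", {
  sph <- make_volume("sphere", 32, 0)
  # spherical symmetry: projections from any orientation agree
  i1 <- project_volume(sph, c(0, 0, 0))
  i2 <- project_volume(sph, c(1.1, 0.6, 2.3))
  expect_lt(max(abs(i1 - i2)) / max(i1), 0.05)

  # identity orientation hits grid points exactly: mass conserved exactly
  cu <- make_volume("cube", 32, 0)
  ic <- project_volume(cu, c(0, 0, 0))
  expect_equal(sum(ic), sum(cu$grid), tolerance = 1e-12)

  # axis-aligned cube projects to a constant-intensity square interior
  core <- ic[13:20, 13:20]
  expect_lt(diff(range(core)) / mean(core), 1e-8)
  expect_equal(max(ic), max(core))

  # mass conservation over random orientations (interpolation tolerance)
  set.seed(42)
  tor <- make_volume("torus", 32, 0)
  for (r in 1:20) {
    ang <- c(runif(1, 0, 2 * pi), acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
    img <- project_volume(tor, ang)
    expect_lt(abs(sum(img) - sum(tor$grid)) / sum(tor$grid), 1e-2)
  }
})

test_that("make_dataset obeys counts, labels, determinism and range bounds", {
  ps <- fixture_ps()
  expect_s3_class(ps, "projection_set")
  expect_equal(length(ps), 24)
  expect_equal(dim(ps$images)[2:3], c(48, 48))
  expect_equal(length(unique(ps$labels)), 4)
  # label consistency: each image in exactly one class
  expect_equal(length(ps$labels), 24)
  expect_false(anyNA(ps$labels))

  ps2 <- make_dataset(4, c(6, 6), image_size = 48, seed = 1, grid_size = 24)
  expect_identical(ps$images, ps2$images)

  # per-class counts drawn from the given range
  psr <- make_dataset(8, c(2, 6), image_size = 32, seed = 3, grid_size = 16)
  counts <- table(psr$labels)
  expect_true(all(counts >= 2 & counts <= 6))
  expect_gte(length(psr), 16)
  expect_lte(length(psr), 48)

  expect_error(make_dataset(4, c(5, 2)), "range")
  # variant classes beyond the six base families stay distinguishable
  ps35 <- make_dataset(8, c(2, 2), image_size = 32, seed = 2, grid_size = 16)
  expect_equal(length(unique(ps35$labels)), 8)
})

test_that("noise model: image-parameterized Gaussian plus salt-and-pepper", {
  z <- matrix(0, 100, 100)
  out <- add_noise(z, sp_fraction = 0.01, seed = 1)
  # zero mean/variance input: Gaussian degenerate, salt = pepper = 0
  expect_equal(unclass(out), z, ignore_attr = TRUE)
  expect_equal(length(attr(out, "sp_salt")), 50)
  expect_equal(length(attr(out, "sp_pepper")), 50)

  img <- matrix(runif(64 * 64), 64) + 2
  noisy <- add_noise(img, sp_fraction = 0.01, seed = 2)
  n_sp <- round(0.01 * 64 * 64)
  sp_idx <- c(attr(noisy, "sp_salt"), attr(noisy, "sp_pepper"))
  expect_equal(length(sp_idx), n_sp)
  expect_true(all(noisy[attr(noisy, "sp_salt")] == max(noisy)))
  expect_true(all(noisy[attr(noisy, "sp_pepper")] == min(noisy)))

  # sp_fraction 0: residual is pure Gaussian with the image's moments
  means <- replicate(12, {
    s <- sample.int(1e6, 1)
    resid <- add_noise(img, sp_fraction = 0, seed = s) - img
    mean(resid)
  })
  se <- sd(as.vector(img)) / sqrt(length(img))
  expect_lt(abs(mean(means) - mean(img)), 3 * se)
  # zero-mean variant centers the Gaussian at zero
  resid0 <- add_noise(img, sp_fraction = 0, seed = 9, zero_mean = TRUE) - img
  expect_lt(abs(mean(resid0)), 4 * se)

  expect_identical(add_noise(img, seed = 5), add_noise(img, seed = 5))
})

test_that("MRC2014 stacks and volumes round-trip", {
  ps <- fixture_ps()
  f <- tempfile(fileext = ".mrcs")
  write_mrc(ps, f)
  back <- read_mrc(f)
  expect_equal(dim(back$images), dim(ps$images))
  expect_lt(max(abs(back$images - ps$images)), 1e-4)  # float32 rounding

  v <- make_volume("rod", 24, 0)
  fv <- tempfile(fileext = ".mrc")
  write_mrc(v, fv)
  v2 <- read_mrc(fv)
  expect_lt(max(abs(v2$grid - v$grid)), 1e-6)
})

test_that("PNG directories and label TSVs round-trip", {
  ps <- fixture_ps()
  d <- tempfile()
  write_png_dir(ps, d)
  back <- read_png_dir(d)
  expect_equal(length(back), length(ps))
  expect_identical(back$labels, ps$labels)

  f <- tempfile(fileext = ".tsv")
  write_labels_tsv(ps$labels, f)
  expect_identical(read_labels_tsv(f), ps$labels)
})
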