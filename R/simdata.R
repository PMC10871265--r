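#' Synthetic particle volumes and projection image sets
#'
#' The generator emulates heterogeneous cryo-EM 2D class-average datasets:
#' distinct 3D density shapes are projected at uniformly random orientations,
#' padded and rescaled to a common image size, and optionally degraded with
#' the grainy-texture noise model (Gaussian noise parameterized by the image's
#' own pixel mean and variance, plus salt-and-pepper corruption of a fixed
#' fraction of pixels, emulating hot and dead detector pixels).
#'
#' @name simdata
NULL

.shape_families <- c("sphere", "dumbbell", "cube", "torus", "rod", "lshape")

#' Construct a synthetic 3D density volume
#'
#' Builds a cubic voxel grid holding a nonnegative density for one of six
#' shape families. An optional seeded random perturbation (anisotropic axis
#' scaling plus added spherical lobes) produces distinct class variants from
#' the same base family; this is a geometric stand-in for structurally
#' distinct macromolecules, not an emulation of any real structure.
#'
#' @param shape_id one of `"sphere"`, `"dumbbell"`, `"cube"`, `"torus"`,
#'   `"rod"`, `"lshape"`.
#' @param grid_size edge length of the cubic grid in voxels (>= 16).
#' @param seed integer seed driving the perturbation draw.
#' @param perturb perturbation strength in `[0, 1]`; 0 gives the unperturbed
#'   base shape.
#' @return An object of class `synthetic_volume`: list with `grid` (3D
#'   array), `shape_id`, `seed`.
#' @export
#' @examples
#' v <- make_volume("sphere", 32, seed = 0)
#' sum(v$grid) > 0
make_volume <- function(shape_id, grid_size, seed = 0, perturb = 0) {
  shape_id <- match.arg(shape_id, .shape_families)
  if (grid_size < 16) stop("grid_size must be >= 16")
  n <- as.integer(grid_size)
  ctr <- (n - 1) / 2
  ax <- seq_len(n) - 1 - ctr              # centered voxel coordinates
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))

  sc <- c(1, 1, 1)
  lobes <- NULL
  if (perturb > 0) {
    pr <- with_seed(seed, list(
      sc = runif(3, 1 - 0.3 * perturb, 1 + 0.3 * perturb),
      n_lobes = sample(1:3, 1),
      lobe_pos = matrix(runif(9, -0.28, 0.28), 3, 3),
      lobe_r = runif(3, 0.08, 0.14)
    ))
    sc <- pr$sc
    lobes <- pr
  }
  Xs <- X / sc[1]; Ys <- Y / sc[2]; Zs <- Z / sc[3]

  # signed distance-like indicator with a ~1-voxel soft edge
  soft <- function(d, edge = 1) pmin(pmax((edge - d) / edge, 0), 1)
  r <- n  # unit of shape dimensions below is the grid edge
  dens <- switch(shape_id,
    sphere = soft(sqrt(Xs^2 + Ys^2 + Zs^2) - 0.32 * r),
    dumbbell = {
      d1 <- sqrt(Xs^2 + Ys^2 + (Zs - 0.2 * r)^2) - 0.17 * r
      d2 <- sqrt(Xs^2 + Ys^2 + (Zs + 0.2 * r)^2) - 0.17 * r
      bar <- pmax(sqrt(Xs^2 + Ys^2) - 0.06 * r, abs(Zs) - 0.2 * r)
      soft(pmin(d1, d2, bar))
    },
    cube = soft(pmax(abs(Xs), abs(Ys), abs(Zs)) - 0.26 * r),
    torus = soft(sqrt((sqrt(Xs^2 + Ys^2) - 0.26 * r)^2 + Zs^2) - 0.1 * r),
    rod = soft(pmax(sqrt(Xs^2 + Ys^2) - 0.1 * r, abs(Zs) - 0.36 * r)),
    lshape = {
      b1 <- pmax(abs(Xs) - 0.1 * r, abs(Ys) - 0.1 * r, abs(Zs) - 0.32 * r)
      b2 <- pmax(abs(Xs) - 0.28 * r, abs(Ys) - 0.1 * r,
                 abs(Zs + 0.24 * r) - 0.08 * r)
      soft(pmin(b1, b2))
    })

  if (!is.null(lobes)) {
    for (i in seq_len(lobes$n_lobes)) {
      p <- lobes$lobe_pos[i, ] * r
      d <- sqrt((X - p[1])^2 + (Y - p[2])^2 + (Z - p[3])^2) - lobes$lobe_r[i] * r
      dens <- pmax(dens, soft(d))
    }
  }

  structure(list(grid = dens, shape_id = shape_id, seed = as.integer(seed)),
            class = "synthetic_volume")
}

#' Project a volume along a viewing axis
#'
#' Rotates the volume by the given ZYZ Euler angles (trilinear resampling,
#' zero padding outside the grid, rotation center at `(N-1)/2` on each axis)
#' and integrates along the z axis, yielding a 2D projection image. Total
#' image intensity equals total volume mass up to interpolation error.
#'
#' @param vol a `synthetic_volume` (or any cubic 3D array wrapped in one).
#' @param orientation numeric length-3, ZYZ Euler angles in radians.
#' @return `N x N` numeric projection image.
#' @export
project_volume <- function(vol, orientation = c(0, 0, 0)) {
  grid <- if (inherits(vol, "synthetic_volume")) vol$grid else vol
  stopifnot(length(dim(grid)) == 3, length(unique(dim(grid))) == 1)
  n <- dim(grid)[1]
  ctr <- (n - 1) / 2
  R <- euler_zyz(orientation[1], orientation[2], orientation[3])

  ax <- seq_len(n) - 1 - ctr
  co <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  # sample the rotated volume: source coordinate = R^T (target coordinate)
  src <- co %*% R                           # (R^T co^T)^T
  sx <- src[, 1] + ctr; sy <- src[, 2] + ctr; sz <- src[, 3] + ctr

  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0

  acc <- numeric(n^3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    ok <- xi >= 0 & xi < n & yi >= 0 & yi < n & zi >= 0 & zi < n & w > 0
    idx <- xi[ok] + 1 + yi[ok] * n + zi[ok] * n * n
    acc[ok] <- acc[ok] + w[ok] * grid[idx]
  }
  rot <- array(acc, dim = c(n, n, n))       # [x, y, z]
  # integrate along z; rows of the image index x, columns index y
  apply(rot, c(1, 2), sum)
}

#' Generate a labeled synthetic projection dataset
#'
#' Emulates the study datasets: `n_classes` distinct particles (six base
#' shape families plus seeded perturbation variants), each projected at a
#' uniformly random set of orientations on SO(3); per-class projection
#' counts are drawn uniformly from `projections_per_class`. Images are
#' padded to the common (largest) extent and rescaled to
#' `image_size x image_size`; with `noisy = TRUE` the noise model of
#' [add_noise()] is applied per image.
#'
#' @param n_classes number of particle classes.
#' @param projections_per_class integer length-2 inclusive range, or a single
#'   count.
#' @param image_size output image edge in pixels (default 100).
#' @param noisy logical; apply the noise model.
#' @param seed integer seed; the whole dataset is deterministic under it.
#' @param grid_size voxel grid edge for the underlying volumes.
#' @return A `projection_set`: list with `images` (array `n x H x W`),
#'   `labels` (character), `pixel_size`, `source`.
#' @export
make_dataset <- function(n_classes, projections_per_class, image_size = 100,
                         noisy = FALSE, seed = 0, grid_size = 32) {
  rng <- as.integer(projections_per_class)
  if (length(rng) == 1) rng <- c(rng, rng)
  if (length(rng) != 2 || any(is.na(rng)) || rng[2] < rng[1] || rng[1] < 1)
    stop("projections_per_class must be a nonempty positive range")

  imgs <- list(); labels <- character(0)
  for (cls in seq_len(n_classes)) {
    base <- .shape_families[(cls - 1) %% 6 + 1]
    variant <- (cls - 1) %/% 6
    vol <- make_volume(base, grid_size,
                       seed = derive_seed(seed, cls),
                       perturb = if (variant > 0) 0.8 else 0)
    cnt <- with_seed(derive_seed(seed, 1000 + cls),
                     rng[1] + sample.int(rng[2] - rng[1] + 1, 1) - 1L)
    angs <- with_seed(derive_seed(seed, 2000 + cls), {
      cbind(runif(cnt, 0, 2 * pi), acos(runif(cnt, -1, 1)),
            runif(cnt, 0, 2 * pi))
    })
    for (i in seq_len(cnt)) {
      img <- project_volume(vol, angs[i, ])
      imgs[[length(imgs) + 1]] <- img
      labels <- c(labels, sprintf("class_%02d", cls))
    }
  }

  hmax <- max(vapply(imgs, nrow, 1L)); wmax <- max(vapply(imgs, ncol, 1L))
  side <- max(hmax, wmax)
  arr <- array(0, dim = c(length(imgs), image_size, image_size))
  for (i in seq_along(imgs)) {
    im <- resize_bilinear(pad_center(imgs[[i]], side, side),
                          image_size, image_size)
    if (noisy) im <- add_noise(im, seed = derive_seed(seed, 3000 + i))
    arr[i, , ] <- im
  }
  projection_set(arr, labels = labels,
                 source = sprintf("synthetic n_classes=%d seed=%d%s",
                                  n_classes, seed,
                                  if (noisy) " noisy" else ""))
}

#' Projection set constructor
#'
#' @param images `n x H x W` array, or a list of equal-sized matrices.
#' @param labels optional per-image class labels (length n).
#' @param pixel_size physical length per pixel (arbitrary units).
#' @param source free-text provenance.
#' @return A `projection_set` object.
#' @export
projection_set <- function(images, labels = NULL, pixel_size = 1,
                           source = "unknown") {
  if (is.list(images)) {
    dims <- unique(lapply(images, dim))
    if (length(dims) != 1) stop("all images must share the same size")
    arr <- array(0, dim = c(length(images), dims[[1]][1], dims[[1]][2]))
    for (i in seq_along(images)) arr[i, , ] <- images[[i]]
    images <- arr
  }
  stopifnot(length(dim(images)) == 3, dim(images)[1] >= 1)
  if (!is.null(labels) && length(labels) != dim(images)[1])
    stop("labels length must equal the number of images")
  structure(list(images = images, labels = labels,
                 pixel_size = pixel_size, source = source),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("projection_set: %d images of %dx%d", d[1], d[2], d[3]))
  if (!is.null(x$labels))
    cat(sprintf(", %d classes", length(unique(x$labels))))
  cat(sprintf(" [%s]\n", x$source))
  invisible(x)
}

#' @export
length.projection_set <- function(x) dim(x$images)[1]

#' Apply the grainy-texture + hot/dead pixel noise model
#'
#' Adds Gaussian noise whose mean and variance are the input image's own
#' pixel mean and variance, then sets `round(sp_fraction * H * W)` randomly
#' chosen pixels to the image minimum (dead/pepper) or maximum (hot/salt),
#' half each. With `zero_mean = TRUE` the Gaussian component is centered at
#' zero (variance unchanged).
#'
#' @param image numeric matrix.
#' @param sp_fraction fraction of pixels to corrupt, in `[0, 1)`.
#' @param seed integer seed.
#' @param zero_mean logical; use a zero-mean Gaussian instead of one centered
#'   at the image mean.
#' @return Noisy image; the chosen salt/pepper pixel indices are attached as
#'   attributes `sp_salt` and `sp_pepper`.
#' @export
add_noise <- function(image, sp_fraction = 0.01, seed = 0,
                      zero_mean = FALSE) {
  stopifnot(is.matrix(image), length(image) > 0,
            sp_fraction >= 0, sp_fraction < 1)
  m <- mean(image); s <- sqrt(var(as.vector(image)))
  if (!is.finite(s)) s <- 0
  with_seed(seed, {
    out <- image + rnorm(length(image),
                         mean = if (zero_mean) 0 else m, sd = s)
    n_sp <- round(sp_fraction * length(image))
    salt <- pepper <- integer(0)
    if (n_sp > 0) {
      idx <- sample.int(length(image), n_sp)
      n_salt <- n_sp %/% 2
      salt <- idx[seq_len(n_salt)]
      pepper <- idx[setdiff(seq_len(n_sp), seq_len(n_salt))]
      mx <- max(out); mn <- min(out)
      out[salt] <- mx; out[pepper] <- mn
    }
    structure(out, sp_salt = salt, sp_pepper = pepper)
  })
}
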