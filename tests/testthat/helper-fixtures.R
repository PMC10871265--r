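# Shared fixtures and independent reference implementations (oracles).
# Fixtures are generated in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# small labeled synthetic dataset: 4 shape classes x 6 projections, 48 px
fixture_ps <- function() memo("ps4x6", function()
  make_dataset(4, c(6, 6), image_size = 48, seed = 1, grid_size = 24))

fixture_lps <- function() memo("lps4x6", function()
  line_projection_stack(fixture_ps()))

fixture_graph <- function() memo("g4x6", function()
  build_similarity_graph(memo("sm4x6", function()
    score_matrix(fixture_lps(), "L2")), k = 5))

# hand-built similarity graph from an edge index matrix
manual_graph <- function(edges, n_nodes, weight = 1, directed = FALSE) {
  e <- data.frame(src = edges[, 1], dst = edges[, 2], raw_score = weight,
                  weight = weight, angle_src = 0, angle_dst = 0)
  structure(list(n_nodes = n_nodes, edges = e, directed = directed,
                 measure = "L2", mode = "manual"),
            class = "similarity_graph")
}

clique_graph <- function(sizes = c(6, 6)) {
  off <- 0; ed <- NULL
  for (s in sizes) {
    prs <- t(combn(off + seq_len(s), 2))
    ed <- rbind(ed, prs)
    off <- off + s
  }
  manual_graph(ed, sum(sizes))
}

ring_graph <- function(n = 8)
  manual_graph(cbind(seq_len(n), c(seq_len(n)[-1], 1)), n)

star_graph <- function(leaves = 5)
  manual_graph(cbind(1, 1 + seq_len(leaves)), leaves + 1)

# toy image set for metric learning: stripe orientation classes with random
# phase, so the discriminative feature is diluted among nuisance variation
toy_stripes <- function(n_per = 6, seed = 7, side = 28, noise = 0.6) {
  set.seed(seed)
  classes <- c("vert", "horiz", "diag")
  imgs <- list(); labs <- character(0)
  xy <- expand.grid(r = seq_len(side), c = seq_len(side))
  for (cl in classes) for (i in seq_len(n_per)) {
    ph <- runif(1, 0, 2 * pi)
    v <- switch(cl, vert = xy$c, horiz = xy$r,
                diag = (xy$r + xy$c) / sqrt(2))
    img <- matrix(sin(2 * pi * v / 6 + ph), side) +
      matrix(rnorm(side^2, 0, noise), side)
    imgs[[length(imgs) + 1]] <- img
    labs <- c(labs, cl)
  }
  projection_set(imgs, labels = labs, source = "toy stripes")
}

# ---- oracles ---------------------------------------------------------------

# per-pixel bilinear rotation by -theta about the image center (the naive
# counterpart of the package's sparse rotation operator)
naive_rotate <- function(img, theta_deg) {
  h <- nrow(img); w <- ncol(img)
  th <- theta_deg * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    u <- i - cr; v <- j - cc
    si <- cos(th) * u - sin(th) * v + cr
    sj <- sin(th) * u + cos(th) * v + cc
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    val <- 0
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        wgt <- (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj)
        val <- val + wgt * img[ii, jj]
      }
    }
    out[i, j] <- val
  }
  out
}

naive_line_projections <- function(img, step = 5) {
  angles <- seq(0, 180 - step, by = step)
  t(vapply(angles, function(a) colSums(naive_rotate(img, a)),
           numeric(ncol(img))))
}

# explicit double loop over all angle pairs
naive_pair_score <- function(lp1, lp2, measure) {
  A <- nrow(lp1)
  best <- if (measure %in% c("L1", "L2")) Inf else -Inf
  for (a in seq_len(A)) for (b in seq_len(A)) {
    u <- lp1[a, ]; v <- lp2[b, ]
    val <- switch(measure,
      L1 = sum(abs(u - v)),
      L2 = sqrt(sum((u - v)^2)),
      cosine = sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    if (measure %in% c("L1", "L2")) best <- min(best, val)
    else best <- max(best, val)
  }
  best
}

# exhaustive maximum over all one-to-one matchings (<= 6x6)
brute_force_matching <- function(W) {
  nr <- nrow(W); nc <- ncol(W)
  if (nr > nc) return(brute_force_matching(t(W)))
  best <- 0
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(nc))) {
    sel <- p[seq_len(nr)]
    best <- max(best, sum(W[cbind(seq_len(nr), sel)]))
  }
  best
}

random_partition <- function(n, k, seed) {
  set.seed(seed)
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  unname(split(seq_len(n), labels))
}
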