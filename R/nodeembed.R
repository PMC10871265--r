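#' Similarity-graph node embeddings
#'
#' Three unsupervised node-embedding families behind one interface:
#' biased-random-walk skip-gram embeddings (node2vec), spectral heat-wavelet
#' characteristic-function embeddings (GraphWave, structure only), and a
#' graph-infomax-trained one-layer graph convolutional encoder (attributed).
#' Any user function with signature `function(g, params)` returning an
#' `n x d` matrix plugs into the pipeline unchanged.
#'
#' @name nodeembed
NULL

#' Node embedding parameters
#'
#' @param method `"node2vec"`, `"graphwave"` or `"dgi-gcn"`.
#' @param dim embedding dimensionality (node2vec / dgi).
#' @param p,q node2vec return and in-out bias parameters.
#' @param walks_per_node,walk_length,window,negatives,sg_epochs,sg_alpha
#'   random-walk corpus and skip-gram settings.
#' @param scales,n_sample_points GraphWave heat-kernel scales and number of
#'   characteristic-function sample points (evenly spaced in `[0, 100]`).
#' @param hidden,dgi_epochs,dgi_lr DGI encoder width and training settings.
#' @param seed integer seed.
#' @return A `node_embedding_params` list.
#' @export
node_embedding_params <- function(method = c("node2vec", "graphwave",
                                             "dgi-gcn"),
                                  dim = 128, p = 1, q = 1,
                                  walks_per_node = 10, walk_length = 80,
                                  window = 10, negatives = 5,
                                  sg_epochs = 5, sg_alpha = 0.025,
                                  scales = c(5, 10), n_sample_points = 50,
                                  hidden = 128, dgi_epochs = 100,
                                  dgi_lr = 1e-3, seed = 0) {
  method <- match.arg(method)
  stopifnot(dim >= 2, walk_length >= window)
  structure(as.list(environment()), class = "node_embedding_params")
}

# adjacency structure with nonnegative transition weights
# per-node shift w - min(w) + eps guarantees valid distributions on
# Z-scored (possibly negative) weights
.adjacency <- function(g, directed = NULL, eps = 1e-6) {
  directed <- directed %||% g$directed
  e <- g$edges
  if (!directed && g$directed) e <- symmetrize(g)$edges
  if (!directed) {
    e <- rbind(e, data.frame(src = e$dst, dst = e$src,
                             raw_score = e$raw_score, weight = e$weight,
                             angle_src = e$angle_dst,
                             angle_dst = e$angle_src))
  }
  adj <- vector("list", g$n_nodes)
  for (i in seq_len(g$n_nodes)) adj[[i]] <- list(nbr = integer(0), w = numeric(0))
  sp <- split(seq_len(nrow(e)), e$src)
  for (s in names(sp)) {
    ix <- sp[[s]]
    w <- e$weight[ix]
    adj[[as.integer(s)]] <- list(nbr = e$dst[ix], w = w - min(w) + eps)
  }
  adj
}

# graph-level nonnegative weighted adjacency matrix (symmetrized)
.sym_adj_matrix <- function(g, eps = 1e-6) {
  gu <- if (g$directed) symmetrize(g) else g
  e <- gu$edges
  w <- e$weight
  if (min(w) <= 0) w <- w - min(w) + eps
  A <- matrix(0, g$n_nodes, g$n_nodes)
  A[cbind(e$src, e$dst)] <- w
  A[cbind(e$dst, e$src)] <- w
  A
}

#' Biased random-walk node embeddings (node2vec)
#'
#' Second-order random walks with return parameter `p` and in-out parameter
#' `q`; transition probabilities are proportional to the per-node
#' min-shifted positive edge weight. Walks follow edge direction on
#' directed graphs. The walk corpus is fed to skip-gram with negative
#' sampling (native code). Nodes with no out-edges that never occur in any
#' walk are embedded as zero vectors, with a warning.
#'
#' @param g a `similarity_graph`.
#' @param params a [node_embedding_params()].
#' @return `n x dim` `embedding_matrix`; deterministic under
#'   `params$seed`.
#' @export
node2vec_embed <- function(g, params = node_embedding_params("node2vec")) {
  n <- g$n_nodes
  if (n < 2) stop("graph needs >= 2 nodes")
  adj <- .adjacency(g)
  has_edge <- lapply(adj, function(a) {
    e <- new.env(parent = emptyenv(), size = max(1L, length(a$nbr)))
    for (x in a$nbr) assign(as.character(x), TRUE, envir = e)
    e
  })

  walks <- with_seed(params$seed, {
    out <- matrix(-1L, n * params$walks_per_node, params$walk_length)
    row <- 0
    for (rep in seq_len(params$walks_per_node)) {
      for (start in seq_len(n)) {
        row <- row + 1
        cur <- start; prev <- NA_integer_
        out[row, 1] <- cur - 1L
        for (t in 2:params$walk_length) {
          a <- adj[[cur]]
          if (!length(a$nbr)) break
          w <- a$w
          if (!is.na(prev) && (params$p != 1 || params$q != 1)) {
            bias <- vapply(a$nbr, function(x) {
              if (x == prev) 1 / params$p
              else if (exists(as.character(x), envir = has_edge[[prev]],
                              inherits = FALSE)) 1
              else 1 / params$q
            }, numeric(1))
            w <- w * bias
          }
          nxt <- a$nbr[sample.int(length(a$nbr), 1, prob = w)]
          out[row, t] <- nxt - 1L
          prev <- cur; cur <- nxt
        }
      }
    }
    out
  })

  emb <- skipgram_cpp(walks, n, params$dim, params$window,
                      params$negatives, params$sg_epochs, params$sg_alpha,
                      derive_seed(params$seed, 7))
  # a node is trained only if it occurs in a walk with at least 2 tokens
  lens <- rowSums(walks >= 0)
  seen <- sort(unique(as.integer(walks[walks >= 0 &
                                         row(walks) %in% which(lens >= 2)]))) + 1L
  missing <- setdiff(seq_len(n), seen)
  if (length(missing)) {
    warning(sprintf("%d isolated node(s) embedded as zero vectors",
                    length(missing)))
    emb[missing, ] <- 0
  }
  embedding_matrix(emb, method = "node:node2vec")
}

#' Spectral heat-wavelet node embeddings (GraphWave)
#'
#' For each heat scale `s`, the spectral wavelet is
#' `psi_a = U diag(exp(-s * lambda)) U' delta_a` on the (symmetrized,
#' nonnegative-weight) graph Laplacian; a node's features are the real and
#' imaginary parts of the empirical characteristic function of `psi_a`
#' sampled at `n_sample_points` points evenly spaced in `[0, 100]`.
#' Structure-only: automorphically equivalent nodes get equal rows.
#' Disconnected graphs are allowed (block-diagonal Laplacian).
#'
#' @inheritParams node2vec_embed
#' @return `n x (2 * n_sample_points * length(scales))` `embedding_matrix`.
#' @export
graphwave_embed <- function(g, params = node_embedding_params("graphwave")) {
  A <- .sym_adj_matrix(g)
  n <- nrow(A)
  L <- diag(rowSums(A)) - A
  eig <- eigen(L, symmetric = TRUE)
  tpts <- seq(0, 100, length.out = params$n_sample_points)
  feats <- matrix(0, n, 2 * params$n_sample_points * length(params$scales))
  col0 <- 0
  for (s in params$scales) {
    Psi <- eig$vectors %*% (exp(-s * pmax(eig$values, 0)) * t(eig$vectors))
    for (k in seq_along(tpts)) {
      # empirical characteristic function of column a over graph nodes
      ph <- tpts[k] * Psi
      feats[, col0 + 2 * k - 1] <- colMeans(cos(ph))
      feats[, col0 + 2 * k] <- colMeans(sin(ph))
    }
    col0 <- col0 + 2 * params$n_sample_points
  }
  embedding_matrix(feats, method = "node:graphwave")
}

#' Graph-infomax node embeddings (one-layer GCN encoder)
#'
#' Trains a one-layer GCN encoder `H = PReLU(A_hat X W)` (symmetrized,
#' self-looped, degree-normalized adjacency) with the Deep Graph Infomax
#' objective: a bilinear discriminator learns to tell true (node, graph
#' summary) pairs from corruptions built by row-shuffling the node
#' attributes.
#'
#' @inheritParams node2vec_embed
#' @param node_attrs `n x f` attribute matrix (e.g. image embeddings).
#' @return `n x dim` `embedding_matrix`; deterministic under `params$seed`.
#' @export
dgi_gcn_embed <- function(g, node_attrs,
                          params = node_embedding_params("dgi-gcn")) {
  X <- as.matrix(node_attrs)
  if (nrow(X) != g$n_nodes)
    stop("node_attrs must have one row per graph node")
  n <- g$n_nodes
  A <- .sym_adj_matrix(g) + diag(n)
  dinv <- 1 / sqrt(rowSums(A))
  Ahat <- A * outer(dinv, dinv)
  # column-standardize attributes for conditioning
  X <- scale(X)
  X[, !is.finite(colSums(X))] <- 0
  f <- ncol(X); d <- params$dim

  init <- with_seed(params$seed, list(
    W = matrix(rnorm(f * d, 0, sqrt(1 / f)), f, d),
    M = diag(d) + matrix(rnorm(d * d, 0, 0.01), d, d),
    a = 0.25,
    perms = lapply(seq_len(params$dgi_epochs), function(i) sample.int(n))))
  W <- init$W; M <- init$M; aa <- init$a
  AX <- Ahat %*% X

  adam <- list(mW = W * 0, vW = W * 0, mM = M * 0, vM = M * 0, ma = 0, va = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  prelu <- function(Z) ifelse(Z > 0, Z, aa * Z)

  for (ep in seq_len(params$dgi_epochs)) {
    perm <- init$perms[[ep]]
    AXc <- Ahat %*% X[perm, , drop = FALSE]
    Z <- AX %*% W; H <- prelu(Z)
    Zc <- AXc %*% W; Hc <- prelu(Zc)
    m <- colMeans(H); s <- 1 / (1 + exp(-m))
    u <- M %*% s
    pos <- as.numeric(H %*% u); neg <- as.numeric(Hc %*% u)
    sp <- 1 / (1 + exp(-pos)); sn <- 1 / (1 + exp(-neg))

    gp <- -(1 - sp) / (2 * n); gn <- sn / (2 * n)
    dH <- outer(gp, as.numeric(u))
    dHc <- outer(gn, as.numeric(u))
    du <- crossprod(H, gp) + crossprod(Hc, gn)
    dM <- du %*% t(s)
    ds <- crossprod(M, du)
    dm <- ds * s * (1 - s)
    dH <- dH + matrix(as.numeric(dm) / n, n, d, byrow = TRUE)

    dZ <- dH * ifelse(Z > 0, 1, aa)
    dZc <- dHc * ifelse(Zc > 0, 1, aa)
    da <- sum(dH * Z * (Z <= 0)) + sum(dHc * Zc * (Zc <= 0))
    dW <- crossprod(AX, dZ) + crossprod(AXc, dZc)

    step <- function(p, g, m_, v_) {
      m_ <- b1 * m_ + (1 - b1) * g
      v_ <- b2 * v_ + (1 - b2) * g^2
      list(p = p - params$dgi_lr * (m_ / (1 - b1^ep)) /
             (sqrt(v_ / (1 - b2^ep)) + eps), m = m_, v = v_)
    }
    r <- step(W, dW, adam$mW, adam$vW); W <- r$p; adam$mW <- r$m; adam$vW <- r$v
    r <- step(M, dM, adam$mM, adam$vM); M <- r$p; adam$mM <- r$m; adam$vM <- r$v
    r <- step(aa, da, adam$ma, adam$va); aa <- r$p; adam$ma <- r$m; adam$va <- r$v
  }

  H <- prelu(AX %*% W)
  embedding_matrix(H, method = "node:dgi-gcn")
}

#' Dispatch a node-embedding method
#'
#' Runs the configured method, or any user-supplied function with the same
#' `(g, params)` signature (attributed methods additionally receive
#' `node_attrs`).
#'
#' @inheritParams dgi_gcn_embed
#' @export
node_embed <- function(g, params, node_attrs = NULL) {
  if (is.function(params$method))
    return(params$method(g, params))
  switch(params$method,
    node2vec = node2vec_embed(g, params),
    graphwave = graphwave_embed(g, params),
    "dgi-gcn" = {
      if (is.null(node_attrs))
        stop("dgi-gcn requires node_attrs (image embeddings)")
      dgi_gcn_embed(g, node_attrs, params)
    },
    stop("unknown node embedding method: ", params$method))
}
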