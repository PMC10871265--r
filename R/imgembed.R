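#' Image embeddings and triplet-loss metric learning
#'
#' Projection images are embedded by a convolutional backbone and optionally
#' fine-tuned with a Siamese network: three weight-sharing branches embed an
#' anchor, a positive (same complex) and a negative (different complex), and
#' the triplet loss
#' \deqn{L(A,P,N) = \max(d(f(A),f(P)) - d(f(A),f(N)) + margin,\ 0)}
#' pulls same-complex projections together by at least `margin`. The
#' backbone is frozen; the trainable part is a dense head
#' (512, 256, 256 units; ReLU + batch normalization on the first two).
#'
#' @name imgembed
NULL

.backbones <- c("tiny-cnn", "alexnet", "vgg11", "densenet", "resnet18",
                "efficientnet-b1", "efficientnet-b7", "resnet50-pretrained")

# ---- tiny CNN backbone -----------------------------------------------------

# 'valid' 3x3 convolution of an H x W x Cin array with kernels
# 3 x 3 x Cin x Cout, via shift-and-accumulate
conv3x3 <- function(x, kern) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]; cout <- dim(kern)[4]
  oh <- h - 2; ow <- w - 2
  out <- array(0, dim = c(oh, ow, cout))
  for (f in seq_len(cout)) {
    acc <- matrix(0, oh, ow)
    for (ci in seq_len(cin))
      for (di in 0:2) for (dj in 0:2)
        acc <- acc + kern[di + 1, dj + 1, ci, f] *
          x[(1 + di):(oh + di), (1 + dj):(ow + dj), ci]
    out[, , f] <- acc
  }
  out
}

avgpool2 <- function(x) {
  h <- 2 * (dim(x)[1] %/% 2); w <- 2 * (dim(x)[2] %/% 2)
  x <- x[seq_len(h), seq_len(w), , drop = FALSE]
  (x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE] +
   x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE] +
   x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE] +
   x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]) / 4
}

tiny_cnn_params <- function(seed = 0, channels = c(8, 16, 32)) {
  with_seed(seed, {
    cin <- 3
    kerns <- list()
    for (b in seq_along(channels)) {
      fan_in <- 9 * cin
      kerns[[b]] <- array(rnorm(9 * cin * channels[b], 0,
                                sqrt(2 / fan_in)),
                          dim = c(3, 3, cin, channels[b]))
      cin <- channels[b]
    }
    list(kerns = kerns, channels = channels, seed = as.integer(seed))
  })
}

tiny_cnn_forward <- function(img, params) {
  rng <- range(img)
  img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  x <- array(rep(img, 3), dim = c(dim(img), 3))  # grayscale -> RGB boundary
  for (k in params$kerns) {
    x <- conv3x3(x, k)
    x <- pmax(x, 0)
    x <- avgpool2(x)
  }
  apply(x, 3, mean)  # global average pool
}

#' Backbone image embeddings
#'
#' Embeds every image with the penultimate pooled features of a
#' convolutional backbone. Only the `tiny-cnn` backbone (three conv blocks
#' with seeded random filters, average pooling, global average pool) ships
#' with the package; named ImageNet backbones require downloaded weights
#' and raise an error pointing at the `tiny-cnn` fallback. Images are
#' min-max scaled to `[0, 1]` per image and replicated to 3 channels.
#'
#' @param ps a `projection_set`.
#' @param backbone backbone name; see Details.
#' @param seed seed for the `tiny-cnn` random filters.
#' @return An `embedding_matrix` (`n x d` numeric matrix with attribute
#'   `method`).
#' @export
pretrained_embed <- function(ps, backbone = "tiny-cnn", seed = 0) {
  backbone <- match.arg(backbone, .backbones)
  if (backbone != "tiny-cnn")
    stop(sprintf(paste0(
      "backbone '%s' needs pretrained weights that are not bundled and ",
      "cannot be downloaded here; use backbone = 'tiny-cnn' instead"),
      backbone))
  params <- tiny_cnn_params(seed)
  n <- length(ps)
  emb <- t(vapply(seq_len(n),
                  function(i) tiny_cnn_forward(ps$images[i, , ], params),
                  numeric(sum(utils::tail(params$channels, 1)))))
  embedding_matrix(emb, method = "image:tiny-cnn")
}

#' Embedding matrix constructor
#'
#' @param x numeric matrix, one row per image/node.
#' @param method free-text method tag (`image:*`, `node:*`, `fused:*`).
#' @export
embedding_matrix <- function(x, method = "unknown") {
  x <- as.matrix(x)
  attr(x, "method") <- method
  class(x) <- c("embedding_matrix", class(x))
  x
}

# ---- triplets --------------------------------------------------------------

#' Generate (anchor, positive, negative) training triples
#'
#' In `random` mode every unordered same-class image pair is combined with
#' `n_negatives` negatives sampled uniformly from the other classes; in
#' `per_class` mode each pair gets one random negative from every other
#' class.
#'
#' @param labels per-image class labels.
#' @param n_negatives negatives per pair (`random` mode).
#' @param mode `"random"` or `"per_class"`.
#' @param seed integer seed.
#' @return Integer matrix with columns `anchor`, `positive`, `negative`
#'   (1-based image indices).
#' @export
generate_triples <- function(labels, n_negatives = 10,
                             mode = c("random", "per_class"), seed = 0) {
  mode <- match.arg(mode)
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 classes to build triples")
  with_seed(seed, {
    out <- list()
    for (cl in classes) {
      members <- which(labels == cl)
      if (length(members) < 2) next
      others <- which(labels != cl)
      prs <- combn(members, 2)
      for (p in seq_len(ncol(prs))) {
        if (mode == "random") {
          negs <- others[sample.int(length(others), n_negatives,
                                    replace = TRUE)]
        } else {
          negs <- vapply(setdiff(classes, cl), function(oc) {
            cand <- which(labels == oc)
            cand[sample.int(length(cand), 1)]
          }, integer(1))
        }
        out[[length(out) + 1]] <-
          cbind(anchor = prs[1, p], positive = prs[2, p], negative = negs)
      }
    }
    if (!length(out)) stop("no class has >= 2 members")
    tr <- do.call(rbind, out)
    rownames(tr) <- NULL
    tr
  })
}

#' Triplet loss
#'
#' `max(d(eA, eP) - d(eA, eN) + margin, 0)`; `d` is the squared Euclidean
#' distance by default (the FaceNet convention), or the plain Euclidean
#' norm with `squared = FALSE`.
#'
#' @param eA,eP,eN embedding vectors of equal length.
#' @param margin nonnegative margin (default 0.5).
#' @param squared use squared distances.
#' @return Scalar loss.
#' @export
triplet_loss <- function(eA, eP, eN, margin = 0.5, squared = TRUE) {
  dp <- sum((eA - eP)^2); dn <- sum((eA - eN)^2)
  if (!squared) { dp <- sqrt(dp); dn <- sqrt(dn) }
  max(dp - dn + margin, 0)
}

#' Split complexes into train and test class sets
#'
#' @param labels per-image class labels.
#' @param train_frac fraction of classes assigned to training (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test` class-name vectors (disjoint, union
#'   = all classes; both nonempty).
#' @export
split_complexes <- function(labels, train_frac = 0.7, seed = 0) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to split")
  n_train <- round(train_frac * length(classes))
  n_train <- min(max(n_train, 1), length(classes) - 1)
  with_seed(seed, {
    tr <- sort(sample(classes, n_train))
    list(train = tr, test = setdiff(classes, tr))
  })
}

# ---- dense head with batch norm (manual forward/backward) ------------------

head_init <- function(d_in, units = c(512, 256, 256), seed = 0) {
  with_seed(seed, {
    layers <- list()
    din <- d_in
    for (i in seq_along(units)) {
      u <- units[i]
      layers[[i]] <- list(
        W = matrix(rnorm(din * u, 0, sqrt(2 / din)), din, u),
        b = numeric(u),
        bn = i < length(units),   # BN + ReLU on the first two layers
        gamma = rep(1, u), beta = numeric(u),
        run_mean = numeric(u), run_var = rep(1, u))
      din <- u
    }
    layers
  })
}

head_forward <- function(layers, X, training = FALSE, eps = 1e-5) {
  cache <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    Z <- sweep(X %*% ly$W, 2, ly$b, "+")
    if (ly$bn) {
      if (training) {
        mu <- colMeans(Z)
        vr <- colMeans(sweep(Z, 2, mu)^2)
      } else {
        mu <- ly$run_mean; vr <- ly$run_var
      }
      istd <- 1 / sqrt(vr + eps)
      Xhat <- sweep(sweep(Z, 2, mu), 2, istd, "*")
      Y <- sweep(sweep(Xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      A <- pmax(Y, 0)
      cache[[i]] <- list(X = X, Z = Z, Xhat = Xhat, istd = istd, mu = mu,
                         vr = vr, Y = Y)
      X <- A
    } else {
      cache[[i]] <- list(X = X, Z = Z)
      X <- Z
    }
  }
  list(out = X, cache = cache)
}

head_backward <- function(layers, cache, dOut) {
  grads <- vector("list", length(layers))
  dX <- dOut
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; cc <- cache[[i]]
    if (ly$bn) {
      dY <- dX * (cc$Y > 0)                       # through ReLU
      dgamma <- colSums(dY * cc$Xhat)
      dbeta <- colSums(dY)
      dXhat <- sweep(dY, 2, ly$gamma, "*")
      N <- nrow(dY)
      sum_dxhat <- colSums(dXhat)
      sum_dxhat_xhat <- colSums(dXhat * cc$Xhat)
      dZ <- sweep(
        N * dXhat - matrix(sum_dxhat, N, length(sum_dxhat), byrow = TRUE) -
          cc$Xhat * matrix(sum_dxhat_xhat, N, length(sum_dxhat),
                           byrow = TRUE),
        2, cc$istd / N, "*")
    } else {
      dZ <- dX
      dgamma <- dbeta <- NULL
    }
    grads[[i]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ),
                       gamma = dgamma, beta = dbeta)
    dX <- dZ %*% t(ly$W)
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    zW <- ly$W * 0; zb <- ly$b * 0
    st <- list(mW = zW, vW = zW, mb = zb, vb = zb)
    if (ly$bn) {
      zg <- ly$gamma * 0
      st$mg <- zg; st$vg <- zg; st$mbeta <- zg; st$vbeta <- zg
    }
    st
  })
}

adam_step <- function(layers, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (i in seq_along(layers)) {
    g <- grads[[i]]; s <- state[[i]]
    r <- upd(layers[[i]]$W, g$W, s$mW, s$vW)
    layers[[i]]$W <- r$p; state[[i]]$mW <- r$m; state[[i]]$vW <- r$v
    r <- upd(layers[[i]]$b, g$b, s$mb, s$vb)
    layers[[i]]$b <- r$p; state[[i]]$mb <- r$m; state[[i]]$vb <- r$v
    if (layers[[i]]$bn) {
      r <- upd(layers[[i]]$gamma, g$gamma, s$mg, s$vg)
      layers[[i]]$gamma <- r$p; state[[i]]$mg <- r$m; state[[i]]$vg <- r$v
      r <- upd(layers[[i]]$beta, g$beta, s$mbeta, s$vbeta)
      layers[[i]]$beta <- r$p; state[[i]]$mbeta <- r$m
      state[[i]]$vbeta <- r$v
    }
  }
  list(layers = layers, state = state)
}

#' Siamese network configuration
#'
#' @param backbone `"tiny-cnn"` (bundled) or `"resnet50-pretrained"`
#'   (requires external weights).
#' @param margin triplet-loss margin (default 0.5).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 10).
#' @param batch_size triples per batch (default 2; 32 for split-complex
#'   training runs).
#' @param freeze_until all backbone layers up to this point are frozen; the
#'   bundled backbone is frozen in full (its features are fixed).
#' @param units dense-head layer widths.
#' @param squared use squared Euclidean distances in the loss.
#' @param l2_normalize L2-normalize output embeddings.
#' @param seed seed for weight init and batch shuffling.
#' @return A `siamese_config` list.
#' @export
siamese_config <- function(backbone = "tiny-cnn", margin = 0.5,
                           learning_rate = 1e-4, epochs = 10,
                           batch_size = 2, freeze_until = "backbone",
                           units = c(512, 256, 256), squared = TRUE,
                           l2_normalize = FALSE, seed = 0) {
  stopifnot(margin > 0, epochs >= 1, batch_size >= 1)
  structure(list(backbone = backbone, margin = margin,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, freeze_until = freeze_until,
                 units = units, squared = squared,
                 l2_normalize = l2_normalize, seed = as.integer(seed)),
            class = "siamese_config")
}

#' Train the Siamese encoder on triples
#'
#' Minimizes the mean triplet loss with Adam over the dense head; the
#' convolutional backbone is frozen, so its features are computed once.
#' Triples are split 80/20 into train/validation; per-epoch mean losses for
#' both are recorded.
#'
#' @param ps a `projection_set`.
#' @param triples triple matrix from [generate_triples()].
#' @param cfg a [siamese_config()].
#' @return A `siamese_encoder`: backbone parameters, head weights, config,
#'   and `history` (data.frame epoch/train_loss/val_loss).
#' @export
train_siamese <- function(ps, triples, cfg = siamese_config()) {
  if (is.null(dim(triples)) || nrow(triples) == 0)
    stop("triples must be a nonempty matrix")
  bb <- tiny_cnn_params(cfg$seed)
  n <- length(ps)
  feats <- t(vapply(seq_len(n),
                    function(i) tiny_cnn_forward(ps$images[i, , ], bb),
                    numeric(sum(utils::tail(bb$channels, 1)))))
  d0 <- ncol(feats)

  layers <- head_init(d0, cfg$units, seed = derive_seed(cfg$seed, 1))
  state <- adam_init(layers)

  nt <- nrow(triples)
  split <- with_seed(derive_seed(cfg$seed, 2), sample.int(nt))
  n_val <- max(1, floor(0.2 * nt))
  if (nt < 2) n_val <- 0
  val_idx <- if (n_val > 0) split[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(split, val_idx)

  batch_loss_grad <- function(E, B) {
    # E: 3B x d embeddings stacked [A; P; N]
    eA <- E[seq_len(B), , drop = FALSE]
    eP <- E[B + seq_len(B), , drop = FALSE]
    eN <- E[2 * B + seq_len(B), , drop = FALSE]
    dp <- rowSums((eA - eP)^2); dn <- rowSums((eA - eN)^2)
    if (!cfg$squared) { dp <- sqrt(dp); dn <- sqrt(dn) }
    li <- pmax(dp - dn + cfg$margin, 0)
    act <- li > 0
    g <- matrix(0, 3 * B, ncol(E))
    if (any(act)) {
      if (cfg$squared) {
        gA <- 2 * (eN - eP); gP <- -2 * (eA - eP); gN <- 2 * (eA - eN)
      } else {
        sp <- pmax(dp, 1e-12); sn <- pmax(dn, 1e-12)
        gA <- (eA - eP) / sp - (eA - eN) / sn
        gP <- -(eA - eP) / sp
        gN <- (eA - eN) / sn
      }
      w <- as.numeric(act) / B
      g[seq_len(B), ] <- gA * w
      g[B + seq_len(B), ] <- gP * w
      g[2 * B + seq_len(B), ] <- gN * w
    }
    list(loss = mean(li), grad = g)
  }

  eval_loss <- function(idx) {
    if (!length(idx)) return(NA_real_)
    B <- length(idx)
    X <- feats[c(triples[idx, 1], triples[idx, 2], triples[idx, 3]), ,
               drop = FALSE]
    E <- head_forward(layers, X, training = FALSE)$out
    batch_loss_grad(E, B)$loss
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  t_adam <- 0
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 100 + ep), sample(tr_idx))
    ep_losses <- numeric(0)
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      B <- length(idx)
      X <- feats[c(triples[idx, 1], triples[idx, 2], triples[idx, 3]), ,
                 drop = FALSE]
      fw <- head_forward(layers, X, training = TRUE)
      lg <- batch_loss_grad(fw$out, B)
      if (!is.finite(lg$loss))
        stop(sprintf(
          "NaN/Inf loss at epoch %d (batch starting %d); lr=%g, margin=%g",
          ep, start, cfg$learning_rate, cfg$margin))
      ep_losses <- c(ep_losses, lg$loss)
      grads <- head_backward(layers, fw$cache, lg$grad)
      t_adam <- t_adam + 1
      st <- adam_step(layers, grads, state, cfg$learning_rate, t_adam)
      layers <- st$layers; state <- st$state
      # update batch-norm running statistics (momentum 0.1)
      for (i in seq_along(layers)) {
        if (layers[[i]]$bn) {
          cc <- fw$cache[[i]]
          layers[[i]]$run_mean <- 0.9 * layers[[i]]$run_mean + 0.1 * cc$mu
          layers[[i]]$run_var <- 0.9 * layers[[i]]$run_var + 0.1 * cc$vr
        }
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = mean(ep_losses), val_loss = eval_loss(val_idx)))
  }

  structure(list(backbone = bb, layers = layers, cfg = cfg,
                 input_dim = d0,
                 image_size = dim(ps$images)[2:3], history = history),
            class = "siamese_encoder")
}

#' Embed a projection set with a trained Siamese encoder
#'
#' Inference mode (batch-norm running statistics); deterministic.
#'
#' @param encoder a `siamese_encoder` from [train_siamese()].
#' @param ps a `projection_set` with the training image size.
#' @return `n x 256` `embedding_matrix`.
#' @export
siamese_embed <- function(encoder, ps) {
  if (!identical(dim(ps$images)[2:3], encoder$image_size))
    stop("image size differs from the encoder's training size")
  n <- length(ps)
  feats <- t(vapply(seq_len(n),
                    function(i) tiny_cnn_forward(ps$images[i, , ],
                                                 encoder$backbone),
                    numeric(encoder$input_dim)))
  E <- head_forward(encoder$layers, feats, training = FALSE)$out
  if (isTRUE(encoder$cfg$l2_normalize)) {
    nr <- sqrt(rowSums(E^2)); nr[nr == 0] <- 1
    E <- E / nr
  }
  embedding_matrix(E, method = "image:siamese")
}

#' Save / load a Siamese encoder checkpoint
#'
#' Plain-text JSON checkpoint (weights flattened with dimensions).
#'
#' @param encoder a `siamese_encoder`.
#' @param path file path.
#' @export
save_encoder <- function(encoder, path) {
  ser <- list(
    cfg = unclass(encoder$cfg),
    input_dim = encoder$input_dim,
    image_size = encoder$image_size,
    backbone_seed = encoder$backbone$seed,
    backbone_channels = encoder$backbone$channels,
    layers = lapply(encoder$layers, function(ly) {
      list(W = as.numeric(ly$W), dimW = dim(ly$W), b = ly$b, bn = ly$bn,
           gamma = ly$gamma, beta = ly$beta,
           run_mean = ly$run_mean, run_var = ly$run_var)
    }),
    history = encoder$history)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow0(ser$layers)), function(i) {
    ly <- if (is.data.frame(ser$layers)) lapply(ser$layers, `[[`, i)
          else ser$layers[[i]]
    list(W = matrix(unlist(ly$W), ly$dimW[1], ly$dimW[2]),
         b = as.numeric(unlist(ly$b)), bn = isTRUE(ly$bn),
         gamma = as.numeric(unlist(ly$gamma)),
         beta = as.numeric(unlist(ly$beta)),
         run_mean = as.numeric(unlist(ly$run_mean)),
         run_var = as.numeric(unlist(ly$run_var)))
  })
  bb <- tiny_cnn_params(ser$backbone_seed,
                        channels = as.numeric(unlist(ser$backbone_channels)))
  structure(list(backbone = bb, layers = layers,
                 cfg = do.call(siamese_config,
                               ser$cfg[names(ser$cfg) %in%
                                       names(formals(siamese_config))]),
                 input_dim = ser$input_dim,
                 image_size = as.integer(unlist(ser$image_size)),
                 history = as.data.frame(ser$history)),
            class = "siamese_encoder")
}

nrow0 <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Export / import an embedding matrix as TSV
#'
#' First column is the 0-based image/node index; remaining columns are the
#' embedding dimensions.
#'
#' @param emb an `embedding_matrix`.
#' @param path file path.
#' @export
write_embedding_tsv <- function(emb, path) {
  df <- data.frame(index = seq_len(nrow(emb)) - 1,
                   unclass(emb)[, , drop = FALSE])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  df <- read.delim(path)
  df <- df[order(df$index), ]
  embedding_matrix(as.matrix(df[, -1, drop = FALSE]), method = "imported")
}
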