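#' Semi-supervised AutoML over method combinations
#'
#' A method combination fixes one choice per pipeline stage: image
#' embedding (or none), graph spec (measure, selection mode, direction),
#' node embedding (or none), fusion mode, and clusterer (a spatial
#' algorithm over a selectable distance, or a graph community method).
#' The driver evaluates every combination with hyperparameters tuned on a
#' 70/30 complex split and ranks them by the training-split matching
#' F-score; test metrics are reported but never used for selection.
#'
#' @name pipeline
NULL

#' Method combination descriptor
#'
#' @param image_method `"none"`, `"tiny-cnn"` or `"siamese"`.
#' @param node_method `"none"`, `"node2vec"`, `"graphwave"`, `"dgi-gcn"`,
#'   or a function `(g, params) -> matrix`.
#' @param graph_measure,graph_mode,graph_k,graph_m,graph_directed
#'   similarity-graph spec (ignored when no graph is needed).
#' @param fusion_mode one of the [fusion_config()] modes.
#' @param clusterer a spatial algorithm (`"dbscan"`, `"optics"`, `"birch"`,
#'   `"affinity"`) or `"graph:<method>"` for the eight graph clusterers.
#' @param distance `"auto"` (silhouette-selected) or a fixed measure name.
#' @return A `method_combo` list.
#' @export
method_combo <- function(image_method = "none", node_method = "node2vec",
                         graph_measure = "L2", graph_mode = "top_k",
                         graph_k = 5, graph_m = 3000, graph_directed = TRUE,
                         fusion_mode = "node_only", clusterer = "optics",
                         distance = "auto") {
  structure(list(image_method = image_method, node_method = node_method,
                 graph_measure = graph_measure, graph_mode = graph_mode,
                 graph_k = graph_k, graph_m = graph_m,
                 graph_directed = graph_directed, fusion_mode = fusion_mode,
                 clusterer = clusterer, distance = distance),
            class = "method_combo")
}

#' @export
format.method_combo <- function(x, ...) {
  sprintf("img=%s|node=%s|graph=%s,%s,k=%s,%s|fuse=%s|clust=%s|dist=%s",
          x$image_method,
          if (is.function(x$node_method)) "custom" else x$node_method,
          x$graph_measure, x$graph_mode, x$graph_k,
          if (x$graph_directed) "dir" else "undir",
          x$fusion_mode, x$clusterer, x$distance)
}

#' Run configuration
#'
#' @param combos list of [method_combo()]s.
#' @param seed master seed (fixed and logged in every report row).
#' @param train_frac complex-split fraction.
#' @param out_dir optional output directory for reports and cluster files.
#' @param cache logical; reuse shared intermediate artifacts (graphs,
#'   embeddings) across combos.
#' @export
run_config <- function(combos = default_combos(), seed = 0,
                       train_frac = 0.7, out_dir = NULL, cache = TRUE) {
  structure(list(combos = combos, seed = as.integer(seed),
                 train_frac = train_frac, out_dir = out_dir,
                 cache = cache), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with fields of `run_config`; combos given as
#'   lists of [method_combo()] arguments.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  combos <- if (!is.null(y$combos))
    lapply(y$combos, function(cc) do.call(method_combo, cc))
  else default_combos()
  run_config(combos = combos, seed = y$seed %||% 0,
             train_frac = y$train_frac %||% 0.7,
             out_dir = y$out_dir, cache = y$cache %||% TRUE)
}

#' Default combination list
#'
#' Mirrors the pipeline stages that dominate the method ranking: graph
#' community detection on the L2 graph (directed and undirected), spatial
#' clustering of node embeddings, and fused image + node embeddings.
#'
#' @return list of `method_combo`s.
#' @export
default_combos <- function() {
  c(
    lapply(c("graph:walktrap", "graph:label_prop_async",
             "graph:greedy_modularity", "graph:wcc"),
           function(m) method_combo(node_method = "none",
                                    fusion_mode = "node_only",
                                    clusterer = m)),
    list(
      method_combo(node_method = "node2vec", clusterer = "optics"),
      method_combo(node_method = "node2vec", clusterer = "dbscan"),
      method_combo(node_method = "graphwave", clusterer = "birch"),
      method_combo(image_method = "tiny-cnn", node_method = "node2vec",
                   fusion_mode = "concat_then_reduce",
                   clusterer = "affinity"),
      method_combo(image_method = "siamese", node_method = "node2vec",
                   fusion_mode = "reduce_then_concat", clusterer = "optics"),
      method_combo(image_method = "siamese", node_method = "dgi-gcn",
                   fusion_mode = "concat_then_reduce", clusterer = "optics")
    ))
}

.cache_get <- function(cache, key, build) {
  if (is.null(cache)) return(build())
  if (is.null(cache[[key]])) cache[[key]] <- build()
  cache[[key]]
}

#' Evaluate one method combination
#'
#' Executes graph build, embeddings, fusion, tuning/clustering and the
#' metric suite for a single combination. Any stage failure yields a
#' report marked `failed` (with the stage and message) instead of an
#' error, so a surrounding sweep continues.
#'
#' @param ps a `projection_set`.
#' @param combo a [method_combo()].
#' @param truth ground-truth labels (length `n`).
#' @param seed integer seed.
#' @param split optional list(train, test) of class names; computed via
#'   [split_complexes()] when `NULL`.
#' @param cache optional environment for shared artifacts.
#' @return An `eval_report` augmented with provenance (`combo`, `seed`,
#'   train/test FMMF), or a `failed_report`.
#' @export
evaluate_method <- function(ps, combo, truth, seed = 0, split = NULL,
                            cache = NULL) {
  stage <- "setup"
  tryCatch({
    n <- length(ps)
    stopifnot(length(truth) == n)
    split <- split %||% split_complexes(truth, seed = seed)
    train_idx <- which(truth %in% split$train)

    needs_graph <- !identical(combo$node_method, "none") ||
      startsWith(combo$clusterer, "graph:")
    g <- NULL
    if (needs_graph) {
      stage <- "graph"
      g <- .cache_get(cache, sprintf("graph_%s_%s_%s_%s", combo$graph_measure,
                                     combo$graph_mode, combo$graph_k,
                                     combo$graph_m), function() {
        lps <- .cache_get(cache, "lps", function() line_projection_stack(ps))
        sm <- .cache_get(cache, paste0("sm_", combo$graph_measure),
                         function() score_matrix(lps, combo$graph_measure))
        build_similarity_graph(sm, mode = combo$graph_mode,
                               k = combo$graph_k, m = combo$graph_m)
      })
      if (!combo$graph_directed) g <- symmetrize(g)
    }

    if (startsWith(combo$clusterer, "graph:")) {
      stage <- "graph_cluster"
      fit <- graph_cluster(g, sub("^graph:", "", combo$clusterer),
                           seed = seed)
      emb <- NULL
      measure <- NULL
    } else {
      stage <- "image_embedding"
      img_emb <- switch(combo$image_method,
        none = NULL,
        "tiny-cnn" = .cache_get(cache, "img_tinycnn", function()
          pretrained_embed(ps, "tiny-cnn", seed = seed)),
        siamese = .cache_get(cache, "img_siamese", function() {
          tr_lab <- truth
          tr_ps <- projection_set(
            ps$images[train_idx, , , drop = FALSE],
            labels = truth[train_idx], source = "train split")
          triples <- generate_triples(truth[train_idx], seed = seed)
          # triples index the training subset; train and embed all images
          enc <- train_siamese(tr_ps, triples,
                               siamese_config(seed = seed, batch_size = 32,
                                              epochs = 10))
          siamese_embed(enc, ps)
        }),
        stop("unknown image method: ", combo$image_method))

      stage <- "node_embedding"
      node_emb <- if (identical(combo$node_method, "none")) NULL else {
        prm <- node_embedding_params(
          if (is.function(combo$node_method)) "node2vec"
          else combo$node_method, seed = seed)
        if (is.function(combo$node_method)) prm$method <- combo$node_method
        node_embed(g, prm, node_attrs = img_emb)
      }

      stage <- "fusion"
      emb <- combine(img_emb, node_emb, fusion_config(combo$fusion_mode))

      stage <- "distance_selection"
      measure <- if (identical(combo$distance, "auto"))
        as.character(select_distance(emb, train_idx, truth))
      else combo$distance

      stage <- "tuning"
      fit <- tune_and_fit(emb, combo$clusterer, measure = measure,
                          train_idx = train_idx,
                          train_truth = truth[train_idx])
    }

    stage <- "evaluation"
    rep <- evaluate_clustering(fit$labels, truth, emb = emb,
                               measure = measure %||% "euclidean")
    test_idx <- setdiff(seq_len(n), train_idx)
    rep$train_fmmf <- unname(fmmf(labels_to_partition(fit$labels[train_idx]),
                                  labels_to_partition(truth[train_idx]))["F"])
    rep$test_fmmf <- if (length(test_idx))
      unname(fmmf(labels_to_partition(fit$labels[test_idx]),
                  labels_to_partition(truth[test_idx]))["F"])
    else NA_real_
    rep$combo <- format(combo)
    rep$params <- fit$params
    rep$algorithm <- fit$algorithm
    rep$distance <- measure
    rep$seed <- seed
    rep$labels <- fit$labels
    rep$version <- as.character(utils::packageVersion("projclust"))
    rep
  }, error = function(e) {
    structure(list(failed = TRUE, stage = stage,
                   message = conditionMessage(e), combo = format(combo),
                   seed = seed),
              class = "failed_report")
  })
}

#' Run the AutoML sweep and rank method combinations
#'
#' Fixes one 70/30 complex split for the whole run, evaluates every
#' combination (tuning on the training complexes only), and returns the
#' report table ranked by training-split FMMF.
#'
#' @param ps a `projection_set` with labels (or `truth` supplied).
#' @param config a [run_config()].
#' @param truth ground-truth labels; defaults to `ps$labels`.
#' @return data.frame, one row per non-failed combination, ranked by
#'   `train_fmmf`; failures are attached as attribute `failures`.
#' @export
run_automl <- function(ps, config = run_config(), truth = ps$labels) {
  if (is.null(truth)) stop("ground-truth labels required")
  if (length(unique(truth)) < 2) stop("need >= 2 classes")
  split <- split_complexes(truth, config$train_frac, seed = config$seed)
  cache <- if (isTRUE(config$cache)) new.env(parent = emptyenv()) else NULL

  reports <- lapply(config$combos, function(cc)
    evaluate_method(ps, cc, truth, seed = config$seed, split = split,
                    cache = cache))
  ok <- !vapply(reports, inherits, logical(1), "failed_report")

  rows <- lapply(reports[ok], function(r) {
    data.frame(combo = r$combo, algorithm = r$algorithm,
               distance = r$distance %||% NA_character_,
               n_clusters = r$n_pred_clusters,
               fmm_precision = r$fmm_precision, fmm_recall = r$fmm_recall,
               fmmf = r$fmmf, cmmf = r$cmmf, qi_f = r$qi_f,
               unspa = r$unspa, train_fmmf = r$train_fmmf,
               test_fmmf = r$test_fmmf, seed = r$seed,
               version = r$version, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(tab)) tab <- tab[order(-tab$train_fmmf), ]
  rownames(tab) <- NULL
  attr(tab, "failures") <- reports[!ok]
  attr(tab, "split") <- split
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(tab, file.path(config$out_dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  tab
}

#' t-SNE plot of embeddings colored by label
#'
#' @param emb embedding matrix (`n >= 5` rows).
#' @param labels per-point labels for coloring.
#' @param measure distance measure for the affinities.
#' @param seed integer seed.
#' @param out_path PNG output path.
#' @param ... passed to [tsne_embed()].
#' @return Invisibly, the `n x 2` coordinates.
#' @export
tsne_plot <- function(emb, labels, measure = "euclidean", seed = 0,
                      out_path = "tsne.png", ...) {
  Y <- tsne_embed(emb, measure = measure, seed = seed, ...)
  fl <- factor(labels)
  grDevices::png(out_path, width = 800, height = 700)
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(max(3, nlevels(fl)), "Dark 3")
  graphics::plot(Y[, 1], Y[, 2], col = cols[as.integer(fl)], pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = sprintf("t-SNE (%s distance)", measure))
  graphics::legend("topright", legend = levels(fl),
                   col = cols[seq_len(nlevels(fl))], pch = 19, cex = 0.7)
  invisible(Y)
}
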