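#' Embedding configuration
#'
#' Defaults follow common practice for track-metric embeddings:
#' `n_neighbors = 10`, `min_dist = 0`, two output dimensions.
#'
#' @param method `"umap"` or `"tsne"`.
#' @param n_neighbors Neighbourhood size (>= 2). For t-SNE this sets the
#'   perplexity (capped at `(n - 1) / 3`).
#' @param min_dist UMAP minimum distance.
#' @param n_dimension Output dimensionality (2 for the plotting path).
#' @param seed Integer seed; embeddings are deterministic given the seed.
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(method = c("umap", "tsne"), n_neighbors = 10L,
                             min_dist = 0, n_dimension = 2L, seed = 42L) {
  method <- match.arg(method)
  if (n_neighbors < 2) stop("n_neighbors must be >= 2", call. = FALSE)
  structure(list(method = method, n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist, n_dimension = as.integer(n_dimension),
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Clustering configuration
#'
#' @param clustering_data_source `"embedding"` (cluster the 2-D embedding)
#'   or `"features"` (cluster the z-scored feature matrix).
#' @param min_samples Core-distance neighbourhood size.
#' @param min_cluster_size Smallest allowed cluster (>= 2).
#' @param metric `"euclidean"` or `"canberra"`.
#' @param allow_single_cluster Permit the hierarchy root as a cluster; the
#'   reference default is `FALSE` (a dataset with no internal split is all
#'   noise). Set `TRUE` for degenerate single-mass data.
#' @param seed Integer seed (logged in outputs; the clustering itself is
#'   deterministic).
#' @return A `cluster_config` object.
#' @export
cluster_config <- function(clustering_data_source = c("embedding",
                                                      "features"),
                           min_samples = 20L, min_cluster_size = 200L,
                           metric = c("euclidean", "canberra"),
                           allow_single_cluster = FALSE, seed = 42L) {
  clustering_data_source <- match.arg(clustering_data_source)
  metric <- match.arg(metric)
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2",
                                 call. = FALSE)
  structure(list(clustering_data_source = clustering_data_source,
                 min_samples = as.integer(min_samples),
                 min_cluster_size = as.integer(min_cluster_size),
                 metric = metric,
                 allow_single_cluster = allow_single_cluster,
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Build the z-scored feature matrix for embedding/clustering
#'
#' Selects the given track metric columns, drops tracks with any non-finite
#' selected value (count reported in a message), drops constant columns
#' (with a warning), and z-scores each remaining column (mean 0, sample
#' SD 1).
#'
#' @param ds A `track_dataset` with metrics computed.
#' @param metrics Metric column names (>= 2).
#' @return Numeric matrix with `unique_track_id` row names; attributes
#'   `n_dropped_tracks` and `dropped_columns`.
#' @export
build_feature_matrix <- function(ds, metrics = NULL) {
  assert_dataset(ds)
  if (is.null(metrics)) {
    metrics <- intersect(track_metric_names(), names(ds$tracks))
  }
  miss <- setdiff(metrics, names(ds$tracks))
  if (length(miss) > 0) {
    stop("metric column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(metrics) < 2) stop("need >= 2 metrics", call. = FALSE)
  m <- as.matrix(ds$tracks[, metrics])
  rownames(m) <- ds$tracks$unique_track_id
  ok <- rowSums(!is.finite(m)) == 0
  if (any(!ok)) {
    message("build_feature_matrix: dropped ", sum(!ok),
            " track(s) with non-finite metric values")
  }
  m <- m[ok, , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  const <- !is.finite(sds) | sds == 0
  if (all(const)) stop("all selected metric columns are constant",
                       call. = FALSE)
  if (any(const)) {
    warning("dropping constant metric column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "n_dropped_tracks") <- sum(!ok)
  attr(out, "dropped_columns") <- colnames(ds$tracks[, metrics])[const]
  out
}

#' Embed a feature matrix in two dimensions
#'
#' UMAP (via uwot, single-threaded for determinism) or t-SNE (via Rtsne).
#' Row order and row names are preserved; the same matrix, configuration
#' and seed give identical coordinates.
#'
#' @param m Feature matrix from [build_feature_matrix()].
#' @param config An [embedding_config()].
#' @return `n x n_dimension` coordinate matrix with the input row names.
#' @export
embed_tracks <- function(m, config = embedding_config()) {
  if (!inherits(config, "embedding_config")) {
    stop("config must be an embedding_config", call. = FALSE)
  }
  n <- nrow(m)
  if (n < config$n_neighbors + 1) {
    stop("need at least n_neighbors + 1 = ", config$n_neighbors + 1,
         " rows, got ", n, call. = FALSE)
  }
  set.seed(config$seed)
  coords <- if (config$method == "umap") {
    uwot::umap(m, n_neighbors = config$n_neighbors,
               min_dist = config$min_dist,
               n_components = config$n_dimension,
               n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  } else {
    perp <- min(config$n_neighbors, floor((n - 1) / 3))
    out <- Rtsne::Rtsne(m, dims = config$n_dimension, perplexity = perp,
                        check_duplicates = FALSE, pca = FALSE,
                        num_threads = 1, verbose = FALSE)
    out$Y
  }
  if (any(!is.finite(coords))) {
    stop("embedding produced non-finite coordinates", call. = FALSE)
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}

#' Density-based clustering of tracks (HDBSCAN)
#'
#' Runs HDBSCAN on either the 2-D embedding or the z-scored feature matrix
#' (per `config$clustering_data_source` the caller chooses what to pass).
#' Labels are integers `0, 1, ...` with `-1` for noise.
#'
#' @param x Coordinate or feature matrix with track-id row names.
#' @param config A [cluster_config()].
#' @return A `cluster_assignment`: named integer vector of labels with
#'   attribute `n_clusters`.
#' @export
cluster_tracks <- function(x, config = cluster_config()) {
  if (!inherits(config, "cluster_config")) {
    stop("config must be a cluster_config", call. = FALSE)
  }
  labels <- hdbscan_labels(
    x, min_samples = config$min_samples,
    min_cluster_size = config$min_cluster_size,
    metric = config$metric,
    allow_single_cluster = config$allow_single_cluster
  )
  names(labels) <- rownames(x)
  attr(labels, "n_clusters") <- length(unique(labels[labels >= 0]))
  class(labels) <- "cluster_assignment"
  labels
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", length(x), "tracks,",
      attr(x, "n_clusters"), "cluster(s),",
      sum(unclass(x) == -1L), "noise\n")
  invisible(x)
}

#' Condition fingerprint over clusters
#'
#' Per condition, the percentage of its (clustered-subset) tracks in each
#' cluster label; noise (`-1`) is reported as its own category so that
#' every condition row sums to 100. Conditions absent from the clustered
#' subset get a row of `NaN` with a warning.
#'
#' @param assignment A [cluster_tracks()] result.
#' @param ds The `track_dataset` the assignment was computed from.
#' @return Tibble: one row per condition, one column per cluster label
#'   (noise column `"noise"`).
#' @export
cluster_fingerprint <- function(assignment, ds) {
  assert_dataset(ds)
  ids <- names(assignment)
  lab <- as.integer(unclass(assignment))
  cond_of <- stats::setNames(ds$tracks$condition, ds$tracks$unique_track_id)
  conds <- sort(unique(ds$tracks$condition))
  labs <- sort(unique(lab))
  lab_names <- ifelse(labs == -1L, "noise", paste0("cluster_", labs))
  out <- matrix(NaN, length(conds), length(labs),
                dimnames = list(conds, lab_names))
  for (cn in conds) {
    sel <- cond_of[ids] == cn
    ntot <- sum(sel)
    if (ntot == 0) {
      warning("condition absent from clustered subset: ", cn)
      next
    }
    tab <- table(factor(lab[sel], levels = labs))
    out[cn, ] <- 100 * as.numeric(tab) / ntot
  }
  tibble::as_tibble(out, rownames = "condition")
}

#' Cluster metric profile (Z-scores across cluster means)
#'
#' For each metric, the mean per non-noise cluster is z-scored across the
#' cluster means: `(cluster mean - grand mean of cluster means) / SD of
#' cluster means`. A metric with equal cluster means gives a zero row
#' (0/0 guarded to 0). Noise tracks are excluded.
#'
#' @param ds A `track_dataset` with metrics computed.
#' @param assignment A [cluster_tracks()] result.
#' @param metrics Metric column names.
#' @return Tibble: one row per cluster, one z-score column per metric.
#' @export
cluster_profile <- function(ds, assignment, metrics) {
  assert_dataset(ds)
  lab <- as.integer(unclass(assignment))
  ids <- names(assignment)
  keep <- lab >= 0
  clusters <- sort(unique(lab[keep]))
  if (length(clusters) < 2) {
    stop("need >= 2 non-noise clusters for a cross-cluster Z-score",
         call. = FALSE)
  }
  tr <- ds$tracks[match(ids[keep], ds$tracks$unique_track_id), , drop = FALSE]
  cl <- lab[keep]
  means <- vapply(metrics, function(mname) {
    vapply(clusters, function(k) {
      v <- tr[[mname]][cl == k]
      mean(v[is.finite(v)])
    }, numeric(1))
  }, numeric(length(clusters)))
  means <- matrix(means, nrow = length(clusters),
                  dimnames = list(paste0("cluster_", clusters), metrics))
  z <- apply(means, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col))
    else (col - mean(col)) / s
  })
  z <- matrix(z, nrow = length(clusters),
              dimnames = dimnames(means))
  tibble::as_tibble(z, rownames = "cluster")
}

#' Exemplar tracks per cluster
#'
#' The `k` tracks closest (Euclidean, in the z-scored feature space used
#' for clustering) to their cluster centroid; ties broken by track id
#' order. Requesting more exemplars than a cluster holds returns the whole
#' cluster with a warning.
#'
#' @param m Feature matrix ([build_feature_matrix()]) with track-id rows.
#' @param assignment A [cluster_tracks()] result.
#' @param k Exemplars per cluster.
#' @return Named list: cluster label -> character vector of track ids.
#' @export
exemplar_tracks <- function(m, assignment, k = 5L) {
  lab <- as.integer(unclass(assignment))
  ids <- names(assignment)
  common <- intersect(ids, rownames(m))
  clusters <- sort(unique(lab[lab >= 0]))
  if (length(clusters) == 0) stop("no non-noise clusters", call. = FALSE)
  out <- list()
  for (cc in clusters) {
    members <- intersect(ids[lab == cc], common)
    xm <- m[members, , drop = FALSE]
    centroid <- colMeans(xm)
    dist2 <- rowSums(sweep(xm, 2, centroid)^2)
    ord <- order(dist2, members)  # deterministic tie-break by id
    kk <- k
    if (k > length(members)) {
      warning("cluster ", cc, " has only ", length(members),
              " track(s); returning all")
      kk <- length(members)
    }
    out[[paste0("cluster_", cc)]] <- members[ord][seq_len(kk)]
  }
  out
}
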