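#' Track counts per condition and repeat
#'
#' Exact track counts for every condition x replicate cell, including empty
#' cells (count 0) for conditions/replicates present in the spot table, plus
#' per-condition totals in the `"condition_totals"` attribute.
#'
#' @param ds A `track_dataset`.
#' @return Tibble with columns condition, replicate, n_tracks.
#' @export
group_counts <- function(ds) {
  assert_dataset(ds)
  counts <- ds$tracks |>
    dplyr::count(.data$condition, .data$replicate, name = "n_tracks") |>
    tidyr::complete(.data$condition, .data$replicate,
                    fill = list(n_tracks = 0L)) |>
    dplyr::arrange(.data$condition, .data$replicate)
  attr(counts, "condition_totals") <- counts |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_tracks = sum(.data$n_tracks), .groups = "drop")
  counts
}

cosine_distance_matrix <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    # a zero vector has no direction; treat as orthogonal to everything
    nrm[nrm == 0] <- 1
  }
  s <- tcrossprod(m / nrm)
  s[s > 1] <- 1
  s[s < -1] <- -1
  d <- 1 - s
  diag(d) <- 0
  d
}

#' Replicate / field-of-view similarity dendrogram
#'
#' Summarises each group (field of view, or condition x replicate) by the
#' median of each selected track metric, z-scores the summary features
#' across groups, and agglomerates with complete linkage on the cosine
#' distance (1 - cosine similarity). Used to spot outlier replicates or
#' fields of view.
#'
#' @param ds A `track_dataset` with metrics computed.
#' @param group_by `"fov"` (per source file) or `"condition_replicate"`.
#' @param metrics Metric column names; default: all computed motility
#'   metrics present.
#' @return A `similarity_tree`: list with the `hclust` object, the linkage
#'   table (`$merges`), labels and the distance matrix.
#' @export
similarity_tree <- function(ds, group_by = c("fov", "condition_replicate"),
                            metrics = NULL) {
  assert_dataset(ds)
  group_by <- match.arg(group_by)
  if (is.null(metrics)) {
    metrics <- intersect(track_metric_names(), names(ds$tracks))
  }
  miss <- setdiff(metrics, names(ds$tracks))
  if (length(miss) > 0) {
    stop("metric column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr <- ds$tracks
  tr$.group <- if (group_by == "fov") tr$file_name else
    paste(tr$condition, tr$replicate, sep = "_")
  feat <- tr |>
    dplyr::group_by(.data$.group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metrics),
                                   ~ stats::median(.x[is.finite(.x)])),
                     .groups = "drop")
  empty <- rowSums(is.na(feat[, metrics])) == length(metrics)
  if (any(empty)) {
    warning("excluding group(s) with no finite metric values: ",
            paste(feat$.group[empty], collapse = ", "))
    feat <- feat[!empty, , drop = FALSE]
  }
  if (nrow(feat) < 2) stop("need >= 2 groups to build a tree", call. = FALSE)
  m <- as.matrix(feat[, metrics])
  rownames(m) <- feat$.group
  # z-score each feature across groups; constant features carry no signal
  sds <- apply(m, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  m <- scale(m[, keep, drop = FALSE])
  d <- cosine_distance_matrix(m)
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  structure(
    list(hclust = hc,
         merges = tibble::tibble(step = seq_along(hc$height),
                                 height = hc$height),
         labels = rownames(m),
         distance = d,
         group_by = group_by,
         distance_definition = "1 - cosine similarity of z-scored medians"),
    class = "similarity_tree"
  )
}

#' @export
print.similarity_tree <- function(x, ...) {
  cat("<similarity_tree>", length(x$labels), "groups (", x$group_by,
      "),", x$distance_definition, "\n")
  invisible(x)
}

#' Downsample every condition x repeat cell to the smallest cell
#'
#' Balanced resampling: with `m` the minimum track count over cells, each
#' cell is downsampled to exactly `m` tracks without replacement (seeded).
#' Spots of removed tracks are removed.
#'
#' @param ds A `track_dataset`.
#' @param seed Integer seed.
#' @return A balanced `track_dataset`.
#' @export
resample_balanced <- function(ds, seed = 42) {
  assert_dataset(ds)
  counts <- dplyr::count(ds$tracks, .data$condition, .data$replicate)
  if (any(counts$n == 0)) {
    bad <- counts[counts$n == 0, ]
    stop("empty condition x replicate cell: ",
         paste(bad$condition, bad$replicate, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  m <- min(counts$n)
  set.seed(seed)
  keep <- ds$tracks |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::group_map(function(g, key) {
      ids <- sort(g$unique_track_id)
      sample(ids, m, replace = FALSE)
    })
  subset_tracks(ds, unlist(keep))
}

#' Distribution check between original and resampled data
#'
#' Per condition and metric, a two-sample Kolmogorov-Smirnov test between
#' the original and resampled per-track values; a p-value close to 1 means
#' resampling left the distribution essentially unchanged.
#'
#' @param original,resampled `track_dataset`s sharing conditions.
#' @param metrics Metric column names present in both track tables.
#' @return Tibble condition x metric with the KS p-value (`p_ks`) and
#'   statistic (`statistic`).
#' @export
resampling_check <- function(original, resampled, metrics) {
  assert_dataset(original); assert_dataset(resampled)
  miss <- setdiff(metrics, intersect(names(original$tracks),
                                     names(resampled$tracks)))
  if (length(miss) > 0) {
    stop("metric(s) missing from a track table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  conds <- intersect(unique(original$tracks$condition),
                     unique(resampled$tracks$condition))
  grid <- expand.grid(condition = conds, metric = metrics,
                      stringsAsFactors = FALSE)
  res <- purrr::pmap(grid, function(condition, metric) {
    v1 <- original$tracks[[metric]][original$tracks$condition == condition]
    v2 <- resampled$tracks[[metric]][resampled$tracks$condition == condition]
    v1 <- v1[is.finite(v1)]; v2 <- v2[is.finite(v2)]
    kt <- suppressWarnings(stats::ks.test(v1, v2, exact = FALSE))
    tibble::tibble(condition = condition, metric = metric,
                   statistic = unname(kt$statistic),
                   p_ks = min(1, kt$p.value))
  })
  dplyr::bind_rows(res)
}
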