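# ggplot2 figure builders; each returns a ggplot object so the CLI can
# save PDFs and tests can inspect layers without rendering.

#' Tukey boxplot of a track metric per condition and repeat
#' @param ds A `track_dataset` with the metric computed.
#' @param metric Track metric column name.
#' @return A ggplot object.
#' @export
plot_metric_boxplot <- function(ds, metric) {
  bd <- tukey_boxplot_data(ds, metric)
  dat <- dplyr::filter(ds$tracks, is.finite(.data[[metric]]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$condition,
                                    y = .data[[metric]],
                                    fill = .data$replicate)) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.12, dodge.width = 0.8), size = 0.3, alpha = 0.4) +
    ggplot2::coord_cartesian(ylim = c(bd$axis_low[1], bd$axis_high[1])) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Mirrored effect-size / p-value heatmap
#' @param cm A [pairwise_comparison_matrix()] result.
#' @return A ggplot object.
#' @export
plot_comparison_heatmap <- function(cm) {
  m <- cm$matrix
  df <- expand.grid(a = rownames(m), b = colnames(m),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(m)
  df$what <- ifelse(match(df$a, rownames(m)) < match(df$b, colnames(m)),
                    "Cohen's d", "p-value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%s\n%.3g", .data$what, .data$value)), size = 2.6) +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL, title = cm$metric) +
    ggplot2::theme_minimal()
}

#' Stacked histogram of track counts per condition and repeat
#' @param counts A [group_counts()] tibble.
#' @return A ggplot object.
#' @export
plot_group_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$condition,
                                       y = .data$n_tracks,
                                       fill = .data$replicate)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_tracks),
                       position = ggplot2::position_stack(vjust = 0.5),
                       size = 2.8) +
    ggplot2::labs(x = NULL, y = "tracks", fill = "repeat") +
    ggplot2::theme_minimal()
}

#' Embedding scatter coloured by cluster or condition
#' @param emb Tibble with `dim1`, `dim2` and a colour column.
#' @param colour Column name to colour by.
#' @return A ggplot object.
#' @export
plot_embedding <- function(emb, colour = "cluster") {
  ggplot2::ggplot(emb, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                    colour = factor(.data[[colour]]))) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7) +
    ggplot2::labs(colour = colour) +
    ggplot2::theme_minimal()
}

#' Fingerprint stacked-bar plot
#' @param fp A [cluster_fingerprint()] tibble.
#' @return A ggplot object.
#' @export
plot_fingerprint <- function(fp) {
  long <- tidyr::pivot_longer(fp, -"condition", names_to = "cluster",
                              values_to = "percentage")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition,
                                     y = .data$percentage,
                                     fill = .data$cluster)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of tracks") +
    ggplot2::theme_minimal()
}

#' Cluster-profile Z-score heatmap
#' @param profile A [cluster_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_cluster_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, -"cluster", names_to = "metric",
                              values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$cluster,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Ripley L(r) - r curve with its CSR envelope
#' @param rip A [ripley_track_analysis()] result.
#' @return A ggplot object.
#' @export
plot_ripley <- function(rip) {
  df <- dplyr::left_join(rip$curve, rip$envelope, by = "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$envelope_low,
                                      ymax = .data$envelope_high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$L_minus_r), colour = "blue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = "L(r) - r") +
    ggplot2::theme_minimal()
}

#' ROI distance validation overlay
#'
#' Sampled spot positions with circles of radius equal to the measured
#' distance, over the ROI boundary — a visual check that distances are
#' measured correctly.
#'
#' @param ds Dataset after [distance_to_roi()].
#' @param roi The `roi_geometry` used.
#' @param n_tracks Number of randomly chosen tracks to display.
#' @param seed Seed for the choice of tracks.
#' @return A ggplot object.
#' @export
plot_roi_overlay <- function(ds, roi, n_tracks = 10, seed = 42) {
  set.seed(seed)
  ids <- sort(unique(ds$spots$unique_track_id))
  pick <- sample(ids, min(n_tracks, length(ids)))
  sp <- ds$spots |>
    dplyr::filter(.data$unique_track_id %in% pick) |>
    dplyr::group_by(.data$unique_track_id) |>
    dplyr::slice_head(n = 1) |> dplyr::ungroup()
  boundary <- if (roi$type == "polygon") {
    v <- roi$vertices
    if (roi$closed) v <- rbind(v, v[1, ])
    tibble::tibble(x = v[, 1], y = v[, 2])
  } else {
    tibble::tibble(x = roi$boundary_coords[, "x"],
                   y = roi$boundary_coords[, "y"])
  }
  circ <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
    th <- seq(0, 2 * pi, length.out = 90)
    tibble::tibble(id = sp$unique_track_id[i],
                   x = sp$x[i] + sp$roi_distance[i] * cos(th),
                   y = sp$y[i] + sp$roi_distance[i] * sin(th))
  }))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = boundary, ggplot2::aes(x = .data$x,
                                                     y = .data$y),
                       colour = "grey30") +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y,
                                                 group = .data$id),
                       colour = "red", linewidth = 0.3) +
    ggplot2::geom_point(data = sp, ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "gold3") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Replicate-similarity dendrogram to a file or device
#' @param tree A [similarity_tree()] result.
#' @param ... Passed to `plot()`.
#' @return The tree, invisibly.
#' @export
plot_similarity_tree <- function(tree, ...) {
  hc <- tree$hclust
  hc$labels <- tree$labels
  plot(stats::as.dendrogram(hc), ylab = tree$distance_definition, ...)
  invisible(tree)
}
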