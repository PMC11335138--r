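# Feature vectors with two planted behavioural populations, built directly
# as a matrix (the HDBSCAN/embedding layer is agnostic to where the z-scored
# features came from).
two_blob_matrix <- function(n_per = 250, sep = 10, d = 4, seed = 1) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n_per * d), ncol = d),
             matrix(rnorm(n_per * d, mean = sep), ncol = d))
  rownames(m) <- sprintf("fov1::%03d", seq_len(2 * n_per))
  list(m = m, truth = rep(0:1, each = n_per))
}

test_that("feature matrix is z-scored with NaN tracks and constants dropped", {
  ds <- compute_track_metrics(generate_dataset(
    small_scene(seed = 41, tracks_per_fov = 15)))
  ds$tracks$const_col <- 7
  suppressMessages(expect_warning(
    m <- build_feature_matrix(ds, c("Mean Speed", "Directionality",
                                    "Tortuosity", "const_col")),
    "constant"))
  expect_false("const_col" %in% colnames(m))
  expect_true(all(abs(colMeans(m)) < 1e-12))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-12))
  # tracks with non-finite tortuosity are excluded
  n_nan <- sum(!is.finite(ds$tracks$Tortuosity))
  expect_equal(nrow(m), nrow(ds$tracks) - n_nan)
  expect_equal(attr(m, "n_dropped_tracks"), n_nan)
  ds$tracks$c1 <- 1; ds$tracks$c2 <- 2
  expect_error(suppressWarnings(build_feature_matrix(ds, c("c1", "c2"))),
               "constant")
})

test_that("embedding is deterministic, finite and separates planted blobs", {
  tb <- two_blob_matrix(n_per = 250, seed = 2)
  for (method in c("umap", "tsne")) {
    cfg <- embedding_config(method = method, seed = 7)
    e1 <- embed_tracks(tb$m, cfg)
    expect_equal(dim(e1), c(500, 2))
    expect_true(all(is.finite(e1)))
    expect_identical(rownames(e1), rownames(tb$m))
    e2 <- embed_tracks(tb$m, cfg)
    expect_identical(e1, e2)
    # blob centroids separate further than within-blob spread
    c0 <- colMeans(e1[tb$truth == 0, ]); c1 <- colMeans(e1[tb$truth == 1, ])
    between <- sqrt(sum((c0 - c1)^2))
    r0 <- quantile(sqrt(rowSums(sweep(e1[tb$truth == 0, ], 2, c0)^2)),
                   0.95)
    r1 <- quantile(sqrt(rowSums(sweep(e1[tb$truth == 1, ], 2, c1)^2)),
                   0.95)
    expect_gt(between, max(r0, r1))
  }
  expect_error(embed_tracks(tb$m[1:5, ], embedding_config(n_neighbors = 10)),
               "n_neighbors")
})

test_that("HDBSCAN recovers two blobs with high purity", {
  tb <- two_blob_matrix(n_per = 250, seed = 3)
  lab <- cluster_tracks(tb$m, cluster_config(min_samples = 10,
                                             min_cluster_size = 50))
  lab_i <- as.integer(unclass(lab))
  expect_equal(attr(lab, "n_clusters"), 2)
  assigned <- lab_i >= 0
  tab <- table(lab_i[assigned], tb$truth[assigned])
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gt(purity, 0.95)
})

test_that("HDBSCAN labels uniform noise as noise and a tight mass as one cluster", {
  set.seed(4)
  u <- matrix(runif(200), ncol = 2)
  rownames(u) <- paste0("u", 1:100)
  lu <- cluster_tracks(u, cluster_config(min_samples = 5,
                                         min_cluster_size = 90))
  expect_gte(mean(unclass(lu) == -1L), 0.9)
  # duplicated points forming one tight mass: the hierarchy never splits,
  # so the single cluster is only reachable with allow_single_cluster
  m <- matrix(rep(c(1, 2), each = 60), ncol = 2)
  rownames(m) <- paste0("m", 1:60)
  lm <- cluster_tracks(m, cluster_config(min_samples = 5,
                                         min_cluster_size = 10,
                                         allow_single_cluster = TRUE))
  expect_equal(as.integer(unclass(lm)), rep(0L, 60))
  expect_error(cluster_tracks(u, cluster_config(min_cluster_size = 1000)),
               "exceeds")
})

test_that("canberra metric is supported for clustering", {
  tb <- two_blob_matrix(n_per = 100, sep = 8, seed = 9)
  m <- abs(tb$m) + 1  # canberra needs same-sign magnitudes to behave
  lab <- cluster_tracks(m, cluster_config(min_samples = 10,
                                          min_cluster_size = 40,
                                          metric = "canberra"))
  expect_gte(attr(lab, "n_clusters"), 2)
})

test_that("fingerprint rows sum to 100 and recover planted enrichment", {
  # condition B enriched 4:1 in cluster 0
  n <- 400
  lab <- structure(c(rep(0L, 200), rep(1L, 150), rep(-1L, 50)),
                   names = sprintf("f::%03d", 1:n),
                   n_clusters = 2L, class = "cluster_assignment")
  set.seed(8)
  cond <- character(n)
  cond[1:200] <- sample(c("A", "B"), 200, replace = TRUE,
                        prob = c(0.2, 0.8))
  cond[201:400] <- sample(c("A", "B"), 200, replace = TRUE)
  sp <- make_spots(lapply(1:n, function(i) cbind(c(0, 1), c(0, 0))))
  sp$unique_track_id <- rep(sprintf("f::%03d", 1:n), each = 2)
  sp$condition <- rep(cond, each = 2)
  ds <- track_dataset(sp)
  fp <- cluster_fingerprint(lab, ds)
  sums <- rowSums(as.matrix(fp[, -1]))
  expect_equal(sums, rep(100, nrow(fp)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(c("noise", "cluster_0", "cluster_1") %in% names(fp)))
  # enrichment of B in cluster 0 visible in the fingerprint
  fpa <- fp$cluster_0[fp$condition == "A"]
  fpb <- fp$cluster_0[fp$condition == "B"]
  expect_gt(fpb, fpa)
})

test_that("cluster profile z-scores across cluster means", {
  ds <- make_dataset(list(cbind(c(0, 1), c(0, 0)), cbind(c(0, 2), c(0, 0)),
                          cbind(c(0, 3), c(0, 0)), cbind(c(0, 4), c(0, 0))))
  ds$tracks$met <- c(1, 1, 3, 3)
  lab <- structure(c(0L, 0L, 1L, 1L),
                   names = ds$tracks$unique_track_id,
                   n_clusters = 2L, class = "cluster_assignment")
  prof <- cluster_profile(ds, lab, "met")
  expect_equal(prof$met, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # equal cluster means give a zero column
  ds$tracks$flat <- 2
  prof2 <- cluster_profile(ds, lab, c("met", "flat"))
  expect_equal(prof2$flat, c(0, 0))
  # column permutation permutes output identically
  prof3 <- cluster_profile(ds, lab, c("flat", "met"))
  expect_equal(prof3$met, prof2$met)
  # one cluster is an error
  lab1 <- structure(c(0L, 0L, 0L, -1L),
                    names = ds$tracks$unique_track_id,
                    n_clusters = 1L, class = "cluster_assignment")
  expect_error(cluster_profile(ds, lab1, "met"), ">= 2")
})

test_that("exemplars are nearest to centroids with deterministic ties", {
  m <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(10, 10), c(10, 11), c(10, 12))
  rownames(m) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  lab <- structure(c(0L, 0L, 0L, 1L, 1L, 1L), names = rownames(m),
                   n_clusters = 2L, class = "cluster_assignment")
  ex <- exemplar_tracks(m, lab, k = 1)
  expect_equal(ex$cluster_0, "a1")  # exactly at the centroid
  expect_equal(ex$cluster_1, "b2")
  # tie: a2 and a3 equidistant -> lexicographically smaller id
  ex2 <- exemplar_tracks(m, lab, k = 2)
  expect_equal(ex2$cluster_0, c("a1", "a2"))
  # k larger than the clusters returns all members, warning per cluster
  expect_warning(expect_warning(ex3 <- exemplar_tracks(m, lab, k = 5),
                                "only"), "only")
  expect_equal(length(ex3$cluster_0), 3)
})

test_that("blob exemplars are the nearest members and track the cluster mean", {
  tb <- two_blob_matrix(n_per = 150, seed = 13)
  lab <- cluster_tracks(tb$m, cluster_config(min_samples = 10,
                                             min_cluster_size = 50))
  ex <- exemplar_tracks(tb$m, lab, k = 5)
  for (cl in names(ex)) {
    k <- as.integer(sub("cluster_", "", cl))
    members <- names(lab)[unclass(lab) == k]
    centre <- colMeans(tb$m[members, , drop = FALSE])
    d2 <- rowSums(sweep(tb$m[members, , drop = FALSE], 2, centre)^2)
    names(d2) <- members
    # defining property: no non-exemplar member is closer than an exemplar
    expect_lte(max(d2[ex[[cl]]]), min(d2[setdiff(members, ex[[cl]])]))
    # the exemplar average lies well within the cluster spread
    spread <- apply(tb$m[members, , drop = FALSE], 2, sd)
    ex_centre <- colMeans(tb$m[ex[[cl]], , drop = FALSE])
    expect_true(all(abs(ex_centre - centre) < 0.5 * spread))
  }
})
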