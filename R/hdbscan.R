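# Density-based hierarchical clustering (HDBSCAN) in plain R.
#
# Pipeline: core distances (distance to the (min_samples-1)-th nearest
# other point, the convention of the reference implementations) -> mutual
# reachability distances -> single-linkage dendrogram -> condensed tree
# under min_cluster_size -> excess-of-mass cluster selection. Points never
# absorbed into a selected cluster are labelled -1 (noise).
#
# Written here because no HDBSCAN implementation ships with the supported
# dependency stack; validated against constructed ground truth in the test
# suite.

hdbscan_core_distances <- function(dm, min_samples) {
  apply(dm, 1, function(r) sort(r, partial = min_samples)[min_samples])
}

# Condense the single-linkage hierarchy: clusters smaller than
# min_cluster_size never become clusters of their own; their points fall
# out of the parent at the merge's lambda = 1/height.
hdbscan_condense <- function(hc, n, min_cluster_size) {
  merge <- hc$merge
  height <- hc$height
  lambda_of <- function(h) if (h <= 0) 1e12 else 1 / h
  # member cache per internal node
  members <- vector("list", nrow(merge))
  sizes <- integer(nrow(merge))
  for (k in seq_len(nrow(merge))) {
    get_m <- function(j) if (j < 0) -j else members[[j]]
    members[[k]] <- c(get_m(merge[k, 1]), get_m(merge[k, 2]))
    sizes[k] <- length(members[[k]])
  }
  node_size <- function(j) if (j < 0) 1L else sizes[j]

  clusters <- list()  # each: parent, birth_lambda, children (ids), node
  point_cluster <- integer(n)      # condensed cluster each point leaves from
  point_lambda <- numeric(n)       # lambda at which the point leaves it

  new_cluster <- function(parent, birth) {
    clusters[[length(clusters) + 1]] <<- list(
      parent = parent, birth = birth, children = integer(0),
      stability = 0, points = integer(0))
    length(clusters)
  }
  root_id <- new_cluster(0L, 0)

  # iterative walk: stack of (tree node, condensed cluster id)
  stack <- list(list(node = nrow(merge), cl = root_id))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node; cl <- fr$cl
    repeat {
      lam <- lambda_of(height[node])
      ch <- merge[node, ]
      s1 <- node_size(ch[1]); s2 <- node_size(ch[2])
      big <- c(s1, s2) >= min_cluster_size
      if (all(big)) {
        # true split: remaining points of cl leave at lam
        for (j in 1:2) {
          child_id <- new_cluster(cl, lam)
          clusters[[cl]]$children <- c(clusters[[cl]]$children, child_id)
          stack[[length(stack) + 1]] <- list(node = ch[j], cl = child_id)
        }
        clusters[[cl]]$death <- lam
        break
      }
      # children below min_cluster_size shed their points at lam
      for (j in 1:2) {
        if (!big[j]) {
          pts <- if (ch[j] < 0) -ch[j] else members[[ch[j]]]
          point_cluster[pts] <- cl
          point_lambda[pts] <- lam
          clusters[[cl]]$points <- c(clusters[[cl]]$points, pts)
        }
      }
      if (!any(big)) {
        clusters[[cl]]$death <- lam
        break
      }
      node <- ch[which(big)]
      if (node < 0) { # a single surviving leaf cannot continue a cluster
        point_cluster[-node] <- cl
        point_lambda[-node] <- lam
        clusters[[cl]]$points <- c(clusters[[cl]]$points, -node)
        clusters[[cl]]$death <- lam
        break
      }
    }
  }
  # stability = sum over points of (lambda_leave - lambda_birth); points
  # remaining at a true split leave at the split lambda
  for (i in seq_along(clusters)) clusters[[i]]$stability <- 0
  for (p in seq_len(n)) {
    cl <- point_cluster[p]
    if (cl == 0) next
    clusters[[cl]]$stability <- clusters[[cl]]$stability +
      (point_lambda[p] - clusters[[cl]]$birth)
  }
  # points that persist into child clusters contribute (death - birth)
  for (i in seq_along(clusters)) {
    kids <- clusters[[i]]$children
    if (length(kids) > 0) {
      n_pass <- sum(vapply(kids, function(k) hdbscan_subtree_size(clusters, k),
                           numeric(1)))
      clusters[[i]]$stability <- clusters[[i]]$stability +
        n_pass * (clusters[[i]]$death - clusters[[i]]$birth)
    }
  }
  list(clusters = clusters, point_cluster = point_cluster,
       point_lambda = point_lambda, root = root_id)
}

hdbscan_subtree_size <- function(clusters, id) {
  total <- length(clusters[[id]]$points)
  for (k in clusters[[id]]$children) {
    total <- total + hdbscan_subtree_size(clusters, k)
  }
  total
}

# Excess-of-mass selection: bottom-up, a cluster is selected when its own
# stability exceeds the propagated stability of its children. The root is
# selectable only when allow_single_cluster is TRUE.
hdbscan_select <- function(condensed, allow_single_cluster) {
  clusters <- condensed$clusters
  root <- condensed$root
  selected <- logical(length(clusters))
  propagated <- numeric(length(clusters))
  order_ids <- rev(seq_along(clusters))  # children created after parents
  for (id in order_ids) {
    kids <- clusters[[id]]$children
    if (length(kids) == 0) {
      propagated[id] <- clusters[[id]]$stability
      selected[id] <- TRUE
    } else {
      child_sum <- sum(propagated[kids])
      if (clusters[[id]]$stability > child_sum &&
          (id != root || allow_single_cluster)) {
        selected[id] <- TRUE
        propagated[id] <- clusters[[id]]$stability
        # deselect whole subtree below
        deselect <- kids
        while (length(deselect) > 0) {
          selected[deselect] <- FALSE
          deselect <- unlist(lapply(deselect,
                                    function(k) clusters[[k]]$children))
        }
      } else {
        propagated[id] <- child_sum
      }
    }
  }
  if (!allow_single_cluster) selected[root] <- FALSE
  which(selected)
}

#' @keywords internal
#' HDBSCAN labels for a distance matrix; -1 marks noise.
hdbscan_labels <- function(x, min_samples = 5L, min_cluster_size = 5L,
                           metric = "euclidean",
                           allow_single_cluster = FALSE) {
  dm <- as.matrix(stats::dist(x, method = metric))
  n <- nrow(dm)
  if (min_cluster_size > n) {
    stop("min_cluster_size (", min_cluster_size,
         ") exceeds the number of points (", n, ")", call. = FALSE)
  }
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2",
                                 call. = FALSE)
  min_samples <- min(min_samples, n - 1L)
  diag(dm) <- Inf
  core <- hdbscan_core_distances(dm, min_samples)
  mreach <- pmax(dm, outer(core, core, pmax))
  diag(mreach) <- 0
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  condensed <- hdbscan_condense(hc, n, min_cluster_size)
  sel <- hdbscan_select(condensed, allow_single_cluster)
  labels <- rep(-1L, n)
  if (length(sel) > 0) {
    clusters <- condensed$clusters
    # each point's chain of condensed clusters: attachment cluster upwards
    sel_set <- logical(length(clusters)); sel_set[sel] <- TRUE
    assign_of <- integer(length(clusters))
    # map each selected cluster to a final label later (stable ordering)
    for (p in seq_len(n)) {
      cl <- condensed$point_cluster[p]
      while (cl != 0) {
        if (sel_set[cl]) { labels[p] <- cl; break }
        cl <- clusters[[cl]]$parent
      }
    }
    # relabel 0..k-1 by smallest member point index for determinism
    used <- sort(unique(labels[labels > 0]))
    firsts <- vapply(used, function(u) min(which(labels == u)), integer(1))
    used <- used[order(firsts)]
    relab <- stats::setNames(seq_along(used) - 1L, used)
    labels[labels > 0] <- relab[as.character(labels[labels > 0])]
    # degenerate all-duplicate input: labels may still be -1 everywhere if
    # the hierarchy had zero heights; handled by the lambda cap above
  }
  labels
}
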