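#' Cohen's d standardized effect size
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled sample standard
#' deviation `s_pooled^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2)`.
#' Returns `NaN` when both samples are constant and equal; errors when the
#' pooled SD is zero but the means differ (effect size undefined).
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return A single numeric value.
#' @export
cohens_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("cohens_d requires at least 2 values per sample", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) return(NaN)
    stop("degenerate variance: pooled SD is zero but means differ",
         call. = FALSE)
  }
  dm / sqrt(sp2)
}

# |d*| for every column of an index matrix (columns = group-a index sets)
# computed from sums, vectorized across permutations.
perm_abs_d <- function(v, idx_mat, na, nb) {
  n <- na + nb
  tot <- sum(v); tot2 <- sum(v^2)
  va <- matrix(v[idx_mat], nrow = na)
  sa <- colSums(va); sa2 <- colSums(va^2)
  sb <- tot - sa; sb2 <- tot2 - sa2
  ma <- sa / na; mb <- sb / nb
  vara <- (sa2 - na * ma^2) / (na - 1)
  varb <- (sb2 - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * vara + (nb - 1) * varb) / (n - 2)
  out <- abs(ma - mb) / sqrt(sp2)
  out[sp2 <= 0] <- 0
  out
}

#' Randomization test on Cohen's d
#'
#' Permutation test of the null hypothesis of exchangeability: group labels
#' are randomly re-assigned (preserving group sizes) and the absolute
#' Cohen's d of each re-assignment is compared with the observed one. When
#' the total number of distinct splits `choose(n, n_a)` is at most
#' `exhaustive_limit`, all splits are enumerated and the p-value is the
#' exact proportion `#{|d*| >= |d_obs|} / n_splits`; otherwise `n_iter`
#' seeded Monte-Carlo draws are used with the add-one estimator
#' `p = (1 + #{|d*| >= |d_obs|}) / (1 + n_iter)`, which is never zero.
#'
#' @param a,b Numeric samples (>= 2 values each).
#' @param n_iter Monte-Carlo iterations.
#' @param seed Integer seed (Monte-Carlo mode).
#' @param exhaustive_limit Enumerate exhaustively when the number of splits
#'   is at most this.
#' @return p-value in (0, 1], with attributes `d` (observed Cohen's d),
#'   `mode` ("exhaustive" or "montecarlo") and `n_iterations`.
#' @export
randomization_test <- function(a, b, n_iter = 1000, seed = 42,
                               exhaustive_limit = 20000) {
  d_obs <- cohens_d(a, b)
  v <- c(as.numeric(a), as.numeric(b))
  na <- length(a); nb <- length(b); n <- na + nb
  target <- abs(d_obs)
  if (is.nan(target)) target <- 0
  n_comb <- choose(n, na)
  eps <- 1e-12
  if (n_comb <= exhaustive_limit) {
    idx <- utils::combn(n, na)
    dstar <- perm_abs_d(v, idx, na, nb)
    p <- mean(dstar >= target - eps)
    mode <- "exhaustive"
    iters <- ncol(idx)
  } else {
    set.seed(seed)
    idx <- vapply(seq_len(n_iter), function(i) sample.int(n, na),
                  integer(na))
    dstar <- perm_abs_d(v, idx, na, nb)
    p <- (1 + sum(dstar >= target - eps)) / (1 + n_iter)
    mode <- "montecarlo"
    iters <- n_iter
  }
  structure(p, d = d_obs, mode = mode, n_iterations = iters)
}

#' Replicate-aware bootstrap t-test (SuperPlots style)
#'
#' Treats the biological repeat as the experimental unit. Per bootstrap
#' iteration, tracks are resampled with replacement within each repeat, the
#' mean of each repeat is taken, and the group mean of repeat means is
#' recorded. The two bootstrap distributions of group means are compared by
#' a two-sample unequal-variance (Welch) t-test.
#'
#' @param values_by_repeat_a,values_by_repeat_b Named lists of numeric
#'   vectors, one per biological repeat (>= 2 repeats with >= 2 values each).
#' @param n_boot Bootstrap iterations (>= 2).
#' @param seed Integer seed.
#' @return p-value with attribute `boot_means` (2 x n_boot matrix).
#' @export
bootstrap_superplot_test <- function(values_by_repeat_a, values_by_repeat_b,
                                     n_boot = 1000, seed = 42) {
  if (n_boot < 2) {
    stop("n_boot must be >= 2 (a single draw gives a degenerate ",
         "bootstrap distribution)", call. = FALSE)
  }
  check_group <- function(g, label) {
    if (length(g) < 2) {
      stop("group ", label, " needs >= 2 repeats", call. = FALSE)
    }
    small <- names(g)[vapply(g, length, integer(1)) < 2]
    if (is.null(names(g))) small <- which(vapply(g, length, integer(1)) < 2)
    if (length(small) > 0) {
      stop("repeat(s) with < 2 tracks in group ", label, ": ",
           paste(small, collapse = ", "), call. = FALSE)
    }
  }
  check_group(values_by_repeat_a, "a")
  check_group(values_by_repeat_b, "b")
  set.seed(seed)
  boot_group <- function(g) {
    rep_means <- vapply(g, function(v) {
      m <- matrix(sample(v, length(v) * n_boot, replace = TRUE),
                  ncol = n_boot)
      colMeans(m)
    }, numeric(n_boot))
    rowMeans(rep_means)  # group mean of repeat means, per iteration
  }
  ga <- boot_group(values_by_repeat_a)
  gb <- boot_group(values_by_repeat_b)
  if (stats::sd(ga) == 0 && stats::sd(gb) == 0) {
    p <- if (mean(ga) == mean(gb)) 1 else
      stop("degenerate bootstrap distributions with differing means",
           call. = FALSE)
  } else {
    p <- stats::t.test(ga, gb, var.equal = FALSE)$p.value
  }
  p <- max(p, .Machine$double.xmin)  # probabilities live in (0, 1]
  structure(p, boot_means = rbind(a = ga, b = gb))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)`, order preserved; `m` defaults to the number of
#' p-values.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param m Number of comparisons.
#' @return Adjusted p-values.
#' @export
adjust_bonferroni <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, p_values * m)
}

#' Pairwise condition comparisons for one track metric
#'
#' For every pair of conditions, computes Cohen's d and the p-value of the
#' chosen test on per-track metric values, with optional Bonferroni
#' adjustment over the number of pairs. Non-finite metric values are
#' dropped per pair (counts reported in the output). The mirrored matrix
#' carries d above the diagonal and (adjusted) p below.
#'
#' @param ds A `track_dataset` with the metric computed.
#' @param metric Track metric column name.
#' @param test `"randomization"` or `"bootstrap_t"`.
#' @param adjust Apply Bonferroni over the number of pairs.
#' @param n_iter Iterations for the chosen test.
#' @param seed Integer seed.
#' @return A `comparison_matrix`: list with tidy tibble `$pairs` and the
#'   mirrored `$matrix` (d upper triangle, p lower triangle).
#' @export
pairwise_comparison_matrix <- function(ds, metric,
                                       test = c("randomization",
                                                "bootstrap_t"),
                                       adjust = TRUE, n_iter = 1000,
                                       seed = 42) {
  assert_dataset(ds)
  test <- match.arg(test)
  if (!metric %in% names(ds$tracks)) {
    stop("metric column not found in track table: ", metric, call. = FALSE)
  }
  conds <- sort(unique(ds$tracks$condition))
  if (length(conds) < 2) stop("need >= 2 conditions", call. = FALSE)
  vals <- split(ds$tracks[[metric]], ds$tracks$condition)
  reps <- split(ds$tracks, ds$tracks$condition)
  pairs <- utils::combn(conds, 2)
  m <- ncol(pairs)
  rows <- vector("list", m)
  for (k in seq_len(m)) {
    ca <- pairs[1, k]; cb <- pairs[2, k]
    va <- vals[[ca]]; vb <- vals[[cb]]
    n_dropped <- sum(!is.finite(va)) + sum(!is.finite(vb))
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) < 2 || length(vb) < 2) {
      stop("condition pair (", ca, ", ", cb, ") has < 2 finite values",
           call. = FALSE)
    }
    d <- cohens_d(va, vb)
    p <- if (test == "randomization") {
      as.numeric(randomization_test(va, vb, n_iter = n_iter,
                                    seed = seed + k))
    } else {
      by_rep_a <- split(reps[[ca]][[metric]][is.finite(reps[[ca]][[metric]])],
                        reps[[ca]]$replicate[is.finite(reps[[ca]][[metric]])])
      by_rep_b <- split(reps[[cb]][[metric]][is.finite(reps[[cb]][[metric]])],
                        reps[[cb]]$replicate[is.finite(reps[[cb]][[metric]])])
      as.numeric(bootstrap_superplot_test(by_rep_a, by_rep_b,
                                          n_boot = n_iter, seed = seed + k))
    }
    rows[[k]] <- tibble::tibble(
      group_a = ca, group_b = cb, n_a = length(va), n_b = length(vb),
      n_dropped = n_dropped, cohens_d = d, p_raw = p,
      n_iterations = n_iter, seed = seed + k
    )
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (adjust) adjust_bonferroni(out$p_raw, m = m) else
    out$p_raw
  mat <- matrix(NA_real_, length(conds), length(conds),
                dimnames = list(conds, conds))
  for (k in seq_len(m)) {
    ca <- pairs[1, k]; cb <- pairs[2, k]
    mat[ca, cb] <- out$cohens_d[k]       # upper triangle: effect size
    mat[cb, ca] <- out$p_adjusted[k]     # lower triangle: p-value
  }
  structure(list(pairs = out, matrix = mat, metric = metric, test = test,
                 adjusted = adjust),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat("<comparison_matrix> metric:", x$metric, "| test:", x$test,
      if (x$adjusted) "| Bonferroni-adjusted\n" else "\n")
  print(x$pairs)
  invisible(x)
}

#' Tukey boxplot summary per condition and repeat
#'
#' Five-number boxplot data in the Tukey convention: whiskers extend to the
#' most extreme data point within 1.5x the interquartile range of the box.
#' Axis-limit metadata (`axis_low`/`axis_high`, median +/- 5x IQR per
#' metric, i.e. a 10x-IQR span) is attached for plotting.
#'
#' @param ds A `track_dataset`.
#' @param metric Track metric column name.
#' @return Tibble with one row per condition x replicate.
#' @export
tukey_boxplot_data <- function(ds, metric) {
  assert_dataset(ds)
  if (!metric %in% names(ds$tracks)) {
    stop("metric column not found: ", metric, call. = FALSE)
  }
  v_all <- ds$tracks[[metric]]
  v_all <- v_all[is.finite(v_all)]
  iqr_all <- stats::IQR(v_all)
  med_all <- stats::median(v_all)
  ds$tracks |>
    dplyr::filter(is.finite(.data[[metric]])) |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data[[metric]], 0.25, names = FALSE),
      median = stats::median(.data[[metric]]),
      q3 = stats::quantile(.data[[metric]], 0.75, names = FALSE),
      whisker_low = {
        q1 <- stats::quantile(.data[[metric]], 0.25, names = FALSE)
        iqr <- stats::IQR(.data[[metric]])
        min(.data[[metric]][.data[[metric]] >= q1 - 1.5 * iqr])
      },
      whisker_high = {
        q3 <- stats::quantile(.data[[metric]], 0.75, names = FALSE)
        iqr <- stats::IQR(.data[[metric]])
        max(.data[[metric]][.data[[metric]] <= q3 + 1.5 * iqr])
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(metric = metric,
                  axis_low = med_all - 5 * iqr_all,
                  axis_high = med_all + 5 * iqr_all)
}
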