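#' Build log2-ratio time profiles from strategy-I comparisons
#'
#' A gene enters the profile set when its expression differs significantly
#' (status not `ns`) in at least one of the baseline comparisons; its profile
#' is the vector of log2 ratios versus baseline at every non-baseline time
#' point, in time order.
#'
#' @param comparisons named list of strategy-I `DGEComparison`s in time order.
#' @return data.table of class `"ExpressionProfileSet"`: `gene_id` plus one
#'   `ratio_<sample>` column per comparison.
#' @export
build_profiles <- function(comparisons) {
  if (length(comparisons) == 0) stopf("input error: no comparisons supplied")
  if (is.null(names(comparisons))) stopf("input error: comparisons must be named")
  samples_b <- vapply(comparisons, function(cc) attr(cc, "sample_b"), character(1))
  if (anyNA(samples_b)) stopf("input error: comparison missing its time-point label")
  selected <- sort(unique(unlist(lapply(comparisons, deg_genes))))
  out <- data.table(gene_id = selected)
  for (i in seq_along(comparisons)) {
    cc <- comparisons[[i]]
    ratios <- setNames(cc$log2_ratio, cc$gene_id)
    if (!all(selected %in% cc$gene_id))
      stopf("input error: comparison '%s' is missing selected genes", names(comparisons)[i])
    out[, paste0("ratio_", samples_b[i]) := ratios[selected]]
  }
  setattr(out, "class", c("ExpressionProfileSet", class(out)))
  out[]
}

profile_matrix <- function(profiles) {
  cols <- grep("^ratio_", names(profiles), value = TRUE)
  m <- as.matrix(profiles[, cols, with = FALSE])
  rownames(m) <- profiles$gene_id
  m
}

#' Pearson-correlation distance matrix of profiles
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation of the two log2
#' ratio vectors — anti-correlated patterns are maximally distant (d = 2),
#' not similar. For zero-variance (constant) profiles, where Pearson
#' correlation is undefined, `r` is taken as 1 for identical vectors and 0
#' otherwise.
#'
#' @param profiles an `ExpressionProfileSet` (or matrix with genes as rows).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pearson_distance_matrix <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (nrow(m) < 2) stopf("input error: need at least two profiles")
  if (ncol(m) < 2) stopf("input error: profiles must have length >= 2")
  sds <- apply(m, 1, stats::sd)
  r <- matrix(NA_real_, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  ok <- sds > 0
  if (sum(ok) >= 2) r[ok, ok] <- stats::cor(t(m[ok, , drop = FALSE]))
  if (any(!ok)) {
    for (i in which(!ok)) {
      same <- apply(m, 1, function(v) isTRUE(all.equal(v, m[i, ], tolerance = 1e-12)))
      r[i, ] <- ifelse(same, 1, 0)
      r[, i] <- r[i, ]
    }
  }
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering (average linkage by default) of the Pearson
#' distance matrix, cut to exactly `k` clusters. Profiles are ordered
#' lexicographically by gene id before clustering so the result does not
#' depend on input order; cluster labels are 1..k in order of first
#' appearance over the sorted gene list.
#'
#' @param d symmetric distance matrix with dimnames, or an
#'   `ExpressionProfileSet` (distance computed internally).
#' @param k number of clusters (1..n).
#' @param linkage linkage method passed to [stats::hclust()].
#' @return data.table of class `"ClusterAssignment"`: `gene_id`, `cluster`;
#'   attributes `k`, `linkage`.
#' @export
hcluster <- function(d, k, linkage = "average") {
  if (inherits(d, "ExpressionProfileSet")) d <- pearson_distance_matrix(d)
  n <- nrow(d)
  if (k < 1 || k > n) stopf("input error: k must be between 1 and the number of profiles")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  cl <- if (k == n) {
    setNames(seq_len(n), rownames(d))
  } else {
    tree <- hclust(as.dist(d), method = linkage)
    cutree(tree, k = k)
  }
  # relabel in order of first appearance for determinism
  first <- unique(cl[rownames(d)])
  relabel <- setNames(seq_along(first), first)
  out <- data.table(gene_id = rownames(d), cluster = as.integer(relabel[as.character(cl)]))
  setattr(out, "k", as.integer(k))
  setattr(out, "linkage", linkage)
  setattr(out, "class", c("ClusterAssignment", class(out)))
  out[]
}

# sign-pattern trend tag of a mean profile (log2 ratios vs baseline);
# differences are taken over the baseline-augmented vector c(0, v)
trend_tag <- function(v, eps = 0.25) {
  d <- diff(c(0, v))
  m <- length(d)
  if (d[m] < -eps && max(abs(d[-m])) <= eps) return("drop_late")
  if (m >= 2 && d[m - 1] > eps && d[m] < -eps &&
      (m == 2 || max(abs(d[seq_len(m - 2)])) <= eps)) return("pulse")
  if (all(d <= eps) && any(d < -eps)) return("down")
  if (all(d >= -eps) && any(d > eps)) return("up")
  "other"
}

#' Per-cluster summaries
#'
#' Mean profile, membership count, and a monotonic-trend tag per cluster. The
#' trend tag is assigned from the sign pattern of consecutive differences of
#' the baseline-augmented mean profile: `down` (non-increasing), `up`
#' (non-decreasing), `drop_late` (flat then final drop), `pulse` (rise into
#' the penultimate point then fall), else `other`.
#'
#' @param assignment a `ClusterAssignment`.
#' @param profiles the `ExpressionProfileSet` that was clustered.
#' @param eps dead-band below which a mean difference counts as flat.
#' @return list with `summary` (data.table: cluster, n, trend) and `means`
#'   (matrix of cluster mean profiles, clusters as rows).
#' @export
cluster_summaries <- function(assignment, profiles, eps = 0.25) {
  m <- profile_matrix(profiles)
  if (!setequal(rownames(m), assignment$gene_id))
    stopf("input error: assignment does not cover the profile set")
  cl <- setNames(assignment$cluster, assignment$gene_id)[rownames(m)]
  ks <- sort(unique(cl))
  means <- t(vapply(ks, function(k) colMeans(m[cl == k, , drop = FALSE]), numeric(ncol(m))))
  rownames(means) <- ks
  summary <- data.table(
    cluster = ks,
    n = as.integer(table(cl)[as.character(ks)]),
    trend = vapply(ks, function(k) trend_tag(means[as.character(k), ], eps), character(1))
  )
  list(summary = summary, means = means)
}

#' Plot cluster profiles (optional)
#'
#' Line plot of every member profile per cluster with the cluster mean
#' overlaid, in the style of time-course cluster panels. Requires ggplot2.
#'
#' @param assignment a `ClusterAssignment`.
#' @param profiles the clustered `ExpressionProfileSet`.
#' @param clusters which clusters to draw (default all).
#' @return a ggplot object.
#' @export
plot_cluster_profiles <- function(assignment, profiles, clusters = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("ggplot2 is required for plotting")
  m <- profile_matrix(profiles)
  cl <- setNames(assignment$cluster, assignment$gene_id)[rownames(m)]
  long <- data.table(gene_id = rep(rownames(m), ncol(m)),
                     cluster = rep(cl, ncol(m)),
                     time = rep(colnames(m), each = nrow(m)),
                     ratio = as.vector(m))
  long[, time := factor(time, levels = colnames(m))]
  if (!is.null(clusters)) long <- long[cluster %in% clusters]
  means <- long[, .(ratio = mean(ratio)), by = .(cluster, time)]
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = ratio, group = gene_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "steelblue") +
    ggplot2::geom_line(data = means, ggplot2::aes(group = cluster),
                       colour = "red", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time point", y = "log2 ratio vs baseline")
}
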