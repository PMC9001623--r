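# Genome-wide classification of sections into chromatin-like states:
# k-means on (delta_exp, nu_exp, chi_inf) with canonical relabeling, plus a
# PCA + silhouette diagnostic for choosing the cluster count.

#' Build the standardized feature matrix for clustering
#'
#' Features are the two potential exponents and the extrapolated
#' compressibility, `(delta_exp, nu_exp, chi_inf)`, z-scored column-wise
#' (the exponents are O(10), chi is O(0.1), so raw scales would dominate).
#' Sections flagged unfit are excluded.
#'
#' @param results data.frame of section results with columns `delta_exp`,
#'   `nu_exp`, `chi_inf`, and logical `fit_ok`.
#' @param k minimum usable rows (error below; default 3).
#' @return Standardized numeric matrix with attributes `"center"`,
#'   `"scale"`, `"kept"` (row indices of `results` used), and
#'   `"raw"` (unstandardized matrix).
#' @export
feature_matrix <- function(results, k = 3) {
  ok <- which(results$fit_ok & is.finite(results$chi_inf))
  if (length(ok) < k)
    stop("fewer fit_ok sections than clusters")
  raw <- as.matrix(results[ok, c("delta_exp", "nu_exp", "chi_inf")])
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    warning("constant feature column(s) left at 0 after centering: ",
            paste(colnames(raw)[zero], collapse = ", "))
    scl[zero] <- 1
  }
  m <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  attr(m, "center") <- ctr
  attr(m, "scale") <- scl
  attr(m, "kept") <- ok
  attr(m, "raw") <- raw
  m
}

#' k-means classification with canonical labels
#'
#' Best-inertia solution over `n_restarts` k-means++-style starts. Cluster
#' labels are renumbered by ascending cluster-mean `chi_inf` so label 0 is
#' the least compressible ("most heterochromatin-like") class; this makes
#' labels reproducible across runs and restart orders.
#'
#' @param features matrix from [feature_matrix()] (last column must be the
#'   standardized `chi_inf`).
#' @param k number of clusters (default 3).
#' @param n_restarts random restarts (default 50).
#' @param seed RNG seed.
#' @return Integer labels in `0..k-1` (one per feature row) with attributes
#'   `"inertia"` (total within-cluster sum of squares) and `"centers"`.
#' @export
kmeans_classify <- function(features, k = 3, n_restarts = 50, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (nrow(features) < k) stop("fewer rows than clusters")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 42))
  if (nrow(features) == k) {
    # one point per cluster: k-means is trivial (inertia 0)
    km <- list(cluster = seq_len(k), centers = features, tot.withinss = 0)
  } else {
    km <- kmeans(features, centers = k, nstart = n_restarts, iter.max = 100)
  }
  # canonical relabeling by ascending cluster-mean chi (last feature column)
  ord <- order(km$centers[, ncol(features)])
  relab <- integer(k)
  relab[ord] <- seq_len(k) - 1L
  labels <- relab[km$cluster]
  attr(labels, "inertia") <- km$tot.withinss
  attr(labels, "centers") <- km$centers[ord, , drop = FALSE]
  labels
}

#' PCA projection and per-k clusterings for visual cluster-count selection
#'
#' Projects the standardized features onto their first two principal
#' components and attaches k-means labels for each candidate `k`, together
#' with mean silhouette widths as a quantitative companion to visual
#' inspection of the projection.
#'
#' @param features matrix from [feature_matrix()].
#' @param k_list candidate cluster counts (default `2:5`).
#' @param seed RNG seed shared across the per-k clusterings.
#' @return A list of class `pca_diagnostic`: `projection` (n x 2 matrix),
#'   `explained` (variance fractions of the two components), `labels`
#'   (list, per k), `silhouette` (data.frame k, mean width).
#' @export
pca_diagnostic <- function(features, k_list = 2:5, seed = 1) {
  stopifnot(nrow(features) >= max(k_list))
  pc <- prcomp(features, center = FALSE, scale. = FALSE)
  proj <- pc$x[, 1:2, drop = FALSE]
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  labels <- list()
  sil <- data.frame(k = integer(0), mean_width = numeric(0))
  d <- stats::dist(features)
  for (k in k_list) {
    lab <- kmeans_classify(features, k = k, seed = seed)
    labels[[as.character(k)]] <- lab
    sw <- cluster::silhouette(as.integer(lab) + 1L, d)
    sil <- rbind(sil, data.frame(k = k, mean_width = mean(sw[, "sil_width"])))
  }
  structure(list(projection = proj, explained = expl, labels = labels,
                 silhouette = sil),
            class = "pca_diagnostic")
}

#' @export
print.pca_diagnostic <- function(x, ...) {
  cat(sprintf("<pca_diagnostic> 2 PCs explain %.1f%% of variance\n",
              100 * sum(x$explained)))
  print(x$silhouette, row.names = FALSE)
  invisible(x)
}

#' Export class labels as a bedGraph track
#'
#' One record per section over its core span; unfit (unclassified) sections
#' get the sentinel value -1. Adjacent same-label sections stay separate
#' records.
#'
#' @param results data.frame with columns `chrom`, `core_start`, `core_end`,
#'   `class_label` (NA for unfit).
#' @param path output bedGraph path.
#' @export
export_class_track <- function(results, path) {
  lab <- results$class_label
  lab[is.na(lab)] <- -1
  lines <- sprintf("%s\t%d\t%d\t%d", results$chrom,
                   as.integer(results$core_start),
                   as.integer(results$core_end), as.integer(lab))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Rand index between two labelings
#'
#' Fraction of point pairs on which two partitions agree (both together or
#' both apart); 1 means identical partitions up to relabeling.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
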