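#' Names of the supported clustering algorithms
#' @return Character vector.
#' @export
clustering_algorithms <- function() {
  c("birch", "gmm", "ward", "kmeans", "kmedoids", "spectral")
}

new_partition <- function(ids, labels, algorithm, k, seed) {
  structure(list(ids = ids, labels = as.integer(labels), algorithm = algorithm,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "trait_partition")
}

#' @export
print.trait_partition <- function(x, ...) {
  cat(sprintf("<trait_partition (%s, k = %d): %d individuals>\n",
              x$algorithm, x$k, length(x$ids)))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @describeIn cluster_individuals Labels as a tibble
#'   (`id`, `cluster`, `algorithm`, `k`).
#' @param x A `trait_partition`.
#' @param ... Unused.
#' @export
tidy.trait_partition <- function(x, ...) {
  tibble(id = x$ids, cluster = x$labels, algorithm = x$algorithm, k = x$k)
}

#' @describeIn cluster_individuals One-row summary with cluster sizes.
#' @export
glance.trait_partition <- function(x, ...) {
  sizes <- as.integer(table(factor(x$labels, levels = 0:(x$k - 1))))
  tibble(algorithm = x$algorithm, k = x$k, n = length(x$ids),
         min_size = min(sizes), max_size = max(sizes))
}

# Relabel raw assignments to contiguous 0-based labels in order of first
# appearance, which makes every algorithm's labelling deterministic.
canonical_labels <- function(raw) {
  match(raw, unique(raw)) - 1L
}

#' Cluster individuals in the reduced coordinate space
#'
#' Runs one of six clustering algorithms on the embedding coordinates:
#' `birch` (two-phase clustering-feature condensation followed by Ward
#' agglomeration of the subcluster centroids), `gmm` (Gaussian mixture via
#' EM), `ward` (hierarchical clustering, Ward linkage, cut at `k`),
#' `kmeans`, `kmedoids` (PAM) and `spectral` (Gaussian-affinity spectral
#' embedding followed by k-means). Labels are integers `0..k-1`, contiguous
#' and in order of first appearance, and every algorithm is deterministic
#' given the seed.
#'
#' @param coordinates Numeric matrix (rows = individuals, named) or a
#'   `trait_embedding`.
#' @param algorithm One of [clustering_algorithms()].
#' @param k Number of clusters (`1 <= k <= n`).
#' @param seed Integer seed.
#' @param birch_threshold Radius threshold of the condensation phase.
#' @return A `trait_partition`.
#' @export
cluster_individuals <- function(coordinates, algorithm, k, seed = 1L,
                                birch_threshold = 0.5) {
  if (inherits(coordinates, "trait_embedding")) coordinates <- coordinates$coordinates
  if (!is.matrix(coordinates)) coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  if (!algorithm %in% clustering_algorithms()) {
    abort(sprintf("unknown clustering algorithm '%s'", algorithm))
  }
  if (k < 1) abort("`k` must be >= 1")
  if (k > n) abort(sprintf("k = %d exceeds the %d individuals", k, n))
  ids <- rownames(coordinates) %||% as.character(seq_len(n))
  if (k == 1) return(new_partition(ids, rep(0L, n), algorithm, 1L, seed))
  if (k == n) {
    if (nrow(unique(as.data.frame(coordinates))) < n) {
      abort("k equals n but the points are not all distinct")
    }
    return(new_partition(ids, seq_len(n) - 1L, algorithm, k, seed))
  }
  set.seed(stage_seed(seed, paste0("cluster-", algorithm)))
  raw <- switch(algorithm,
    kmeans = kmeans(coordinates, centers = k, nstart = 10, iter.max = 100)$cluster,
    ward = cutree(hclust(dist(coordinates), method = "ward.D2"), k = k),
    kmedoids = cluster::pam(coordinates, k = k, cluster.only = TRUE),
    gmm = gmm_labels(coordinates, k),
    spectral = spectral_labels(coordinates, k),
    birch = birch_labels(coordinates, k, birch_threshold))
  new_partition(ids, canonical_labels(raw), algorithm, k, seed)
}

#' @importFrom mclust Mclust mclustBIC
gmm_labels <- function(coordinates, k) {
  fit <- mclust::Mclust(coordinates, G = k, verbose = FALSE)
  if (is.null(fit)) abort("Gaussian mixture fit failed")
  fit$classification
}

# Spectral clustering: same Gaussian/median-bandwidth affinity as the
# Laplacian eigenmaps embedding, then k-means on the spectral coordinates.
spectral_labels <- function(coordinates, k) {
  D <- as.matrix(dist(coordinates))
  emb <- embed_laplacian(D, k = min(k, nrow(D) - 1))
  kmeans(emb$coordinates, centers = k, nstart = 10, iter.max = 100)$cluster
}

# Simplified BIRCH: a single pass assigns each point to the nearest
# clustering feature (n, linear sum, squared sum) whose radius stays within
# the threshold, creating a new feature otherwise; the feature centroids
# are then agglomerated with Ward linkage and points inherit their
# feature's cluster.
birch_labels <- function(coordinates, k, threshold) {
  n <- nrow(coordinates)
  cf_n <- integer(0)
  cf_ls <- NULL   # one row per feature: linear sum
  cf_ss <- numeric(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    x <- coordinates[i, ]
    placed <- FALSE
    if (length(cf_n)) {
      cent <- cf_ls / cf_n
      d2 <- colSums((t(cent) - x)^2)
      j <- which.min(d2)
      new_n <- cf_n[j] + 1
      new_ls <- cf_ls[j, ] + x
      new_ss <- cf_ss[j] + sum(x^2)
      radius2 <- max(new_ss / new_n - sum((new_ls / new_n)^2), 0)
      if (sqrt(radius2) <= threshold) {
        cf_n[j] <- new_n; cf_ls[j, ] <- new_ls; cf_ss[j] <- new_ss
        assign[i] <- j
        placed <- TRUE
      }
    }
    if (!placed) {
      cf_n <- c(cf_n, 1L)
      cf_ls <- rbind(cf_ls, x)
      cf_ss <- c(cf_ss, sum(x^2))
      assign[i] <- length(cf_n)
    }
  }
  if (length(cf_n) < k) {
    abort(sprintf("BIRCH produced %d subclusters for k = %d; lower `birch_threshold`",
                  length(cf_n), k))
  }
  cent <- cf_ls / cf_n
  glob <- cutree(hclust(dist(cent), method = "ward.D2"), k = k)
  glob[assign]
}

#' Mean silhouette over a range of cluster counts
#'
#' Clusters the coordinates for each `k` and reports the mean silhouette
#' coefficient (Euclidean, in the reduced space), the standard guide for
#' choosing the number of clusters.
#'
#' @param coordinates Coordinate matrix or `trait_embedding`.
#' @param algorithm Clustering algorithm.
#' @param k_range Integer vector with `2 <= k <= n - 1`.
#' @param seed Integer seed.
#' @return Tibble with columns `k`, `mean_silhouette`.
#' @export
silhouette_profile <- function(coordinates, algorithm, k_range, seed = 1L) {
  if (inherits(coordinates, "trait_embedding")) coordinates <- coordinates$coordinates
  n <- nrow(coordinates)
  if (any(k_range < 2 | k_range > n - 1)) {
    abort("every k must satisfy 2 <= k <= n - 1")
  }
  purrr::map_dfr(k_range, function(k) {
    part <- cluster_individuals(coordinates, algorithm, k, seed)
    sil <- silhouette_individuals(coordinates, part)
    tibble(k = k, mean_silhouette = mean(sil$silhouette))
  })
}

#' Per-individual silhouette values
#'
#' Computes the silhouette coefficient of each individual (cohesion versus
#' nearest-other-cluster separation, Euclidean distances in the reduced
#' space). Individuals in singleton clusters get silhouette 0, the common
#' convention. Output rows are grouped by cluster and sorted by decreasing
#' silhouette within cluster, ready for the classic silhouette plot.
#'
#' @param coordinates Coordinate matrix or `trait_embedding`.
#' @param partition A `trait_partition` on the same individuals.
#' @return Tibble with columns `id`, `cluster`, `silhouette`.
#' @export
silhouette_individuals <- function(coordinates, partition) {
  if (inherits(coordinates, "trait_embedding")) coordinates <- coordinates$coordinates
  n <- nrow(coordinates)
  k <- partition$k
  if (k < 2 || k > n - 1) abort("silhouettes need 2 <= k <= n - 1")
  if (nrow(unique(as.data.frame(coordinates))) < 3) {
    abort("degenerate coordinates (fewer than three distinct points): silhouettes undefined")
  }
  sil <- cluster::silhouette(partition$labels + 1L, dist(coordinates))
  out <- tibble(id = partition$ids, cluster = partition$labels,
                silhouette = sil[, "sil_width"])
  dplyr::arrange(out, .data$cluster, dplyr::desc(.data$silhouette))
}

#' Concordance table between two partitions
#'
#' Cross-tabulates two partitions of the same individuals: entry (r, o) is
#' the number of individuals placed in reference cluster r and in cluster o
#' of the other partition. Row sums therefore give the reference cluster
#' sizes, column sums the other partition's, and all entries sum to n.
#' Optionally reorders the rows greedily so the heaviest counts fall on the
#' diagonal — a display aid only, the counts are the data.
#'
#' @param reference,other `trait_partition`s over the same ids (the
#'   pipeline treats the k-means result as the reference).
#' @param align Greedy diagonal reordering of the rows for display.
#' @return Integer matrix of class `concordance_table` with attributes
#'   `reference` and `other` naming the algorithms.
#' @export
concordance <- function(reference, other, align = FALSE) {
  if (!identical(sort(reference$ids), sort(other$ids))) {
    abort("partitions cover different individuals")
  }
  o <- other$labels[match(reference$ids, other$ids)]
  counts <- table(factor(reference$labels, levels = 0:(reference$k - 1)),
                  factor(o, levels = 0:(other$k - 1)))
  m <- matrix(as.integer(counts), nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  if (align) {
    ord <- integer(0)
    left <- seq_len(nrow(m))
    for (j in seq_len(min(dim(m)))) {
      pick <- left[which.max(m[left, j])]
      ord <- c(ord, pick)
      left <- setdiff(left, pick)
    }
    m <- m[c(ord, left), , drop = FALSE]
  }
  structure(m, class = c("concordance_table", "matrix", "array"),
            reference = reference$algorithm, other = other$algorithm)
}
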