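two_blobs <- function(n_per = 50, sep = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2, 0, sd), n_per, 2),
             matrix(rnorm(n_per * 2, sep, sd), n_per, 2))
  rownames(X) <- sprintf("p%03d", seq_len(2 * n_per))
  list(X = X, labels = rep(0:1, each = n_per))
}

test_that("all six algorithms recover two planted blobs and are seed-stable", {
  tb <- two_blobs()
  for (alg in clustering_algorithms()) {
    p1 <- cluster_individuals(tb$X, alg, 2, seed = 11)
    expect_equal(sort(unique(p1$labels)), 0:1, label = alg)
    expect_equal(mclust::adjustedRandIndex(p1$labels, tb$labels), 1, label = alg)
    p2 <- cluster_individuals(tb$X, alg, 2, seed = 11)
    expect_identical(p1$labels, p2$labels, label = alg)
  }
  expect_error(cluster_individuals(tb$X, "dbscan", 2), "unknown")
  expect_error(cluster_individuals(tb$X[1:3, ], "kmeans", 5), "exceeds")
  # degenerate counts
  expect_equal(unique(cluster_individuals(tb$X, "kmeans", 1)$labels), 0L)
  Xs <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE,
               dimnames = list(letters[1:4], NULL))
  pn <- cluster_individuals(Xs, "kmeans", 4, seed = 2)
  expect_equal(sort(unique(pn$labels)), 0:3)
})

test_that("labels are contiguous from zero in order of first appearance", {
  tb <- two_blobs(n_per = 20)
  for (alg in clustering_algorithms()) {
    p <- cluster_individuals(tb$X, alg, 2, seed = 3)
    expect_equal(p$labels[1], 0L, label = alg)
    expect_equal(sort(unique(p$labels)), 0:(p$k - 1), label = alg)
  }
})

test_that("the silhouette profile peaks at the planted cluster count", {
  tb <- two_blobs(n_per = 30)
  prof <- silhouette_profile(tb$X, "kmeans", 2:6, seed = 5)
  expect_equal(prof$k[which.max(prof$mean_silhouette)], 2)
  expect_true(all(prof$mean_silhouette >= -1 & prof$mean_silhouette <= 1))
  expect_error(silhouette_profile(tb$X, "kmeans", 1:3, seed = 5), "2 <= k")
})

test_that("per-individual silhouettes match the brute-force formula", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(paste0("i", 1:n), NULL))
    k <- sample(2:(n - 2), 1)
    part <- cluster_individuals(X, "kmeans", k, seed = rep)
    got <- silhouette_individuals(X, part)
    want <- silhouette_oracle(X, part$labels)
    expect_equal(got$silhouette[match(part$ids, got$id)], want, tolerance = 1e-12)
    # grouped by cluster, decreasing within cluster
    expect_true(!is.unsorted(got$cluster))
  }

  # two blobs: every silhouette is high
  tb <- two_blobs(n_per = 15)
  part <- cluster_individuals(tb$X, "kmeans", 2, seed = 1)
  expect_true(all(silhouette_individuals(tb$X, part)$silhouette > 0.8))

  # a point equidistant between its own and the other cluster scores 0
  X <- matrix(c(0, 0, 0, 2, 4, 0, 4, 2, 2, 1), 5, 2, byrow = TRUE,
              dimnames = list(paste0("i", 1:5), NULL))
  part <- phenodist:::new_partition(rownames(X), c(0, 0, 1, 1, 0), "kmeans", 2, 1)
  sil <- silhouette_individuals(X, part)
  expect_equal(sil$silhouette[sil$id == "i5"], 0)

  # degenerate coordinates trigger the undefined guard
  Xd <- matrix(0, 5, 2, dimnames = list(paste0("i", 1:5), NULL))
  Xd[5, ] <- 1
  pd <- phenodist:::new_partition(rownames(Xd), c(0, 0, 0, 0, 1), "kmeans", 2, 1)
  expect_error(silhouette_individuals(Xd, pd), "undefined")
})

test_that("concordance tables cross-tabulate with conserved marginals", {
  ids <- paste0("i", 1:4)
  ref <- phenodist:::new_partition(ids, c(0, 0, 1, 1), "kmeans", 2, 1)
  oth <- phenodist:::new_partition(ids, c(0, 1, 1, 1), "ward", 2, 1)
  ct <- concordance(ref, oth)
  expect_equal(unname(unclass(ct)[,]), matrix(c(1, 1, 0, 2), 2, 2, byrow = TRUE))
  # partition against itself: diagonal of cluster sizes
  self <- concordance(ref, ref)
  expect_equal(unname(unclass(self)[,]), diag(c(2, 2)))

  set.seed(23)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    ids <- paste0("i", 1:n)
    ka <- sample(2:4, 1); kb <- sample(2:4, 1)
    a <- phenodist:::new_partition(ids, phenodist:::canonical_labels(sample(ka, n, TRUE)),
                                   "kmeans", ka, 1)
    b <- phenodist:::new_partition(ids, phenodist:::canonical_labels(sample(kb, n, TRUE)),
                                   "gmm", kb, 1)
    ct <- concordance(a, b)
    expect_equal(sum(ct), n)
    expect_equal(unname(rowSums(ct)),
                 as.integer(table(factor(a$labels, levels = 0:(a$k - 1)))))
    expect_equal(unname(colSums(ct)),
                 as.integer(table(factor(b$labels, levels = 0:(b$k - 1)))))
  }
  bad <- phenodist:::new_partition(paste0("x", 1:4), c(0, 0, 1, 1), "kmeans", 2, 1)
  expect_error(concordance(ref, bad), "different individuals")
})
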