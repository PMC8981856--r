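test_that("undefined pairs are surfaced or mean-imputed on request", {
  D <- matrix(c(0, 1, NA, 1, 0, 2, NA, 2, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  idm <- phenodist:::new_individual_dist(D, matrix(1L, 3, 3), "semantic")
  expect_error(resolve_undefined(idm, "error"), "\\(a, c\\)")
  expect_message(fixed <- resolve_undefined(idm, "mean_impute"), "1 undefined")
  expect_equal(fixed$D["a", "c"], mean(c(1, 2)))
  # no undefined entries: input returned unchanged
  D2 <- D; D2[is.na(D2)] <- 3
  idm2 <- phenodist:::new_individual_dist(D2, matrix(1L, 3, 3), "semantic")
  expect_identical(resolve_undefined(idm2, "error"), idm2)
})

test_that("PCoA reconstructs Euclidean geometry and matches classical scaling", {
  X <- planar_points(5, 2)
  D <- as.matrix(dist(X))
  emb <- embed_pcoa(D, 2)
  expect_equal(as.matrix(dist(emb$coordinates)), D, tolerance = 1e-9)
  expect_true(all(diff(emb$eigenvalues) <= 1e-9))
  # independent oracle: stats::cmdscale on the same input
  ref <- cmdscale(D, k = 2, eig = TRUE)
  expect_equal(abs(emb$coordinates), abs(ref$points), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(emb$eigenvalues[1:2], ref$eig[1:2], tolerance = 1e-9)
  # positive eigenvalues carry the centred variance
  Xc <- scale(X, scale = FALSE)
  expect_equal(sum(emb$eigenvalues[emb$eigenvalues > 1e-9]), sum(Xc^2),
               tolerance = 1e-9)

  # two points at distance d map to +/- d/2 on one axis
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  e2 <- embed_pcoa(d2, 1)
  expect_equal(unname(sort(e2$coordinates[, 1])), c(-2, 2))

  # degenerate all-zero distances leave no positive eigenvalue to embed
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(embed_pcoa(z, 1), "positive eigenvalue")
  expect_error(embed_pcoa(D, 5), "positive eigenvalue")
})

test_that("stress-1 matches its analytic cases and is rigid-motion invariant", {
  X <- planar_points(6, 2)
  D <- as.matrix(dist(X))
  expect_equal(stress1(D, X), 0)
  # coincident configuration: numerator equals denominator
  expect_equal(stress1(D, matrix(0, 6, 2)), 1)
  # single pair, observed 2, embedded 1
  D1 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(stress1(D1, matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)), 0.5)
  expect_error(stress1(matrix(0, 2, 2), matrix(0, 2, 2)), "zero")

  # rotation, reflection, translation leave stress-1 unchanged
  s0 <- stress1(D, X * 1.1)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(stress1(D, (X * 1.1) %*% R), s0)
  expect_equal(stress1(D, sweep((X * 1.1) %*% diag(c(-1, 1)), 2, c(3, -2), "+")), s0)
})

test_that("metric MDS recovers embeddable configurations and is seed-deterministic", {
  set.seed(42)
  X <- matrix(rnorm(20 * 3), 20, 3)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- paste0("p", 1:20)
  emb <- embed_mmds(D, 3, seed = 9)
  expect_lt(emb$stress1, 0.01)

  # colinear points embed perfectly in one dimension
  x1 <- matrix(c(0, 1, 3, 7), 4, 1)
  D1 <- as.matrix(dist(x1))
  e1 <- embed_mmds(D1, 1, seed = 2)
  expect_lt(e1$stress1, 1e-6)

  # determinism under a fixed seed
  e_a <- embed_mmds(D, 2, seed = 5)
  e_b <- embed_mmds(D, 2, seed = 5)
  expect_identical(e_a$coordinates, e_b$coordinates)
  expect_identical(e_a$stress1, e_b$stress1)
})

test_that("metric MDS stress-1 does not increase with dimensionality", {
  set.seed(4)
  X <- matrix(rnorm(15 * 4), 15, 4)
  D <- as.matrix(dist(X))
  stresses <- vapply(1:4, function(k) embed_mmds(D, k, seed = 3)$stress1, numeric(1))
  expect_true(all(diff(stresses) <= 1e-9))
})

test_that("Laplacian eigenmaps separate well-separated blobs along the first component", {
  set.seed(8)
  blob1 <- matrix(rnorm(10 * 2, 0, 0.1), 10, 2)
  blob2 <- matrix(rnorm(10 * 2, 10, 0.1), 10, 2)
  D <- as.matrix(dist(rbind(blob1, blob2)))
  emb <- embed_laplacian(D, 1)
  signs <- sign(emb$coordinates[, 1])
  expect_true(all(signs[1:10] == signs[1]))
  expect_true(all(signs[11:20] == signs[11]))
  expect_true(signs[1] != signs[11])
  expect_equal(length(emb$eigenvalues), 20)

  # identical points give a flat zero-variance embedding
  z <- matrix(0, 4, 4)
  ez <- embed_laplacian(z, 2)
  expect_equal(max(abs(ez$coordinates)), 0)

  # the default bandwidth rule is the median off-diagonal distance
  Dm <- matrix(10, 3, 3); diag(Dm) <- 0
  expect_equal(median(Dm[upper.tri(Dm)]), 10)
})

test_that("dimension selection applies the stress threshold rule", {
  expect_equal(select_dimensions(c(0.4, 0.25, 0.19, 0.15)), 3L)
  expect_equal(select_dimensions(c(0.1)), 1L)
  expect_error(select_dimensions(c(0.5, 0.4)), "more dimensions")
  prof <- tibble::tibble(k = 2:5, stress1 = c(0.4, 0.25, 0.19, 0.15))
  expect_equal(select_dimensions(prof), 4L)
  expect_identical(select_dimensions(prof, rule = "report_only"), prof)
})
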