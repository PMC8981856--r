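new_embedding <- function(method, coordinates, eigenvalues = numeric(),
                          stress1 = NA_real_, seed = NA_integer_) {
  colnames(coordinates) <- paste0("dim", seq_len(ncol(coordinates)))
  structure(list(method = method, coordinates = coordinates,
                 eigenvalues = eigenvalues, stress1 = stress1, seed = seed),
            class = "trait_embedding")
}

#' @export
print.trait_embedding <- function(x, ...) {
  cat(sprintf("<trait_embedding (%s): %d individuals x %d dims%s>\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates),
              if (is.na(x$stress1)) "" else sprintf(", stress1 = %.4f", x$stress1)))
  invisible(x)
}

#' @describeIn embed_pcoa Coordinates as a tibble (`id` + one column per
#'   dimension).
#' @param x A `trait_embedding`.
#' @param ... Unused.
#' @export
tidy.trait_embedding <- function(x, ...) {
  dplyr::bind_cols(tibble(id = rownames(x$coordinates)),
                   as_tibble(x$coordinates))
}

#' @describeIn embed_pcoa One-row summary (method, dimensions, stress-1).
#' @export
glance.trait_embedding <- function(x, ...) {
  tibble(method = x$method, n = nrow(x$coordinates), k = ncol(x$coordinates),
         stress1 = x$stress1, n_eigenvalues = length(x$eigenvalues))
}

# Extract a plain distance matrix from whatever the caller hands over.
as_dist_matrix <- function(D) {
  if (inherits(D, "individual_dist")) D <- D$D
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("`D` must be a square distance matrix")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("i", seq_len(nrow(D)))
  if (anyNA(D)) abort("`D` contains undefined entries; apply resolve_undefined() first")
  if (any(abs(diag(D)) > 1e-12)) abort("`D` must have a zero diagonal")
  if (max(abs(D - t(D))) > 1e-8) abort("`D` must be symmetric")
  D
}

#' Resolve undefined pairwise distances
#'
#' Pairs of individuals sharing no observed variable have no defined
#' distance. Before embedding, such entries must either abort the analysis
#' (`policy = "error"`) or be filled with the mean of the defined
#' off-diagonal distances (`policy = "mean_impute"`), in which case the
#' number of filled pairs is reported.
#'
#' @param idm An `individual_dist` (or plain matrix with possible `NA`s).
#' @param policy `"error"` or `"mean_impute"`.
#' @return The `individual_dist` with a complete `D`.
#' @export
resolve_undefined <- function(idm, policy = c("error", "mean_impute")) {
  policy <- match.arg(policy)
  plain <- !inherits(idm, "individual_dist")
  D <- if (plain) idm else idm$D
  und <- which(upper.tri(D) & is.na(D), arr.ind = TRUE)
  if (nrow(und) == 0) return(idm)
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  if (policy == "error") {
    shown <- head(sprintf("(%s, %s)", ids[und[, 1]], ids[und[, 2]]), 10)
    abort(sprintf("%d undefined pair(s): %s%s", nrow(und),
                  paste(shown, collapse = ", "),
                  if (nrow(und) > 10) ", ..." else ""))
  }
  fill <- mean(D[upper.tri(D)], na.rm = TRUE)
  if (!is.finite(fill)) abort("no defined off-diagonal distances to impute from")
  D[is.na(D)] <- fill
  diag(D) <- 0
  message(sprintf("imputed %d undefined pair(s) with the mean defined distance %.4f",
                  nrow(und), fill))
  if (plain) D else { idm$D <- D; idm }
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centres the squared distance matrix (\eqn{-\tfrac12 J D^2 J}),
#' eigendecomposes it, and returns coordinates scaled by the square roots
#' of the top `k` positive eigenvalues. Negative eigenvalues (which signal
#' a non-Euclidean input) are reported in `eigenvalues` but never enter the
#' coordinates; no correction is applied to them.
#'
#' @param D Distance input (`individual_dist`, `dist` or matrix).
#' @param k Number of dimensions; must not exceed the number of positive
#'   eigenvalues.
#' @return A `trait_embedding` with all eigenvalues (non-increasing).
#' @export
embed_pcoa <- function(D, k) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (k < 1) abort("`k` must be >= 1")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  n_pos <- sum(e$values > tol)
  if (k > n_pos) {
    abort(sprintf("k = %d exceeds the %d positive eigenvalue(s) of the PCoA", k, n_pos))
  }
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  rownames(coords) <- rownames(D)
  new_embedding("pcoa", coords, eigenvalues = e$values)
}

#' Kruskal stress-1 of a configuration
#'
#' \deqn{stress1 = \sqrt{\sum_{j>i} (\hat\delta_{ij} - \delta_{ij})^2 /
#'   \sum_{j>i} \delta_{ij}^2}}
#' where \eqn{\delta} are the observed distances and \eqn{\hat\delta} the
#' Euclidean distances between coordinate rows. Below 0.2 is conventionally
#' read as a good representation.
#'
#' @param D_obs Observed distances (matrix/`dist`/`individual_dist`).
#' @param coordinates Numeric matrix, one row per individual.
#' @return The stress-1 value (0 for a perfect configuration).
#' @export
stress1 <- function(D_obs, coordinates) {
  D <- as_dist_matrix(D_obs)
  if (nrow(coordinates) != nrow(D)) abort("coordinate rows must match `D_obs`")
  up <- upper.tri(D)
  denom <- sum(D[up]^2)
  if (denom == 0) abort("all observed distances are zero: stress-1 undefined")
  Dhat <- as.matrix(dist(coordinates))
  sqrt(sum((Dhat[up] - D[up])^2) / denom)
}

#' Metric multidimensional scaling by stress majorisation
#'
#' SMACOF-style iterative minimisation of raw stress with the Guttman
#' transform, started from a classical-scaling configuration plus `n_init`
#' random Gaussian configurations; the configuration with the lowest final
#' stress-1 is kept. A fixed seed makes the result bit-identical across
#' runs.
#'
#' @param D Distance input.
#' @param k Target dimensionality.
#' @param seed Integer seed for the random initialisations.
#' @param n_init Number of random starts (default 4).
#' @param max_iter Majorisation iterations per start (default 300).
#' @param tol Relative stress-decrease convergence threshold (default 1e-6).
#' @return A `trait_embedding` with `stress1` computed from the final
#'   coordinates. Non-convergence raises a warning and returns the best
#'   iterate.
#' @export
embed_mmds <- function(D, k, seed = 1L, n_init = 4, max_iter = 300, tol = 1e-6) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (k < 1) abort("`k` must be >= 1")
  set.seed(seed)
  # classical-scaling start (padded with zeros beyond the positive spectrum)
  # is always tried alongside the random starts
  starts <- list(torgerson_start(D, k))
  for (init in seq_len(n_init)) starts <- c(starts, list(matrix(rnorm(n * k), n, k)))
  best <- NULL; best_stress <- Inf; any_converged <- FALSE
  for (X in starts) {
    res <- smacof_run(D, X, max_iter, tol)
    any_converged <- any_converged || res$converged
    s <- stress1(D, res$X)
    if (s < best_stress) { best_stress <- s; best <- res$X }
  }
  if (!any_converged) {
    warn(sprintf("metric MDS did not converge within %d iterations; best iterate returned",
                 max_iter))
  }
  rownames(best) <- rownames(D)
  new_embedding("mmds", best, stress1 = best_stress, seed = as.integer(seed))
}

torgerson_start <- function(D, k) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(-0.5 * J %*% (D * D) %*% J, symmetric = TRUE)
  n_pos <- sum(e$values > 0)
  X <- matrix(0, n, k)
  take <- seq_len(min(k, n_pos))
  if (length(take)) {
    X[, take] <- e$vectors[, take, drop = FALSE] %*%
      diag(sqrt(e$values[take]), length(take))
  }
  X
}

# One SMACOF descent: raw stress sigma(X) = sum (delta - d(X))^2, updated
# with the unweighted Guttman transform X <- B(X) X / n.
smacof_run <- function(D, X, max_iter, tol) {
  n <- nrow(D)
  raw_stress <- function(X) {
    dX <- as.matrix(dist(X))
    sum((D[upper.tri(D)] - dX[upper.tri(dX)])^2)
  }
  s_old <- raw_stress(X)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dX <- as.matrix(dist(X))
    ratio <- ifelse(dX > 0, D / dX, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    s_new <- raw_stress(X)
    if (s_old - s_new <= tol * max(s_old, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    s_old <- s_new
  }
  list(X = X, converged = converged)
}

#' Laplacian eigenmaps spectral embedding
#'
#' Converts distances into a Gaussian affinity
#' \eqn{W_{ij} = \exp(-D_{ij}^2 / 2\sigma^2)} with bandwidth \eqn{\sigma}
#' equal to the median off-diagonal distance (the default rule), then embeds
#' with the eigenvectors of the symmetric normalised graph Laplacian that
#' belong to the smallest non-trivial eigenvalues. The full Laplacian
#' spectrum (ascending) is reported for the scree diagnostic.
#'
#' @param D Distance input.
#' @param k Number of embedding components.
#' @param bandwidth `"median"` or a positive number.
#' @param threshold Optional affinity cut-off: entries below it are zeroed.
#'   A graph disconnected after thresholding is an error.
#' @return A `trait_embedding`.
#' @export
embed_laplacian <- function(D, k, bandwidth = "median", threshold = NULL) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (k < 1 || k > n - 1) abort("`k` must lie in [1, n - 1]")
  sigma <- if (identical(bandwidth, "median")) {
    median(D[upper.tri(D)])
  } else {
    as.numeric(bandwidth)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    # degenerate inputs (all points identical): flat zero-variance embedding
    coords <- matrix(0, n, k, dimnames = list(rownames(D), NULL))
    return(new_embedding("laplacian", coords, eigenvalues = rep(0, n)))
  }
  W <- exp(-D^2 / (2 * sigma^2))
  diag(W) <- 0
  if (!is.null(threshold)) {
    W[W < threshold] <- 0
    if (graph_components(W > 0) > 1) {
      abort("affinity graph is disconnected after thresholding")
    }
  }
  deg <- rowSums(W)
  deg[deg == 0] <- .Machine$double.eps
  inv_sqrt <- 1 / sqrt(deg)
  Lsym <- diag(n) - (inv_sqrt * W) %*% diag(inv_sqrt)
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  lam <- rev(e$values)                       # ascending
  vec <- e$vectors[, rev(seq_len(n)), drop = FALSE]
  take <- seq(2, k + 1)                      # drop the trivial constant mode
  coords <- vec[, take, drop = FALSE] * inv_sqrt
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(coords))) {
    piv <- which.max(abs(coords[, j]))
    if (coords[piv, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(D)
  new_embedding("laplacian", coords, eigenvalues = lam)
}

graph_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  comps
}

#' Stress-1 profile over embedding dimensionalities
#'
#' Runs metric MDS for each dimensionality in `k_range` and collects the
#' stress-1 values, the standard diagnostic for choosing the dimension of
#' the reduced space.
#'
#' @param D Distance input.
#' @param k_range Integer vector of dimensionalities.
#' @param seed,n_init,max_iter,tol See [embed_mmds()].
#' @return Tibble with columns `k`, `stress1`.
#' @export
stress_profile <- function(D, k_range, seed = 1L, n_init = 4,
                           max_iter = 300, tol = 1e-6) {
  purrr::map_dfr(k_range, function(k) {
    emb <- embed_mmds(D, k, seed = stage_seed(seed, paste0("mmds", k)),
                      n_init = n_init, max_iter = max_iter, tol = tol)
    tibble(k = k, stress1 = emb$stress1)
  })
}

#' Choose the embedding dimensionality
#'
#' With `rule = "stress_threshold"`, returns the smallest dimensionality
#' whose stress-1 falls below the threshold (0.2 by convention). With
#' `rule = "report_only"` the diagnostic series is returned untouched for a
#' manual elbow reading, which is deliberately not automated.
#'
#' @param diagnostics Either a tibble with columns `k` and `stress1`, or a
#'   numeric vector of stress values for k = 1, 2, ... (or an eigenvalue
#'   series for `report_only`).
#' @param rule `"stress_threshold"` or `"report_only"`.
#' @param threshold Stress-1 cut-off (default 0.2).
#' @return The selected `k` (integer), or the diagnostic series for
#'   `report_only`.
#' @export
select_dimensions <- function(diagnostics, rule = c("stress_threshold", "report_only"),
                              threshold = 0.2) {
  rule <- match.arg(rule)
  if (rule == "report_only") return(diagnostics)
  if (is.data.frame(diagnostics)) {
    ks <- diagnostics$k; ss <- diagnostics$stress1
  } else {
    ks <- seq_along(diagnostics); ss <- as.numeric(diagnostics)
  }
  if (!length(ss)) abort("empty diagnostic series")
  ok <- which(ss < threshold)
  if (!length(ok)) {
    abort(sprintf("no dimensionality reaches stress1 < %g; evaluate more dimensions",
                  threshold))
  }
  as.integer(ks[ok[1]])
}
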