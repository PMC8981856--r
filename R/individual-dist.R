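new_individual_dist <- function(D, M, method) {
  structure(list(ids = rownames(D), D = D, cardinality = M, method = method),
            class = "individual_dist")
}

#' @export
print.individual_dist <- function(x, ...) {
  nu <- sum(is.na(x$D[upper.tri(x$D)]))
  cat(sprintf("<individual_dist (%s): %d individuals%s>\n", x$method,
              length(x$ids),
              if (nu) sprintf(", %d undefined pair(s)", nu) else ""))
  invisible(x)
}

#' @describeIn semantic_distance_matrix Long-format pair table
#'   (`id_a`, `id_b`, `distance`, `n_variables`), upper triangle only.
#' @param x An `individual_dist`.
#' @param ... Unused.
#' @export
tidy.individual_dist <- function(x, ...) {
  prs <- unordered_pairs(length(x$ids))
  tibble(id_a = x$ids[prs[, 1]], id_b = x$ids[prs[, 2]],
         distance = x$D[prs], n_variables = as.integer(x$cardinality[prs]))
}

#' @describeIn semantic_distance_matrix One-row summary (method, size,
#'   defined-pair count, distance range).
#' @export
glance.individual_dist <- function(x, ...) {
  up <- x$D[upper.tri(x$D)]
  tibble(method = x$method, n = length(x$ids),
         n_pairs = length(up), n_undefined = sum(is.na(up)),
         min_distance = if (all(is.na(up))) NA_real_ else min(up, na.rm = TRUE),
         max_distance = if (all(is.na(up))) NA_real_ else max(up, na.rm = TRUE))
}

# Per-variable pairwise distance matrices (NA where a member is missing).
# Qualitative: lookup in the normalised modality matrix. Quantitative:
# |a - b| rescaled so the largest observed difference maps to `scale_to`
# (100 for the semantic distance); range 0 or all-missing gives all zeros.
per_variable_distances <- function(dataset, matrices) {
  specs <- dataset_specs(dataset)
  n <- nrow(dataset)
  out <- list()
  for (i in seq_len(nrow(specs))) {
    v <- specs$name[i]
    vals <- dataset[[v]]
    if (specs$kind[i] == "qualitative") {
      m <- matrices[[v]]
      if (is.null(m)) abort(sprintf("no modality matrix supplied for variable '%s'", v))
      if (!isTRUE(attr(m, "normalised"))) {
        abort(sprintf("modality matrix for '%s' must be normalised first", v))
      }
      idx <- match(vals, rownames(m))
      bad <- !is.na(vals) & is.na(idx)
      if (any(bad)) {
        abort(sprintf("value '%s' of variable '%s' has no row in its modality matrix",
                      vals[which(bad)[1]], v))
      }
      dm <- matrix(NA_real_, n, n)
      obs <- !is.na(idx)
      dm[obs, obs] <- unclass(m)[idx[obs], idx[obs]]
    } else {
      dm <- abs(outer(vals, vals, "-"))
      top <- suppressWarnings(max(dm, na.rm = TRUE))
      if (is.finite(top) && top > 0) dm <- dm * 100 / top else dm[!is.na(dm)] <- 0
    }
    dimnames(dm) <- list(dataset$id, dataset$id)
    out[[v]] <- dm
  }
  out
}

#' Semantic distance between two individuals
#'
#' The semantic distance is the weighted mean of per-variable distances over
#' the set M of variables observed in both individuals: qualitative
#' per-variable distances are looked up in the variable's normalised
#' modality matrix, quantitative ones are absolute differences on the same
#' 0-100 scale. If M is empty the distance is undefined (`NA`), not an
#' error.
#'
#' @param a,b Named lists or one-row data frames of variable values (`NA`
#'   for missing).
#' @param specs Spec table (provides kinds and weights).
#' @param matrices Named list of normalised `modality_dist` matrices for
#'   the qualitative variables.
#' @param quant_scale Named vector: for each quantitative variable, the
#'   denominator mapping the largest observed absolute difference to 100
#'   (computed dataset-wide by [semantic_distance_matrix()]).
#' @return List with `distance` (possibly `NA`) and `n_variables` (the
#'   cardinality of M).
#' @export
semantic_pair_distance <- function(a, b, specs, matrices, quant_scale = NULL) {
  validate_specs(specs)
  a <- as.list(a); b <- as.list(b)
  num <- 0; den <- 0; m_card <- 0L
  for (i in seq_len(nrow(specs))) {
    v <- specs$name[i]
    av <- a[[v]]; bv <- b[[v]]
    if (is.null(av) || is.null(bv) || is.na(av) || is.na(bv)) next
    if (specs$kind[i] == "qualitative") {
      m <- matrices[[v]]
      if (is.null(m)) abort(sprintf("no modality matrix supplied for variable '%s'", v))
      if (!isTRUE(attr(m, "normalised"))) {
        abort(sprintf("modality matrix for '%s' must be normalised first", v))
      }
      if (!av %in% rownames(m) || !bv %in% rownames(m)) {
        abort(sprintf("value missing from the modality matrix of '%s'", v))
      }
      d <- unclass(m)[av, bv]
    } else {
      if (is.null(quant_scale) || !v %in% names(quant_scale)) {
        abort(sprintf("supply `quant_scale` for quantitative variable '%s'", v))
      }
      sc <- quant_scale[[v]]
      d <- if (sc > 0) abs(as.numeric(av) - as.numeric(bv)) * 100 / sc else 0
    }
    w <- specs$weight[i]
    num <- num + w * d
    den <- den + w
    m_card <- m_card + 1L
  }
  list(distance = if (m_card == 0 || den == 0) NA_real_ else num / den,
       n_variables = m_card)
}

#' Semantic distance matrix between all individuals
#'
#' Computes the ontology-backed weighted semantic distance for every
#' unordered pair of individuals, ignoring missing values: each pair is
#' averaged over the variables observed in both members only, and the
#' number of variables used is recorded alongside the distance. Pairs
#' sharing no observed variable are undefined (`NA` in `D`, cardinality 0)
#' and reported with a warning; the embedding step decides how to handle
#' them.
#'
#' @param dataset A `trait_dataset`.
#' @param matrices Named list of **normalised** modality matrices covering
#'   every qualitative variable (see [build_all_modality_matrices()]).
#' @return An `individual_dist`: symmetric `D` on the 0-100 scale with zero
#'   diagonal, plus the per-pair cardinality matrix.
#' @export
semantic_distance_matrix <- function(dataset, matrices) {
  specs <- dataset_specs(dataset)
  n <- nrow(dataset)
  pervar <- per_variable_distances(dataset, matrices)
  D <- matrix(0, n, n); W <- matrix(0, n, n); M <- matrix(0L, n, n)
  for (i in seq_len(nrow(specs))) {
    dm <- pervar[[specs$name[i]]]
    obs <- !is.na(dm)
    w <- specs$weight[i]
    D[obs] <- D[obs] + w * dm[obs]
    W <- W + w * obs
    M <- M + obs
  }
  D <- ifelse(W > 0, D / W, NA_real_)
  diag(D) <- 0  # an individual is at distance zero from itself by definition
  dimnames(D) <- dimnames(M) <- list(dataset$id, dataset$id)
  warn_undefined(D, dataset$id)
  new_individual_dist(D, M, method = "semantic")
}

warn_undefined <- function(D, ids) {
  up <- which(upper.tri(D) & is.na(D), arr.ind = TRUE)
  if (nrow(up)) {
    shown <- head(sprintf("(%s, %s)", ids[up[, 1]], ids[up[, 2]]), 5)
    warn(sprintf("%d pair(s) share no observed variable and are undefined: %s%s",
                 nrow(up), paste(shown, collapse = ", "),
                 if (nrow(up) > 5) ", ..." else ""))
  }
  invisible(NULL)
}

#' Gower-style distance matrix with explicit missing-value masking
#'
#' A per-variable construction in the Gower spirit: quantitative variables
#' contribute Manhattan distances `|a - b|`, divided by the variable's
#' observed range by default (a zero range contributes zeros); qualitative
#' variables are one-hot dummy-coded with an extra missing-value indicator
#' and contribute the Dice dissimilarity between dummy vectors, with any
#' pair flagged by the missing indicator masked out as undefined. The final
#' distance is the element-wise mean of the per-variable matrices over
#' their defined entries, and the number of contributing variables is kept
#' per pair.
#'
#' @param dataset A `trait_dataset`.
#' @param range_normalise Divide quantitative contributions by the observed
#'   range (classic Gower). `FALSE` uses the raw Manhattan difference.
#' @return An `individual_dist` with `D` in the unit interval on complete
#'   data.
#' @export
gower_distance_matrix <- function(dataset, range_normalise = TRUE) {
  specs <- dataset_specs(dataset)
  n <- nrow(dataset)
  D <- matrix(0, n, n); M <- matrix(0L, n, n)
  for (i in seq_len(nrow(specs))) {
    vals <- dataset[[specs$name[i]]]
    if (specs$kind[i] == "quantitative") {
      dm <- abs(outer(vals, vals, "-"))
      if (range_normalise) {
        rng <- suppressWarnings(diff(range(vals, na.rm = TRUE)))
        if (is.finite(rng) && rng > 0) dm <- dm / rng else dm[!is.na(dm)] <- 0
      }
    } else {
      dm <- dice_dummy_distances(vals)
    }
    obs <- !is.na(dm)
    D[obs] <- D[obs] + dm[obs]
    M <- M + obs
  }
  D <- ifelse(M > 0, D / M, NA_real_)
  diag(D) <- 0
  dimnames(D) <- dimnames(M) <- list(dataset$id, dataset$id)
  warn_undefined(D, dataset$id)
  new_individual_dist(D, M, method = "gower")
}

# One qualitative variable: one-hot dummies over its observed modalities
# plus a missing indicator; pairwise Dice dissimilarity on the dummies;
# pairs where either member is flagged missing are set to NA.
dice_dummy_distances <- function(vals) {
  n <- length(vals)
  lev <- unique(vals[!is.na(vals)])
  dummies <- matrix(0L, n, length(lev) + 1L)
  dummies[cbind(seq_len(n), match(vals, lev, nomatch = length(lev) + 1L))] <- 1L
  # Dice dissimilarity 1 - 2|X&Y| / (|X|+|Y|); each row has exactly one bit
  inter <- tcrossprod(dummies)
  dm <- 1 - 2 * inter / 2
  flagged <- is.na(vals)
  dm[flagged, ] <- NA_real_
  dm[, flagged] <- NA_real_
  dm
}
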