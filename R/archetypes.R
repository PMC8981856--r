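new_archetype_set <- function(table, mode, fraction = NA_real_, seed = NA_integer_) {
  structure(as_tibble(table), mode = mode, fraction = fraction,
            seed = as.integer(seed),
            class = c("archetype_set", class(as_tibble(table))))
}

#' Single archetype per cluster: the individual nearest the centroid
#'
#' For each cluster, the centroid is the mean coordinate of its members and
#' the archetype is the member at minimum Euclidean distance from it. Ties
#' are broken towards the member whose id sorts first, so the choice is
#' deterministic.
#'
#' @param coordinates Coordinate matrix or `trait_embedding`.
#' @param partition A `trait_partition`.
#' @return An `archetype_set` tibble with columns `cluster`, `id`, `mode`.
#' @export
single_archetype <- function(coordinates, partition) {
  if (inherits(coordinates, "trait_embedding")) coordinates <- coordinates$coordinates
  rows <- purrr::map_dfr(sort(unique(partition$labels)), function(cl) {
    members <- which(partition$labels == cl)
    xs <- coordinates[members, , drop = FALSE]
    centroid <- colMeans(xs)
    d <- sqrt(rowSums((xs - matrix(centroid, nrow(xs), ncol(xs), byrow = TRUE))^2))
    best <- members[d == min(d)]
    pick <- best[order(partition$ids[best])][1]
    tibble(cluster = cl, id = partition$ids[pick])
  })
  rows$mode <- "single"
  new_archetype_set(rows, mode = "single")
}

#' Multiple archetypes per cluster: a seeded random sample
#'
#' Samples a fixed fraction of each cluster uniformly without replacement
#' (5% by default), taking at least one individual per cluster so none is
#' left unrepresented; the sample size is \eqn{\lceil fraction \cdot
#' size\rceil}. A fixed seed reproduces the selection exactly.
#'
#' @param partition A `trait_partition`.
#' @param fraction Sampled fraction per cluster, in (0, 1].
#' @param seed Integer seed.
#' @return An `archetype_set` tibble with columns `cluster`, `id`, `mode`.
#' @export
multiple_archetypes <- function(partition, fraction = 0.05, seed = 1L) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  set.seed(stage_seed(seed, "archetypes"))
  rows <- purrr::map_dfr(sort(unique(partition$labels)), function(cl) {
    members <- partition$ids[partition$labels == cl]
    size <- max(1L, as.integer(ceiling(fraction * length(members))))
    tibble(cluster = cl, id = sort(sample(members, size)))
  })
  rows$mode <- "multiple"
  new_archetype_set(rows, mode = "multiple", fraction = fraction, seed = seed)
}
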