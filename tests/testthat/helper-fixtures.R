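# Shared builders for the test suite. Everything is constructed in code or
# read from the plain-text fixtures bundled under inst/extdata.

fx <- phenodist::builtin_fixtures()

prickles_modalities <- c("Low", "Medium", "High", "Very high")

# The hand-tailored prickles matrix (two subgroups, order preserved).
prickles_matrix_expected <- matrix(
  c(0, 1, 5, 6,
    1, 0, 4, 5,
    5, 4, 0, 1,
    6, 5, 1, 0), 4, 4, byrow = TRUE,
  dimnames = list(prickles_modalities, prickles_modalities))

demo_specs <- function() {
  dplyr::bind_rows(
    phenodist::variable_spec("Quantity of prickles", "qualitative", "ontology_file", fx$prickles_normal),
    phenodist::variable_spec("Petal colour", "qualitative", "colour_table", fx$colours),
    phenodist::variable_spec("Geographic origin", "qualitative", "geo_table", fx$geo),
    phenodist::variable_spec("Breeding period", "qualitative", "period_table", fx$periods),
    phenodist::variable_spec("Number of flowers by volume", "quantitative", "numeric"))
}

demo_dataset <- function() {
  phenodist::read_trait_table(fx$dataset, demo_specs())
}

# A tiny all-qualitative dataset built in code: two variables over ontology
# fixtures is overkill, so the specs point at the prickles fixture and a
# binary {0,100} matrix is supplied directly where needed.
qual_dataset <- function(values, var_names = paste0("v", seq_along(values[[1]]))) {
  df <- tibble::tibble(id = sprintf("i%02d", seq_along(values)))
  for (j in seq_along(var_names)) {
    df[[var_names[j]]] <- vapply(values, function(r) {
      v <- r[[j]]
      if (is.null(v) || (length(v) == 1 && is.na(v))) NA_character_ else as.character(v)
    }, character(1))
  }
  specs <- dplyr::bind_rows(lapply(var_names, function(nm) {
    phenodist::variable_spec(nm, "qualitative", "ontology_file", "unused")
  }))
  phenodist:::new_trait_dataset(df, specs)
}

# Binary {0, 100} normalised modality matrix over the given labels.
binary_modality_matrix <- function(labels) {
  m <- matrix(100, length(labels), length(labels), dimnames = list(labels, labels))
  diag(m) <- 0
  phenodist:::new_modality_dist(m, normalised = TRUE)
}

# Independent brute-force oracle for the Gower variant: literal dummy
# coding with a missing indicator, Dice dissimilarity per qualitative
# variable, range-normalised Manhattan per quantitative variable, masked
# element-wise mean.
gower_oracle <- function(dataset) {
  specs <- phenodist::dataset_specs(dataset)
  n <- nrow(dataset)
  per_var <- lapply(seq_len(nrow(specs)), function(i) {
    vals <- dataset[[specs$name[i]]]
    dm <- matrix(NA_real_, n, n)
    if (specs$kind[i] == "quantitative") {
      rng <- suppressWarnings(diff(range(vals, na.rm = TRUE)))
      for (a in 1:n) for (b in 1:n) {
        if (!is.na(vals[a]) && !is.na(vals[b])) {
          dm[a, b] <- if (is.finite(rng) && rng > 0) abs(vals[a] - vals[b]) / rng else 0
        }
      }
    } else {
      lev <- unique(vals[!is.na(vals)])
      dummies <- matrix(0L, n, length(lev) + 1L)
      for (a in 1:n) {
        j <- match(vals[a], lev)
        if (is.na(j)) j <- length(lev) + 1L
        dummies[a, j] <- 1L
      }
      for (a in 1:n) for (b in 1:n) {
        if (dummies[a, length(lev) + 1L] == 1L || dummies[b, length(lev) + 1L] == 1L) next
        inter <- sum(dummies[a, ] & dummies[b, ])
        dm[a, b] <- 1 - 2 * inter / (sum(dummies[a, ]) + sum(dummies[b, ]))
      }
    }
    dm
  })
  D <- matrix(NA_real_, n, n)
  M <- matrix(0L, n, n)
  for (a in 1:n) for (b in 1:n) {
    vals <- vapply(per_var, function(dm) dm[a, b], numeric(1))
    M[a, b] <- sum(!is.na(vals))
    if (M[a, b] > 0) D[a, b] <- mean(vals, na.rm = TRUE)
  }
  diag(D) <- 0
  list(D = D, M = M)
}

# Brute-force per-sample silhouette straight from the textbook formula.
silhouette_oracle <- function(coords, labels) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  vapply(seq_len(n), function(i) {
    own <- labels[i]
    mates <- which(labels == own & seq_len(n) != i)
    if (!length(mates)) return(0)
    a <- mean(d[i, mates])
    b <- min(vapply(setdiff(unique(labels), own), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

planar_points <- function(n = 5, d = 2, seed = 13) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d, dimnames = list(paste0("p", 1:n), NULL))
}

expect_symmetric_zero_diag <- function(D, tol = 1e-10) {
  expect_lt(max(abs(D - t(D)), na.rm = TRUE), tol)
  expect_true(all(abs(diag(D)) < tol))
}
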