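# Random normalised modality matrix over m labels (max entry 100).
random_modality_matrix <- function(labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1) {
    m[upper.tri(m)] <- runif(choose(n, 2), 1, 80)
    m <- m + t(m)
    m <- m * 100 / max(m)
  }
  phenodist:::new_modality_dist(m, normalised = TRUE)
}

test_that("pairwise semantic distance follows the weighted missing-aware mean", {
  labels <- c("x", "y", "z")
  mats <- list(v1 = random_modality_matrix(labels),
               v2 = random_modality_matrix(labels))
  specs <- dplyr::bind_rows(
    variable_spec("v1", "qualitative", "ontology_file", "unused"),
    variable_spec("v2", "qualitative", "ontology_file", "unused"))

  # identical complete records
  r <- semantic_pair_distance(list(v1 = "x", v2 = "y"), list(v1 = "x", v2 = "y"),
                              specs, mats)
  expect_equal(r$distance, 0)
  expect_equal(r$n_variables, 2)

  # two observed variables with distances 0 and 50, equal weights
  m50 <- phenodist:::new_modality_dist(
    matrix(c(0, 50, 50, 0) * 2, 2, 2, dimnames = list(c("p", "q"), c("p", "q"))) / 2,
    normalised = TRUE)
  mats2 <- list(v1 = binary_modality_matrix(c("p", "q")), v2 = m50)
  r2 <- semantic_pair_distance(list(v1 = "p", v2 = "p"), list(v1 = "p", v2 = "q"),
                               specs, mats2)
  expect_equal(r2$distance, 25)
  expect_equal(r2$n_variables, 2)

  # weights shift the mean: w = (3, 1) puts 3/4 of the mass on v1
  specs_w <- specs
  specs_w$weight <- c(3, 1)
  r3 <- semantic_pair_distance(list(v1 = "p", v2 = "p"), list(v1 = "p", v2 = "q"),
                               specs_w, mats2)
  expect_equal(r3$distance, (3 * 0 + 1 * 50) / 4)

  # disjoint observed variables: undefined, not an error
  r4 <- semantic_pair_distance(list(v1 = "x", v2 = NA), list(v1 = NA, v2 = "y"),
                               specs, mats)
  expect_true(is.na(r4$distance))
  expect_equal(r4$n_variables, 0)
})

test_that("equal-weight semantic distance equals the mean of observed per-variable distances", {
  set.seed(101)
  labels <- letters[1:4]
  n_vars <- 4
  mats <- setNames(lapply(1:n_vars, function(i) random_modality_matrix(labels)),
                   paste0("v", 1:n_vars))
  specs <- dplyr::bind_rows(lapply(names(mats), function(nm) {
    variable_spec(nm, "qualitative", "ontology_file", "unused")
  }))
  for (rep in 1:40) {
    vals <- lapply(1:2, function(i) {
      v <- sample(c(labels, NA), n_vars, replace = TRUE)
      setNames(as.list(v), names(mats))
    })
    got <- semantic_pair_distance(vals[[1]], vals[[2]], specs, mats)
    per_var <- numeric()
    for (nm in names(mats)) {
      a <- vals[[1]][[nm]]; b <- vals[[2]][[nm]]
      if (!is.na(a) && !is.na(b)) per_var <- c(per_var, unclass(mats[[nm]])[a, b])
    }
    if (length(per_var)) {
      expect_equal(got$distance, mean(per_var))
    } else {
      expect_true(is.na(got$distance))
    }
    expect_equal(got$n_variables, length(per_var))
  }
})

test_that("the semantic distance matrix is symmetric with tracked cardinalities", {
  ds <- demo_dataset()
  built <- build_all_modality_matrices(dataset_specs(ds))
  idm <- suppressWarnings(semantic_distance_matrix(ds, built$normalised))
  expect_s3_class(idm, "individual_dist")
  expect_symmetric_zero_diag(idm$D)
  expect_true(all(idm$D >= -1e-12 & idm$D <= 100 + 1e-9, na.rm = TRUE))
  expect_true(all(idm$cardinality <= nrow(dataset_specs(ds))))
  off <- row(idm$D) != col(idm$D)
  expect_equal(is.na(idm$D[off]), unname(idm$cardinality[off] == 0))

  # quantitative variables are rescaled so the largest observed gap is 100
  sp <- dplyr::bind_rows(variable_spec("q", "quantitative", "numeric"))
  df <- tibble::tibble(id = c("a", "b", "c"), q = c(0, 5, 10))
  dsq <- phenodist:::new_trait_dataset(df, sp)
  idq <- semantic_distance_matrix(dsq, list())
  expect_equal(idq$D["a", "b"], 50)
  expect_equal(idq$D["a", "c"], 100)
  expect_equal(unname(idq$cardinality["a", "c"]), 1)

  # an all-missing individual is undefined against everyone but itself
  df2 <- tibble::tibble(id = c("a", "b", "c"), q = c(0, 5, NA))
  ds2 <- phenodist:::new_trait_dataset(df2, sp)
  expect_warning(id2 <- semantic_distance_matrix(ds2, list()), "undefined")
  expect_true(all(is.na(id2$D["c", c("a", "b")])))
  expect_equal(id2$D["c", "c"], 0)
})

test_that("the Gower variant matches simple matching on complete qualitative data", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:8, 1); p <- sample(2:5, 1)
    vals <- replicate(n, as.list(sample(letters[1:3], p, replace = TRUE)),
                      simplify = FALSE)
    ds <- qual_dataset(vals)
    idm <- gower_distance_matrix(ds)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      mismatch <- mean(unlist(vals[[i]]) != unlist(vals[[j]]))
      expect_equal(idm$D[i, j], mismatch)
    }
  }
})

test_that("two complete all-qualitative records differing everywhere are at distance 1", {
  ds <- qual_dataset(list(list("a", "x", "p"), list("b", "y", "q")))
  idm <- gower_distance_matrix(ds)
  expect_equal(idm$D[1, 2], 1)
  ds2 <- qual_dataset(list(list("a", "x"), list("a", "x")))
  expect_equal(gower_distance_matrix(ds2)$D[1, 2], 0)
  # 4 variables, 2 matching and 2 differing
  ds3 <- qual_dataset(list(list("a", "x", "p", "m"), list("a", "x", "q", "n")))
  expect_equal(gower_distance_matrix(ds3)$D[1, 2], 0.5)
})

test_that("the Gower variant equals the dummy-coding + Dice oracle on incomplete data", {
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(5:20, 1)
    p_qual <- sample(2:4, 1)
    df <- tibble::tibble(id = sprintf("i%02d", 1:n))
    specs <- list()
    for (j in 1:p_qual) {
      v <- sample(c(letters[1:3], NA), n, replace = TRUE, prob = c(.3, .25, .25, .2))
      df[[paste0("v", j)]] <- v
      specs[[length(specs) + 1]] <- variable_spec(paste0("v", j), "qualitative",
                                                  "ontology_file", "unused")
    }
    q <- rnorm(n); q[runif(n) < 0.25] <- NA
    df$num <- q
    specs[[length(specs) + 1]] <- variable_spec("num", "quantitative", "numeric")
    ds <- phenodist:::new_trait_dataset(df, dplyr::bind_rows(specs))
    got <- suppressWarnings(gower_distance_matrix(ds))
    want <- gower_oracle(ds)
    expect_equal(unname(got$D), unname(want$D))
    expect_equal(unname(got$cardinality), unname(want$M))
    expect_symmetric_zero_diag(got$D)
    expect_true(all(got$D >= -1e-12 & got$D <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("binary modality matrices collapse the semantic distance onto Gower", {
  set.seed(55)
  labels <- letters[1:4]
  for (rep in 1:5) {
    n <- sample(5:10, 1); p <- sample(2:4, 1)
    vals <- replicate(n, as.list(sample(labels, p, replace = TRUE)), simplify = FALSE)
    ds <- qual_dataset(vals)
    mats <- setNames(lapply(1:p, function(i) binary_modality_matrix(labels)),
                     paste0("v", 1:p))
    sem <- semantic_distance_matrix(ds, mats)
    gow <- gower_distance_matrix(ds)
    expect_equal(sem$D / 100, gow$D)
    expect_equal(sem$cardinality, gow$cardinality)
  }
})
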