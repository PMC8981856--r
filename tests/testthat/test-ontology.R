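test_that("the bundled prickles ontologies reproduce the printed expert matrices", {
  g <- read_concept_graph(fx$prickles_normal)
  expect_setequal(leaf_concepts(g), prickles_modalities)
  m <- expert_distance_matrix(g, order = prickles_modalities)
  expect_equal(unclass(m)[,], prickles_matrix_expected)
  expect_equal(m["Low", "Very high"], 6)
  expect_equal(m["Medium", "High"], 4)
  expect_equal(m["High", "Very high"], 1)

  # ordinal variant without subgroup separation
  m_flat <- expert_distance_matrix(read_concept_graph(fx$prickles_flat),
                                   order = prickles_modalities)
  expect_equal(m_flat["Low", "Very high"], 3)
  expect_equal(unclass(m_flat)[,],
               matrix(c(0, 1, 2, 3, 1, 0, 1, 2, 2, 1, 0, 1, 3, 2, 1, 0), 4, 4,
                      dimnames = dimnames(prickles_matrix_expected)))

  # equidistant variant: every off-diagonal entry is 1
  m_eq <- expert_distance_matrix(read_concept_graph(fx$prickles_equidistant),
                                 order = prickles_modalities)
  off <- unclass(m_eq)[,][upper.tri(m_eq)]
  expect_true(all(off == 1))
})

test_that("CSV edge lists load, and conflicting or negative distances are rejected", {
  g <- read_concept_graph(fx$prickles_normal_csv, format = "csv")
  expect_equal(unclass(expert_distance_matrix(g, order = prickles_modalities))[,],
               prickles_matrix_expected)

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("concept_a,concept_b,distance", "a,b,2.5"), tmp)
  g2 <- read_concept_graph(tmp)
  expect_equal(length(g2$concepts), 2)
  expect_equal(nrow(g2$distances), 1)
  expect_equal(unclass(expert_distance_matrix(g2))["a", "b"], 2.5)

  conflict <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("concept_a,concept_b,distance", "a,b,1", "b,a,3"), conflict)
  expect_error(read_concept_graph(conflict), "conflicting")

  mirrored <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("concept_a,concept_b,distance", "a,b,1", "b,a,1"), mirrored)
  expect_equal(nrow(read_concept_graph(mirrored)$distances), 1)

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("concept_a,concept_b,distance", "a,b,-1"), neg)
  expect_error(read_concept_graph(neg), "non-negative")
})

test_that("concept graphs round-trip through both on-disk dialects", {
  g <- read_concept_graph(fx$prickles_normal)
  owl <- withr::local_tempfile(fileext = ".owl")
  write_concept_graph(g, owl, "owl")
  g2 <- read_concept_graph(owl)
  expect_setequal(g2$concepts, g$concepts)
  expect_equal(dplyr::arrange(g2$is_a, parent, child),
               dplyr::arrange(g$is_a, parent, child))
  expect_equal(dplyr::arrange(g2$distances, concept_a, concept_b),
               dplyr::arrange(g$distances, concept_a, concept_b))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_concept_graph(g, csv, "csv")
  g3 <- read_concept_graph(csv)
  expect_equal(dplyr::arrange(g3$distances, concept_a, concept_b),
               dplyr::arrange(g$distances, concept_a, concept_b))
  # a complete graph over m leaves exports choose(m, 2) distance rows
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), choose(4, 2))

  empty <- concept_graph(character())
  p <- withr::local_tempfile(fileext = ".owl")
  write_concept_graph(empty, p, "owl")
  expect_equal(length(read_concept_graph(p)$concepts), 0)
})

test_that("matrix extraction is order-stable under statement permutation", {
  base <- read_concept_graph(fx$prickles_normal_csv, format = "csv")
  set.seed(11)
  for (rep in 1:5) {
    perm <- base$distances[sample(nrow(base$distances)), ]
    g <- concept_graph(base$concepts, distances = perm)
    expect_equal(unclass(expert_distance_matrix(g, order = prickles_modalities))[,],
                 prickles_matrix_expected)
  }
})

test_that("missing leaf pairs error unless the tree-path fallback applies", {
  g <- concept_graph(c("root", "a", "b"),
                     is_a = data.frame(parent = "root", child = c("a", "b")),
                     distances = data.frame(concept_a = "a", concept_b = "b",
                                            distance = 2))
  expect_equal(unclass(expert_distance_matrix(g))["a", "b"], 2)

  g2 <- concept_graph(c("root", "a", "b", "c"),
                      is_a = data.frame(parent = "root", child = c("a", "b", "c")),
                      distances = data.frame(concept_a = c("a", "b"),
                                             concept_b = c("b", "c"),
                                             distance = c(2, 3)))
  expect_error(expert_distance_matrix(g2), "\\(a, c\\)")
  # with every tree edge on the a-root-c path annotated, the fallback sums them
  g3 <- concept_graph(c("root", "a", "b", "c"),
                      is_a = data.frame(parent = c("root", "root", "root"),
                                        child = c("a", "b", "c")),
                      distances = data.frame(
                        concept_a = c("a", "b", "a", "root", "root"),
                        concept_b = c("b", "c", "root", "b", "c"),
                        distance = c(2, 5, 1, 1, 4)))
  m <- expert_distance_matrix(g3, fallback = TRUE)
  expect_equal(unclass(m)["a", "c"], 1 + 4)
  expect_equal(unclass(m)["a", "b"], 2)  # direct annotation wins over the path
})

test_that("single-concept graphs yield the 1x1 zero matrix", {
  g <- concept_graph("only")
  m <- expert_distance_matrix(g)
  expect_equal(phenodist:::plain_matrix(m),
               matrix(0, 1, 1, dimnames = list("only", "only")))
})
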