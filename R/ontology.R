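#' Build a concept graph with expert distances
#'
#' A concept graph represents the modalities of a qualitative variable as
#' ontology concepts, optionally organised by `is_a` edges into a rooted
#' tree or forest, with expert-provided numeric distances attached to
#' unordered concept pairs. The self-distance is implicitly 0.
#'
#' @param concepts Character vector of unique concept labels, in declared
#'   order (this order drives matrix label order downstream).
#' @param is_a Optional tibble/data frame with columns `parent`, `child`.
#' @param distances Tibble/data frame with columns `concept_a`, `concept_b`,
#'   `distance` (non-negative). One direction suffices; the pair is treated
#'   as unordered and mirrored automatically. The same pair stored twice
#'   with conflicting values is an error.
#' @return An object of class `concept_graph`.
#' @export
#' @examples
#' g <- concept_graph(c("a", "b"), distances = data.frame(
#'   concept_a = "a", concept_b = "b", distance = 2.5))
#' expert_distance_matrix(g)
concept_graph <- function(concepts, is_a = NULL, distances = NULL) {
  concepts <- as.character(concepts)
  if (anyDuplicated(concepts)) {
    abort(sprintf("duplicated concept label(s): %s",
                  paste(unique(concepts[duplicated(concepts)]), collapse = ", ")))
  }
  if (is.null(is_a)) {
    is_a <- tibble(parent = character(), child = character())
  } else {
    is_a <- as_tibble(is_a)[, c("parent", "child")]
    unknown <- setdiff(c(is_a$parent, is_a$child), concepts)
    if (length(unknown)) abort(sprintf("is_a edge names unknown concept(s): %s",
                                       paste(unknown, collapse = ", ")))
    if (anyDuplicated(is_a$child)) {
      abort("is_a edges must form a tree or forest (a child has two parents)")
    }
    # cycle check by repeated leaf-stripping
    edges <- is_a
    nodes <- concepts
    repeat {
      leaves <- setdiff(nodes, edges$parent)
      if (!length(leaves)) abort("is_a edges contain a cycle")
      nodes <- setdiff(nodes, leaves)
      edges <- edges[edges$child %in% nodes, , drop = FALSE]
      if (!length(nodes)) break
    }
  }
  if (!is.null(distances) && !nrow(as.data.frame(distances))) distances <- NULL
  if (is.null(distances)) {
    distances <- tibble(concept_a = character(), concept_b = character(),
                        distance = numeric())
  } else {
    distances <- as_tibble(distances)[, c("concept_a", "concept_b", "distance")]
    distances$distance <- as.numeric(distances$distance)
    unknown <- setdiff(c(distances$concept_a, distances$concept_b), concepts)
    if (length(unknown)) abort(sprintf("distance row names unknown concept(s): %s",
                                       paste(unknown, collapse = ", ")))
    if (anyNA(distances$distance)) abort("expert distances must be numeric")
    if (any(distances$distance < 0)) {
      abort("expert distances must be non-negative")
    }
    key <- pair_key(distances$concept_a, distances$concept_b)
    agg <- tapply(distances$distance, key, function(v) length(unique(v)))
    if (any(agg > 1)) {
      bad <- names(agg)[agg > 1][1]
      abort(sprintf("conflicting distances stored for pair (%s)",
                    gsub("\r", ", ", bad)))
    }
    distances <- distances[!duplicated(key), , drop = FALSE]
    # canonical order: a < b lexicographically within each unordered pair
    swap <- distances$concept_a > distances$concept_b
    tmp <- distances$concept_a[swap]
    distances$concept_a[swap] <- distances$concept_b[swap]
    distances$concept_b[swap] <- tmp
    same <- distances$concept_a == distances$concept_b
    if (any(same & distances$distance != 0)) {
      abort("a concept cannot be at non-zero distance from itself")
    }
    distances <- distances[!same, , drop = FALSE]
  }
  structure(list(concepts = concepts, is_a = is_a, distances = distances),
            class = "concept_graph")
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf("<concept_graph: %d concepts, %d is_a edges, %d expert distances>\n",
              length(x$concepts), nrow(x$is_a), nrow(x$distances)))
  invisible(x)
}

#' Leaf concepts of a graph
#' @param graph A `concept_graph`.
#' @return Character vector of concepts with no children, in declared order.
#' @export
leaf_concepts <- function(graph) {
  setdiff(graph$concepts, graph$is_a$parent)
}

#' Read a concept graph from OWL or CSV
#'
#' Two on-disk dialects are supported. The OWL (RDF/XML) dialect stores
#' concepts as `owl:Class` nodes (hierarchy via `rdfs:subClassOf`) and
#' expert distances as annotated `has_distance` object-property assertions:
#' an `owl:Axiom` block carrying the pair plus a real-valued `distance`
#' literal. A reified alternative is also accepted on read: an individual
#' typed `Distance` linking the two concepts and holding the `distance`
#' value. The CSV dialect is a plain edge list `concept_a,concept_b,distance`
#' (header required); it carries no hierarchy.
#'
#' Distances are unordered: one stored direction is mirrored automatically,
#' and only a pair stored twice with conflicting values is an error, as is
#' any negative distance.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"owl"` or `"csv"`.
#' @return A [concept_graph()].
#' @export
read_concept_graph <- function(path, format = c("auto", "owl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("ontology file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "owl"
  }
  if (format == "csv") read_concept_graph_csv(path) else read_concept_graph_owl(path)
}

read_concept_graph_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("concept_a", "concept_b", "distance")
  if (!all(need %in% names(df))) {
    abort("ontology CSV must have header columns concept_a,concept_b,distance")
  }
  concepts <- unique(c(rbind(df$concept_a, df$concept_b)))
  concept_graph(concepts, distances = df)
}

owl_ns <- function() {
  c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl = "http://www.w3.org/2002/07/owl#")
}

owl_frag <- function(iri) sub("^.*[#/]", "", iri)

read_concept_graph_owl <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(sprintf("cannot parse OWL file '%s': %s",
                                                    path, conditionMessage(e))))
  ns <- owl_ns()
  classes <- xml2::xml_find_all(doc, ".//owl:Class[@rdf:about]", ns)
  label_of <- function(node, iri) {
    lab <- xml2::xml_find_first(node, "./rdfs:label", ns)
    if (inherits(lab, "xml_missing")) owl_frag(iri) else xml2::xml_text(lab)
  }
  iris <- xml2::xml_attr(classes, "about")
  labels <- purrr::map2_chr(as.list(classes), iris, label_of)
  iri2label <- setNames(labels, owl_frag(iris))
  lookup <- function(iri) {
    frag <- owl_frag(iri)
    if (frag %in% names(iri2label)) unname(iri2label[[frag]]) else frag
  }
  is_a <- purrr::map2_dfr(as.list(classes), iris, function(cl, iri) {
    sup <- xml2::xml_find_all(cl, "./rdfs:subClassOf[@rdf:resource]", ns)
    if (!length(sup)) return(tibble(parent = character(), child = character()))
    tibble(parent = vapply(xml2::xml_attr(sup, "resource"), lookup, character(1)),
           child = lookup(iri))
  })
  if (!nrow(is_a)) is_a <- NULL

  # dialect 1: annotated object-property assertions (owl:Axiom blocks)
  axioms <- xml2::xml_find_all(doc, ".//owl:Axiom", ns)
  dist_rows <- purrr::map_dfr(as.list(axioms), function(ax) {
    prop <- xml2::xml_find_first(ax, "./owl:annotatedProperty", ns)
    if (inherits(prop, "xml_missing")) return(NULL)
    if (owl_frag(xml2::xml_attr(prop, "resource")) != "has_distance") return(NULL)
    src <- xml2::xml_attr(xml2::xml_find_first(ax, "./owl:annotatedSource", ns), "resource")
    tgt <- xml2::xml_attr(xml2::xml_find_first(ax, "./owl:annotatedTarget", ns), "resource")
    val <- xml2::xml_find_first(ax, "./*[local-name() = 'distance']")
    if (inherits(val, "xml_missing")) return(NULL)
    tibble(concept_a = lookup(src), concept_b = lookup(tgt),
           distance = as.numeric(xml2::xml_text(val)))
  })

  # dialect 2 (read-only): reified Distance individuals linking two concepts
  reified <- xml2::xml_find_all(doc, ".//*[local-name() = 'Distance']")
  dist_rows2 <- purrr::map_dfr(as.list(reified), function(node) {
    refs <- xml2::xml_find_all(node, "./*[@rdf:resource]", ns)
    refs <- refs[!xml2::xml_name(refs) %in% c("type")]
    res <- xml2::xml_attr(refs, "resource")
    res <- res[owl_frag(res) %in% names(iri2label)]
    val <- xml2::xml_find_first(node, "./*[local-name() = 'distance']")
    if (length(res) != 2 || inherits(val, "xml_missing")) return(NULL)
    tibble(concept_a = lookup(res[1]), concept_b = lookup(res[2]),
           distance = as.numeric(xml2::xml_text(val)))
  })
  dist_rows <- bind_rows(dist_rows, dist_rows2)
  if (nrow(dist_rows) && any(is.na(dist_rows$distance))) {
    abort(sprintf("non-numeric distance literal in '%s'", path))
  }
  concept_graph(unique(labels), is_a = is_a, distances = dist_rows)
}

#' Write a concept graph to OWL or CSV
#'
#' The OWL writer always emits the canonical annotated-assertion dialect
#' described in [read_concept_graph()]; reading the file back reproduces the
#' graph. The CSV writer emits the `concept_a,concept_b,distance` edge list
#' (hierarchy, which CSV cannot carry, is dropped).
#'
#' @param graph A [concept_graph()].
#' @param path Output path.
#' @param format `"owl"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_concept_graph <- function(graph, path, format = c("owl", "csv")) {
  format <- match.arg(format)
  if (!inherits(graph, "concept_graph")) abort("`graph` must be a concept_graph")
  ok <- tryCatch({
    if (format == "csv") {
      readr::write_csv(graph$distances, path, progress = FALSE)
    } else {
      writeLines(owl_serialise(graph), path, useBytes = TRUE)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("could not write ontology at '%s'", path))
  invisible(path)
}

concept_iri <- function(label) {
  # IRI fragment: label with non-word characters collapsed to underscores
  gsub("_+", "_", gsub("[^A-Za-z0-9]", "_", label))
}

owl_serialise <- function(graph) {
  iri <- setNames(concept_iri(graph$concepts), graph$concepts)
  if (anyDuplicated(iri)) {
    iri <- setNames(paste0(iri, "_", seq_along(iri)), graph$concepts)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
           " xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
           " xmlns:owl=\"http://www.w3.org/2002/07/owl#\"",
           " xmlns=\"http://example.org/trait-ontology#\"",
           " xml:base=\"http://example.org/trait-ontology\">"),
    "  <owl:Ontology rdf:about=\"http://example.org/trait-ontology\"/>",
    "  <owl:ObjectProperty rdf:about=\"#has_distance\"/>",
    "  <owl:AnnotationProperty rdf:about=\"#distance\"/>")
  parent_of <- setNames(graph$is_a$parent, graph$is_a$child)
  for (cpt in graph$concepts) {
    lines <- sprintf("  <owl:Class rdf:about=\"#%s\">", iri[[cpt]])
    lines <- c(lines, sprintf("    <rdfs:label>%s</rdfs:label>", xml_escape(cpt)))
    if (cpt %in% names(parent_of)) {
      lines <- c(lines, sprintf("    <rdfs:subClassOf rdf:resource=\"#%s\"/>",
                                iri[[parent_of[[cpt]]]]))
    }
    out <- c(out, lines, "  </owl:Class>")
  }
  for (i in seq_len(nrow(graph$distances))) {
    a <- graph$distances$concept_a[i]; b <- graph$distances$concept_b[i]
    out <- c(out,
      "  <owl:Axiom>",
      sprintf("    <owl:annotatedSource rdf:resource=\"#%s\"/>", iri[[a]]),
      sprintf("    <owl:annotatedProperty rdf:resource=\"#has_distance\"/>"),
      sprintf("    <owl:annotatedTarget rdf:resource=\"#%s\"/>", iri[[b]]),
      sprintf("    <distance rdf:datatype=\"http://www.w3.org/2002/07/owl#real\">%s</distance>",
              num_chr(graph$distances$distance[i])),
      "  </owl:Axiom>")
  }
  c(out, "</rdf:RDF>")
}

#' Extract the expert modality distance matrix of a graph
#'
#' Builds the symmetric leaf-pair distance matrix from the expert
#' annotations. Every unordered pair of leaf concepts must carry a distance;
#' with `fallback = TRUE` a missing pair may instead be filled by summing
#' expert distances along the unique `is_a` tree path between the two
#' leaves, provided every consecutive pair on that path is annotated.
#'
#' @param graph A [concept_graph()].
#' @param order Optional label order for rows/columns (defaults to declared
#'   leaf order).
#' @param fallback Fill missing pairs by tree-path summation (default off:
#'   hand-tailored leaf-pair distances are the reference).
#' @return Labelled symmetric matrix with zero diagonal, of class
#'   `modality_dist` (unnormalised).
#' @export
expert_distance_matrix <- function(graph, order = NULL, fallback = FALSE) {
  leaves <- leaf_concepts(graph)
  if (!length(leaves)) abort("graph has no leaf concepts")
  order <- order %||% leaves
  if (!setequal(order, leaves)) abort("`order` must be a permutation of the leaf concepts")
  n <- length(order)
  m <- matrix(0, n, n, dimnames = list(order, order))
  known <- setNames(graph$distances$distance,
                    pair_key(graph$distances$concept_a, graph$distances$concept_b))
  missing_pairs <- character()
  for (p in seq_len(n - 1)) for (q in seq(p + 1, n)) {
    key <- pair_key(order[p], order[q])
    val <- known[key]
    if (is.na(val) && fallback) val <- tree_path_distance(graph, order[p], order[q], known)
    if (is.na(val)) {
      missing_pairs <- c(missing_pairs, sprintf("(%s, %s)", order[p], order[q]))
    } else {
      m[p, q] <- m[q, p] <- unname(val)
    }
  }
  if (length(missing_pairs)) {
    abort(sprintf("no expert distance for leaf pair(s): %s",
                  paste(missing_pairs, collapse = "; ")))
  }
  new_modality_dist(m, variable = NA_character_, normalised = FALSE)
}

# Unique path between two nodes in the is_a forest; sum of expert distances
# over consecutive node pairs, NA if any hop lacks an annotation.
tree_path_distance <- function(graph, a, b, known) {
  parent_of <- setNames(graph$is_a$parent, graph$is_a$child)
  ancestry <- function(x) {
    path <- x
    while (x %in% names(parent_of)) { x <- parent_of[[x]]; path <- c(path, x) }
    path
  }
  pa <- ancestry(a); pb <- ancestry(b)
  common <- intersect(pa, pb)
  if (!length(common)) return(NA_real_)
  top <- common[1]
  path <- c(pa[seq_len(match(top, pa))], rev(pb[seq_len(match(top, pb) - 1)]))
  hops <- known[pair_key(path[-length(path)], path[-1])]
  if (anyNA(hops)) NA_real_ else sum(hops)
}
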