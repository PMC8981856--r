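new_modality_dist <- function(m, variable = NA_character_, normalised = FALSE) {
  structure(m, class = c("modality_dist", "matrix", "array"),
            variable = variable, normalised = normalised)
}

#' @export
print.modality_dist <- function(x, ...) {
  cat(sprintf("<modality_dist%s%s: %d modalities>\n",
              if (is.na(attr(x, "variable"))) "" else paste0(" '", attr(x, "variable"), "'"),
              if (isTRUE(attr(x, "normalised"))) " (normalised)" else "",
              nrow(x)))
  print(plain_matrix(x), ...)
  invisible(x)
}

#' Build the modality distance matrix of one qualitative variable
#'
#' Dispatches on the variable's distance source: an ontology file yields the
#' expert leaf-pair matrix; a colour table yields pairwise L*a*b* colour
#' differences; a geo table yields pairwise great-circle distances; a period
#' table yields pairwise median-year gaps. The result is unnormalised.
#'
#' @param spec One-row spec from [variable_spec()] (qualitative).
#' @param source The loaded source: a [concept_graph()] for
#'   `ontology_file`, or the matching [read_lookup_table()] tibble. When
#'   `NULL`, the source is read from `spec$source_path`.
#' @param modalities Optional subset/order of modality labels; defaults to
#'   every label the source declares.
#' @param delta_e_method Colour difference method, see [delta_e()].
#' @return A `modality_dist` matrix (symmetric, zero diagonal).
#' @export
build_modality_matrix <- function(spec, source = NULL, modalities = NULL,
                                  delta_e_method = "euclidean") {
  if (nrow(as.data.frame(spec)) != 1) abort("`spec` must be a single variable spec row")
  if (spec$kind != "qualitative") {
    abort(sprintf("variable '%s' is quantitative: no modality matrix", spec$name))
  }
  if (is.null(source)) {
    source <- switch(spec$source,
      ontology_file = read_concept_graph(spec$source_path),
      colour_table = read_lookup_table(spec$source_path, "colour"),
      geo_table = read_lookup_table(spec$source_path, "geo"),
      period_table = read_lookup_table(spec$source_path, "period"))
  }
  if (spec$source == "ontology_file") {
    all_mods <- leaf_concepts(source)
  } else {
    all_mods <- source$label
  }
  modalities <- modalities %||% all_mods
  unresolved <- setdiff(modalities, all_mods)
  if (length(unresolved)) {
    abort(sprintf("modalit%s not resolvable in the source of '%s': %s",
                  if (length(unresolved) > 1) "ies" else "y",
                  spec$name, paste(unresolved, collapse = ", ")))
  }
  n <- length(modalities)
  if (spec$source == "ontology_file") {
    m <- expert_distance_matrix(source, order = NULL)
    m <- unclass(m)[modalities, modalities, drop = FALSE]
  } else {
    rows <- source[match(modalities, source$label), , drop = FALSE]
    f <- switch(spec$source,
      colour_table = function(i, j) delta_e(unlist(rows[i, c("L", "a", "b")]),
                                            unlist(rows[j, c("L", "a", "b")]),
                                            method = delta_e_method),
      geo_table = function(i, j) geo_distance(unlist(rows[i, c("lat", "lon")]),
                                              unlist(rows[j, c("lat", "lon")])),
      period_table = function(i, j) period_distance(unlist(rows[i, c("start", "end")]),
                                                    unlist(rows[j, c("start", "end")])))
    m <- matrix(0, n, n, dimnames = list(modalities, modalities))
    if (n > 1) {
      prs <- unordered_pairs(n)
      for (r in seq_len(nrow(prs))) {
        i <- prs[r, 1]; j <- prs[r, 2]
        m[i, j] <- m[j, i] <- f(i, j)
      }
    }
  }
  new_modality_dist(m, variable = spec$name, normalised = FALSE)
}

#' Normalise a modality distance matrix to the 0-100 scale
#'
#' Linear max-scaling: every entry is multiplied by `100 / max(entries)`, so
#' the largest distance becomes exactly 100 and ratios between entries are
#' preserved. An all-zero matrix is returned unchanged and the map is
#' idempotent. Putting every variable on the same scale prevents variables
#' with wide raw ranges (kilometres, years) from out-weighting the others in
#' the individual-level distance.
#'
#' @param m A `modality_dist` (or plain labelled square matrix).
#' @return The normalised `modality_dist`.
#' @export
normalise_matrix <- function(m) {
  variable <- attr(m, "variable") %||% NA_character_
  mm <- plain_matrix(m)
  check_square_labelled(mm, "modality matrix")
  top <- max(mm)
  if (top > 0) mm <- mm * 100 / top
  new_modality_dist(mm, variable = variable, normalised = TRUE)
}

#' Load every qualitative variable's source and build its matrices
#'
#' Convenience used by the pipeline: reads each declared source once,
#' builds the raw modality matrix and its normalised form, and returns the
#' modality sets for dataset validation.
#'
#' @param specs Spec table.
#' @param delta_e_method Colour difference method.
#' @return List with `sources`, `raw`, `normalised` (named by variable) and
#'   `modalities` (named list of label vectors).
#' @export
build_all_modality_matrices <- function(specs, delta_e_method = "euclidean") {
  validate_specs(specs)
  qual <- specs[specs$kind == "qualitative", , drop = FALSE]
  sources <- list(); raw <- list(); normd <- list(); mods <- list()
  for (i in seq_len(nrow(qual))) {
    sp <- qual[i, , drop = FALSE]
    src <- switch(sp$source,
      ontology_file = read_concept_graph(sp$source_path),
      colour_table = read_lookup_table(sp$source_path, "colour"),
      geo_table = read_lookup_table(sp$source_path, "geo"),
      period_table = read_lookup_table(sp$source_path, "period"))
    m <- build_modality_matrix(sp, src, delta_e_method = delta_e_method)
    sources[[sp$name]] <- src
    raw[[sp$name]] <- m
    normd[[sp$name]] <- normalise_matrix(m)
    mods[[sp$name]] <- rownames(m)
  }
  list(sources = sources, raw = raw, normalised = normd, modalities = mods)
}
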