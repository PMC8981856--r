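#' Declare the variables of a trait table
#'
#' A variable specification ties each column of a trait table to its type and
#' to the source its modality distances come from. Qualitative variables name
#' a distance source file (an ontology with expert distances, or a lookup
#' table of colour coordinates, geographic locations or time-period bounds);
#' quantitative variables carry no source. The weight enters the semantic
#' distance as the per-variable weight of the weighted mean.
#'
#' @param name Variable name, matching the trait-table column header.
#' @param kind `"qualitative"` or `"quantitative"`.
#' @param source One of `"ontology_file"`, `"colour_table"`, `"geo_table"`,
#'   `"period_table"` (qualitative) or `"numeric"` (quantitative).
#' @param source_path Path of the distance source file; `NA` for numeric.
#' @param weight Non-negative weight, default 1 (equal weights).
#'
#' @return A one-row tibble; bind rows of these to form a spec table.
#' @export
#' @examples
#' variable_spec("Quantity of prickles", "qualitative", "ontology_file",
#'               system.file("extdata", "prickles_normal.owl", package = "phenodist"))
variable_spec <- function(name, kind = c("qualitative", "quantitative"),
                          source = c("ontology_file", "colour_table",
                                     "geo_table", "period_table", "numeric"),
                          source_path = NA_character_, weight = 1) {
  kind <- match.arg(kind)
  source <- match.arg(source)
  if (!is.numeric(weight) || length(weight) != 1 || is.na(weight) || weight < 0) {
    abort("`weight` must be a single non-negative number")
  }
  if (kind == "quantitative" && source != "numeric") {
    abort(sprintf("quantitative variable '%s' must have source 'numeric'", name))
  }
  if (kind == "qualitative") {
    if (source == "numeric") {
      abort(sprintf("qualitative variable '%s' cannot have source 'numeric'", name))
    }
    if (is.na(source_path) || !nzchar(source_path)) {
      abort(sprintf("qualitative variable '%s' must name a source file", name))
    }
  }
  tibble(name = name, kind = kind, source = source,
         source_path = as.character(source_path), weight = as.numeric(weight))
}

validate_specs <- function(specs) {
  needed <- c("name", "kind", "source", "source_path", "weight")
  if (!all(needed %in% names(specs))) {
    abort(sprintf("spec table must have columns: %s", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(specs$name)) {
    abort(sprintf("duplicated variable names in specs: %s",
                  paste(unique(specs$name[duplicated(specs$name)]), collapse = ", ")))
  }
  if (any(specs$weight < 0 | is.na(specs$weight))) {
    abort("all variable weights must be non-negative")
  }
  bad <- specs$kind == "quantitative" & specs$source != "numeric"
  if (any(bad)) abort(sprintf("quantitative variables must have source 'numeric': %s",
                              paste(specs$name[bad], collapse = ", ")))
  invisible(specs)
}

#' Read a trait table
#'
#' Reads an individuals-by-variables table (CSV or TSV, UTF-8, header row,
#' first column = individual identifier). Empty cells and the literal token
#' `"NA"` become missing values; anything else in a qualitative column must
#' be one of the variable's declared modalities when `modalities` is given.
#'
#' @param path CSV/TSV file path (`.tsv`/`.tab` are read tab-separated).
#' @param specs Variable spec table from [variable_spec()].
#' @param modalities Optional named list of character vectors: the legal
#'   modality set per qualitative variable. When supplied, any other value is
#'   an error naming the individual, variable and value.
#'
#' @return A tibble of class `trait_dataset` with an `id` column followed by
#'   one column per declared variable, and the specs attached as attribute
#'   `"specs"`. Row order is preserved.
#' @export
read_trait_table <- function(path, specs, modalities = NULL) {
  validate_specs(specs)
  if (!file.exists(path)) abort(sprintf("trait table not found: %s", path))
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 1) abort("trait table has no columns")
  names(raw)[1] <- "id"
  unknown <- setdiff(names(raw)[-1], specs$name)
  if (length(unknown)) {
    abort(sprintf("unknown column(s) in trait table: %s", paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(specs$name, names(raw)[-1])
  if (length(missing_cols)) {
    abort(sprintf("trait table lacks declared column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(raw$id)) abort("individual identifiers must not be missing")
  if (anyDuplicated(raw$id)) {
    abort(sprintf("duplicated individual identifier(s): %s",
                  paste(unique(raw$id[duplicated(raw$id)]), collapse = ", ")))
  }
  for (v in specs$name[specs$kind == "quantitative"]) {
    val <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- !is.na(raw[[v]]) & is.na(val)
    if (any(bad)) {
      abort(sprintf("non-numeric value '%s' for quantitative variable '%s' (individual '%s')",
                    raw[[v]][which(bad)[1]], v, raw$id[which(bad)[1]]))
    }
    if (any(!is.finite(val) & !is.na(val))) {
      abort(sprintf("non-finite value for quantitative variable '%s'", v))
    }
    raw[[v]] <- val
  }
  out <- raw[, c("id", specs$name)]
  ds <- new_trait_dataset(out, specs)
  if (!is.null(modalities)) validate_dataset(ds, modalities)
  ds
}

new_trait_dataset <- function(data, specs) {
  structure(as_tibble(data), specs = specs,
            class = c("trait_dataset", class(as_tibble(data))))
}

#' Validate qualitative values against their modality sets
#'
#' @param dataset A `trait_dataset`.
#' @param modalities Named list of legal modality vectors per qualitative
#'   variable.
#' @return The dataset, invisibly; errors name the first offending
#'   individual, variable and value.
#' @export
validate_dataset <- function(dataset, modalities) {
  specs <- dataset_specs(dataset)
  for (v in intersect(names(modalities), specs$name[specs$kind == "qualitative"])) {
    vals <- dataset[[v]]
    bad <- !is.na(vals) & !(vals %in% modalities[[v]])
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("individual '%s': value '%s' for variable '%s' is not a declared modality",
                    dataset$id[i], vals[i], v))
    }
  }
  invisible(dataset)
}

#' Extract the variable specs attached to a trait dataset
#' @param dataset A `trait_dataset`.
#' @return The spec tibble.
#' @export
dataset_specs <- function(dataset) {
  specs <- attr(dataset, "specs")
  if (is.null(specs)) abort("dataset carries no variable specs")
  specs
}

#' Per-individual missing-value counts
#'
#' Number of missing variables per individual, used downstream as the
#' dot-size channel of the scatterplot matrix (more missing = larger dot,
#' flagging a less reliable position).
#'
#' @param dataset A `trait_dataset`.
#' @return A named integer vector, one entry per individual.
#' @export
missing_counts <- function(dataset) {
  specs <- dataset_specs(dataset)
  vals <- as.data.frame(dataset[, specs$name, drop = FALSE])
  setNames(rowSums(is.na(vals)), dataset$id)
}
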