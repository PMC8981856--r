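# Internal helpers shared across modules.

# Deterministic per-stage sub-seed derived from the single pipeline seed.
# Must stay below 2^31 - 1 so it is a valid R integer.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483629)
}

# Square labelled numeric matrix check used by exporters and plotters.
check_square_labelled <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("%s must be a numeric matrix", what))
  }
  if (nrow(m) != ncol(m)) {
    abort(sprintf("%s must be square (got %d x %d)", what, nrow(m), ncol(m)))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("%s must have row and column labels", what))
  }
  invisible(m)
}

# All unordered index pairs of 1..n as a two-column matrix (i < j).
unordered_pairs <- function(n) {
  if (n < 2) return(matrix(integer(), ncol = 2))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Canonical unordered pair key.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Full-precision number formatting so text exports round-trip exactly.
num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
}

`%||%` <- rlang::`%||%`

# Strip S3 class and bespoke attributes, keeping dim/dimnames intact (safe
# for 1 x 1 matrices, unlike `[ , ]`).
plain_matrix <- function(m) {
  a <- unclass(m)
  attributes(a) <- attributes(a)[c("dim", "dimnames")]
  a
}
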