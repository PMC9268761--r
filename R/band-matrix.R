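#' Construct a band matrix
#'
#' A band matrix is the object scored from marker gels: a binary
#' genotype-by-locus presence/absence matrix in which each column is one
#' scored band (locus) amplified by a primer of a dominant marker system
#' (RAPD, ISSR, SCoT, or any user-defined system). Entry 1 means the band is
#' present in that genotype's lane, 0 that it is absent; heterozygotes are
#' indistinguishable from dominant homozygotes, which is why only presence is
#' recorded.
#'
#' Locus identifiers follow the syntax `SYSTEM:PRIMER:index`
#' (e.g. `"RAPD:OPA7:3"`), from which per-locus metadata (primer code and
#' marker system) is parsed when `locus_meta` is not supplied.
#'
#' @param values integer or logical matrix of 0/1 band calls with genotype
#'   row names and locus column names.
#' @param locus_meta optional data frame with columns `locus_id`, `primer`,
#'   `system`, one row per column of `values` (in order). Parsed from the
#'   column names when `NULL`.
#' @return An object of class `band_matrix`: a list with elements `values`
#'   (integer matrix), `genotype_ids`, `locus_ids`, and `locus_meta`.
#' @examples
#' m <- matrix(c(1, 1, 0, 1, 1, 1), nrow = 2,
#'             dimnames = list(c("red", "yellow"),
#'                             c("RAPD:OPA2:1", "RAPD:OPA2:2", "SCoT:SCoT3:1")))
#' bm <- band_matrix(m)
#' bm$locus_meta
#' @export
band_matrix <- function(values, locus_meta = NULL) {
  if (!is.matrix(values))
    abort_format("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_format("band matrix needs genotype row names and locus column names")
  if (is.null(locus_meta))
    locus_meta <- parse_locus_ids(colnames(values))
  obj <- structure(list(values = values,
                        genotype_ids = rownames(values),
                        locus_ids = colnames(values),
                        locus_meta = locus_meta),
                   class = "band_matrix")
  validate_band_matrix(obj)
}

parse_locus_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    abort_format(sprintf(
      "locus id(s) not of the form SYSTEM:PRIMER:index: %s",
      paste(ids[bad], collapse = ", ")))
  data.frame(locus_id = ids,
             primer = vapply(parts, `[`, "", 2L),
             system = vapply(parts, `[`, "", 1L),
             stringsAsFactors = FALSE)
}

validate_band_matrix <- function(x) {
  v <- x$values
  if (anyNA(v) || !all(v %in% c(0L, 1L)))
    abort_format("band matrix entries must all be 0 or 1 with no missing values")
  if (nrow(v) < 2L)
    abort_validation("a band matrix needs at least 2 genotypes")
  if (ncol(v) < 1L)
    abort_validation("a band matrix needs at least 1 locus")
  if (anyDuplicated(rownames(v)))
    abort_format("duplicate genotype ids")
  if (anyDuplicated(colnames(v)))
    abort_format("duplicate locus ids")
  zero <- colSums(v) == 0L
  if (any(zero))
    abort_validation(sprintf(
      "locus %s has no band in any genotype; a scored band must be present in at least one lane",
      paste(colnames(v)[zero], collapse = ", ")))
  m <- x$locus_meta
  if (!identical(m$locus_id, colnames(v)))
    abort_format("locus_meta rows must match matrix columns in order")
  # a primer belongs to exactly one system
  map <- unique(m[, c("primer", "system")])
  if (anyDuplicated(map$primer))
    abort_format("a primer code maps to more than one marker system")
  x
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d genotypes x %d loci (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$locus_meta$system)),
                            as.integer(table(x$locus_meta$system))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$values)
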