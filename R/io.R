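#' Read a band matrix from CSV
#'
#' Expects a header row `genotype,<locus_1>,...,<locus_n>` with locus ids of
#' the form `SYSTEM:PRIMER:index` and 0/1 cells. Genotype and locus order are
#' preserved as in the file.
#'
#' @param path path to a band-matrix CSV file.
#' @return A [band_matrix()].
#' @seealso [write_band_matrix()]
#' @export
read_band_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L || names(df)[1L] != "genotype")
    abort_format("band-matrix CSV must start with a `genotype` column")
  loci <- names(df)[-1L]
  if (anyDuplicated(loci))
    abort_format(sprintf("duplicate locus id(s): %s",
                         paste(unique(loci[duplicated(loci)]), collapse = ", ")))
  if (anyDuplicated(df$genotype))
    abort_format(sprintf("duplicate genotype id(s): %s",
                         paste(unique(df$genotype[duplicated(df$genotype)]),
                               collapse = ", ")))
  cells <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(cells %in% c("0", "1")))
    abort_format("band-matrix cells must be 0 or 1")
  v <- matrix(as.integer(cells), nrow = nrow(df),
              dimnames = list(df$genotype, loci))
  band_matrix(v)
}

#' Write a band matrix to CSV
#'
#' Inverse of [read_band_matrix()]: `write_band_matrix()` then
#' `read_band_matrix()` reproduces the object, and reading then writing
#' reproduces the file byte-for-byte (modulo line endings).
#'
#' @param m a [band_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(m, path) {
  df <- data.frame(genotype = m$genotype_ids, m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a morphological trait table from CSV
#'
#' Long format with columns `genotype,trait,replicate,value`: one measured
#' replicate per row. Replicates must be positive integers and values finite
#' numbers.
#'
#' @param path path to a trait CSV file.
#' @return A `trait_table`: a data frame with the four columns above.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "trait", "replicate", "value")
  if (!identical(names(df), need))
    abort_format(sprintf("trait CSV must have columns %s",
                         paste(need, collapse = ",")))
  trait_table(df)
}

#' Construct a trait table
#'
#' @param df data frame with columns `genotype`, `trait`, `replicate`,
#'   `value`.
#' @return The validated data frame with class `trait_table`.
#' @export
trait_table <- function(df) {
  if (nrow(df) > 0L) {
    rep_num <- suppressWarnings(as.numeric(df$replicate))
    if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != floor(rep_num)))
      abort_format("replicate must be a positive integer")
    val <- suppressWarnings(as.numeric(df$value))
    if (anyNA(val) || any(!is.finite(val)))
      abort_format("trait values must be finite numbers")
    df$replicate <- as.integer(rep_num)
    df$value <- val
  }
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write a trait table to CSV
#'
#' @param t a trait table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(t, path) {
  utils::write.table(as.data.frame(t), path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are parent height minus child height, with leaves at height
#' zero and each internal node at half its merge distance, so the tree is
#' ultrametric: every leaf-to-root path length equals the root height and the
#' path between two leaves equals their cophenetic distance.
#'
#' @param tree a dendrogram from [wpgma()].
#' @param path optional output path; when `NULL` the Newick string is
#'   returned instead of written.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  n <- length(tree$labels)
  node_h <- tree$height / 2   # stored heights are merge distances
  render <- function(id) {
    # id < 0: leaf; id > 0: internal merge
    if (id < 0L) list(txt = tree$labels[-id], h = 0)
    else {
      l <- render(tree$merge[id, 1L])
      r <- render(tree$merge[id, 2L])
      h <- node_h[id]
      list(txt = sprintf("(%s:%s,%s:%s)",
                         l$txt, format_blen(h - l$h),
                         r$txt, format_blen(h - r$h)),
           h = h)
    }
  }
  nwk <- if (n == 1L) sprintf("%s;", tree$labels) else
    paste0(render(n - 1L)$txt, ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Write a Table-1-style marker report
#'
#' Writes the per-primer/per-system locus-classification report produced by
#' [marker_report()] as TSV, and optionally a JSON rendering with the same
#' content plus the fidelity line.
#'
#' @param report data frame from [marker_report()].
#' @param path output TSV path.
#' @param json_path optional JSON output path.
#' @param fidelity optional [fidelity_percent()] result appended to the JSON.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(report, path, json_path = NULL,
                                fidelity = NULL) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  if (!is.null(json_path)) {
    out <- list(report = report)
    if (!is.null(fidelity)) out$fidelity <- unclass(fidelity)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Write a similarity or distance matrix as square CSV
#'
#' @param m square named matrix ([dice_similarity()], [to_distance()], ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(genotype = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
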