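# Binary similarity coefficients on band matrices.
#
# For a genotype pair, a = loci present in both, b = present only in the
# first, c = present only in the second, d = absent in both:
#   Dice            2a / (2a + b + c)     joint absences ignored
#   Jaccard          a / (a + b + c)      joint absences ignored
#   simple matching (a + d) / (a+b+c+d)   joint absences counted as agreement
# Dice >= Jaccard always (2x/(1+x) >= x on [0,1]).

similarity_core <- function(m, method) {
  v <- m$values
  a <- tcrossprod(v)                       # shared presences
  rs <- rowSums(v)
  n_loci <- ncol(v)
  if (method %in% c("dice", "jaccard")) {
    empty <- rs == 0
    if (any(empty))
      abort_validation(sprintf(
        "similarity undefined for genotype(s) with no bands: %s",
        paste(rownames(v)[empty], collapse = ", ")))
  }
  tot <- outer(rs, rs, `+`)                # 2a + b + c
  s <- switch(method,
    dice = 2 * a / tot,
    jaccard = a / (tot - a),
    simple_matching = (a + (n_loci - tot + a)) / n_loci)
  diag(s) <- 1
  structure(s, method = method, class = c("similarity_matrix", "matrix"))
}

#' Dice similarity between genotypes
#'
#' Genetic similarity from binary band data by the Dice coefficient,
#' `2a / (2a + b + c)`: the standard coefficient for dominant markers, where
#' a shared band is evidence of relatedness but a band absent from both
#' genotypes carries no information (dominant scoring cannot distinguish the
#' causes of absence).
#'
#' @param m a [band_matrix()]; every genotype must carry at least one band.
#' @return A symmetric genotype-by-genotype matrix of class
#'   `similarity_matrix` with unit diagonal, values in `[0, 1]` and a
#'   `method` attribute.
#' @examples
#' v <- rbind(red = c(1, 1, 0, 1, 0), yellow = c(1, 0, 1, 1, 0))
#' colnames(v) <- paste0("RAPD:OPA2:", 1:5)
#' dice_similarity(band_matrix(v))["red", "yellow"]  # 2*2/(2*2+1+1) = 2/3
#' @export
dice_similarity <- function(m) similarity_core(m, "dice")

#' @rdname dice_similarity
#' @details `jaccard_similarity()` computes `a / (a + b + c)`;
#'   `simple_matching()` computes `(a + d) / (a + b + c + d)`, which unlike
#'   the other two rewards joint band absence.
#' @export
jaccard_similarity <- function(m) similarity_core(m, "jaccard")

#' @rdname dice_similarity
#' @export
simple_matching <- function(m) similarity_core(m, "simple_matching")

#' Convert a similarity matrix to a distance matrix
#'
#' Elementwise complement `D = 1 - S` with an exactly zero diagonal: the
#' conventional transform for coefficient-derived similarities, preserving
#' the pair ranking that agglomerative clustering consumes.
#'
#' @param s a `similarity_matrix`.
#' @return A symmetric matrix of class `distance_matrix` with zero diagonal.
#' @export
to_distance <- function(s) {
  d <- 1 - unclass(s)
  diag(d) <- 0
  structure(d, method = attr(s, "method"),
            class = c("distance_matrix", "matrix"))
}
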