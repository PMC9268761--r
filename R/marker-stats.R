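#' Classify one locus column
#'
#' A locus (band) is *monomorphic* when present in every genotype,
#' *unique* when present in exactly one, and otherwise *polymorphic*.
#' Unique loci are a subclass of polymorphic loci: wherever counts are
#' tallied, `n_unique <= n_polymorphic` and
#' `n_monomorphic + n_polymorphic = n_total`.
#'
#' @param column binary 0/1 vector of band presence across genotypes
#'   (length >= 2, not all zero).
#' @return One of `"monomorphic"`, `"polymorphic"`, `"unique"`.
#' @examples
#' classify_locus(c(1, 1, 1, 1, 1))  # monomorphic
#' classify_locus(c(0, 1, 0, 0, 0))  # unique
#' @export
classify_locus <- function(column) {
  if (length(column) < 2L)
    abort_validation("a locus column needs at least 2 genotypes")
  if (anyNA(column) || !all(column %in% c(0, 1)))
    abort_format("locus column entries must be 0 or 1")
  s <- sum(column)
  if (s == 0L)
    abort_validation("all-zero locus column: band present in no genotype")
  if (s == length(column)) "monomorphic"
  else if (s == 1L) "unique"
  else "polymorphic"
}

locus_classes <- function(m) {
  vapply(seq_len(ncol(m$values)),
         function(j) classify_locus(m$values[, j]), "")
}

#' Per-primer locus summary
#'
#' Counts total, monomorphic, polymorphic and unique loci for one primer and
#' the polymorphism percentage: 100 * polymorphic / total. The raw percentage
#' is reported alongside the printed (floored-integer) convention used in
#' published marker tables, where e.g. 2 polymorphic of 3 loci prints as 66%.
#'
#' @param m a [band_matrix()].
#' @param primer_code primer whose loci are summarized.
#' @return A one-row data frame with columns `primer`, `system`, `n_total`,
#'   `n_monomorphic`, `n_polymorphic`, `n_unique`, `polymorphism_pct_raw`,
#'   `polymorphism_pct_printed`.
#' @export
primer_summary <- function(m, primer_code) {
  meta <- m$locus_meta
  sel <- meta$primer == primer_code
  if (!any(sel))
    abort_lookup(sprintf("unknown primer: %s", primer_code))
  cls <- vapply(which(sel), function(j) classify_locus(m$values[, j]), "")
  n_total <- length(cls)
  n_mono <- sum(cls == "monomorphic")
  n_uni <- sum(cls == "unique")
  n_poly <- n_total - n_mono          # unique counted inside polymorphic
  raw <- 100 * n_poly / n_total
  data.frame(primer = primer_code,
             system = meta$system[sel][1L],
             n_total = n_total,
             n_monomorphic = n_mono,
             n_polymorphic = n_poly,
             n_unique = n_uni,
             polymorphism_pct_raw = raw,
             polymorphism_pct_printed = floor(raw),
             stringsAsFactors = FALSE)
}

#' Per-system summary across primers
#'
#' Aggregates the per-primer summaries of one marker system (e.g. all RAPD
#' primers): column totals, per-primer count averages, and the average
#' polymorphism percentage. Following the printed-table convention, the
#' polymorphism average is the arithmetic mean of the per-primer *printed*
#' (floored) percentages; it is reported both raw and rounded half-up to two
#' decimals.
#'
#' @param m a [band_matrix()].
#' @param system marker system label (e.g. `"RAPD"`).
#' @return A list of class `system_summary` with the per-primer data frame
#'   and the totals/averages.
#' @export
system_summary <- function(m, system) {
  meta <- m$locus_meta
  primers <- unique(meta$primer[meta$system == system])
  if (length(primers) == 0L)
    abort_lookup(sprintf("unknown marker system: %s", system))
  per <- do.call(rbind, lapply(primers, function(p) primer_summary(m, p)))
  avg_pct <- mean(per$polymorphism_pct_printed)
  structure(list(
    system = system,
    primer_summaries = per,
    n_primers = length(primers),
    n_total = sum(per$n_total),
    n_monomorphic = sum(per$n_monomorphic),
    n_polymorphic = sum(per$n_polymorphic),
    n_unique = sum(per$n_unique),
    avg_total = sum(per$n_total) / length(primers),
    avg_monomorphic = sum(per$n_monomorphic) / length(primers),
    avg_polymorphic = sum(per$n_polymorphic) / length(primers),
    avg_unique = sum(per$n_unique) / length(primers),
    avg_polymorphism_pct = avg_pct,
    avg_polymorphism_pct_printed = round_half_up(avg_pct, 2)
  ), class = "system_summary")
}

#' @export
print.system_summary <- function(x, ...) {
  cat(sprintf("%s: %d primers, %d loci (%d monomorphic, %d polymorphic, %d unique), avg polymorphism %.2f%%\n",
              x$system, x$n_primers, x$n_total, x$n_monomorphic,
              x$n_polymorphic, x$n_unique, x$avg_polymorphism_pct))
  invisible(x)
}

#' RAPD/SCoT percentage fidelity index
#'
#' The fidelity of marker system A relative to system B contrasts their
#' unique-band yield with their total locus yield:
#' `100 * u_a / u_b` minus `100 * l_a / l_b`, where `u` are unique-locus
#' counts and `l` total-locus counts. Each term is rounded half-up to two
#' decimals before subtraction, matching the printed intermediate values of
#' published tables (e.g. counts (4, 5, 15, 38) give 80.00 - 39.47 = 40.53).
#'
#' @param summary_a,summary_b [system_summary()] objects (or lists with
#'   elements `n_unique` and `n_total`) for systems A and B.
#' @return A list of class `fidelity_result` with the counts, both terms
#'   (raw and rounded) and `fidelity_pct`.
#' @export
fidelity_percent <- function(summary_a, summary_b) {
  u_a <- summary_a$n_unique; l_a <- summary_a$n_total
  u_b <- summary_b$n_unique; l_b <- summary_b$n_total
  if (u_b == 0)
    abort_validation("fidelity undefined: reference system has no unique bands")
  if (l_b == 0)
    abort_validation("fidelity undefined: reference system has no loci")
  term_u <- 100 * u_a / u_b
  term_l <- 100 * l_a / l_b
  structure(list(u_a = u_a, u_b = u_b, l_a = l_a, l_b = l_b,
                 term_unique = term_u,
                 term_total = term_l,
                 term_unique_rounded = round_half_up(term_u, 2),
                 term_total_rounded = round_half_up(term_l, 2),
                 fidelity_pct = round_half_up(term_u, 2) - round_half_up(term_l, 2)),
            class = "fidelity_result")
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf("fidelity: %d/%d x 100 - %d/%d x 100 = %.2f - %.2f = %.2f%%\n",
              x$u_a, x$u_b, x$l_a, x$l_b,
              x$term_unique_rounded, x$term_total_rounded, x$fidelity_pct))
  invisible(x)
}

#' Full marker report across all systems
#'
#' One row per primer plus `Average` and `Total` rows per system and a grand
#' `Total` row, in the layout of a published dominant-marker summary table.
#' Count averages in `Average` rows are exact; the polymorphism cell of an
#' `Average` row is the mean of the per-primer printed (floored) percentages.
#'
#' @param m a [band_matrix()].
#' @return A data frame with columns `system`, `primer`, `n_total`,
#'   `n_monomorphic`, `n_polymorphic`, `n_unique`, `polymorphism_pct`.
#'   Per-primer rows carry the printed (floored) percentage; `Average` rows
#'   the mean of those; `Total` rows carry `NA`.
#' @export
marker_report <- function(m) {
  systems <- unique(m$locus_meta$system)
  blocks <- lapply(systems, function(sys) {
    s <- system_summary(m, sys)
    per <- s$primer_summaries
    rbind(
      data.frame(system = sys, primer = per$primer,
                 n_total = as.numeric(per$n_total),
                 n_monomorphic = as.numeric(per$n_monomorphic),
                 n_polymorphic = as.numeric(per$n_polymorphic),
                 n_unique = as.numeric(per$n_unique),
                 polymorphism_pct = as.numeric(per$polymorphism_pct_printed),
                 stringsAsFactors = FALSE),
      data.frame(system = sys, primer = "Average",
                 n_total = s$avg_total, n_monomorphic = s$avg_monomorphic,
                 n_polymorphic = s$avg_polymorphic, n_unique = s$avg_unique,
                 polymorphism_pct = s$avg_polymorphism_pct,
                 stringsAsFactors = FALSE),
      data.frame(system = sys, primer = "Total",
                 n_total = s$n_total, n_monomorphic = s$n_monomorphic,
                 n_polymorphic = s$n_polymorphic, n_unique = s$n_unique,
                 polymorphism_pct = NA_real_, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, blocks)
  cls <- locus_classes(m)
  grand <- data.frame(system = "All", primer = "Total",
                      n_total = length(cls),
                      n_monomorphic = sum(cls == "monomorphic"),
                      n_polymorphic = sum(cls != "monomorphic"),
                      n_unique = sum(cls == "unique"),
                      polymorphism_pct = NA_real_, stringsAsFactors = FALSE)
  rbind(out, grand)
}
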