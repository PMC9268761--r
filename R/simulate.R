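#' Specify a synthetic band matrix
#'
#' A band spec fixes, per primer block, exactly how many loci of each class
#' the generated matrix must contain: `n_monomorphic` all-present columns,
#' `n_unique` single-carrier columns, and `n_polymorphic - n_unique` columns
#' carried by between 2 and n - 1 genotypes. Generation is deterministic
#' given the seed, and classifying the generated matrix recovers the spec's
#' counts exactly — the generator's defining property.
#'
#' @param genotype_ids character vector of at least 2 genotype labels.
#' @param blocks data frame with columns `system`, `primer`, `n_total`,
#'   `n_monomorphic`, `n_polymorphic`, `n_unique`, one row per primer block.
#' @param seed integer seed.
#' @param unique_owner_pool optional subset of `genotype_ids` from which the
#'   carriers of unique bands are drawn (default: all genotypes). Lets a
#'   simulation plant an outlier genotype that hoards private bands.
#' @param carrier_sets optional list of genotype subsets (each of size 2 to
#'   n - 1); when given, the carriers of non-unique polymorphic columns are
#'   drawn from this pool instead of uniformly, which plants group structure
#'   (e.g. pairs of genotypes sharing most of their bands).
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(genotype_ids, blocks, seed = 1L,
                      unique_owner_pool = NULL, carrier_sets = NULL) {
  n <- length(genotype_ids)
  if (n < 2L || anyDuplicated(genotype_ids))
    abort_validation("need at least 2 distinct genotype ids")
  need <- c("system", "primer", "n_total", "n_monomorphic", "n_polymorphic",
            "n_unique")
  if (!all(need %in% names(blocks)))
    abort_format(sprintf("blocks must have columns %s", paste(need, collapse = ", ")))
  with(blocks, {
    if (any(n_monomorphic + n_polymorphic != n_total))
      abort_validation("infeasible block: n_monomorphic + n_polymorphic != n_total")
    if (any(n_unique > n_polymorphic))
      abort_validation("infeasible block: n_unique > n_polymorphic")
    if (any(c(n_total, n_monomorphic, n_polymorphic, n_unique) < 0))
      abort_validation("infeasible block: negative count")
    if (any(n_polymorphic - n_unique > 0) && n < 3L)
      abort_validation("infeasible block: non-unique polymorphic columns need at least 3 genotypes")
  })
  if (!is.null(unique_owner_pool) && !all(unique_owner_pool %in% genotype_ids))
    abort_validation("unique_owner_pool must be a subset of genotype_ids")
  if (!is.null(carrier_sets)) {
    ok <- vapply(carrier_sets, function(s)
      all(s %in% genotype_ids) && length(s) >= 2L && length(s) <= n - 1L, TRUE)
    if (!all(ok))
      abort_validation("carrier_sets entries must be genotype subsets of size 2..n-1")
  }
  structure(list(genotype_ids = genotype_ids, blocks = blocks,
                 seed = as.integer(seed),
                 unique_owner_pool = unique_owner_pool,
                 carrier_sets = carrier_sets),
            class = "band_spec")
}

#' Generate a band matrix from a spec
#'
#' Emits, for each primer block, exactly the specified number of
#' monomorphic (all-ones), unique (single random carrier) and intermediate
#' polymorphic columns (carrier count uniform on 2..n-1, carrier set uniform
#' — or drawn from the spec's `carrier_sets` pool), then shuffles column
#' order within the block. Locus ids are assigned `SYSTEM:PRIMER:i` in final
#' column order. Identical seed and spec give an identical matrix.
#'
#' @param spec a [band_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return A [band_matrix()] whose [primer_summary()] reproduces the spec's
#'   counts exactly.
#' @export
generate_band_matrix <- function(spec, seed = NULL) {
  if (!inherits(spec, "band_spec"))
    abort_argument("spec must be a band_spec")
  g <- spec$genotype_ids
  n <- length(g)
  owners <- if (is.null(spec$unique_owner_pool)) g else spec$unique_owner_pool
  with_seed(if (is.null(seed)) spec$seed else seed, {
    cols <- list(); ids <- character(0)
    for (b in seq_len(nrow(spec$blocks))) {
      blk <- spec$blocks[b, ]
      make <- list()
      for (i in seq_len(blk$n_monomorphic)) make <- c(make, list(rep(1L, n)))
      for (i in seq_len(blk$n_unique)) {
        v <- rep(0L, n)
        v[match(sample(owners, 1L), g)] <- 1L
        make <- c(make, list(v))
      }
      n_mid <- blk$n_polymorphic - blk$n_unique
      for (i in seq_len(n_mid)) {
        v <- rep(0L, n)
        carriers <- if (is.null(spec$carrier_sets)) {
          k <- (2:(n - 1L))[sample.int(n - 2L, 1L)]
          sample(g, k)
        } else {
          spec$carrier_sets[[sample(length(spec$carrier_sets), 1L)]]
        }
        v[match(carriers, g)] <- 1L
        make <- c(make, list(v))
      }
      if (blk$n_total > 0L) {
        make <- make[sample(length(make))]
        cols <- c(cols, make)
        ids <- c(ids, sprintf("%s:%s:%d", blk$system, blk$primer,
                              seq_len(blk$n_total)))
      }
    }
    v <- do.call(cbind, cols)
    dimnames(v) <- list(g, ids)
    band_matrix(v)
  })
}

#' Specify a synthetic morphological trait table
#'
#' Replicate measurements are drawn independently from
#' `Normal(mean, sd)` per (genotype, trait) cell — the simplest noise model
#' consistent with data reported as mean +/- standard error.
#'
#' @param cells data frame with columns `genotype`, `trait`, `mean`, `sd`,
#'   `n` (replicates, >= 2; `sd >= 0`).
#' @param seed integer seed.
#' @return A list of class `morpho_spec`.
#' @export
morpho_spec <- function(cells, seed = 1L) {
  need <- c("genotype", "trait", "mean", "sd", "n")
  if (!all(need %in% names(cells)))
    abort_format(sprintf("cells must have columns %s", paste(need, collapse = ", ")))
  if (any(cells$sd < 0)) abort_validation("sd must be >= 0")
  if (any(cells$n < 2)) abort_validation("each cell needs n >= 2 replicates")
  structure(list(cells = cells, seed = as.integer(seed)),
            class = "morpho_spec")
}

#' Generate a trait table from a spec
#'
#' @param spec a [morpho_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return A `trait_table` with `n` replicate rows per (genotype, trait).
#' @export
generate_trait_table <- function(spec, seed = NULL) {
  if (!inherits(spec, "morpho_spec"))
    abort_argument("spec must be a morpho_spec")
  with_seed(if (is.null(seed)) spec$seed else seed, {
    rows <- lapply(seq_len(nrow(spec$cells)), function(i) {
      cell <- spec$cells[i, ]
      data.frame(genotype = cell$genotype, trait = cell$trait,
                 replicate = seq_len(cell$n),
                 value = stats::rnorm(cell$n, cell$mean, cell$sd),
                 stringsAsFactors = FALSE)
    })
    trait_table(do.call(rbind, rows))
  })
}

#' Five-genotype kalanchoe study fixture
#'
#' A synthetic stand-in for a dominant-marker survey of five kalanchoe
#' (*Kalanchoe blossfeldiana*) flower-colour genotypes (red, yellow, purple,
#' orange, violet) genotyped with four RAPD, four ISSR and four SCoT
#' primers. The band spec's per-primer locus-class counts are the published
#' counts of that survey — 70 loci in total: 15 RAPD (5 monomorphic, 10
#' polymorphic, 4 unique), 17 ISSR (14/3/0) and 38 SCoT (16/22/5) — so the
#' marker-statistics report computed from the generated matrix reproduces
#' the published summary table cell for cell. The band *patterns* behind
#' those counts were never published, so patterns here are random draws
#' consistent with the counts: similarity values and dendrograms computed
#' from the fixture are self-consistent, not historical.
#'
#' The morphological spec embeds the survey's published trait maxima
#' (yellow: 40 cm plant height; orange: 9 inflorescences, 321 flowers,
#' 2.1 cm flower length; violet: 40 petals) and fills the remaining cells
#' with plausible synthetic values chosen to echo the reported significance
#' pattern; 10 replicate plants per genotype, flower-level traits entered as
#' per-plant means of 50 flowers.
#'
#' @param seed integer seed stored in both specs.
#' @return A list with elements `band` (a [band_spec()]) and `morpho`
#'   (a [morpho_spec()]).
#' @export
kalanchoe_fixture <- function(seed = 1L) {
  genotypes <- c("red", "yellow", "purple", "orange", "violet")
  blocks <- data.frame(
    system = rep(c("RAPD", "ISSR", "SCoT"), each = 4L),
    primer = c("OPA2", "OPA7", "OPA9", "OPA10",
               "ISSR-3", "ISSR-5", "ISSR-8", "ISSR-10",
               "SCoT3", "SCoT11", "SCoT13", "SCoT14"),
    n_total       = c(2, 8, 3, 2,  4, 3, 6, 4,  9,  9, 11, 9),
    n_monomorphic = c(1, 2, 1, 1,  4, 3, 4, 3,  3,  5,  4, 4),
    n_polymorphic = c(1, 6, 2, 1,  0, 0, 2, 1,  6,  4,  7, 5),
    n_unique      = c(0, 2, 2, 0,  0, 0, 0, 0,  3,  1,  1, 0),
    stringsAsFactors = FALSE)

  traits <- rbind(
    # plant-level traits: means over 10 plants
    tr("plant_height_cm",    c(28, 40, 27, 36, 26),            3),
    tr("n_inflorescences",   c(4.5, 5, 7, 9, 7.5),             1),
    tr("n_flowers",          c(180, 190, 270, 321, 280),       30),
    # flower-level traits: per-plant means of 50 flowers
    tr("flower_length_cm",   c(1.2, 1.7, 1.25, 2.1, 1.3),      0.1),
    tr("flower_diameter_mm", c(21, 14, 18, 23, 25),            1.5),
    tr("n_petals",           c(4.6, 4.4, 4.8, 5.0, 40),        1))
  traits$genotype <- rep(genotypes, times = 6)

  list(band = band_spec(genotypes, blocks, seed = seed),
       morpho = morpho_spec(traits, seed = seed))
}

# one trait row-block: means in fixture genotype order, common sd, n = 10
tr <- function(trait, means, sd) {
  data.frame(genotype = NA_character_, trait = trait, mean = means,
             sd = sd, n = 10L, stringsAsFactors = FALSE)
}
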