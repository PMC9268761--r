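#' Per-genotype trait summaries
#'
#' Sample mean and standard error (sd with n - 1 denominator over sqrt(n))
#' for every (genotype, trait) group, the quantities behind mean +/- SE bar
#' charts. Groups with a single replicate get `NA` standard error and are
#' flagged in the `se_defined` column.
#'
#' @param t a trait table (see [trait_table()]).
#' @return A data frame `(genotype, trait, n, mean, se, se_defined)`.
#' @export
summarize_traits <- function(t) {
  df <- as.data.frame(t)
  if (nrow(df) == 0L)
    return(data.frame(genotype = character(), trait = character(),
                      n = integer(), mean = numeric(), se = numeric(),
                      se_defined = logical(), stringsAsFactors = FALSE))
  key <- interaction(df$genotype, df$trait, drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(df, key), function(g) {
    n <- nrow(g)
    data.frame(genotype = g$genotype[1L], trait = g$trait[1L], n = n,
               mean = mean(g$value),
               se = if (n >= 2L) stats::sd(g$value) / sqrt(n) else NA_real_,
               se_defined = n >= 2L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Fisher's LSD comparisons and letter display
#'
#' For a single trait, fits a one-way ANOVA across genotypes and declares a
#' pair (i, j) significantly different when
#' `|mean_i - mean_j| > t(1 - alpha/2, df_within) * sqrt(MSE * (1/n_i + 1/n_j))`
#' — Fisher's (unprotected) least significant difference, which uses the
#' pooled within-group mean square as a common error term. The pairwise
#' pattern is summarized as a compact letter display: genotypes share a
#' letter exactly when they are not significantly different.
#'
#' A `pairwise_t` method is available for comparison; it uses each pair's
#' own pooled variance instead of the common MSE.
#'
#' @param t a trait table.
#' @param trait trait to analyse.
#' @param alpha significance level (default 0.05).
#' @param method `"lsd"` (pooled ANOVA error, default) or `"pairwise_t"`.
#' @return An object of class `lsd_result`: a list with the ANOVA table
#'   entries (`F`, `df_between`, `df_within`, `mse`, `p_value`), `alpha`,
#'   the balanced-design `lsd` threshold (`NA` if group sizes differ), the
#'   logical `significant` pair matrix, per-genotype `means` (with n and
#'   SE), and `letters`.
#' @examples
#' tt <- trait_table(data.frame(
#'   genotype = rep(c("A", "B", "C"), each = 3),
#'   trait = "plant_height_cm", replicate = rep(1:3, 3),
#'   value = c(1, 2, 3, 11, 12, 13, 11.5, 12.5, 13.5)))
#' r <- lsd_test(tt, "plant_height_cm")
#' r$letters  # A gets its own letter; B and C share one
#' @export
lsd_test <- function(t, trait, alpha = 0.05, method = c("lsd", "pairwise_t")) {
  method <- match.arg(method)
  df <- as.data.frame(t)
  df <- df[df$trait == trait, , drop = FALSE]
  if (nrow(df) == 0L)
    abort_argument(sprintf("no records for trait %s", trait))
  groups <- split(df$value, df$genotype)
  if (length(groups) < 2L)
    abort_argument("LSD needs at least 2 genotypes")
  if (any(lengths(groups) < 2L))
    abort_argument("every genotype needs at least 2 replicates")
  if (alpha >= 1 || alpha <= 0) {
    if (alpha == 1) warning("alpha = 1 is degenerate: every non-zero difference is 'significant'")
    else abort_argument("alpha must be in (0, 1)")
  }

  fit <- stats::aov(value ~ genotype, data = df)
  # zero residual variance (all groups constant) is legal input here: the
  # F-test is vacuous but the LSD threshold (0) and letters are well defined
  an <- withCallingHandlers(stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mse <- an[["Mean Sq"]][2L]
  df_w <- an[["Df"]][2L]

  g_ids <- names(groups)
  means <- vapply(groups, mean, 0)
  ns <- lengths(groups)
  tc <- stats::qt(1 - alpha / 2, df_w)

  ng <- length(g_ids)
  sig <- matrix(FALSE, ng, ng, dimnames = list(g_ids, g_ids))
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    diffm <- abs(means[i] - means[j])
    thr <- if (method == "lsd") {
      tc * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    } else {
      sp2 <- ((ns[i] - 1) * stats::var(groups[[i]]) +
              (ns[j] - 1) * stats::var(groups[[j]])) / (ns[i] + ns[j] - 2)
      stats::qt(1 - alpha / 2, ns[i] + ns[j] - 2) *
        sqrt(sp2 * (1 / ns[i] + 1 / ns[j]))
    }
    sig[i, j] <- sig[j, i] <- diffm > thr
  }

  letters <- cld_letters(!sig)
  structure(list(
    trait = trait, alpha = alpha, method = method,
    F = an[["F value"]][1L], df_between = an[["Df"]][1L], df_within = df_w,
    mse = mse, p_value = an[["Pr(>F)"]][1L],
    lsd = if (length(unique(ns)) == 1L) unname(tc * sqrt(mse * 2 / ns[1L]))
          else NA_real_,
    significant = sig,
    means = data.frame(genotype = g_ids, n = as.integer(ns), mean = means,
                       se = vapply(groups, function(g)
                         stats::sd(g) / sqrt(length(g)), 0),
                       letters = letters[g_ids],
                       row.names = NULL, stringsAsFactors = FALSE),
    letters = letters), class = "lsd_result")
}

#' @export
print.lsd_result <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.3f, p = %.4g, MSE = %.4g, LSD(%.2g) = %.4g\n",
              x$trait, x$df_between, x$df_within, x$F, x$p_value, x$mse,
              x$alpha, x$lsd))
  print(x$means, ...)
  invisible(x)
}

#' Compact letter display from a non-significance matrix
#'
#' Insert-and-absorb algorithm: start with a single letter covering all
#' groups; for each significantly different pair, split every letter column
#' containing both into two (one without each member), then absorb columns
#' contained in others. Two groups share a letter exactly when their pairwise
#' comparison is non-significant.
#'
#' @param nonsig symmetric logical matrix with dimnames; `TRUE` means the
#'   pair is not significantly different.
#' @param order_by optional numeric vector (e.g. group means) used to assign
#'   letter `a` to the highest-ranked group, as in published figures.
#' @return Named character vector of letter strings, one per group.
#' @export
cld_letters <- function(nonsig, order_by = NULL) {
  ids <- rownames(nonsig)
  cols <- list(ids)                      # letter columns: character vectors
  ng <- length(ids)
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    if (nonsig[i, j]) next
    a <- ids[i]; b <- ids[j]
    hit <- vapply(cols, function(s) a %in% s && b %in% s, TRUE)
    if (!any(hit)) next
    new_cols <- list()
    for (k in seq_along(cols)) {
      if (!hit[k]) { new_cols <- c(new_cols, cols[k]); next }
      new_cols <- c(new_cols, list(setdiff(cols[[k]], a)),
                    list(setdiff(cols[[k]], b)))
    }
    # absorb: drop any column whose members are a subset of another kept
    # column (proper subset, or an exact duplicate appearing later)
    keep <- rep(TRUE, length(new_cols))
    for (k in seq_along(new_cols)) {
      for (l in seq_along(new_cols)) {
        if (k == l || !keep[l]) next
        if (all(new_cols[[k]] %in% new_cols[[l]]) &&
            (length(new_cols[[k]]) < length(new_cols[[l]]) || k > l)) {
          keep[k] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  # letter order: by group appearance by default, or so that the
  # highest-ranked group (e.g. largest mean) gets letter "a"
  if (is.null(order_by)) {
    cols <- cols[order(vapply(cols, function(s) min(match(s, ids)), 0))]
  } else {
    rank_of <- function(s) min(rank(-order_by, ties.method = "first")[match(s, ids)])
    cols <- cols[order(vapply(cols, rank_of, 0))]
  }
  if (length(cols) > length(letters))
    abort_validation("compact letter display needs more than 26 letter columns")
  out <- vapply(ids, function(g) {
    paste(letters[which(vapply(cols, function(s) g %in% s, TRUE))],
          collapse = "")
  }, "")
  names(out) <- ids
  out
}

#' Trait-profile distance between genotypes
#'
#' Builds each genotype's profile of per-trait means, optionally z-scores
#' each trait across genotypes (recommended: traits measured in cm, mm and
#' raw counts otherwise contribute on wildly different scales), and returns
#' the Euclidean distance matrix that feeds the morphological dendrogram.
#'
#' @param s trait summary from [summarize_traits()] (or a trait table, which
#'   is summarized first).
#' @param standardize z-score trait means across genotypes (default `TRUE`).
#'   Constant traits cannot be standardized and are dropped with a warning.
#' @return A symmetric matrix of class `distance_matrix`.
#' @export
morpho_distance <- function(s, standardize = TRUE) {
  if (inherits(s, "trait_table")) s <- summarize_traits(s)
  wide <- stats::xtabs(mean ~ genotype + trait, data = s)
  if (any(is.na(wide)))
    abort_validation("every genotype needs a mean for every trait")
  wide <- matrix(as.numeric(wide), nrow(wide), ncol(wide),
                 dimnames = dimnames(wide))
  miss <- !table(s$genotype, s$trait)
  if (any(miss))
    abort_validation("every genotype needs a mean for every trait")
  if (standardize) {
    sds <- apply(wide, 2L, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping constant trait(s): %s",
                      paste(colnames(wide)[sds == 0], collapse = ", ")))
      wide <- wide[, sds > 0, drop = FALSE]
    }
    wide <- scale(wide)
  }
  d <- as.matrix(stats::dist(wide))
  structure(d, method = "euclidean",
            class = c("distance_matrix", "matrix"))
}
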