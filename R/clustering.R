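#' WPGMA / UPGMA agglomerative clustering
#'
#' Builds a rooted ultrametric dendrogram from a symmetric distance matrix by
#' iteratively merging the closest pair of clusters at height equal to their
#' distance, then replacing the pair by a single node whose distance to every
#' other cluster is the average of the two members' distances. Under WPGMA
#' (the default) that average is the simple mean `(d_ik + d_jk) / 2`,
#' independent of cluster sizes; UPGMA weights by cluster size. Ties in the
#' minimum distance are broken deterministically by the lexicographic order
#' of the candidate pairs' smallest member labels (then the larger's), so
#' identical inputs always give identical trees.
#'
#' The returned object stores heights as merge *distances* in the `hclust`
#' convention; node heights in the ultrametric sense are half that, so the
#' cophenetic distance between two leaves reproduces the distance at which
#' their clusters merged. The result inherits from `hclust` and can be
#' plotted or converted with the usual tools.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   genotype dimnames (a `distance_matrix` from [to_distance()],
#'   [morpho_distance()], a base matrix, or a `dist`).
#' @param method `"wpgma"` (default) or `"upgma"`.
#' @return An object of class `c("band_dendrogram", "hclust")`.
#' @examples
#' d <- matrix(c(0, 2, 6, 10,
#'               2, 0, 6, 10,
#'               6, 6, 0, 8,
#'               10, 10, 8, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' t <- wpgma(d)
#' t$height / 2        # node heights 1, 3, 4.5
#' write_newick(t)     # "(((A:1.0,B:1.0):2.0,C:3.0):1.5,D:4.5);"
#' @export
wpgma <- function(d, method = c("wpgma", "upgma")) {
  method <- match.arg(method)
  if (inherits(d, "dist")) d <- as.matrix(d)
  dmeth <- attr(d, "method")
  d <- unclass(d)
  n <- nrow(d)
  if (is.null(rownames(d))) dimnames(d) <- list(paste0("g", seq_len(n)),
                                                paste0("g", seq_len(n)))
  if (n < 2L)
    abort_argument("clustering needs at least 2 genotypes")
  if (!isTRUE(all.equal(d, t(d))) || any(d < 0) || any(diag(d) != 0))
    abort_validation("input must be a symmetric non-negative matrix with zero diagonal")
  labels <- rownames(d)

  # active clusters: id (hclust convention: -leaf or +merge), members, size,
  # and the lexicographically smallest member label used for tie-breaking
  act_id <- -seq_len(n)
  act_key <- labels
  act_size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(act_id)
    dm <- d; dm[lower.tri(dm, diag = TRUE)] <- Inf
    dmin <- min(dm)
    cand <- which(dm == dmin, arr.ind = TRUE)
    # tie-break: order candidate pairs by (smaller member label, larger's)
    lo <- pmin(act_key[cand[, 1L]], act_key[cand[, 2L]])
    hi <- pmax(act_key[cand[, 1L]], act_key[cand[, 2L]])
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    # left child = cluster whose lexicographically smallest member is smaller,
    # so rendered trees list older/lower-labelled clusters first
    merge[step, ] <- if (act_key[i] <= act_key[j]) c(act_id[i], act_id[j])
                     else c(act_id[j], act_id[i])
    height[step] <- dmin

    others <- setdiff(seq_len(m), c(i, j))
    new_d <- if (method == "wpgma") (d[i, others] + d[j, others]) / 2
             else (act_size[i] * d[i, others] + act_size[j] * d[j, others]) /
                  (act_size[i] + act_size[j])

    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, new_d), c(new_d, 0))
    act_id <- c(act_id[others], step)
    act_key <- c(act_key[others], min(act_key[c(i, j)]))
    act_size <- c(act_size[others], act_size[i] + act_size[j])
  }

  ord <- integer(0)
  walk <- function(id) {
    if (id < 0L) ord <<- c(ord, -id)
    else { walk(merge[id, 1L]); walk(merge[id, 2L]) }
  }
  walk(n - 1L)

  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = method,
                 call = match.call(), dist.method = dmeth),
            class = c("band_dendrogram", "hclust"))
}

# leaf index sets below each internal node
merge_leafsets <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    grab <- function(id) if (id < 0L) -id else sets[[id]]
    sets[[i]] <- c(grab(tree$merge[i, 1L]), grab(tree$merge[i, 2L]))
  }
  sets
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is twice the height of the lowest common ancestor of leaves
#' i and j — i.e. the distance at which their clusters merged. The result is
#' always ultrametric: for any three leaves the two largest pairwise
#' distances are equal.
#'
#' @param tree a dendrogram from [wpgma()].
#' @return A symmetric matrix of class `distance_matrix` with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  n <- length(tree$labels)
  out <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  sets <- merge_leafsets(tree)
  for (i in seq_len(n - 1L)) {
    left <- if (tree$merge[i, 1L] < 0L) -tree$merge[i, 1L] else sets[[tree$merge[i, 1L]]]
    right <- if (tree$merge[i, 2L] < 0L) -tree$merge[i, 2L] else sets[[tree$merge[i, 2L]]]
    out[left, right] <- tree$height[i]
    out[right, left] <- tree$height[i]
  }
  structure(out, class = c("distance_matrix", "matrix"))
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 merges of greatest height (ties resolved by removing
#' later merges first, which for monotone trees is simply the last k - 1
#' merges) and returns the resulting leaf partition. This reproduces the
#' usual reading of a dendrogram into its k top-level groups without having
#' to choose a cut height.
#'
#' @param tree a dendrogram from [wpgma()].
#' @param k number of clusters, between 1 and the number of leaves.
#' @return A data frame `(genotype, cluster)` with clusters numbered by
#'   first appearance in leaf order; carries `k` as an attribute.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n || k != floor(k))
    abort_argument(sprintf("k must be an integer in [1, %d]", n))
  k <- as.integer(k)
  # union-find over the first n - k merges (heights are monotone, so the
  # removed merges are exactly the k - 1 highest, later merges first on ties)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  sets <- merge_leafsets(tree)
  if (n - k >= 1L) for (i in seq_len(n - k)) {
    le <- sets[[i]]
    r <- find(le[1L])
    for (x in le[-1L]) parent[find(x)] <- r
  }
  root <- vapply(seq_len(n), find, 0L)
  cluster <- as.integer(factor(root, levels = unique(root)))
  structure(data.frame(genotype = tree$labels, cluster = cluster,
                       stringsAsFactors = FALSE),
            k = k)
}
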