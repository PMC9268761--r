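# Independent oracles and random-case generators used across test files.
# Each oracle is a deliberately naive, separate code path from the package.

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)

locus_classes_of <- function(m) apply(m$values, 2, classify_locus)

# brute-force (a, b, c, d) contingency tally for one genotype pair
pair_tally <- function(x, y) {
  a <- b <- c <- d <- 0L
  for (k in seq_along(x)) {
    if (x[k] == 1 && y[k] == 1) a <- a + 1L
    else if (x[k] == 1 && y[k] == 0) b <- b + 1L
    else if (x[k] == 0 && y[k] == 1) c <- c + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c, d = d)
}

# straight-line WPGMA: clusters as plain lists, recurrence written longhand;
# returns the cophenetic matrix, which is representation-independent
wpgma_oracle_cophenetic <- function(d) {
  labs <- rownames(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  dd <- d
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA); bestd <- Inf; bestkey <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      key <- sort(c(min(labs[clusters[[i]]]), min(labs[clusters[[j]]])))
      better <- dd[i, j] < bestd ||
        (dd[i, j] == bestd && (key[1] < bestkey[1] ||
                               (key[1] == bestkey[1] && key[2] < bestkey[2])))
      if (better) { best <- c(i, j); bestd <- dd[i, j]; bestkey <- key }
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- bestd; coph[b, a] <- bestd
    }
    newrow <- sapply(seq_len(m), function(k) (dd[i, k] + dd[j, k]) / 2)
    keep <- setdiff(seq_len(m), c(i, j))
    dd2 <- matrix(0, length(keep) + 1, length(keep) + 1)
    for (p in seq_along(keep)) for (q in seq_along(keep))
      dd2[p, q] <- dd[keep[p], keep[q]]
    for (p in seq_along(keep)) {
      dd2[p, length(keep) + 1] <- newrow[keep[p]]
      dd2[length(keep) + 1, p] <- newrow[keep[p]]
    }
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    dd <- dd2
  }
  coph
}

# max over triples of d(i,j) - max(d(i,k), d(j,k)); <= 0 means ultrametric
ultrametric_excess <- function(d) {
  n <- nrow(d)
  worst <- -Inf
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i == j || j == k || i == k) next
    worst <- max(worst, d[i, j] - max(d[i, k], d[j, k]))
  }
  worst
}

random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 10)
  d <- d + t(d)
  dimnames(d) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  d
}

# random band matrix with no all-zero column and no empty genotype row
random_band_values <- function(n_geno, n_loci, p = 0.5) {
  repeat {
    v <- matrix(rbinom(n_geno * n_loci, 1, p), n_geno, n_loci)
    if (all(colSums(v) > 0) && all(rowSums(v) > 0)) break
  }
  dimnames(v) <- list(paste0("g", seq_len(n_geno)),
                      sprintf("RAPD:OPA2:%d", seq_len(n_loci)))
  v
}

# random feasible band spec over >= 3 genotypes
random_band_spec <- function(seed) {
  n_geno <- sample(3:8, 1)
  n_blocks <- sample(1:4, 1)
  blocks <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    n_total <- sample(1:12, 1)
    n_mono <- sample(0:n_total, 1)
    n_poly <- n_total - n_mono
    n_uni <- if (n_poly > 0) sample(0:n_poly, 1) else 0L
    data.frame(system = c("RAPD", "ISSR", "SCoT", "XYZ")[b],
               primer = paste0("P", b), n_total = n_total,
               n_monomorphic = n_mono, n_polymorphic = n_poly,
               n_unique = n_uni, stringsAsFactors = FALSE)
  }))
  # an all-monomorphic spec can be drawn; it is feasible, keep it
  band_spec(paste0("g", seq_len(n_geno)), blocks, seed = seed)
}

# spec with one outlier genotype holding private bands and two tight pairs
# sharing most of theirs; the planted k = 3 partition for recovery tests
planted_spec <- function(seed) {
  band_spec(
    c("red", "yellow", "purple", "orange", "violet"),
    data.frame(system = rep(c("RAPD", "ISSR", "SCoT"), each = 1),
               primer = c("P1", "P2", "P3"),
               n_total = c(10, 10, 10), n_monomorphic = c(2, 2, 2),
               n_polymorphic = c(8, 8, 8), n_unique = c(2, 2, 2),
               stringsAsFactors = FALSE),
    seed = seed,
    unique_owner_pool = "yellow",
    carrier_sets = list(c("orange", "violet"), c("red", "purple")))
}

# partition equality up to cluster relabeling
same_partition <- function(assign_df, reference) {
  got <- split(assign_df$genotype, assign_df$cluster)
  got <- lapply(got, sort)
  ref <- lapply(reference, sort)
  length(got) == length(ref) &&
    setequal(sapply(got, paste, collapse = "|"),
             sapply(ref, paste, collapse = "|"))
}
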