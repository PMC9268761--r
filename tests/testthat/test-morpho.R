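make_tt <- function(values_by_group, trait = "plant_height_cm") {
  rows <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(genotype = g, trait = trait, replicate = seq_along(v),
               value = v, stringsAsFactors = FALSE)
  }))
  trait_table(rows)
}

test_that("trait summaries give exact means and n-1 standard errors", {
  tt <- make_tt(list(A = c(10, 10, 10), B = c(1, 2, 3)))
  s <- summarize_traits(tt)
  sA <- s[s$genotype == "A", ]
  expect_equal(sA$mean, 10)
  expect_equal(sA$se, 0)
  sB <- s[s$genotype == "B", ]
  expect_equal(sB$mean, 2)
  expect_equal(sB$se, 1 / sqrt(3))

  # order invariance
  tt_rev <- trait_table(as.data.frame(tt)[rev(seq_len(nrow(tt))), ])
  expect_equal(summarize_traits(tt_rev), s)

  # single replicate: SE undefined and flagged
  s1 <- summarize_traits(make_tt(list(A = 5, B = c(1, 2))))
  expect_true(is.na(s1$se[s1$genotype == "A"]))
  expect_false(s1$se_defined[s1$genotype == "A"])
})

test_that("the three-group worked example yields letters a/b/b", {
  tt <- make_tt(list(A = c(1, 2, 3), B = c(11, 12, 13),
                     C = c(11.5, 12.5, 13.5)))
  r <- lsd_test(tt, "plant_height_cm", alpha = 0.05)
  expect_equal(r$mse, 1)
  expect_identical(r$df_within, 6L)
  expect_equal(r$lsd, qt(0.975, 6) * sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$lsd, 1.998, tolerance = 1e-3)
  expect_true(r$significant["A", "B"] && r$significant["A", "C"])
  expect_false(r$significant["B", "C"])
  expect_identical(unname(r$letters[c("A", "B", "C")]), c("a", "b", "b"))
})

test_that("degenerate inputs behave as documented", {
  # identical groups: non-significant, one shared letter
  tt <- make_tt(list(A = c(5, 5, 5), B = c(5, 5, 5)))
  r <- lsd_test(tt, "plant_height_cm")
  expect_false(r$significant["A", "B"])
  expect_identical(unname(r$letters), c("a", "a"))

  # alpha = 1: every non-zero difference flagged, with a warning
  tt2 <- make_tt(list(A = c(1, 2), B = c(5, 6)))
  expect_warning(r2 <- lsd_test(tt2, "plant_height_cm", alpha = 1),
                 "degenerate")
  expect_true(r2$significant["A", "B"])

  expect_error(lsd_test(make_tt(list(A = c(1, 2))), "plant_height_cm"),
               class = "markerdiv_argument_error")
  expect_error(lsd_test(make_tt(list(A = 1, B = c(1, 2))), "plant_height_cm"),
               class = "markerdiv_argument_error")
})

test_that("an extreme genotype earns an unshared letter", {
  # one genotype 10 pooled sd above the rest: its letter is private
  fx_cells <- expand.grid(genotype = c("red", "yellow", "purple", "orange",
                                       "violet"),
                          stringsAsFactors = FALSE)
  fx_cells$trait <- "n_petals"
  fx_cells$mean <- c(5, 5, 5, 5, 40)
  fx_cells$sd <- 1
  fx_cells$n <- 10L
  for (s in 1:5) {
    tt <- generate_trait_table(morpho_spec(fx_cells, seed = s))
    r <- lsd_test(tt, "n_petals")
    vio <- strsplit(r$letters[["violet"]], "")[[1]]
    others <- unlist(strsplit(unlist(r$letters[setdiff(names(r$letters),
                                                       "violet")]), ""))
    expect_length(intersect(vio, others), 0)
  }
})

test_that("letter sharing exactly encodes non-significance (reconstruction)", {
  set.seed(404)
  for (rep in 1:200) {
    ng <- sample(3:6, 1)
    ids <- paste0("g", seq_len(ng))
    nonsig <- matrix(TRUE, ng, ng, dimnames = list(ids, ids))
    pairs <- which(upper.tri(nonsig), arr.ind = TRUE)
    flip <- runif(nrow(pairs)) < 0.4
    for (p in which(flip)) {
      nonsig[pairs[p, 1], pairs[p, 2]] <- FALSE
      nonsig[pairs[p, 2], pairs[p, 1]] <- FALSE
    }
    lets <- cld_letters(nonsig)
    share <- outer(seq_len(ng), seq_len(ng), Vectorize(function(i, j) {
      length(intersect(strsplit(lets[i], "")[[1]],
                       strsplit(lets[j], "")[[1]])) > 0
    }))
    diag(share) <- TRUE
    expect_identical(unname(share), unname(nonsig))
    expect_true(all(nchar(lets) > 0))
  }
})

test_that("unprotected LSD familywise error sits in the expected band", {
  # all means equal, 5 groups of 10: P(any significant pair) must exceed the
  # per-test alpha and stay below the Bonferroni-style upper envelope
  set.seed(505)
  n_rep <- 300
  any_sig <- logical(n_rep)
  cells <- data.frame(genotype = paste0("g", 1:5), trait = "t",
                      mean = 0, sd = 1, n = 10L)
  for (i in seq_len(n_rep)) {
    tt <- generate_trait_table(morpho_spec(cells, seed = 7000 + i))
    r <- lsd_test(tt, "t")
    any_sig[i] <- any(r$significant[upper.tri(r$significant)])
  }
  fwer <- mean(any_sig)
  expect_gt(fwer, 0.05)
  expect_lt(fwer, 1 - (1 - 0.05)^10)
})

test_that("morpho distance matches hand-computed z-score geometry", {
  # two genotypes, one trait, no standardization: distance = mean difference
  tt <- make_tt(list(A = c(0, 0), B = c(2, 2)))
  d <- morpho_distance(summarize_traits(tt), standardize = FALSE)
  expect_equal(d["A", "B"], 2)

  # identical profiles at zero distance
  tt2 <- make_tt(list(A = c(3, 3), B = c(3, 3)))
  expect_equal(morpho_distance(summarize_traits(tt2),
                               standardize = FALSE)["A", "B"], 0)

  # 3 genotypes x 2 traits, hand-computed z-scores
  s <- data.frame(genotype = rep(c("A", "B", "C"), 2),
                  trait = rep(c("t1", "t2"), each = 3),
                  n = 2, mean = c(1, 2, 3, 10, 20, 60), se = 0,
                  se_defined = TRUE)
  z1 <- (c(1, 2, 3) - 2) / 1
  z2 <- (c(10, 20, 60) - 30) / sd(c(10, 20, 60))
  d3 <- morpho_distance(s)
  expect_equal(d3["A", "B"],
               sqrt((z1[1] - z1[2])^2 + (z2[1] - z2[2])^2), tolerance = 1e-12)
  expect_equal(d3["A", "C"],
               sqrt((z1[1] - z1[3])^2 + (z2[1] - z2[3])^2), tolerance = 1e-12)

  # standardized distance is invariant to affine rescaling of one trait
  s_resc <- s
  s_resc$mean[s_resc$trait == "t2"] <- s_resc$mean[s_resc$trait == "t2"] * 25.4 + 7
  expect_equal(unclass(morpho_distance(s_resc)), unclass(d3),
               tolerance = 1e-12)

  # constant trait dropped with a warning under standardization
  s_const <- s
  s_const$mean[s_const$trait == "t2"] <- 5
  expect_warning(d_c <- morpho_distance(s_const), "t2")
  expect_equal(d_c["A", "C"], abs(z1[1] - z1[3]), tolerance = 1e-12)
})
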