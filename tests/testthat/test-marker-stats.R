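test_that("locus classification matches column-sum brute force", {
  expect_identical(classify_locus(c(1, 1, 1, 1, 1)), "monomorphic")
  expect_identical(classify_locus(c(0, 1, 0, 0, 0)), "unique")
  expect_identical(classify_locus(c(1, 1, 0, 0, 0)), "polymorphic")
  expect_error(classify_locus(c(0, 0, 0, 0, 0)),
               class = "markerdiv_validation_error")

  set.seed(5)
  for (rep in 1:20) {
    v <- random_band_values(5, 50)
    cls <- apply(v, 2, classify_locus)
    sums <- colSums(v)
    expect_identical(sum(cls == "monomorphic"), sum(sums == 5))
    expect_identical(sum(cls == "unique"), sum(sums == 1))
    expect_identical(sum(cls == "polymorphic"), sum(sums > 1 & sums < 5))
  }
})

test_that("primer summaries use the floored printed-percentage convention", {
  # blocks built to the published per-primer shapes: (8,2,6,2) prints 75,
  # (3,1,2,2) prints floor(200/3) = 66, an all-monomorphic block prints 0
  spec <- band_spec(paste0("g", 1:5), data.frame(
    system = c("RAPD", "RAPD", "ISSR"),
    primer = c("OPA7", "OPA9", "ISSR-3"),
    n_total = c(8, 3, 4), n_monomorphic = c(2, 1, 4),
    n_polymorphic = c(6, 2, 0), n_unique = c(2, 2, 0)), seed = 9)
  m <- generate_band_matrix(spec)

  s7 <- primer_summary(m, "OPA7")
  expect_identical(unname(unlist(s7[c("n_total", "n_monomorphic",
                                      "n_polymorphic", "n_unique")])),
                   c(8L, 2L, 6L, 2L))
  expect_identical(s7$polymorphism_pct_printed, 75)
  s9 <- primer_summary(m, "OPA9")
  expect_identical(s9$polymorphism_pct_printed, 66)
  expect_equal(s9$polymorphism_pct_raw, 200 / 3)
  s3 <- primer_summary(m, "ISSR-3")
  expect_identical(unname(unlist(s3[c("n_total", "n_monomorphic",
                                      "n_polymorphic", "n_unique")])),
                   c(4L, 4L, 0L, 0L))
  expect_identical(s3$polymorphism_pct_printed, 0)

  expect_error(primer_summary(m, "OPZ99"), class = "markerdiv_lookup_error")
})

test_that("system summary totals and averages follow the published layout", {
  # the four RAPD primer shapes of the kalanchoe fixture
  spec <- band_spec(paste0("g", 1:5), data.frame(
    system = "RAPD", primer = c("OPA2", "OPA7", "OPA9", "OPA10"),
    n_total = c(2, 8, 3, 2), n_monomorphic = c(1, 2, 1, 1),
    n_polymorphic = c(1, 6, 2, 1), n_unique = c(0, 2, 2, 0)), seed = 2)
  s <- system_summary(generate_band_matrix(spec), "RAPD")
  expect_identical(s$n_total, 15L)
  expect_identical(s$n_unique, 4L)
  expect_equal(s$avg_total, 3.75)
  expect_equal(s$avg_polymorphism_pct, 60.25)

  # single-primer system: averages collapse to that primer's values
  one <- band_spec(paste0("g", 1:5), data.frame(
    system = "SCoT", primer = "SCoT3", n_total = 9, n_monomorphic = 3,
    n_polymorphic = 6, n_unique = 3), seed = 4)
  s1 <- system_summary(generate_band_matrix(one), "SCoT")
  expect_equal(s1$avg_total, 9)
  expect_equal(s1$avg_polymorphism_pct, 66)

  expect_error(system_summary(generate_band_matrix(one), "AFLP"),
               class = "markerdiv_lookup_error")
})

test_that("summary counts agree with a brute-force column scan", {
  set.seed(31)
  for (rep in 1:20) {
    spec <- random_band_spec(seed = rep)
    m <- generate_band_matrix(spec)
    for (sys in unique(spec$blocks$system)) {
      s <- system_summary(m, sys)
      in_sys <- m$locus_meta$system == sys
      sums <- colSums(m$values[, in_sys, drop = FALSE])
      n <- nrow(m$values)
      expect_identical(s$n_total, sum(in_sys))
      expect_identical(s$n_monomorphic, sum(sums == n))
      expect_identical(s$n_polymorphic, sum(sums < n))
      expect_identical(s$n_unique, sum(sums == 1))
      expect_identical(s$n_monomorphic + s$n_polymorphic, s$n_total)
      expect_true(s$n_unique <= s$n_polymorphic)
    }
  }
})

test_that("polymorphism percentage is invariant under row/column permutation", {
  set.seed(17)
  v <- random_band_values(6, 30)
  m <- band_matrix(v)
  base_pct <- primer_summary(m, "OPA2")$polymorphism_pct_raw
  for (i in 1:5) {
    v2 <- v[sample(nrow(v)), sample(ncol(v))]
    # rebuild ids so column order is the identity again, values permuted
    expect_equal(primer_summary(band_matrix(v2), "OPA2")$polymorphism_pct_raw,
                 base_pct)
  }
})

test_that("fidelity index rounds both terms to 2 decimals before subtracting", {
  a <- list(n_unique = 4, n_total = 15)
  b <- list(n_unique = 5, n_total = 38)
  f <- fidelity_percent(a, b)
  expect_equal(f$term_unique_rounded, 80)
  expect_equal(f$term_total_rounded, 39.47)
  expect_equal(f$fidelity_pct, 40.53)

  expect_equal(fidelity_percent(b, b)$fidelity_pct, 0)

  # exact-rational recomputation of the swapped direction
  g <- fidelity_percent(b, a)
  term_u <- round(500 / 4, 2)          # 125 exactly
  term_l <- floor(100 * 3800 / 15 + 0.5) / 100   # half-up on 253.33..
  expect_equal(g$fidelity_pct, term_u - term_l)

  expect_error(fidelity_percent(a, list(n_unique = 0, n_total = 38)),
               class = "markerdiv_validation_error")
  expect_error(fidelity_percent(a, list(n_unique = 5, n_total = 0)),
               class = "markerdiv_validation_error")
})
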