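test_that("count matrix construction conserves totals and rejects empties", {
  ps <- data.frame(product_id = c("a", "b"), total_f3 = c(9L, 2L),
                   total_f4 = c(1L, 8L))
  cm <- build_counts(ps)
  expect_equal(unname(cm$lib_sizes), c(11, 9))
  expect_equal(rownames(cm$counts), c("a", "b"))
  expect_error(build_counts(ps[0, ]), "empty")
})

test_that("TMM factors are 1 for identical and proportional libraries", {
  set.seed(40)
  a <- rpois(300, 50) + 1
  expect_equal(tmm_factor(a, a), 1, tolerance = 1e-12)
  expect_equal(tmm_factor(a, 2L * a), 1, tolerance = 1e-12)
  f <- tmm_factors(cbind(F3 = a, F4 = 2L * a))
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  expect_equal(prod(f), 1, tolerance = 1e-12)
})

test_that("TMM corrects composition bias within 5% of the direct formula", {
  set.seed(41)
  a <- rpois(400, 80) + 1
  b <- a
  infl <- sample(400, 40)
  b[infl] <- b[infl] * 8L  # 10% of genes inflated in library b
  got <- tmm_factor(a, b)
  want <- tmm_direct(a, b)
  expect_lt(abs(got / want - 1), 0.05)
  # and the bias direction is right: a's proportions of unchanged genes are
  # relatively higher, so the factor exceeds 1
  expect_gt(got, 1)
})

test_that("TMM factors agree with the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  for (rep in 1:5) {
    m <- cbind(rpois(500, exp(rnorm(500, 4, 1))) + 1,
               rpois(500, exp(rnorm(500, 4, 1))) + 1)
    ours <- tmm_factors(m)
    theirs <- edgeR::calcNormFactors(m, method = "TMM")
    expect_lt(abs(ours[1] / ours[2] - theirs[1] / theirs[2]) /
                (theirs[1] / theirs[2]), 0.05)
  }
})

test_that("normalization follows the reads-per-million formula exactly", {
  expect_equal(normalize_counts(500, 1e6, 1), 500)
  expect_equal(normalize_counts(500, 2e6, 1), 250)
  expect_equal(normalize_counts(100, 1e6, 0.8), 125)
  expect_error(normalize_counts(1, 0, 1), "library_size")
})

test_that("the exact binomial test matches enumeration and binom.test", {
  expect_equal(de_test(100, 100, 1e6, 1e6), 1)
  expect_equal(de_test(0, 0, 1e6, 1e6), 1)
  expect_equal(de_test(3, 10, 1e6, 1e6),
               binom_two_sided_enum(3, 13, 0.5), tolerance = 1e-12)
  set.seed(43)
  for (rep in 1:30) {
    k1 <- rpois(1, 40); k2 <- rpois(1, 15)
    s1 <- runif(1, 0.5, 2) * 1e6; s2 <- runif(1, 0.5, 2) * 1e6
    if (k1 + k2 == 0) next
    got <- de_test(k1, k2, s1, s2)
    bt <- stats::binom.test(k1, k1 + k2, s1 / (s1 + s2))$p.value
    expect_equal(got, bt, tolerance = 1e-9)
    expect_gt(got, 0); expect_lte(got, 1)
    # symmetry under swapping libraries with equal sizes
    expect_equal(de_test(k1, k2, s1, s1), de_test(k2, k1, s1, s1),
                 tolerance = 1e-12)
  }
})

test_that("extreme single-library expression is called differential", {
  counts <- matrix(c(0L, 500L, 83244L, 500L), 2, 2,
                   dimnames = list(c("miR21", "flat"), c("F3", "F4")))
  de <- call_de(counts)
  m21 <- de[de$product_id == "miR21", ]
  expect_lt(m21$pvalue, 0.001)
  expect_equal(m21$call, "down")  # absent in F3, huge in F4
})

test_that("DE calls require strictly more than 2-fold and p < 0.001", {
  # equal library sizes; fold exactly 2 stays ns despite a tiny p
  counts <- matrix(c(4000L, 96000L, 2000L, 98000L), 2, 2,
                   dimnames = list(c("x2", "bulk"), c("F3", "F4")))
  de <- call_de(counts, factors = c(1, 1))
  x2 <- de[de$product_id == "x2", ]
  expect_lt(x2$pvalue, 1e-6)
  expect_equal(x2$log2fc, 1, tolerance = 1e-9)
  expect_equal(x2$call, "ns")
  # fold > 2 with insufficient evidence stays ns
  counts2 <- matrix(c(8L, 500L, 1L, 500L), 2, 2,
                    dimnames = list(c("weak", "bulk"), c("F3", "F4")))
  de2 <- call_de(counts2, factors = c(1, 1))
  weak <- de2[de2$product_id == "weak", ]
  expect_gt(abs(weak$log2fc), 1)
  expect_gt(weak$pvalue, 0.001)
  expect_equal(weak$call, "ns")
  # both thresholds passed: a 4.96-fold change with strong evidence is up
  counts3 <- matrix(c(4960L, 95040L, 1000L, 99000L), 2, 2,
                    dimnames = list(c("up1", "bulk"), c("F3", "F4")))
  de3 <- call_de(counts3, factors = c(1, 1))
  up1 <- de3[de3$product_id == "up1", ]
  expect_equal(2^up1$log2fc, 4.96, tolerance = 0.01)
  expect_equal(up1$call, "up")
})

test_that("pseudocounts only apply when a raw count is zero", {
  counts <- matrix(c(10L, 0L, 10L, 20L), 2, 2,
                   dimnames = list(c("pos", "zero"), c("F3", "F4")))
  de <- call_de(counts, factors = c(1, 1))
  pos <- de[de$product_id == "pos", ]
  expect_equal(pos$log2fc, log2(pos$norm_f3 / pos$norm_f4))
  zero <- de[de$product_id == "zero", ]
  expect_true(is.finite(zero$log2fc))
})
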