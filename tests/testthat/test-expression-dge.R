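# exact Audic-Claverie values computed once with arbitrary-precision rational
# arithmetic (Python fractions.Fraction over the closed-form terms) and frozen
AC_EXACT <- list(
  list(x = 0L, y = 0L, r = 1.0, p = 1),
  list(x = 5L, y = 5L, r = 1.0, p = 1),
  list(x = 5L, y = 0L, r = 1.0, p = 0.0625),
  list(x = 0L, y = 5L, r = 1.0, p = 0.125),
  list(x = 3L, y = 17L, r = 1.0, p = 0.005153656005859375),
  list(x = 20L, y = 40L, r = 1.0, p = 0.02697858746238372),
  list(x = 50L, y = 50L, r = 1.0, p = 1),
  list(x = 50L, y = 0L, r = 1.0, p = 1.7763568394002505e-15),
  list(x = 7L, y = 2L, r = 0.5, p = 0.89742417314433776),
  list(x = 2L, y = 7L, r = 0.5, p = 0.024843773814967232),
  list(x = 30L, y = 11L, r = 0.5, p = 0.62546690677941663),
  list(x = 0L, y = 9L, r = 0.5, p = 0.00015241579027587258),
  list(x = 7L, y = 2L, r = 2.0, p = 0.020423715896966926),
  list(x = 13L, y = 42L, r = 2.0, p = 0.48401206532574026),
  list(x = 42L, y = 13L, r = 2.0, p = 2.0768211925284545e-10),
  list(x = 1L, y = 1L, r = 2.0, p = 1),
  list(x = 25L, y = 50L, r = 2.0, p = 1),
  list(x = 50L, y = 25L, r = 0.5, p = 1),
  list(x = 10L, y = 30L, r = 1.0, p = 0.0044428675464587286),
  list(x = 30L, y = 10L, r = 1.0, p = 0.0029009820282226428),
  list(x = 49L, y = 23L, r = 1.0, p = 0.0042363454928012641),
  list(x = 8L, y = 0L, r = 2.0, p = 0.00030483158055174517),
  list(x = 0L, y = 8L, r = 0.5, p = 0.00045724737082761773),
  list(x = 17L, y = 3L, r = 1.0, p = 0.002979278564453125)
)

test_that("TPM normalization follows its algebraic identity", {
  expect_identical(tpm_normalize(5, 1e6), 5)
  expect_identical(tpm_normalize(0, 1e6), 0)
  withr::with_seed(1, counts <- rpois(100, 40))
  clean_total <- 250000
  tpm <- tpm_normalize(counts, clean_total)
  mapped_fraction <- sum(counts) / clean_total
  expect_equal(sum(tpm), 1e6 * mapped_fraction, tolerance = 1e-6)
  expect_error(tpm_normalize(5, 0), "positive")
})

test_that("Audic-Claverie p-values match exact rational anchors", {
  for (cs in AC_EXACT) {
    p <- audic_claverie_p(cs$x, cs$y, 1e6, 1e6 * cs$r)
    expect_equal(p, cs$p, tolerance = 1e-10, label = sprintf("x=%d y=%d r=%g", cs$x, cs$y, cs$r))
  }
  # hand-derived closed form: x=5, y=0, N1=N2 -> lower tail C(5,0)/2^5
  expect_equal(audic_claverie_p(5, 0, 1e5, 1e5), 2 * (1 / 32), tolerance = 1e-12)
  expect_error(audic_claverie_p(-1, 0, 1, 1), "non-negative")
  expect_error(audic_claverie_p(1.5, 0, 1, 1), "non-negative")
  expect_error(audic_claverie_p(1, 1, 0, 1), "positive")
})

test_that("Audic-Claverie agrees with the enumeration oracle over the full grid", {
  # all x, y <= 50 at library-size ratios 0.5, 1, 2
  for (r in c(0.5, 1, 2)) {
    N1 <- 1e6; N2 <- r * 1e6
    grid <- expand.grid(x = 0:50, y = 0:50)
    p_pkg <- audic_claverie_p(grid$x, grid$y, N1, N2)
    p_orc <- mapply(ac_oracle, grid$x, grid$y, N1, N2)
    expect_lt(max(abs(p_pkg - p_orc) / pmax(p_orc, 1e-300)), 1e-10)
  }
})

test_that("large-count p-values stay finite and ordered", {
  p_far <- audic_claverie_p(5000, 50, 1e6, 1e6)
  p_near <- audic_claverie_p(5000, 4900, 1e6, 1e6)
  expect_true(p_far >= 0 && p_far < 1e-100)  # no NaN/overflow in deep libraries
  expect_true(p_near > 0.1)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.3), 0.3)
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(2, p <- runif(200)^2)
  q <- bh_adjust(p)
  expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  # monotone in sorted-p order, invariant under permutation
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(length(p))
  expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
})

make_em <- function(counts, totals) {
  structure(list(counts = counts,
                 tpm = sweep(counts, 2, totals, "/") * 1e6,
                 clean_totals = totals), class = "ExpressionMatrix")
}

test_that("compare_libraries applies the DEG rules", {
  counts <- rbind(
    zero_both = c(0L, 0L),
    planted_up = c(20L, 160L),
    flat = c(100L, 100L),
    absent_then_on = c(0L, 50L)
  )
  colnames(counts) <- c("0h", "6h")
  em <- make_em(counts, c("0h" = 1e6, "6h" = 1e6))
  cc <- compare_libraries(em, "0h", "6h")

  expect_identical(cc[gene_id == "zero_both", status], "ns")
  expect_true(is.na(cc[gene_id == "zero_both", p_value]))
  expect_identical(cc[gene_id == "planted_up", status], "up")
  expect_equal(cc[gene_id == "planted_up", log2_ratio], 3)
  expect_identical(cc[gene_id == "flat", status], "ns")
  expect_equal(cc[gene_id == "flat", p_value], 1)
  # zero-handling: ratio uses one pseudo-tag on the zero side only
  expect_equal(cc[gene_id == "absent_then_on", log2_ratio], log2(50 / 1))
  expect_error(compare_libraries(em, "0h", "0h"), "differ")
})

test_that("comparison strategies generate the stated pair lists", {
  samples <- c("0h", "6h", "12h", "18h", "24h")
  counts <- matrix(5L, nrow = 3, ncol = 5,
                   dimnames = list(c("a", "b", "c"), samples))
  em <- make_em(counts, setNames(rep(1e5, 5), samples))
  sI <- run_strategy(em, "I")
  expect_identical(names(sI), c("0h_vs_6h", "0h_vs_12h", "0h_vs_18h", "0h_vs_24h"))
  sII <- run_strategy(em, "II")
  expect_identical(names(sII), c("0h_vs_6h", "6h_vs_12h", "12h_vs_18h", "18h_vs_24h"))
  # rule generalizes to any number of time points
  em3 <- make_em(counts[, 1:3], setNames(rep(1e5, 3), samples[1:3]))
  sII3 <- run_strategy(em3, "II")
  expect_identical(names(sII3), c("0h_vs_6h", "6h_vs_12h"))
  expect_error(run_strategy(em, "III"), "arg")
})

test_that("overlap_counts enumerates the Venn partition", {
  s <- overlap_counts(list(A = letters[1:7], B = letters[1:7]))
  expect_identical(s[region == "A&B", n], 7L)
  expect_identical(nrow(s), 1L)

  s <- overlap_counts(list(A = c("a", "b"), B = c("c", "d")))
  expect_identical(sort(s$region), c("A", "B"))
  expect_identical(s$n, c(2L, 2L))

  s <- overlap_counts(list(S1 = c("a", "b", "c"), S2 = c("b", "c", "d"), S3 = "c"))
  get <- function(r) s[region == r, n]
  expect_identical(get("S1"), 1L)          # only a
  expect_identical(get("S1&S2"), 1L)       # b
  expect_identical(get("S1&S2&S3"), 1L)    # c
  expect_identical(get("S2"), 1L)          # d
})

test_that("direction tallies report side-specific percentages", {
  counts <- rbind(g1 = c(10L, 100L, 1000L), g2 = c(100L, 10L, 100L),
                  g3 = c(100L, 1000L, 10L))
  colnames(counts) <- c("0h", "6h", "12h")
  em <- make_em(counts, setNames(rep(1e6, 3), colnames(counts)))
  cA <- compare_libraries(em, "0h", "6h")
  cB <- compare_libraries(em, "6h", "12h")
  tl <- direction_tallies(cA, cB)
  expect_identical(tl$n_common, 3L)
  expect_identical(tl$a$up, 2L)
  expect_identical(tl$a$down, 1L)
  expect_equal(tl$a$up_pct, pct(2, 3))
  expect_identical(tl$b$up, 2L)
})
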