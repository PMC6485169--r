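tab <- function(a, b, c, d) contingency_table(a, b, c, d)

test_that("head-to-head counting with ties crediting both sides", {
  t1 <- head_to_head(c(1, 2, 3), c(2, 3, 4), better = "lower")
  expect_equal(unclass(t1)[, ], rbind(c(3L, 0L), c(0L, 3L)),
               ignore_attr = TRUE)
  # one tie among 10 targets, nine other wins for A, two for B
  a <- c(1, 1, 1, 1, 1, 1, 1, 1, 5, 9)
  b <- c(2, 2, 2, 2, 2, 2, 2, 2, 5, 3)
  t2 <- head_to_head(a, b, better = "lower")
  expect_equal(unclass(t2)[, ], rbind(c(9L, 1L), c(2L, 8L)),
               ignore_attr = TRUE)
  # identical lists: every target a success for both
  t3 <- head_to_head(1:5, 1:5)
  expect_equal(unclass(t3)[, ], rbind(c(5L, 0L), c(5L, 0L)),
               ignore_attr = TRUE)
  # higher-is-better flips the comparison
  t4 <- head_to_head(c(0.9, 0.2), c(0.5, 0.4), better = "higher")
  expect_equal(unclass(t4)[, ], rbind(c(1L, 1L), c(1L, 1L)),
               ignore_attr = TRUE)
  expect_error(head_to_head(1:3, 1:4), "length")
  expect_error(contingency_table(3, 2, 1, 1), "equal totals")
  expect_error(contingency_table(-1, 6, 2, 3), "non-negative")
})

test_that("one-sided Fisher reproduces printed CASP values exactly", {
  expect_equal(fisher_one_sided(tab(8, 2, 2, 8)), 2126 / 184756,
               tolerance = 1e-12)
  expect_equal(round(fisher_one_sided(tab(7, 3, 3, 7)), 5), 0.08945)
  expect_equal(round(fisher_one_sided(tab(8, 2, 2, 8)), 5), 0.01151)
  expect_equal(round(fisher_one_sided(tab(6, 4, 4, 6)), 4), 0.3281)
  expect_equal(round(fisher_one_sided(tab(5, 5, 5, 5)), 4), 0.6719)
  expect_equal(round(fisher_one_sided(tab(6, 4, 5, 5)), 1), 0.5)
  expect_equal(round(fisher_one_sided(tab(9, 1, 2, 8)), 6), 0.002739)
  expect_equal(fisher_one_sided(tab(0, 10, 10, 0)), 1)  # P(X >= 0)
})

test_that("one-sided Fisher reproduces printed benchmark values", {
  expect_equal(round(fisher_one_sided(tab(14, 6, 6, 14)), 5), 0.01282)
  expect_equal(round(fisher_one_sided(tab(9, 11, 3, 17)), 5), 0.04118)
  expect_equal(round(fisher_one_sided(tab(9, 11, 1, 19)), 6), 0.004181)
  expect_equal(round(fisher_one_sided(tab(9, 11, 4, 16)), 3), 0.088)
  expect_equal(round(fisher_one_sided(tab(16, 4, 4, 16)), 5), 0.00018)
  expect_equal(round(fisher_one_sided(tab(10, 10, 1, 19)), 6), 0.001671)
  expect_equal(round(fisher_one_sided(tab(10, 10, 2, 18)), 6), 0.006907)
  expect_equal(round(fisher_one_sided(tab(15, 5, 5, 15)), 6), 0.001924)
  expect_equal(round(fisher_one_sided(tab(11, 9, 9, 11)), 4), 0.3762)
  expect_equal(round(fisher_one_sided(tab(12, 8, 8, 12)), 4), 0.1715)
})

test_that("one-sided Fisher agrees with the conditional-test reference", {
  set.seed(301)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    a <- sample(0:n, 1); c_ <- sample(0:n, 1)
    mine <- fisher_one_sided(tab(a, n - a, c_, n - c_))
    ref <- stats::fisher.test(rbind(c(a, n - a), c(c_, n - c_)),
                              alternative = "greater")$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("two-sided Fisher is the doubling of the one-sided value", {
  expect_equal(round(fisher_two_sided(tab(9, 11, 1, 19)), 6), 0.008362)
  expect_equal(fisher_two_sided(tab(5, 5, 5, 5)), 1)  # clamped at 1
  set.seed(311)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    a <- sample(0:n, 1)
    c_ <- sample(0:n, 1)
    t0 <- tab(a, n - a, c_, n - c_)
    expect_equal(fisher_two_sided(t0), min(1, 2 * fisher_one_sided(t0)))
  }
  # every printed two-sided benchmark value is the doubling of the
  # one-sided test on the same win/loss counts
  counts <- list(c(9, 11, 3, 17), c(9, 11, 4, 16), c(9, 11, 3, 17),
                 c(9, 11, 1, 19), c(14, 6, 6, 14), c(11, 9, 9, 11),
                 c(12, 8, 8, 12), c(16, 4, 4, 16), c(10, 10, 1, 19),
                 c(10, 10, 2, 18), c(10, 10, 1, 19), c(10, 10, 9, 11),
                 c(15, 5, 5, 15), c(14, 6, 6, 14), c(15, 5, 5, 15),
                 c(11, 9, 9, 11))
  two <- c(0.08236, 0.1760, 0.08236, 0.008362, 0.02564, 0.7524, 0.3431,
           0.00036, 0.003342, 0.01381, 0.003342, 1, 0.003848, 0.02564,
           0.003848, 0.7524)
  for (i in seq_along(counts)) {
    p2 <- fisher_two_sided(do.call(tab, as.list(counts[[i]])))
    expect_lt(abs(p2 - two[i]) / two[i], 1e-3)
  }
})

test_that("hypergeometric tail complementarity holds", {
  set.seed(321)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- sample(0:n, 1); c_ <- sample(0:n, 1)
    t1 <- tab(a, n - a, c_, n - c_)
    upper <- fisher_one_sided(t1)
    # mirrored alternative: swap the rows
    t2 <- tab(c_, n - c_, a, n - a)
    lower_ge <- fisher_one_sided(t2)  # P(X' >= c) = P(X <= a) by symmetry
    point <- stats::dhyper(a, a + c_, 2 * n - a - c_, n)
    expect_equal(upper + lower_ge - point, 1, tolerance = 1e-12)
  }
})

test_that("Barnard p-values reproduce the printed calibration values", {
  expect_lt(abs(barnard_one_sided(tab(6, 4, 5, 5)) - 0.4119), 5e-4)
  expect_lt(abs(barnard_one_sided(tab(5, 5, 5, 5)) - 0.9991), 5e-4)
  expect_lt(abs(barnard_one_sided(tab(7, 3, 3, 7)) - 0.05789), 5e-5)
  expect_lt(abs(barnard_one_sided(tab(8, 2, 2, 8)) - 0.005909), 5e-6)
  expect_lt(abs(barnard_one_sided(tab(6, 4, 4, 6)) - 0.2617), 5e-4)
  expect_lt(abs(barnard_one_sided(tab(9, 1, 2, 8)) - 0.001288), 5e-6)
  # benchmark-dataset (n = 20) Barnard values
  expect_lt(abs(barnard_one_sided(tab(9, 11, 3, 17)) - 0.02489), 5e-5)
  expect_lt(abs(barnard_one_sided(tab(14, 6, 6, 14)) - 0.008299), 5e-6)
  expect_lt(abs(barnard_one_sided(tab(9, 11, 1, 19)) - 0.001879), 5e-6)
})

test_that("Barnard maximizes over the nuisance probability", {
  t1 <- tab(10, 0, 0, 10)
  p <- barnard_one_sided(t1)
  expect_lte(p, fisher_one_sided(t1))
  # evaluating the tail at any single pi never exceeds the reported max
  n1 <- 10; n2 <- 10
  t_ <- evodiverse:::wald_pooled(n1, n2)
  t_obs <- t_[11, 1]
  sel <- which(t_ >= t_obs - 1e-7 * max(1, abs(t_obs)), arr.ind = TRUE)
  for (pi in c(0.05, 0.2, 0.5, 0.8, 0.95)) {
    v <- sum(stats::dbinom(sel[, 1] - 1, n1, pi) *
             stats::dbinom(sel[, 2] - 1, n2, pi))
    expect_lte(v, p + 1e-12)
  }
})

test_that("both tests are invariant to swapping rows with the labels", {
  # swapping the two rows while also relabeling success <-> failure
  # ([[a,b],[c,d]] -> [[d,c],[b,a]]) states the same one-sided hypothesis,
  # so every p-value must be unchanged
  set.seed(331)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    a <- sample(0:n, 1); c_ <- sample(0:n, 1)
    t1 <- tab(a, n - a, c_, n - c_)
    t2 <- tab(n - c_, c_, n - a, a)
    expect_equal(fisher_one_sided(t1), fisher_one_sided(t2),
                 tolerance = 1e-12)
    expect_equal(fisher_two_sided(t1), fisher_two_sided(t2),
                 tolerance = 1e-12)
    expect_equal(barnard_one_sided(t1), barnard_one_sided(t2),
                 tolerance = 1e-6)
  }
})
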