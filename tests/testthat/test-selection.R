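test_that("strong dominance requires strictly lower everywhere", {
  expect_true(dominates(c(1, 1, 1), c(2, 2, 2)))
  expect_false(dominates(c(1, 2, 3), c(1, 3, 4)))  # equality breaks it
  expect_false(dominates(c(1, 3), c(3, 1)))
  expect_false(dominates(c(3, 1), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("Pareto rank and count on chains and ties", {
  chain <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(pareto_rank(chain), c(0, 1, 2))
  expect_equal(pareto_count(chain), c(2, 1, 0))
  same <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(pareto_rank(same), c(0, 0, 0))
  expect_equal(pareto_count(same), c(0, 0, 0))
})

test_that("sum of ranks equals sum of counts on random sets", {
  set.seed(111)
  for (i in 1:20) {
    obj <- matrix(sample(1:8, 45, TRUE), ncol = 3)
    expect_equal(sum(pareto_rank(obj)), sum(pareto_count(obj)))
    br <- brute_pr_pc(obj)
    expect_equal(pareto_rank(obj), br$PR, ignore_attr = TRUE)
    expect_equal(pareto_count(obj), br$PC, ignore_attr = TRUE)
  }
})

test_that("non-dominated sorting reproduces the printed example", {
  obj <- rbind(c(1, 1), c(1, 2), c(2, 2))
  fs <- fast_nondominated_sort(obj, 3)
  # under strong dominance (1,2) is non-dominated ((1,1) shares the 1)
  expect_equal(fs$fronts[[1]], c(1, 2))
  expect_equal(fs$fronts[[2]], 3)
  allsame <- matrix(5, 4, 3)
  fs2 <- fast_nondominated_sort(allsame, 4)
  expect_equal(length(fs2$fronts), 1)
  expect_equal(fs2$fronts[[1]], 1:4)
})

test_that("front generation stops once N is covered", {
  obj <- cbind(1:10)  # strict chain: ten singleton fronts
  fs <- fast_nondominated_sort(obj, 4)
  expect_equal(length(fs$fronts), 4)
  expect_equal(unlist(fs$fronts), 1:4)
})

test_that("sorting agrees with the peeling oracle on random instances", {
  set.seed(121)
  for (i in 1:60) {
    n <- sample(4:64, 1)
    m <- sample(2:3, 1)
    obj <- matrix(sample(1:10, n * m, TRUE) + stats::runif(n * m, 0, 0.01),
                  ncol = m)
    N <- sample(seq_len(n), 1)
    got <- fast_nondominated_sort(obj, N)$fronts
    want <- peel_fronts(obj, N)
    expect_equal(length(got), length(want))
    for (k in seq_along(want)) expect_equal(sort(got[[k]]), sort(want[[k]]))
  }
  # 200-point instance as a deeper spot check
  set.seed(122)
  obj <- matrix(stats::rnorm(600), ncol = 3)
  got <- fast_nondominated_sort(obj, 200)$fronts
  want <- peel_fronts(obj, 200)
  for (k in seq_along(want)) expect_equal(sort(got[[k]]), sort(want[[k]]))
})

test_that("crowding distance: boundaries infinite, interior normalized gaps", {
  expect_equal(crowding_distance(cbind(c(3))), Inf)
  expect_equal(crowding_distance(cbind(c(3, 9))), c(Inf, Inf))
  d <- crowding_distance(cbind(c(0, 5, 10)))
  expect_equal(d, c(Inf, 1, Inf))
  # degenerate objective contributes nothing to interior members
  d2 <- crowding_distance(cbind(c(0, 5, 10), c(7, 7, 7)))
  expect_equal(d2, c(Inf, 1, Inf))
  set.seed(131)
  obj <- matrix(stats::runif(60), 20, 3)
  expect_equal(crowding_distance(obj), brute_crowding(obj))
})

test_that("survival selectors match their brute-force reimplementations", {
  set.seed(141)
  for (i in 1:40) {
    n <- 2 * sample(3:32, 1)
    m <- sample(2:3, 1)
    obj <- matrix(sample(1:9, n * m, TRUE) + stats::runif(n * m, 0, 1e-3),
                  ncol = m)
    N <- n / 2
    for (meth in c("evo_diverse", "mea", "mea_pr", "mea_prpc")) {
      got <- evodiverse:::select_indices(obj, N, meth)
      want <- brute_select(obj, N, meth)
      expect_equal(got, want, info = meth)
    }
  }
})

test_that("selector edge cases follow the printed rules", {
  # all 2N mutually non-dominated with distinct crowding: highest crowding win
  obj <- cbind(1:8, 8:1)  # one big front
  sel <- evodiverse:::select_indices(obj, 4, "evo_diverse")
  cd <- crowding_distance(obj)
  expect_equal(sort(sel), sort(order(-cd)[1:4]))
  # |F1| = N: output is exactly F1
  obj2 <- rbind(cbind(1:4, 4:1), cbind(11:14, 14:11))
  sel2 <- evodiverse:::select_indices(obj2, 4, "evo_diverse")
  expect_equal(sort(sel2), 1:4)
  # mea keeps the N lowest totals with stable ties
  obj3 <- cbind(c(5, 1, 5, 0), c(0, 0, 0, 0))
  expect_equal(evodiverse:::select_indices(obj3, 3, "mea"), c(4, 2, 1))
  # distinct PRs dominate the ordering regardless of totals
  obj4 <- rbind(c(10, 10), c(1, 1), c(0.5, 2))  # 2 dominates 1; 3 vs 1 too
  sel4 <- evodiverse:::select_indices(obj4, 2, "mea_pr")
  expect_equal(sort(sel4), c(2, 3))
  # PR tie broken by higher PC first
  obj5 <- rbind(c(1, 1), c(2, 0.5), c(3, 3), c(2.5, 4), c(4, 5))
  pr <- pareto_rank(obj5)
  pc <- pareto_count(obj5)
  sel5 <- evodiverse:::select_indices(obj5, 3, "mea_prpc")
  expect_equal(sel5, order(pr, -pc, rowSums(obj5))[1:3])
})

test_that("front elitism and output size hold for population selection", {
  set.seed(151)
  for (i in 1:20) {
    N <- sample(4:16, 1)
    obj <- matrix(stats::rnorm(2 * N * 3), ncol = 3)
    out <- select_evo_diverse(obj[1:N, ], obj[(N + 1):(2 * N), ], N)
    sel <- attr(out, "selected")
    expect_equal(length(sel), N)
    expect_true(all(sel %in% seq_len(2 * N)))
    F1 <- fast_nondominated_sort(obj, 2 * N)$fronts[[1]]
    if (length(F1) <= N) expect_true(all(F1 %in% sel))
  }
})

test_that("record-list populations are selected like matrices", {
  set.seed(161)
  recs <- lapply(1:6, function(i) {
    ob <- stats::rnorm(3)
    list(objectives = ob, total = sum(ob), id = i)
  })
  out <- select_mea(recs[1:3], recs[4:6], 3)
  expect_equal(length(out), 3)
  totals <- vapply(recs, `[[`, numeric(1), "total")
  expect_equal(vapply(out, `[[`, numeric(1), "id"), order(totals)[1:3])
})
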