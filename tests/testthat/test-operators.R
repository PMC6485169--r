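test_that("Metropolis criterion honors its limits", {
  expect_true(metropolis_accept(-1, 0))
  expect_false(metropolis_accept(1, 0))   # alpha 0: uphill probability 0
  expect_true(metropolis_accept(0, 0))    # flat moves pass at any alpha
  expect_true(metropolis_accept(0, 2))
  expect_error(metropolis_accept(Inf, 1), "finite")
  expect_error(metropolis_accept(1, -1), "non-negative")
})

test_that("uphill acceptance rate matches exp(-dE/alpha)", {
  set.seed(101)
  acc <- sum(vapply(1:1e5, function(i) metropolis_accept(1, 2), logical(1)))
  expect_lt(abs(acc / 1e5 - exp(-0.5)), 0.01)
})

make_setup <- function(l = 14, seed = 1, n_per_pos = 20) {
  set.seed(seed)
  tt <- make_toy_native("helix", l)
  list(tt = tt,
       lib9 = make_synthetic_library(tt$native, 9, n_per_pos),
       lib3 = make_synthetic_library(tt$native, 3, n_per_pos))
}

test_that("init_population is reproducible and randomized away from extended", {
  su <- make_setup()
  m <- score_model()
  set.seed(7)
  p1 <- init_population(su$tt$sequence, 2, su$lib9, m)
  set.seed(7)
  p2 <- init_population(su$tt$sequence, 2, su$lib9, score_model())
  expect_equal(length(p1), 2)
  expect_identical(p1[[1]]$dihedrals, p2[[1]]$dihedrals)
  expect_identical(p1[[2]]$coords, p2[[2]]$coords)
  ext <- build_extended(su$tt$sequence)
  for (conf in p1)
    expect_false(isTRUE(all.equal(conf$dihedrals, ext$dihedrals)))
  expect_error(init_population("ALAGSVIE", 2, su$lib3, m), "9")
})

test_that("stage-1 search never accepts a steric-increasing move", {
  su <- make_setup(seed = 3)
  m <- score_model()
  ext <- build_extended(su$tt$sequence)
  # drive the stage-1 loop directly and track the accepted-score sequence
  set.seed(5)
  cur <- ext$dihedrals
  cur_s <- evodiverse:::.cpp_stage_score(cur, 0L, m$params,
                                         unclass(ext$geometry))
  for (i in 1:60) {
    res <- evodiverse:::.cpp_mmc_stage(cur, su$lib9$entries, 9L, 0L, 0,
                                       1L, -1L, m$params,
                                       unclass(ext$geometry), 1e9)
    s <- evodiverse:::.cpp_stage_score(res$dihedrals, 0L, m$params,
                                       unclass(ext$geometry))
    expect_lte(s, cur_s + 1e-12)
    cur <- res$dihedrals
    cur_s <- s
  }
})

test_that("variation applies exactly one unconditional f = 3 move", {
  su <- make_setup(seed = 9)
  # start from the native so moves can genuinely worsen the score
  parent <- su$tt$native
  before <- parent$dihedrals
  set.seed(11)
  worse_seen <- FALSE
  m <- score_model()
  ps <- score3(parent, m)
  for (i in 1:30) {
    child <- variation(parent, su$lib3)
    expect_identical(parent$dihedrals, before)  # parent untouched
    expect_lte(sum(child$dihedrals != parent$dihedrals), 9)
    if (score3(child, m) > ps) worse_seen <- TRUE
  }
  expect_true(worse_seen)  # no Metropolis filter: worse offspring returned
  # identity library: offspring equals parent
  idlib <- identity_library(parent, 3)
  same <- variation(parent, idlib)
  expect_equal(same$dihedrals, parent$dihedrals)
})

test_that("improvement is greedy, monotone and budget-aware", {
  su <- make_setup(seed = 13)
  m <- score_model()
  set.seed(17)
  start <- variation(build_extended(su$tt$sequence), su$lib3)
  # k = 0 returns the input having spent only the initial scoring call
  n0 <- evaluations(m)
  out0 <- improvement(start, su$lib3, m, k = 0)
  expect_equal(out0$dihedrals, start$dihedrals)
  expect_equal(evaluations(m) - n0, 1)
  # identity-only library: unchanged after exactly k failed proposals
  idlib <- identity_library(start, 3)
  n1 <- evaluations(m)
  outi <- improvement(start, idlib, m, k = 5)
  expect_equal(outi$dihedrals, start$dihedrals)
  expect_equal(evaluations(m) - n1, 6)  # initial score + 5 failures
  # accepted-score trace is strictly decreasing
  set.seed(19)
  out <- improvement(start, su$lib3, m, k = 20)
  tr <- attr(out, "trace")
  expect_true(all(diff(tr) < 0))
  expect_lte(score3(out, score_model()), score3(start, score_model()))
})

test_that("improvement never raises score3 across 100 seeded runs", {
  su <- make_setup(l = 12, seed = 23, n_per_pos = 10)
  m <- score_model()
  fresh <- score_model()
  set.seed(29)
  for (i in 1:100) {
    start <- variation(build_extended(su$tt$sequence), su$lib3)
    out <- improvement(start, su$lib3, m, k = 8)
    expect_lte(score3(out, fresh), score3(start, fresh) + 1e-12)
  }
})

test_that("init -> variation -> improvement is reproducible under a seed", {
  su <- make_setup(seed = 31)
  go <- function() {
    m <- score_model()
    set.seed(37)
    pop <- init_population(su$tt$sequence, 2, su$lib9, m)
    child <- variation(pop[[1]], su$lib3)
    out <- improvement(child, su$lib3, m, k = 10)
    list(d = out$dihedrals, n = evaluations(m))
  }
  a <- go()
  b <- go()
  expect_identical(a$d, b$d)
  expect_identical(a$n, b$n)
})
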