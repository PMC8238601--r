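test_that("greedy selection reproduces the worked minimal cover", {
  sets <- list(c1 = c("p1", "p2", "p3"), c2 = c("p3", "p4"), c3 = "p4")
  sel <- tcc_select(sets, paste0("p", 1:4))
  expect_equal(sel$order, c("c1", "c2"))
  expect_equal(sel$cumulative_coverage, c(0.75, 1))
  # exhaustive confirmation that {c1, c2} is the unique minimal cover
  expect_equal(oracle_best_coverage(sets, paste0("p", 1:4)), c(3L, 4L, 4L))

  one <- tcc_select(list(only = c("p1", "p2")), c("p1", "p2"))
  expect_equal(one$order, "only")
  expect_equal(one$cumulative_coverage, 1)

  singles <- tcc_select(list(b = "p2", a = "p1", c = "p3"), paste0("p", 1:3))
  expect_equal(singles$order, c("a", "b", "c"))  # equal gain: id tie-break
  expect_equal(singles$cumulative_coverage, c(1, 2, 3) / 3)
})

test_that("ties break by effective-target total then id, deterministically", {
  sets <- list(small = c("p1", "p2"), big = c("p1", "p2", "p3"))
  sel <- tcc_select(sets, c("p1", "p2"))
  # p3 lies outside the universe, so effective totals tie and the id decides
  expect_equal(sel$order[1], "big")
  sets2 <- list(zz = c("p1", "p2", "p3"), aa = c("p1", "p2"))
  sel2 <- tcc_select(sets2, paste0("p", 1:3))
  expect_equal(sel2$order[1], "zz")       # larger effective total wins
  sel3 <- tcc_select(list(zz = c("p1", "p2"), aa = c("p1", "p2")),
                     c("p1", "p2"))
  expect_equal(sel3$order, "aa")          # equal totals: lexicographic id
  expect_identical(sel3$order,
                   tcc_select(list(aa = c("p1", "p2"), zz = c("p1", "p2")),
                              c("p1", "p2"))$order)
})

test_that("zero-marginal-gain components are never selected", {
  sets <- list(c1 = c("p1", "p2"), dup = c("p1", "p2"), off = "q9")
  sel <- tcc_select(sets, c("p1", "p2"))
  expect_equal(sel$order, "c1")
  expect_false(any(c("dup", "off") %in% sel$order))
})

test_that("empty inputs follow the contract", {
  expect_error(tcc_select(list(c1 = "p1"), character()), "empty")
  sel <- tcc_select(list(), c("p1"))
  expect_length(sel$order, 0L)
  expect_equal(nrow(coverage_curve(sel)), 0L)
})

test_that("coverage curve reports marginals and two-decimal percentages", {
  sel <- tcc_select(list(c1 = c("p1", "p2", "p3"), c2 = c("p3", "p4"),
                         c3 = "p4"), paste0("p", 1:4))
  cc <- coverage_curve(sel)
  expect_equal(cc$rank, 1:2)
  expect_equal(cc$component, c("c1", "c2"))
  expect_equal(cc$marginal, c(3L, 1L))
  expect_equal(cc$cumulative_percent, c(75, 100))

  full <- tcc_select(list(a = "p1"), "p1")
  expect_equal(coverage_curve(full)$cumulative_percent, 100)
})

test_that("the core group is the shortest prefix reaching the coverage target", {
  sel <- tcc_select(list(c1 = c("p1", "p2", "p3"), c2 = c("p3", "p4"),
                         c3 = "p4"), paste0("p", 1:4))
  expect_equal(cacg_at(sel, 1)$components, c("c1", "c2"))
  expect_true(cacg_at(sel, 1)$reached)
  expect_equal(cacg_at(sel, 0.5)$components, "c1")

  partial <- tcc_select(list(c1 = "p1"), c("p1", "p2"))
  out <- cacg_at(partial, 1)
  expect_false(out$reached)
  expect_equal(out$components, "c1")
  expect_equal(out$coverage, 0.5)
})

test_that("exact-mode optimum agrees with exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:25) {
    u <- sample(4:12, 1)
    universe <- sprintf("p%02d", seq_len(u))
    m <- sample(3:8, 1)
    sets <- lapply(seq_len(m), function(i) {
      sample(universe, sample.int(u, 1))
    })
    names(sets) <- sprintf("c%02d", seq_len(m))
    sel <- tcc_select(sets, universe, mode = "exact")
    expect_equal(sel$optimal_by_k$covered,
                 oracle_best_coverage(sets, universe))
  }
})

test_that("greedy holds the (1 - 1/e) prefix guarantee on random instances", {
  set.seed(41)
  bound <- 1 - exp(-1)
  for (rep in 1:60) {
    u <- sample(5:20, 1)
    universe <- sprintf("p%02d", seq_len(u))
    m <- sample(3:12, 1)
    sets <- lapply(seq_len(m), function(i) sample(universe, sample.int(u, 1)))
    names(sets) <- sprintf("c%02d", seq_len(m))
    sel <- tcc_select(sets, universe)
    opt <- oracle_best_coverage(sets, universe)
    cum <- c(sel$cumulative_coverage,
             rep(max(c(0, sel$cumulative_coverage)), m))[seq_len(m)] * u
    expect_true(all(cum >= bound * opt - 1e-9))
    covers <- length(unique(unlist(sets))) == u
    expect_equal(max(c(0, sel$cumulative_coverage)) == 1, covers)
  }
})

test_that("adding a component never lowers coverage at fixed rank", {
  set.seed(51)
  universe <- sprintf("p%02d", 1:15)
  sets <- lapply(1:6, function(i) sample(universe, sample.int(15, 1)))
  names(sets) <- sprintf("c%02d", 1:6)
  base <- tcc_select(sets, universe)
  extra <- c(sets, list(c99 = sample(universe, 8)))
  more <- tcc_select(extra, universe)
  k <- length(base$cumulative_coverage)
  pad <- function(x, n) c(x, rep(max(c(0, x)), n))[seq_len(n)]
  expect_true(all(pad(more$cumulative_coverage, k) >=
                    pad(base$cumulative_coverage, k) - 1e-12))
})
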