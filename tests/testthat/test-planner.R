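test_that("both searches reproduce the enumeration oracle with all ties", {
  for (seed in 1:12) {
    s <- rand_stim(8, seed = seed)
    set.seed(seed + 100)
    row <- sample(0:6, 1); pos <- sample(0:row, 1); d <- sample(1:6, 1)
    ob <- oracle_best(s, c(row, pos), d)
    for (m in c("dp", "bruteforce")) {
      pl <- best_paths(s, c(row, pos), d, method = m)
      expect_equal(pl$max_score, ob$max)
      expect_identical(path_strings(pl), ob$seqs)
    }
  }
})

test_that("worked example plans: depth 1 goes right, depth 2 finds the 97", {
  f <- fig1_stimulus()
  d1 <- best_paths(f, c(0, 0), 1)
  expect_equal(d1$max_score, 64)
  expect_identical(path_strings(d1), "R")
  d2 <- best_paths(f, c(0, 0), 2)
  expect_equal(d2$max_score, 97)
  expect_identical(path_strings(d2), "LL")
})

test_that("uniform values tie every path and depth truncates silently", {
  u <- uniform_stim()
  expect_length(best_paths(u, c(0, 0), 3)$paths, 8)
  s <- rand_stim(8, seed = 5)
  expect_equal(best_paths(s, c(3, 1), 99), best_paths(s, c(3, 1), 4))
  top <- best_paths(s, c(7, 2), 3)
  expect_equal(top$max_score, 0)
  expect_length(top$paths, 0)
})

test_that("max score is non-decreasing in depth from a fixed start", {
  for (seed in 1:5) {
    s <- rand_stim(10, seed = seed)
    sc <- vapply(1:9, function(d) best_paths(s, c(0, 0), d)$max_score, 0)
    expect_true(all(diff(sc) >= 0))
  }
})

test_that("traversal executes r steps per plan and composes across depths", {
  f <- fig1_stimulus()
  a11 <- simulate_actor(f, strategy(1, 1))
  expect_identical(a11$steps, c("R", "R"))
  expect_identical(a11$score, 80)
  expect_identical(simulate_actor(f, strategy(1, 2))$score, 97)
  # (2, 5) equals applying (1, 5) then (1, 4) stepwise
  for (s in small_ensemble(3)) {
    p25 <- simulate_actor(s, strategy(2, 5))$steps
    manual <- character()
    row <- 0; pos <- 0
    depths <- rep(c(5, 4), length.out = s$n_rows - 1)
    for (d in depths) {
      pl <- best_paths(s, c(row, pos), d)
      st <- sort(vapply(pl$paths, `[`, "", 1))[1]
      manual <- c(manual, st)
      row <- row + 1; pos <- pos + (st == "R")
    }
    expect_identical(p25, manual)
  }
})

test_that("random tie rule is reproducible under a seed", {
  u <- uniform_stim(8)
  set.seed(31); p1 <- simulate_actor(u, strategy(1, 3), tie_rule = "random")$steps
  set.seed(31); p2 <- simulate_actor(u, strategy(1, 3), tie_rule = "random")$steps
  expect_identical(p1, p2)
})

test_that("workload formulas take their stated values and reject r > d", {
  expect_equal(workload_bruteforce(strategy(1, 1)), 4)
  expect_equal(workload_bruteforce(strategy(1, 2)), 12)
  expect_equal(workload_bruteforce(strategy(2, 4)), 40)
  expect_equal(workload_efficient(strategy(1, 1)), 3)
  expect_equal(workload_efficient(strategy(1, 5)), 23)
  expect_equal(workload_first_step(2), 9)
  expect_error(strategy(3, 2), "must not exceed")
})

test_that("instrumented counters match the operation-count model", {
  s <- rand_stim(10, seed = 9)
  for (d in 1:6) {
    bf <- count_operations(s, c(0, 0), d, algorithm = "bruteforce")
    expect_equal(bf$summations, d * 2^d)
    expect_equal(bf$comparisons, 2^d)
    dp <- count_operations(s, c(0, 0), d, algorithm = "dp")
    # a from-scratch pass totals W1(d) = (3/2) d (d + 1) operations
    expect_equal(dp$summations + dp$comparisons, workload_first_step(d))
    expect_equal(dp$summations, d * (d + 1))
  }
})

test_that("iso-workload contours slope up for brute force, down for the DP", {
  # brute force: at constant W, increasing r must be compensated by larger d
  d_for <- function(W, r) uniroot(function(d) (d + 1) * 2^d / r - W, c(0.1, 20))$root
  W <- workload_bruteforce(strategy(2, 4))
  expect_true(d_for(W, 3) > d_for(W, 2))
  # efficient: along a contour through (r, d) with d > r the slope is negative
  dd_dr <- function(r, d) -(3 * d - 3 * r - 0.5) / (3 * r + 2)
  expect_true(dd_dr(1, 5) < 0)
  expect_true(dd_dr(2, 7) < 0)
})
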