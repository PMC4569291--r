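test_that("disk redundancy equals the exhaustive oracle on small lattices", {
  grid <- strategy_grid(3)
  for (seed in 1:8) {
    s <- rand_stim(4, seed = seed)
    for (row in 0:2) for (pos in 0:row) {
      for (cnt in c("pairs", "depth_pairs", "strategies")) {
        expect_equal(
          disk_redundancy(s, c(row, pos), grid, count = cnt),
          oracle_disk_redundancy(s, c(row, pos), grid, count = cnt),
          info = sprintf("seed %d (%d,%d) %s", seed, row, pos, cnt))
      }
    }
  }
})

test_that("stimulus redundancy aggregates per-disk counts", {
  s <- rand_stim(7, seed = 11)
  rep7 <- stimulus_redundancy(s)
  expect_equal(rep7$total, sum(rep7$per_disk))
  manual <- sum(vapply(0:6, function(row) sum(vapply(0:row, function(pos)
    disk_redundancy(s, c(row, pos)), 0L)), 0))
  expect_equal(rep7$total, manual)
})

test_that("degenerate strategy sets and uniform stimuli hit the bounds", {
  u <- uniform_stim(12)
  # single strategy: no pairs to overlap
  expect_equal(disk_redundancy(u, c(2, 1), data.frame(r = 1, d = 3)), 0)
  # all-tie uniform stimulus: every pair of the full grid overlaps at an
  # interior disk (all 28 strategies are effective at depth 7)
  expect_equal(disk_redundancy(u, c(2, 1), count = "pairs"), choose(28, 2))
  expect_equal(disk_redundancy(u, c(2, 1), count = "strategies"), 28)
  expect_equal(disk_redundancy(u, c(2, 1), count = "depth_pairs"), choose(7, 2))
})

test_that("annealer accepts every downhill move and tracks incrementally", {
  a <- anneal_stimulus(n_rows = 10, schedule = anneal_schedule(c(1, 0.5), c(400, 400)),
                       seed = 21)
  tr <- a$trace
  expect_true(all(tr$accepted[tr$delta <= 0] == 1))
  # running minimum of the redundancy trace never increases
  expect_true(all(diff(cummin(tr$redundancy)) <= 0))
  # incremental bookkeeping equals a full recomputation of the final stimulus
  expect_equal(a$r_final, stimulus_redundancy(a$stimulus)$total)
  expect_equal(a$per_disk, stimulus_redundancy(a$stimulus)$per_disk)
})

test_that("uphill acceptance follows exp(-dR/T)", {
  a <- anneal_stimulus(n_rows = 8, schedule = anneal_schedule(3, 4000), seed = 11,
                       count = "depth_pairs")
  up <- a$trace[a$trace$delta > 0, ]
  expect_gt(nrow(up), 500)
  p <- exp(-up$delta / 3)
  expected <- sum(p)
  tol <- 4 * sqrt(sum(p * (1 - p)))
  expect_lt(abs(sum(up$accepted) - expected), tol)
  # and the most common uphill size individually
  one <- up[up$delta == 1, ]
  expect_gt(nrow(one), 50)
  expect_lt(abs(mean(one$accepted) - exp(-1 / 3)),
            4 * sqrt(exp(-1 / 3) * (1 - exp(-1 / 3)) / nrow(one)))
})

test_that("a design run is reproducible from its seed", {
  a1 <- anneal_stimulus(n_rows = 8, schedule = anneal_schedule(c(1, 0.5), c(200, 200)),
                        seed = 77)
  a2 <- anneal_stimulus(n_rows = 8, schedule = anneal_schedule(c(1, 0.5), c(200, 200)),
                        seed = 77)
  expect_identical(a1$stimulus$rows, a2$stimulus$rows)
  expect_identical(a1$trace, a2$trace)
})

test_that("annealed stimuli are less redundant and structured for diagnosis", {
  stims <- small_ensemble(3)
  runs <- anneal_ensemble(3, base_seed = 42L)$runs
  expect_true(all(vapply(runs, `[[`, 0, "reduction") > 0))
  # disk-value variance peaks on the top row of the ensemble average
  vars <- rowMeans(vapply(stims,
                          function(s) vapply(s$rows, var, 0)[-1], numeric(11)))
  expect_equal(which.max(vars), 11L)
})
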