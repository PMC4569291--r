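test_that("sigmoid choice probability reproduces its stated values", {
  expect_equal(choice_probability(0, 5, 0), 0.5)
  expect_equal(choice_probability(3, 1, 0), 1 / (1 + exp(-3)), tolerance = 1e-12)
  expect_equal(choice_probability(3, 1, 0), 0.9526, tolerance = 1e-4)
  expect_equal(choice_probability(-10, 1, 1e9), 1)   # bias limit
  expect_equal(choice_probability(-3, 1, 0), 1 - choice_probability(3, 1, 0))
})

test_that("a fixed (1,2) actor on the worked example logs L, L and 97 points", {
  co <- generate_cohort(actor_spec("fixed_strategy", r = 1, d = 2),
                        fig1_stimulus(), seed = 1)
  expect_equal(nrow(co), 3)
  expect_equal(co$pos, c(0, 0, 0))
  expect_equal(co$total[1], 97)
  expect_equal(co$points, c(0, 16, 81))
})

test_that("noise-free fixed actors reproduce the ideal planner exactly", {
  stims <- small_ensemble(3)
  for (d in c(1, 3, 5)) {
    co <- generate_cohort(actor_spec("fixed_strategy", r = 1, d = d), stims, seed = d)
    for (s in stims) {
      tt <- co[co$stimulus == s$id, ]
      expect_equal(tt$total[1], simulate_actor(s, strategy(1, d))$score)
    }
  }
})

test_that("a near-deterministic sigmoid actor always takes the better branch", {
  stims <- small_ensemble(3)
  co <- generate_cohort(actor_spec("sigmoid", d = 3, beta = 1e6), stims, seed = 2)
  for (s in stims) {
    tt <- co[co$stimulus == s$id, ]
    for (t in seq_len(s$n_rows - 1L)) {
      row <- tt$row[t]; pos <- tt$pos[t]
      e <- s$n_rows - 1L - row
      d_eff <- min(3L, e)
      sL <- disk_value(s, c(row + 1, pos)) +
        (if (d_eff > 1) best_paths(s, c(row + 1, pos), d_eff - 1)$max_score else 0)
      sR <- disk_value(s, c(row + 1, pos + 1)) +
        (if (d_eff > 1) best_paths(s, c(row + 1, pos + 1), d_eff - 1)$max_score else 0)
    step <- tt$pos[t + 1] - tt$pos[t]
      if (sL > sR) expect_equal(step, 0L)
      if (sR > sL) expect_equal(step, 1L)
    }
  }
})

test_that("heuristic actors plan on merged values but score true points", {
  stims <- small_ensemble(3)
  co <- generate_cohort(actor_spec("heuristic_seek_large", r = 1, d = 4, k = 8),
                        stims, seed = 3)
  for (s in stims) {
    tt <- co[co$stimulus == s$id, ]
    merged <- reweight_stimulus(s, "seek_large", 8)
    plan_path <- simulate_actor(merged, strategy(1, 4))
    expect_equal(tt$pos, c(0, cumsum(plan_path$steps == "R")))
    expect_equal(tt$total[1], path_score(s, plan_path$steps))
  }
})

test_that("misses follow the stated probability and award the penalty", {
  stims <- small_ensemble(3)
  co <- generate_cohort(actor_spec("fixed_strategy", d = 3, miss_prob = 0.2,
                                   penalty = -50, n = 40),
                        stims, seed = 4)
  touched <- co[co$touch > 0, ]
  n <- nrow(touched)
  expect_lt(abs(sum(!touched$hit) - 0.2 * n), 3 * sqrt(n * 0.2 * 0.8))
  expect_true(all(touched$points[!touched$hit] == -50))
  totals <- tapply(co$points, co$trial, sum)
  expect_equal(as.vector(totals[as.character(co$trial)]), co$total)
})

test_that("random-depth cohorts realize the draw distribution mean", {
  stims <- small_ensemble(3)
  co <- generate_cohort(actor_spec("random_depth", depth_range = 1:5, n = 60),
                        stims, seed = 5, assign = "random")
  d <- co$depth[!is.na(co$depth)]
  expect_lt(abs(mean(d) - 3), 3 * sd(d) / sqrt(length(d)))
  co0 <- generate_cohort(actor_spec("random_depth", depth_range = 0:5, n = 60),
                         stims, seed = 6, assign = "random")
  expect_setequal(unique(co0$depth[!is.na(co0$depth)]), 0:5)
})

test_that("trial logs survive a CSV round trip and are validated on read", {
  stims <- small_ensemble(3)
  co <- generate_cohort(list(actor_spec("fixed_strategy", d = 2, n = 2),
                             actor_spec("random_depth", n = 2)),
                        stims, n_trials = 2, seed = 8)
  tf <- tempfile(fileext = ".csv")
  write_trials(co, tf)
  back <- read_trials(tf)
  expect_equal(nrow(back), nrow(co))
  expect_equal(back$pos, co$pos)
  expect_equal(back$total, co$total)
  # a log that skips a row is rejected
  bad <- co
  bad$row[2] <- bad$row[2] + 1L
  write_trials(bad, tf)
  expect_error(read_trials(tf), "skip")
  # tampered totals are rejected
  bad2 <- co
  bad2$total[bad2$trial == 1] <- bad2$total[bad2$trial == 1] + 5
  write_trials(bad2, tf)
  expect_error(read_trials(tf), "total")
})

test_that("cohort generation rejects nonsense and records conditions", {
  expect_error(generate_cohort(actor_spec("fixed_strategy"), fig1_stimulus(),
                               n_trials = 0), "positive")
  expect_error(actor_spec("fixed_strategy", penalty = -10), "penalty")
  expect_error(actor_spec("heuristic_seek_large", k = 9), "k must be")
  co <- generate_cohort(actor_spec("fixed_strategy", d = 2, speed = "slow",
                                   penalty = -50),
                        fig1_stimulus(), seed = 9)
  expect_true(all(co$speed == "slow" & co$penalty == -50))
  expect_true(all(is.finite(co$rt) & co$rt > 0))
})
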