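# A strictly right-increasing stimulus: depth-1 plans are unique everywhere
# (right child always strictly larger), so the greedy and anti-greedy
# traversals are unambiguous.
graded_stim <- function(n_rows = 8) {
  stimulus(lapply(seq_len(n_rows), function(k) disk_values[seq_len(k)]),
           id = "graded")
}

# Hand-built trial log from explicit step sequences.
manual_trials <- function(stim, step_lists, actor_prefix = "manual") {
  do.call(rbind, lapply(seq_along(step_lists), function(i) {
    bits <- as.integer(step_lists[[i]] == "R")
    pos <- c(0L, cumsum(bits))
    n <- stim$n_rows
    pts <- c(0, vapply(seq_len(n - 1L),
                       function(t) stim$rows[[t + 1L]][pos[t + 1L] + 1L], 0))
    data.frame(actor = sprintf("%s_%d", actor_prefix, i), kind = "manual",
               stimulus = stim$id, speed = "fast", penalty = -1, trial = i,
               touch = 0:(n - 1L), row = 0:(n - 1L), pos = pos,
               depth = NA_integer_, hit = TRUE, points = pts, rt = NA_real_,
               total = sum(pts), stringsAsFactors = FALSE)
  }))
}

test_that("an exact actor votes for its own strategy at every interior disk", {
  stims <- small_ensemble(3)
  co <- generate_cohort(actor_spec("fixed_strategy", r = 1, d = 2), stims, seed = 1)
  vt <- vote_overlaps(co, stims, strategy_grid(5), min_visits = 1)
  s12 <- which(vt$strategies$r == 1 & vt$strategies$d == 2)
  expect_true(all(vt$votes[, s12] == 1))
})

test_that("(2,5) votes decompose into (1,5)-then-(1,4) votes where plans are unique", {
  stims <- small_ensemble(2)
  co <- generate_cohort(list(actor_spec("fixed_strategy", r = 2, d = 5),
                             actor_spec("random_depth", n = 3)), stims, seed = 2)
  grid <- data.frame(r = c(2, 1, 1), d = c(5, 5, 4))
  vt <- vote_overlaps(co, stims, grid, min_visits = 1)
  tch <- vt$touches
  by_id <- split(stims, vapply(stims, `[[`, "", "id"))
  n <- stims[[1]]$n_rows
  for (i in which(tch$row <= n - 3)) {
    s <- by_id[[tch$stimulus[i]]][[1]]
    e <- n - 1 - tch$row[i]
    here <- best_paths(s, c(tch$row[i], tch$pos[i]), min(5, e))
    if (length(here$paths) != 1) next
    nxt_pos <- tch$pos[i] + (here$paths[[1]][1] == "R")
    nxt <- best_paths(s, c(tch$row[i] + 1, nxt_pos), min(4, e - 1))
    if (length(nxt$paths) != 1) next
    j <- which(tch$trial == tch$trial[i] & tch$row == tch$row[i] + 1)
    if (!length(j)) next
    expect_equal(vt$votes[i, 1], vt$votes[i, 2] * vt$votes[j, 3],
                 info = sprintf("touch %d", i))
  }
})

test_that("a random stepper matches any single-step plan about half the time", {
  stims <- small_ensemble(3)
  co <- generate_cohort(actor_spec("random_depth", depth_range = 0L, n = 30),
                        stims, seed = 3, assign = "random")
  vt <- vote_overlaps(co, stims, data.frame(r = 1L, d = 1:5))
  rates <- colMeans(vt$votes)
  n <- nrow(vt$votes)
  expect_true(all(abs(rates - 0.5) < 4 * sqrt(0.25 / n) + 0.05))
})

test_that("evidence is 2 for self-overlap, 1 for chance, 0 for avoidance", {
  stims <- small_ensemble(3)
  grid <- data.frame(r = 1L, d = 1:5)
  # self-overlap
  co <- generate_cohort(actor_spec("fixed_strategy", r = 1, d = 3, n = 4),
                        stims, seed = 4)
  set.seed(11)
  ev <- evidence(vote_overlaps(co, stims, grid), N = 200)
  expect_lt(abs(ev$E[ev$d == 3] - 2), 0.1)
  expect_equal(which.max(ev$E), 3L)
  expect_true(all(ev$E >= 0 & ev$E <= 2.05))
  # chance
  co0 <- generate_cohort(actor_spec("random_depth", depth_range = 0L, n = 30),
                         stims, seed = 5, assign = "random")
  set.seed(12)
  ev0 <- evidence(vote_overlaps(co0, stims, grid), N = 200)
  expect_true(all(abs(ev0$E - 1) < 0.2))
  # perfect avoidance of the greedy strategy on a tie-free gradient
  g <- graded_stim(8)
  anti <- manual_trials(g, list(rep("L", 7), rep("L", 7)))
  set.seed(13)
  evA <- evidence(vote_overlaps(anti, g, data.frame(r = 1L, d = 1L)), N = 100)
  expect_identical(evA$E, 0)
})

test_that("fixed-strategy cohorts are recovered by the evidence argmax", {
  stims <- small_ensemble(3)
  grid <- data.frame(r = 1L, d = 1:5)
  for (d0 in c(2, 4)) {
    co <- generate_cohort(actor_spec("fixed_strategy", r = 1, d = d0, n = 3),
                          stims, seed = 20 + d0)
    set.seed(30 + d0)
    ev <- evidence(vote_overlaps(co, stims, grid), N = 200)
    expect_equal(ev$d[which.max(ev$E)], d0)
  }
})

test_that("unique overlaps are rare, truncation-bounded, and track depth", {
  stims <- small_ensemble(6)
  deep <- generate_cohort(actor_spec("sigmoid", d = 5, beta = 1, n = 40),
                          stims, n_trials = 2, seed = 6)
  shal <- generate_cohort(actor_spec("sigmoid", d = 1, beta = 1, n = 40),
                          stims, n_trials = 2, seed = 8)
  ud_deep <- unique_overlap_depths(deep, stims, depths = 1:7)
  ud_shal <- unique_overlap_depths(shal, stims, depths = 1:7)
  # the penultimate row can never yield a unique overlap: every depth
  # collapses to the same one-step plan there
  expect_equal(ud_deep$n_unique[ud_deep$row == 10], 0)
  expect_true(is.na(ud_deep$mean_depth[ud_deep$row == 10]))
  # near the stimulus end estimates are bounded by the rows remaining
  late <- ud_deep[ud_deep$row >= 7 & ud_deep$n_unique > 0, ]
  if (nrow(late)) expect_true(all(late$mean_depth <= 11 - late$row))
  # deeper planning shows up as deeper unique-overlap estimates
  m <- function(ud) {
    sel <- ud$n_unique > 0 & ud$row <= 8
    sum(ud$mean_depth[sel] * ud$n_unique[sel]) / sum(ud$n_unique[sel])
  }
  expect_gt(sum(ud_deep$n_unique), 0)
  expect_gt(sum(ud_shal$n_unique), 0)
  expect_gt(m(ud_deep), m(ud_shal) + 1)
})

test_that("a depth never used by the cohort receives no unique votes", {
  stims <- small_ensemble(3)
  co <- generate_cohort(list(actor_spec("fixed_strategy", r = 1, d = 1, n = 3),
                             actor_spec("fixed_strategy", r = 1, d = 3, n = 3)),
                        stims, seed = 7)
  vt <- vote_overlaps(co, stims, data.frame(r = 1L, d = 1:5))
  nm <- rowSums(vt$votes)
  dmatch <- as.vector(vt$votes %*% (1:5))
  expect_false(any(dmatch[nm == 1] == 2))
})

test_that("score advantage is zero against the generating ideal", {
  stims <- small_ensemble(3)
  co <- generate_cohort(actor_spec("fixed_strategy", r = 1, d = 3, n = 2),
                        stims, seed = 8)
  adv <- score_advantage(co, stims, strategy_grid(5))
  self <- adv[adv$r == 1 & adv$d == 3, ]
  expect_equal(self$A, 0)
  expect_equal(self$se, 0)
  # a shallow cohort loses to deep ideals over the last rows
  co1 <- generate_cohort(actor_spec("fixed_strategy", r = 1, d = 1, n = 2),
                         stims, seed = 9)
  adv1 <- score_advantage(co1, stims, strategy_grid(5))
  expect_lt(adv1$A[adv1$r == 1 & adv1$d == 5], adv1$A[adv1$r == 1 & adv1$d == 1])
  expect_error(score_advantage(co[0, ], stims), "no trials")
})

test_that("zero-crossing estimation finds linear roots and flags non-crossings", {
  tab <- data.frame(r = 1L, d = 1:5, A = 3 - (1:5), se = 0, n = 10)
  class(tab) <- c("score_advantage", "data.frame")
  est <- estimate_strategy(tab)
  expect_equal(est$d_hat, 3)
  expect_true(est$crossed)
  tab$A <- 10 - tab$d    # decreasing but never crossing within range
  expect_false(estimate_strategy(tab)$crossed)
  tab$A <- tab$d         # increasing: no root at all
  est3 <- estimate_strategy(tab)
  expect_false(est3$crossed)
  expect_true(is.na(est3$d_hat))
})

test_that("reweighting merges value classes by worth, not location", {
  s <- rand_stim(12, seed = 10)
  sk8 <- reweight_stimulus(s, "seek_large", 8)
  expect_true(all(unlist(sk8$rows) %in% c(1, 81)))
  sk7 <- reweight_stimulus(s, "seek_large", 7)
  expect_true(all(unlist(sk7$rows) %in% c(1, 64, 81)))
  av1 <- reweight_stimulus(s, "avoid_small", 1)
  expect_true(all(unlist(av1$rows)[unlist(s$rows) == 81] == 1000))
  expect_true(all(unlist(av1$rows)[unlist(s$rows) != 81] == unlist(s$rows)[unlist(s$rows) != 81]))
  expect_error(reweight_stimulus(s, "seek_large", 9), "k must be")
})

test_that("reweighting analysis separates heuristic from full-information cohorts", {
  stims <- small_ensemble(2)
  # the heuristic cohort's effective world: stimuli already merged at k = 5
  K <- 5
  stim_k <- lapply(stims, reweight_stimulus, mode = "seek_large", k = K)
  co_h <- generate_cohort(list(actor_spec("fixed_strategy", r = 1, d = 3, n = 2),
                               actor_spec("fixed_strategy", r = 1, d = 4, n = 2)),
                          stim_k, seed = 11)
  set.seed(14)
  hr <- heuristic_rms(co_h, stim_k, "seek_large", k_range = 1:8,
                      strategies = strategy_grid(5), N = 50)
  # merging j <= K size classes changes nothing in the merged world: exactly 0
  expect_identical(hr$deviation[hr$k <= K], rep(0, K))
  expect_true(all(hr$deviation[hr$k > K] > 0))
  # a full-information cohort is perturbed by every effective reweighting
  # (merging only the 1-point class, k = 1, is structurally a no-op)
  co_f <- generate_cohort(actor_spec("fixed_strategy", r = 1, d = 4, n = 4),
                          stims, seed = 12)
  set.seed(15)
  hr_f <- heuristic_rms(co_f, stims, "seek_large", k_range = 1:8,
                        strategies = strategy_grid(5), N = 50)
  expect_identical(hr_f$deviation[1], 0)
  expect_true(all(hr_f$deviation[-1] > 0))
  set.seed(16)
  hr_a <- heuristic_rms(co_f, stims, "avoid_small", k_range = 1:4,
                        strategies = strategy_grid(5), N = 50)
  expect_true(all(hr_a$deviation > 0))
})
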