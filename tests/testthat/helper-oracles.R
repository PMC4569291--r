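# Independent oracles: plain R enumeration of paths and redundancy, used to
# check the C++ search and design routines. These deliberately share no code
# with the package internals.

# All step sequences of length d from start, with their scores.
oracle_paths <- function(stim, start, d) {
  e <- stim$n_rows - 1L - start[1]
  d <- min(d, e)
  if (d == 0L) return(data.frame(steps = character(), score = numeric()))
  combos <- expand.grid(rep(list(c("L", "R")), d), stringsAsFactors = FALSE)
  scores <- apply(combos, 1L, function(st) {
    row <- start[1]; pos <- start[2]; total <- 0
    for (s in st) {
      row <- row + 1L
      if (s == "R") pos <- pos + 1L
      total <- total + stim$rows[[row + 1L]][pos + 1L]
    }
    total
  })
  data.frame(steps = apply(combos, 1L, paste, collapse = ""), score = scores,
             stringsAsFactors = FALSE)
}

# Maximum score and the sorted set of all maximizing step strings.
oracle_best <- function(stim, start, d) {
  p <- oracle_paths(stim, start, d)
  if (nrow(p) == 0L) return(list(max = 0, seqs = character()))
  m <- max(p$score)
  list(max = m, seqs = sort(p$steps[p$score == m]))
}

path_strings <- function(plan) sort(vapply(plan$paths, paste, "", collapse = ""))

# Independent disk redundancy. Prefix sets are computed from the enumeration
# oracle; overlap and counting follow the documented definitions.
oracle_disk_redundancy <- function(stim, coord, grid = strategy_grid(),
                                   count = "pairs") {
  e <- stim$n_rows - 1L - coord[1]
  if (e <= 0L) return(0L)
  if (count == "depth_pairs") {
    depths <- sort(unique(grid$d[grid$d <= e]))
    if (length(depths) < 2L) return(0L)
    pref <- lapply(depths, function(d) oracle_best(stim, coord, d)$seqs)
    cnt <- 0L
    for (a in seq_along(depths)) for (b in seq_along(depths)) {
      if (b <= a) next
      m <- min(depths[a], depths[b])
      if (length(intersect(substr(pref[[a]], 1, m), substr(pref[[b]], 1, m))))
        cnt <- cnt + 1L
    }
    return(cnt)
  }
  de <- pmin(grid$d, e)
  re <- pmin(grid$r, de)
  pref <- lapply(seq_len(nrow(grid)), function(i)
    unique(substr(oracle_best(stim, coord, de[i])$seqs, 1, re[i])))
  overlap <- matrix(FALSE, nrow(grid), nrow(grid))
  for (a in seq_len(nrow(grid))) for (b in seq_len(nrow(grid))) {
    if (b <= a) next
    m <- min(re[a], re[b])
    overlap[a, b] <- length(intersect(substr(pref[[a]], 1, m),
                                      substr(pref[[b]], 1, m))) > 0L
  }
  if (count == "pairs") sum(overlap) else sum(apply(overlap | t(overlap), 1, any))
}

# Monte Carlo evaluation of a per-row depth policy: greedy step from the
# enumeration oracle, ties and depth 0 split uniformly.
oracle_policy_mc <- function(stim, policy, n_runs) {
  n <- stim$n_rows
  scores <- replicate(n_runs, {
    row <- 0L; pos <- 0L; total <- 0
    for (k in seq_len(n - 1L)) {
      d <- policy[k]
      if (d == 0L) step <- sample(c("L", "R"), 1L)
      else {
        firsts <- unique(substr(oracle_best(stim, c(row, pos), d)$seqs, 1, 1))
        step <- if (length(firsts) == 2L) sample(firsts, 1L) else firsts
      }
      row <- row + 1L
      if (step == "R") pos <- pos + 1L
      total <- total + stim$rows[[row + 1L]][pos + 1L]
    }
    total
  })
  list(mean = mean(scores), se = sd(scores) / sqrt(n_runs))
}

rand_stim <- function(n_rows = 8L, seed = NULL, id = "test") {
  if (!is.null(seed)) set.seed(seed)
  random_stimulus(n_rows, id = id)
}

# A valued stimulus with all disks equal (every plan tied everywhere).
uniform_stim <- function(n_rows = 9L, value = 16) {
  stimulus(lapply(seq_len(n_rows), function(k) rep(value, k)), id = "uniform")
}

# Small annealed ensemble shared across test files that need realistic
# (tie-poor, diagnostic) stimuli without paying for the full study ensemble.
.test_cache <- new.env()
small_ensemble <- function(n = 3L) {
  key <- paste0("ens", n)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- anneal_ensemble(n, base_seed = 42L)$stimuli
  .test_cache[[key]]
}
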