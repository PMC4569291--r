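# Strategy recovery from trial logs: score advantage with zero-crossing depth
# estimation, path-overlap voting and normalized evidence, unique-overlap
# depths, and the value-reweighting (heuristic) analysis.

as_stimulus_list <- function(stimuli) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  ids <- vapply(stimuli, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("stimulus ids must be unique")
  names(stimuli) <- ids
  stimuli
}

# ---------------------------------------------------------------------------
# Vote machinery
#
# A "vote context" fixes everything that depends on the trials alone: the
# per-touch next-step codes (packed L/R bits at every comparison length) and
# the grouping of touches by (stimulus, row). Votes and random-baseline match
# probabilities are then computed against any stimulus set sharing the same
# geometry and ids, which is what the reweighting analysis exploits.

make_vote_context <- function(trials, stimuli, strategies, dmax = max(strategies$d)) {
  stimuli <- as_stimulus_list(stimuli)
  n <- unique(vapply(stimuli, `[[`, 0L, "n_rows"))
  if (length(n) != 1L) stop("all stimuli must share n_rows")
  if (!all(unique(trials$stimulus) %in% names(stimuli)))
    stop("trials reference unknown stimuli")
  o <- order(trials$trial, trials$touch)
  tr <- trials[o, , drop = FALSE]
  if (nrow(tr) %% n != 0L || any(tabulate(factor(tr$trial)) != n))
    stop("every trial must contain one touch per stimulus row")
  n_tr <- nrow(tr) %/% n
  POS <- matrix(tr$pos, nrow = n_tr, ncol = n, byrow = TRUE)
  first <- seq(1L, nrow(tr), by = n)
  stim_of_trial <- tr$stimulus[first]
  trial_of <- tr$trial[first]
  actor_of <- if ("actor" %in% names(tr)) tr$actor[first] else as.character(trial_of)
  B <- POS[, 2:n, drop = FALSE] - POS[, 1:(n - 1L), drop = FALSE]
  if (any(B < 0L | B > 1L)) stop("trials violate the child relation")
  mmax <- min(7L, n - 1L)
  codes <- matrix(NA_integer_, n_tr * (n - 1L), mmax)
  Cm <- B
  codes[, 1L] <- as.vector(B)
  if (mmax >= 2L) for (m in 2:mmax) {
    valid <- seq_len(n - m)
    Cm2 <- matrix(NA_integer_, n_tr, n - 1L)
    Cm2[, valid] <- Cm[, valid, drop = FALSE] + B[, valid + (m - 1L), drop = FALSE] * 2L^(m - 1L)
    Cm <- Cm2
    codes[, m] <- as.vector(Cm)
  }
  touches <- data.frame(
    trial = rep(trial_of, times = n - 1L),
    actor = rep(actor_of, times = n - 1L),
    stimulus = rep(stim_of_trial, times = n - 1L),
    row = rep(0:(n - 2L), each = n_tr),
    pos = as.vector(POS[, seq_len(n - 1L), drop = FALSE]),
    stringsAsFactors = FALSE)
  groups <- split(seq_len(nrow(touches)),
                  paste(touches$stimulus, touches$row, sep = "\r"))
  list(touches = touches, codes = codes, n_rows = n, strategies = strategies,
       dmax = as.integer(dmax), groups = groups,
       stim_ids = names(stimuli))
}

# Votes (and, when U is supplied, per-touch random-match probabilities
# averaged over N = ncol(U) uniform step draws) of every touch against every
# strategy's plan prefixes on the given stimulus set.
compute_votes <- function(ctx, stimuli, U = NULL) {
  stimuli <- as_stimulus_list(stimuli)
  n <- ctx$n_rows
  strat <- ctx$strategies
  pt <- lapply(stimuli, function(s) cpp_plan_table(stim_values(s), n, ctx$dmax))
  nt <- nrow(ctx$touches)
  ns <- nrow(strat)
  votes <- matrix(0L, nt, ns)
  rand <- if (!is.null(U)) matrix(NA_real_, nt, ns)
  for (gname in names(ctx$groups)) {
    idx <- ctx$groups[[gname]]
    parts <- strsplit(gname, "\r", fixed = TRUE)[[1]]
    sid <- parts[1]
    row <- as.integer(parts[2])
    e <- n - 1L - row
    pos_g <- ctx$touches$pos[idx]
    mem_cache <- list()
    for (s in seq_len(ns)) {
      de <- min(strat$d[s], e)
      re <- min(strat$r[s], de)
      key <- paste(de, re)
      M <- mem_cache[[key]]
      if (is.null(M)) {
        M <- matrix(FALSE, row + 1L, 2L^re)
        for (p in 0:row) {
          cds <- pt[[sid]][[disk_index(row, p)]][[de]]
          M[p + 1L, unique(bitwAnd(cds, 2L^re - 1L)) + 1L] <- TRUE
        }
        mem_cache[[key]] <- M
      }
      code_g <- ctx$codes[idx, re]
      votes[idx, s] <- as.integer(M[cbind(pos_g + 1L, code_g + 1L)])
      if (!is.null(U)) {
        dr <- floor(U[idx, , drop = FALSE] * 2L^re)
        hit <- M[cbind(rep(pos_g + 1L, times = ncol(U)), as.vector(dr) + 1L)]
        rand[idx, s] <- rowMeans(matrix(hit, nrow = length(idx)))
      }
    }
  }
  list(votes = votes, rand = rand)
}

#' Path-overlap votes of trials against ideal planners
#'
#' For every disk touched (below the top row), each strategy (r, d) receives
#' a binary vote: 1 iff the actor's next \code{min(r, d, rows remaining)}
#' steps coincide with the corresponding prefix of at least one stored
#' optimal plan of that strategy from that disk (all score ties are stored;
#' no partial credit). Per-disk strategy calls are only issued for disks
#' visited at least \code{min_visits} times.
#'
#' @param trials trial-log data.frame (see \code{\link{generate_cohort}}).
#' @param stimuli list of \code{"stimulus"} objects covering the trials.
#' @param strategies data.frame with columns r, d (default
#'   \code{\link{strategy_grid}}).
#' @param min_visits minimum visits for a per-disk strategy call (default 10).
#' @return object of class \code{"vote_table"}: list with \code{strategies},
#'   \code{touches} (one row per scored touch), \code{votes} (touches x
#'   strategies 0/1 matrix), \code{per_disk} (visit and vote counts),
#'   \code{calls} (per-disk winning strategy where visits suffice), and the
#'   internal context reused by \code{\link{evidence}}.
#' @export
vote_overlaps <- function(trials, stimuli, strategies = strategy_grid(),
                          min_visits = 10L) {
  stimuli <- as_stimulus_list(stimuli)
  ctx <- make_vote_context(trials, stimuli, strategies)
  votes <- compute_votes(ctx, stimuli)$votes
  key <- paste(ctx$touches$stimulus, ctx$touches$row, ctx$touches$pos, sep = "\r")
  agg <- rowsum(votes, key)
  visits <- as.vector(rowsum(rep(1L, nrow(votes)), key))
  kp <- strsplit(rownames(agg), "\r", fixed = TRUE)
  per_disk <- data.frame(stimulus = vapply(kp, `[`, "", 1L),
                         row = as.integer(vapply(kp, `[`, "", 2L)),
                         pos = as.integer(vapply(kp, `[`, "", 3L)),
                         visits = visits, stringsAsFactors = FALSE)
  colnames(agg) <- sprintf("r%d_d%d", strategies$r, strategies$d)
  eligible <- per_disk$visits >= min_visits
  calls <- per_disk[eligible, , drop = FALSE]
  if (nrow(calls)) {
    win <- apply(agg[eligible, , drop = FALSE], 1L, which.max)
    calls$r <- strategies$r[win]
    calls$d <- strategies$d[win]
  }
  structure(list(strategies = strategies, touches = ctx$touches, votes = votes,
                 per_disk = cbind(per_disk, as.data.frame(agg)),
                 calls = calls, min_visits = min_visits,
                 ctx = ctx, stimuli = stimuli),
            class = "vote_table")
}

#' @export
print.vote_table <- function(x, ...) {
  cat(sprintf("Vote table: %d touches x %d strategies; %d disks called (>= %d visits)\n",
              nrow(x$votes), nrow(x$strategies), nrow(x$calls), x$min_visits))
  invisible(x)
}

#' Normalized path-overlap evidence E(r, d)
#'
#' The raw vote count for each strategy is normalized by the expected vote
#' count of a random traverser over the same disks, estimated from N uniform
#' step draws per touch: E = V_s / <V_R>. E = 1 indicates chance behavior,
#' E = 2 a perfect overlap (two choices per step), E = 0 perfect avoidance.
#' Evidence does not self-average across depths (E(1,1) = E(1,3) = 2 is
#' compatible with E(1,2) = 0), so no mean depth is derived from it.
#'
#' @param votes a \code{"vote_table"}.
#' @param stimuli stimulus set to compute plans on (default: the set stored
#'   in \code{votes}; the reweighting analysis passes modified values here).
#' @param N random path draws per touch for the denominator (default 100).
#' @return object of class \code{"evidence_table"}: data.frame with columns
#'   r, d, votes, random_mean, E, flagged (TRUE where the random baseline was
#'   degenerate and E is NA).
#' @export
evidence <- function(votes, stimuli = votes$stimuli, N = 100L) {
  if (!inherits(votes, "vote_table")) stop("votes must be a vote_table")
  U <- matrix(runif(nrow(votes$votes) * N), ncol = N)
  evidence_core(votes$ctx, stimuli, U)
}

evidence_core <- function(ctx, stimuli, U) {
  cv <- compute_votes(ctx, stimuli, U = U)
  vs <- colSums(cv$votes)
  vr <- colSums(cv$rand)
  flagged <- vr <= 0
  E <- ifelse(flagged, NA_real_, vs / vr)
  out <- data.frame(r = ctx$strategies$r, d = ctx$strategies$d,
                    votes = vs, random_mean = vr, E = E, flagged = flagged)
  class(out) <- c("evidence_table", "data.frame")
  out
}

#' Per-row depth estimates from unique overlaps
#'
#' Keeps only touches whose next step coincides with the plan of exactly one
#' depth of computation (r = 1) and averages that depth per stimulus row.
#' Near the stimulus end, depths collapse under truncation so unique overlaps
#' disappear (the penultimate row can never produce one); such rows are
#' reported with \code{n_unique = 0} and \code{NA} depth.
#'
#' @param trials trial-log data.frame.
#' @param stimuli list of \code{"stimulus"} objects.
#' @param depths candidate depths (default 1:7).
#' @return data.frame with columns row, n_unique, mean_depth.
#' @export
unique_overlap_depths <- function(trials, stimuli, depths = 1:7) {
  stimuli <- as_stimulus_list(stimuli)
  strategies <- data.frame(r = 1L, d = as.integer(depths))
  ctx <- make_vote_context(trials, stimuli, strategies)
  votes <- compute_votes(ctx, stimuli)$votes
  nmatch <- rowSums(votes)
  uni <- nmatch == 1L
  dmatch <- as.vector(votes %*% depths)
  rows <- 0:(ctx$n_rows - 2L)
  out <- data.frame(row = rows,
                    n_unique = vapply(rows, function(rr)
                      sum(uni & ctx$touches$row == rr), 0L),
                    mean_depth = vapply(rows, function(rr) {
                      sel <- uni & ctx$touches$row == rr
                      if (any(sel)) mean(dmatch[sel]) else NA_real_
                    }, numeric(1)))
  out
}

# ---------------------------------------------------------------------------
# Score advantage

#' Score advantage of actors over ideal planners
#'
#' A(r, d) is the mean difference between an actor's score and the ideal
#' (r, d) planner's score on the same stimulus, accumulated over the last
#' \code{last_rows} stimulus rows (default 3, where the differences between
#' strategies are largest).
#'
#' @param trials trial-log data.frame; must be non-empty.
#' @param stimuli list of \code{"stimulus"} objects.
#' @param strategies data.frame with columns r, d.
#' @param last_rows size of the terminal row window (default 3).
#' @return object of class \code{"score_advantage"}: data.frame with columns
#'   r, d, A, se, n.
#' @export
score_advantage <- function(trials, stimuli, strategies = strategy_grid(),
                            last_rows = 3L) {
  if (nrow(trials) == 0L) stop("no trials")
  stimuli <- as_stimulus_list(stimuli)
  n <- stimuli[[1]]$n_rows
  cut <- n - last_rows
  # ideal last-window scores per stimulus per strategy
  ideal <- sapply(seq_len(nrow(strategies)), function(s) {
    vapply(stimuli, function(st) {
      bits <- cpp_traverse_strategy(stim_values(st), n, strategies$r[s],
                                    strategies$d[s], FALSE)
      pos <- cumsum(bits)
      rows <- seq_len(n - 1L)  # row stepped onto
      sum(vapply(which(rows >= cut), function(i)
        st$rows[[rows[i] + 1L]][pos[i] + 1L], numeric(1)))
    }, numeric(1))
  })
  ideal <- matrix(ideal, nrow = length(stimuli))
  rownames(ideal) <- names(stimuli)
  sel <- trials$row >= cut
  actor_last <- rowsum(trials$points[sel], trials$trial[sel])
  stim_of_trial <- trials$stimulus[!duplicated(trials$trial)]
  names(stim_of_trial) <- trials$trial[!duplicated(trials$trial)]
  stim_idx <- match(stim_of_trial[rownames(actor_last)], names(stimuli))
  out <- do.call(rbind, lapply(seq_len(nrow(strategies)), function(s) {
    diffs <- actor_last[, 1L] - ideal[stim_idx, s]
    data.frame(r = strategies$r[s], d = strategies$d[s],
               A = mean(diffs), se = sd(diffs) / sqrt(length(diffs)),
               n = length(diffs))
  }))
  attr(out, "last_rows") <- last_rows
  class(out) <- c("score_advantage", "data.frame")
  out
}

#' Estimate the strategy from score-advantage zero crossings
#'
#' Score advantage decreases approximately linearly in the depth of
#' computation, and the depth at which it crosses zero estimates the actor's
#' depth. For every recalculation period with at least three depths an
#' ordinary least-squares line in d is fitted; the root of the line is the
#' depth estimate and its standard error follows from the fit covariance by
#' the delta method. Fits that do not cross zero within the depth range are
#' flagged rather than extrapolated silently.
#'
#' @param table a \code{"score_advantage"} table.
#' @return data.frame with columns r, d_hat, se, crossed (FALSE where the
#'   fitted line has non-negative slope or its root lies outside the fitted
#'   depth range).
#' @export
estimate_strategy <- function(table) {
  out <- do.call(rbind, lapply(sort(unique(table$r)), function(rr) {
    sub <- table[table$r == rr, ]
    if (nrow(sub) < 3L) return(NULL)
    fit <- lm(A ~ d, data = sub)
    a <- coef(fit)[1]; b <- coef(fit)[2]
    if (is.na(b) || b >= 0)
      return(data.frame(r = rr, d_hat = NA_real_, se = NA_real_, crossed = FALSE))
    root <- unname(-a / b)
    # exact ideal cohorts produce zero-residual fits; the perfect-fit warning
    # from summary.lm is expected there
    vc <- suppressWarnings(vcov(fit))
    grad <- c(-1 / b, a / b^2)
    se <- sqrt(drop(t(grad) %*% vc %*% grad))
    data.frame(r = rr, d_hat = root, se = se,
               crossed = root >= min(sub$d) && root <= max(sub$d))
  }))
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Heuristic reweighting

#' Reweight disk values to emulate decision heuristics
#'
#' \code{seek_large} merges the k smallest size classes to 1 point (k = 8
#' leaves only 1- and 81-point disks), emulating an actor that only seeks out
#' the largest disks. \code{avoid_small} raises the k largest size classes to
#' 1000 points so that planning is driven solely by avoiding the smallest
#' disks. Membership is by value class, not location. The result carries
#' out-of-catalogue values (1000) for \code{avoid_small} and is intended for
#' planning analyses, not for presentation or serialization.
#'
#' @param stimulus a \code{"stimulus"}.
#' @param mode \code{"seek_large"} or \code{"avoid_small"}.
#' @param k number of merged size classes, 1..8.
#' @return a \code{"stimulus"} with modified values (same id and geometry).
#' @export
reweight_stimulus <- function(stimulus, mode = c("seek_large", "avoid_small"), k) {
  mode <- match.arg(mode)
  if (k < 1 || k > 8) stop("k must be between 1 and 8")
  classes <- sort(disk_values)
  rows <- lapply(stimulus$rows, function(v) {
    if (mode == "seek_large") v[v %in% classes[seq_len(k)]] <- 1
    else v[v %in% classes[(length(classes) - k + 1L):length(classes)]] <- 1000
    v
  })
  structure(list(id = stimulus$id, n_rows = stimulus$n_rows, rows = rows,
                 reweighted = list(mode = mode, k = k)),
            class = "stimulus")
}

#' Reweighting (heuristic) analysis of evidence
#'
#' For each number k of merged size classes, the evidence table is recomputed
#' from the same trials against plans on the reweighted stimuli, and the
#' deviation from the evidence on the unmodified stimuli is summarized over
#' the strategy grid (RMS by default, signed mean optionally). The random
#' baselines of both evidence tables share the same step draws, so a
#' reweighting that leaves the plans unchanged yields a deviation of exactly
#' zero. A cohort whose effective stimulus is already merged at level k (a
#' true heuristic cohort) therefore shows zero deviation at that k, while a
#' full-information cohort shows positive deviations throughout.
#'
#' @param trials trial-log data.frame.
#' @param stimuli list of \code{"stimulus"} objects.
#' @param mode \code{"seek_large"} or \code{"avoid_small"}.
#' @param k_range merge counts to scan (default 1:8).
#' @param strategies strategy grid (default \code{\link{strategy_grid}}).
#' @param N random draws per touch for the evidence denominators.
#' @param deviation \code{"rms"} (default) or \code{"signed_mean"}.
#' @return object of class \code{"heuristic_report"}: data.frame with columns
#'   mode, k, deviation (plus the per-k evidence tables as attribute
#'   \code{"evidence"}).
#' @export
heuristic_rms <- function(trials, stimuli, mode = c("seek_large", "avoid_small"),
                          k_range = 1:8, strategies = strategy_grid(), N = 100L,
                          deviation = c("rms", "signed_mean")) {
  mode <- match.arg(mode)
  deviation <- match.arg(deviation)
  stimuli <- as_stimulus_list(stimuli)
  ctx <- make_vote_context(trials, stimuli, strategies)
  U <- matrix(runif(nrow(ctx$touches) * N), ncol = N)
  e_orig <- evidence_core(ctx, stimuli, U)
  tables <- list()
  dev <- vapply(k_range, function(k) {
    stim_k <- lapply(stimuli, reweight_stimulus, mode = mode, k = k)
    e_k <- evidence_core(ctx, stim_k, U)
    tables[[as.character(k)]] <<- e_k
    delta <- e_k$E - e_orig$E
    delta <- delta[!is.na(delta)]
    if (deviation == "rms") sqrt(mean(delta^2)) else mean(delta)
  }, numeric(1))
  out <- data.frame(mode = mode, k = as.integer(k_range), deviation = dev)
  attr(out, "evidence") <- tables
  attr(out, "evidence_original") <- e_orig
  attr(out, "deviation_type") <- deviation
  class(out) <- c("heuristic_report", "data.frame")
  out
}
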