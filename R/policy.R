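#' Enumerate all per-row depth policies
#'
#' A policy assigns a depth of computation to the step leaving each row
#' (recalculating at every step, r = 1). Because an actor should look to the
#' end of the stimulus whenever possible, the last five entries are forced to
#' the descending tail (5, 4, 3, 2, 1); the free prefix entries each take a
#' value in {0, ..., 5}, where 0 denotes a uniformly random step. For 12 rows
#' this yields 6^6 = 46,656 policies of 11 entries each.
#'
#' @param n_rows number of stimulus rows (default 12; must be at least 7).
#' @return integer matrix, one policy per row, \code{n_rows - 1} columns.
#' @export
enumerate_policies <- function(n_rows = 12L) {
  if (n_rows < 7L) stop("policy enumeration requires at least 7 rows")
  n_free <- n_rows - 6L
  free <- as.matrix(expand.grid(rep(list(0:5), n_free)))[, n_free:1, drop = FALSE]
  tail <- matrix(rep(5:1, each = nrow(free)), nrow = nrow(free))
  m <- cbind(free, tail)
  dimnames(m) <- list(NULL, paste0("row", seq_len(n_rows - 1L) - 1L))
  m
}

#' The fixed maximum-look-ahead policy
#'
#' Depth 5 at every free step followed by the forced descending tail:
#' (5, 5, 5, 5, 5, 5, 5, 4, 3, 2, 1) for 12 rows.
#' @param n_rows number of stimulus rows.
#' @export
max_lookahead_policy <- function(n_rows = 12L) {
  if (n_rows < 7L) stop("requires at least 7 rows")
  c(rep(5L, n_rows - 6L), 5:1)
}

#' Exact expected score fraction of one policy
#'
#' Propagates the actor's position distribution forward one row at a time.
#' At each disk the step direction is the greedy direction of the optimal
#' depth-d plan; ties between equally good first steps (and depth 0) split the
#' probability equally between L and R. The expectation is exact, not
#' simulated, and is expressed per stimulus as a fraction of that stimulus's
#' maximum full-length path score.
#'
#' @param stimuli a \code{"stimulus"} or list of them.
#' @param policy integer vector of depths, one per step; entry i may not
#'   exceed the rows remaining above row i.
#' @return object of class \code{"policy_score"}: list with
#'   \code{per_stimulus_fraction}, \code{mean_fraction}, \code{variance}.
#' @examples
#' f <- fig1_stimulus()
#' policy_expected_fraction(f, c(2, 1))$mean_fraction   # 1: optimum reachable
#' @export
policy_expected_fraction <- function(stimuli, policy) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  fr <- vapply(stimuli, function(s) {
    if (length(policy) != s$n_rows - 1L)
      stop("policy must have one depth per step of the stimulus")
    cpp_policy_expected(stim_values(s), s$n_rows, as.integer(policy)) / max_score(s)
  }, numeric(1))
  structure(list(per_stimulus_fraction = fr,
                 mean_fraction = mean(fr),
                 variance = if (length(fr) > 1L) var(fr) else 0),
            class = "policy_score")
}

#' @export
print.policy_score <- function(x, ...) {
  cat(sprintf("Policy score: mean fraction %.4f over %d stimuli (variance %.3g)\n",
              x$mean_fraction, length(x$per_stimulus_fraction), x$variance))
  invisible(x)
}

#' Expected fractions of every enumerated policy
#'
#' Evaluates all policies from \code{\link{enumerate_policies}} on each
#' stimulus by exact forward propagation (the enumeration shares prefix
#' computations, and the forced tail contributes its dynamic-programming
#' maximum). Rows follow the order of \code{\link{enumerate_policies}}.
#'
#' @param stimuli list of \code{"stimulus"} objects (equal \code{n_rows}).
#' @return numeric matrix of score fractions, policies x stimuli.
#' @export
eval_policies <- function(stimuli) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  n_rows <- stimuli[[1]]$n_rows
  fr <- vapply(stimuli, function(s) {
    if (s$n_rows != n_rows) stop("all stimuli must share n_rows")
    cpp_eval_policies(stim_values(s), s$n_rows) / max_score(s)
  }, numeric(6^(n_rows - 6L)))
  fr
}

#' Rank all policies over a stimulus ensemble
#'
#' Returns the best and worst policies by mean score fraction together with
#' the fixed maximum-look-ahead baseline.
#'
#' @param stimuli list of \code{"stimulus"} objects.
#' @return list of three entries (\code{best}, \code{worst},
#'   \code{max_lookahead}), each holding \code{policy}, \code{mean_fraction}
#'   and \code{variance}, plus \code{mean_fractions} for all policies.
#' @export
rank_policies <- function(stimuli) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  fr <- eval_policies(stimuli)
  mf <- rowMeans(fr)
  vf <- apply(fr, 1L, var)
  pols <- enumerate_policies(stimuli[[1]]$n_rows)
  pick <- function(i) list(policy = unname(pols[i, ]), mean_fraction = mf[i],
                           variance = if (length(stimuli) > 1L) vf[i] else 0)
  ml <- nrow(pols)  # all free depths 5 is the last enumerated policy
  stopifnot(all(pols[ml, ] == max_lookahead_policy(stimuli[[1]]$n_rows)))
  list(best = pick(which.max(mf)), worst = pick(which.min(mf)),
       max_lookahead = pick(ml), mean_fractions = mf)
}
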