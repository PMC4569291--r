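#' Planning strategy (r, d)
#'
#' An ideal planner is parameterized by its depth of computation \code{d} (how
#' many forthcoming rows it evaluates) and its recalculation period \code{r}
#' (how many steps of the computed plan it executes before recomputing).
#' Planners must recalculate when they reach the end of the pre-computed part,
#' hence \code{r <= d}.
#'
#' @param r recalculation period in steps, \code{>= 1}.
#' @param d depth of computation in rows, \code{>= r}.
#' @return an object of class \code{"strategy"}.
#' @export
strategy <- function(r, d) {
  r <- as.integer(r); d <- as.integer(d)
  if (r < 1L) stop("r must be at least 1")
  if (r > d) stop("r must not exceed d")
  structure(list(r = r, d = d), class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("Strategy (r = %d, d = %d)\n", x$r, x$d)); invisible(x)
}

as_strategy <- function(x) {
  if (inherits(x, "strategy")) x else strategy(x[[1]], x[[2]])
}

#' All strategies with r <= d <= dmax
#'
#' The default analysis grid: every pair (r, d) with 1 <= r <= d <= dmax.
#' @param dmax largest depth (default 7, the depth to which diagnostic
#'   stimuli are optimized).
#' @return data.frame with columns \code{r} and \code{d}.
#' @export
strategy_grid <- function(dmax = 7L) {
  d <- rep(seq_len(dmax), times = seq_len(dmax))
  r <- unlist(lapply(seq_len(dmax), seq_len))
  data.frame(r = r, d = d)
}

#' Optimal paths from a disk at bounded depth
#'
#' Finds the maximum cumulative score over all step sequences of length
#' \code{min(d, rows remaining)} from \code{start}, retaining every maximally
#' scoring sequence (ties are kept, as required by the redundancy analysis).
#' Two interchangeable algorithms are provided: plain enumeration of all
#' \code{2^d} paths, and the row-by-row dynamic program that keeps, per
#' reachable disk per level, the best incoming sum.
#'
#' @param stimulus a \code{"stimulus"}.
#' @param start \code{c(row, pos)}, 0-based.
#' @param d depth of computation, \code{>= 1}; silently truncated to the rows
#'   remaining above \code{start}.
#' @param method \code{"dp"} (default) or \code{"bruteforce"}.
#' @return an object of class \code{"plan_result"}: list with \code{max_score},
#'   \code{paths} (list of character step vectors, all ties), and \code{depth}
#'   (the effective depth). A top-row start yields score 0 and no paths.
#' @examples
#' f <- fig1_stimulus()
#' best_paths(f, c(0, 0), d = 2)$max_score   # 97
#' @export
best_paths <- function(stimulus, start = c(0L, 0L), d, method = c("dp", "bruteforce")) {
  method <- match.arg(method)
  check_coord(stimulus, start)
  if (d < 1L) stop("d must be at least 1")
  res <- cpp_plan(stim_values(stimulus), stimulus$n_rows, start[1], start[2], as.integer(d), method)
  structure(list(max_score = res$score,
                 paths = lapply(res$codes, code_to_bits, len = res$depth) |>
                   lapply(bits_to_steps),
                 depth = res$depth),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("Plan: max score %g over %d optimal path(s) at depth %d\n",
              x$max_score, length(x$paths), x$depth))
  invisible(x)
}

#' Traverse a stimulus as an ideal (r, d) planner
#'
#' Starting from the bottom disk the planner repeatedly computes the optimal
#' paths at depth \code{min(d, rows remaining)}, executes the first
#' \code{min(r, plan length)} steps, and recomputes, until it reaches the top
#' row. Among tied optimal plans the default rule takes the lexicographically
#' first sequence (L before R); \code{tie_rule = "random"} draws uniformly,
#' reproducibly under \code{set.seed()}.
#'
#' @param stimulus a \code{"stimulus"}.
#' @param strat a \code{"strategy"} (or a length-2 vector \code{c(r, d)}).
#' @param tie_rule \code{"lexicographic"} or \code{"random"}.
#' @return list with \code{steps} (character), \code{score} (points collected
#'   after the start disk) and \code{strategy}.
#' @examples
#' simulate_actor(fig1_stimulus(), strategy(1, 1))$score   # 80
#' simulate_actor(fig1_stimulus(), strategy(1, 2))$score   # 97
#' @export
simulate_actor <- function(stimulus, strat, tie_rule = c("lexicographic", "random")) {
  tie_rule <- match.arg(tie_rule)
  strat <- as_strategy(strat)
  bits <- cpp_traverse_strategy(stim_values(stimulus), stimulus$n_rows,
                                strat$r, strat$d, tie_rule == "random")
  list(steps = bits_to_steps(bits),
       score = path_score(stimulus, bits),
       strategy = strat)
}

#' Workload of the brute-force search
#'
#' Expected number of elementary operations per step for an (r, d) planner
#' enumerating all 2^d paths: each path costs d summations plus one
#' comparison, recomputed every r steps, giving (d + 1) 2^d / r. Fractional
#' values for r > 1 are per-step averages.
#'
#' @param strat a \code{"strategy"} or \code{c(r, d)}.
#' @return operations per step (numeric).
#' @export
workload_bruteforce <- function(strat) {
  s <- as_strategy(strat)
  (s$d + 1) * 2^s$d / s$r
}

#' Workload of the efficient (dynamic-programming) search
#'
#' Steady-state per-step operation count of the row-by-row search as printed
#' in the source analysis: 3dr - (3/2) r^2 - (1/2) r + 2d. The companion
#' first-step count (a full pass with nothing to reuse) is
#' W1(d) = (3/2) d (d + 1), returned by \code{workload_first_step}. The
#' printed steady-state constant terms differ from the sum of the derivation's
#' intermediate expressions by (d - r); \code{\link{count_operations}} reports
#' instrumented counts so both can be inspected.
#'
#' @param strat a \code{"strategy"} or \code{c(r, d)}.
#' @return operations per recalculation (numeric).
#' @export
workload_efficient <- function(strat) {
  s <- as_strategy(strat)
  3 * s$d * s$r - 1.5 * s$r^2 - 0.5 * s$r + 2 * s$d
}

#' @rdname workload_efficient
#' @param d depth of computation.
#' @export
workload_first_step <- function(d) 1.5 * d * (d + 1)

#' Instrumented operation counts of one search
#'
#' Runs either search once from \code{start} with instrumented counters and
#' returns the summations and comparisons actually performed. For the
#' brute-force search these equal d 2^d and 2^d at effective depth d; for the
#' dynamic program a from-scratch pass totals W1(d) = (3/2) d (d + 1)
#' operations.
#'
#' @inheritParams best_paths
#' @param algorithm \code{"dp"} or \code{"bruteforce"}.
#' @return list with \code{summations} and \code{comparisons}.
#' @export
count_operations <- function(stimulus, start = c(0L, 0L), d,
                             algorithm = c("dp", "bruteforce")) {
  algorithm <- match.arg(algorithm)
  check_coord(stimulus, start)
  cpp_count_ops(stim_values(stimulus), stimulus$n_rows, start[1], start[2],
                as.integer(d), algorithm)
}

#' Maximum full-length path score of a stimulus
#'
#' Convenience wrapper: the dynamic-programming maximum from the start disk
#' with depth equal to the number of rows above it.
#' @param stimulus a \code{"stimulus"}.
#' @export
max_score <- function(stimulus) {
  cpp_best_score(stim_values(stimulus), stimulus$n_rows, 0L, 0L, stimulus$n_rows - 1L)
}
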