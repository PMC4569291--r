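#' Annealing schedule for stimulus design
#'
#' The diagnostic-stimulus designer anneals the temperature from 1 to 0.5 to
#' 0.25 to 0.125, running 1000 / T Metropolis steps at each temperature
#' (15,000 proposals in total per stimulus).
#'
#' @param temperatures strictly decreasing vector of temperatures.
#' @param steps_per_t integer vector of proposal counts per temperature
#'   (default \code{round(1000 / temperatures)}).
#' @return object of class \code{"anneal_schedule"}.
#' @export
anneal_schedule <- function(temperatures = c(1, 0.5, 0.25, 0.125),
                            steps_per_t = round(1000 / temperatures)) {
  if (any(diff(temperatures) >= 0)) stop("temperatures must be strictly decreasing")
  if (length(steps_per_t) != length(temperatures)) stop("one step count per temperature")
  structure(list(temperatures = temperatures, steps_per_t = as.integer(steps_per_t)),
            class = "anneal_schedule")
}

#' Redundancy of one disk for a set of strategies
#'
#' A stimulus is uninformative at a disk when distinct strategies predict
#' overlapping paths from it. The default statistic counts unordered pairs of
#' distinct (r, d) strategies whose stored optimal-plan prefixes, truncated
#' to the pair's smaller effective recalculation period, coincide for at
#' least one tie combination. Because same-depth strategies predict identical
#' plans from a disk and deep strategies collapse near the stimulus top, part
#' of this count is an irreducible floor; the fraction of redundancy the
#' annealer can remove is therefore smaller than under depth-based counting.
#' Two alternatives are kept: \code{count = "depth_pairs"} counts unordered
#' pairs of distinct depths (restricted to depths no larger than the rows
#' remaining) with overlapping optimal-path sets, which anneals away about
#' half of the initial redundancy but yields stimuli that separate depths
#' more strongly than the reference ensemble behaves downstream; and
#' \code{count = "strategies"} counts strategies participating in at least
#' one overlap. The methods vignette compares the three.
#'
#' @param stimulus a \code{"stimulus"}.
#' @param coord \code{c(row, pos)}; a top-row disk has redundancy 0.
#' @param strategies data.frame with columns \code{r}, \code{d}; default all
#'   pairs with \code{1 <= r <= d <= 7} (\code{\link{strategy_grid}}).
#' @param count \code{"pairs"} (default), \code{"depth_pairs"} or
#'   \code{"strategies"}.
#' @return non-negative integer count.
#' @export
disk_redundancy <- function(stimulus, coord, strategies = strategy_grid(),
                            count = c("pairs", "depth_pairs", "strategies")) {
  count <- match.arg(count)
  check_coord(stimulus, coord)
  cpp_disk_redundancy(stim_values(stimulus), stimulus$n_rows, coord[1], coord[2],
                      as.integer(strategies$r), as.integer(strategies$d),
                      c(pairs = 1L, depth_pairs = 0L, strategies = 2L)[[count]])
}

#' Redundancy of a whole stimulus
#'
#' Sums \code{\link{disk_redundancy}} over every disk with at least one row
#' above it.
#'
#' @inheritParams disk_redundancy
#' @param dmax largest depth of the strategy grid (default 7).
#' @return object of class \code{"redundancy_report"}: list with
#'   \code{per_disk} (integer vector in flat bottom-up order) and \code{total}.
#' @export
stimulus_redundancy <- function(stimulus, dmax = 7L,
                                count = c("pairs", "depth_pairs", "strategies")) {
  count <- match.arg(count)
  res <- cpp_stimulus_redundancy(stim_values(stimulus), stimulus$n_rows,
                                 as.integer(dmax),
                                 c(pairs = 1L, depth_pairs = 0L, strategies = 2L)[[count]])
  structure(list(per_disk = res$per_disk, total = res$total),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf("Stimulus redundancy: total %g over %d disks\n",
              x$total, length(x$per_disk)))
  invisible(x)
}

#' Design a diagnostic stimulus by Metropolis annealing
#'
#' Starts from a random assignment of disk values (uniform over the nine
#' squared integers) and minimizes stimulus redundancy: each iteration
#' re-values one uniformly chosen disk with a fresh uniform draw, accepting
#' the change if it lowers the redundancy (or leaves it unchanged) and
#' otherwise with probability exp(-dR / T). Redundancy is recomputed
#' incrementally over the changed disk's cone of influence, which equals the
#' full recomputation exactly.
#'
#' @param n_rows number of rows (default 12).
#' @param schedule an \code{\link{anneal_schedule}}.
#' @param seed optional integer seed (applied via \code{set.seed}).
#' @param init optional initial \code{"stimulus"}; default random.
#' @param dmax largest strategy depth entering the redundancy (default 7).
#' @param count redundancy counting rule, see \code{\link{disk_redundancy}}.
#' @param trace keep the per-iteration trace (default TRUE).
#' @param id label for the designed stimulus.
#' @return list with \code{stimulus}, \code{r_init}, \code{r_final},
#'   \code{reduction} (fractional decrease), \code{per_disk}, and (optionally)
#'   \code{trace}, a data.frame with columns iteration, temperature, delta,
#'   redundancy, accepted.
#' @export
anneal_stimulus <- function(n_rows = 12L, schedule = anneal_schedule(), seed = NULL,
                            init = NULL, dmax = 7L,
                            count = c("pairs", "depth_pairs", "strategies"),
                            trace = TRUE, id = "annealed") {
  count <- match.arg(count)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- random_stimulus(n_rows, id = id)
  else n_rows <- init$n_rows
  res <- cpp_anneal(stim_values(init), n_rows, schedule$temperatures,
                    schedule$steps_per_t, as.integer(dmax),
                    c(pairs = 1L, depth_pairs = 0L, strategies = 2L)[[count]], trace)
  rows <- split(res$values, rep(seq_len(n_rows), seq_len(n_rows)))
  out <- list(stimulus = stimulus(unname(rows), id = id),
              r_init = res$r_init, r_final = res$r_final,
              reduction = if (res$r_init > 0) 1 - res$r_final / res$r_init else 0,
              per_disk = res$per_disk)
  if (trace) out$trace <- as.data.frame(res$trace)
  out
}

#' Design an ensemble of diagnostic stimuli
#'
#' Runs \code{\link{anneal_stimulus}} once per stimulus with seeds
#' \code{base_seed + 0:(n_stimuli - 1)}, so an ensemble is fully identified by
#' \code{(n_stimuli, base_seed)}.
#'
#' @param n_stimuli number of stimuli.
#' @param base_seed integer; run i uses seed \code{base_seed + i - 1}.
#' @param ... passed to \code{\link{anneal_stimulus}}.
#' @return list with \code{stimuli} (list of \code{"stimulus"}) and
#'   \code{runs} (per-run design summaries without traces).
#' @export
anneal_ensemble <- function(n_stimuli, base_seed = 1L, ...) {
  runs <- lapply(seq_len(n_stimuli), function(i) {
    r <- anneal_stimulus(seed = base_seed + i - 1L, trace = FALSE,
                         id = sprintf("annealed_%03d", i), ...)
    r
  })
  list(stimuli = lapply(runs, `[[`, "stimulus"), runs = runs)
}
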