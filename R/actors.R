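#' Probability of stepping left under the sigmoid choice model
#'
#' Maps the depth-limited score difference between the best left-first and
#' best right-first continuations to a choice probability,
#' \code{P_L = plogis(beta * (sL - sR) + eta)}. \code{beta} is the
#' sensitivity: at \code{beta = 1} the better direction is taken about 95\% of
#' the time already at the smallest possible score difference of 3 points.
#' \code{eta} is a leftward bias. (The source text prints the complement of
#' this sigmoid, which contradicts its own description of \code{beta} and
#' \code{eta}; the form used here reproduces the stated behavior.)
#'
#' @param delta score difference \code{sL - sR} in points.
#' @param beta sensitivity (inverse temperature), default 1.
#' @param eta leftward bias, default 0.
#' @return probability of choosing the left step.
#' @examples
#' choice_probability(3, 1, 0)   # ~0.9526
#' @export
choice_probability <- function(delta, beta = 1, eta = 0) {
  plogis(beta * delta + eta)
}

#' Specify a synthetic actor
#'
#' Synthetic actors stand in for human participants. Kinds:
#' \describe{
#'   \item{fixed_strategy}{ideal (r, d) planner.}
#'   \item{random_depth}{redraws the depth uniformly from \code{depth_range}
#'     at every row, recalculating every step (r = 1).}
#'   \item{sigmoid}{depth-d planner whose step is drawn from
#'     \code{\link{choice_probability}} on the depth-limited conditional
#'     scores (r = 1).}
#'   \item{heuristic_seek_large, heuristic_avoid_small}{(r, d) planner that
#'     plans on the reweighted stimulus (see \code{\link{reweight_stimulus}})
#'     with \code{k} merged size classes, but scores on the true one.}
#' }
#' Touches miss the disk with probability \code{miss_prob}; a miss awards
#' \code{penalty} (-1 or -50) instead of the disk's points and the traversal
#' continues from the intended disk.
#'
#' @param kind actor model, see above.
#' @param r,d strategy parameters (d ignored by random_depth).
#' @param depth_range depths drawn by random_depth actors (default 1:5; include
#'   0 to allow uniformly random steps).
#' @param beta,eta sigmoid parameters (scalar or one value per depth).
#' @param k number of reweighted size classes for heuristic actors (1..8).
#' @param miss_prob per-touch miss probability.
#' @param penalty points lost on a miss, -1 or -50.
#' @param speed condition label, \code{"fast"} or \code{"slow"}.
#' @param tie_rule tie rule for optimal plans.
#' @param rt_meanlog location of the log-normal reaction time, per speed
#'   label; reaction times are emitted for pipeline exercise only.
#' @param n number of identical actors this spec expands to.
#' @param id base label for actor ids.
#' @return object of class \code{"actor_spec"}.
#' @export
actor_spec <- function(kind = c("fixed_strategy", "random_depth", "sigmoid",
                                "heuristic_seek_large", "heuristic_avoid_small"),
                       r = 1L, d = 3L, depth_range = 1:5, beta = 1, eta = 0,
                       k = NULL, miss_prob = 0, penalty = -1,
                       speed = c("fast", "slow"),
                       tie_rule = c("lexicographic", "random"),
                       rt_meanlog = c(fast = log(0.8), slow = log(1.3)),
                       n = 1L, id = NULL) {
  kind <- match.arg(kind)
  speed <- match.arg(speed)
  tie_rule <- match.arg(tie_rule)
  if (!penalty %in% c(-1, -50)) stop("penalty must be -1 or -50")
  if (miss_prob < 0 || miss_prob > 1) stop("miss_prob must be in [0, 1]")
  if (kind %in% c("heuristic_seek_large", "heuristic_avoid_small")) {
    if (is.null(k)) stop("heuristic actors need k")
    if (k < 1 || k > 8) stop("k must be between 1 and 8")
  }
  if (kind != "random_depth") strategy(r, d)  # validates r <= d
  if (is.null(id))
    id <- switch(kind,
                 fixed_strategy = sprintf("fixed_r%d_d%d", r, d),
                 random_depth = "random_depth",
                 sigmoid = sprintf("sigmoid_d%d", d),
                 sprintf("%s_k%d_r%d_d%d", kind, k, r, d))
  structure(list(kind = kind, r = as.integer(r), d = as.integer(d),
                 depth_range = as.integer(depth_range), beta = beta, eta = eta,
                 k = k, miss_prob = miss_prob, penalty = penalty, speed = speed,
                 tie_rule = tie_rule, rt_meanlog = rt_meanlog,
                 n = as.integer(n), id = id),
            class = "actor_spec")
}

# One traversal; returns list(bits, depths) where depths[t] is the depth used
# for the step leaving row t-1.
traverse_actor <- function(spec, stimulus) {
  vals <- stim_values(stimulus)
  n <- stimulus$n_rows
  tie_random <- spec$tie_rule == "random"
  switch(spec$kind,
    fixed_strategy = {
      bits <- cpp_traverse_strategy(vals, n, spec$r, spec$d, tie_random)
      list(bits = bits, depths = rep(spec$d, n - 1L))
    },
    random_depth = {
      depths <- sample(spec$depth_range, n - 1L, replace = TRUE)
      bits <- cpp_traverse_depths(vals, n, depths, if (tie_random) 1L else 0L,
                                  spec$beta, spec$eta)
      list(bits = bits, depths = depths)
    },
    sigmoid = {
      depths <- rep(spec$d, n - 1L)
      bits <- cpp_traverse_depths(vals, n, depths, 2L,
                                  rep_len(spec$beta, 7L), rep_len(spec$eta, 7L))
      list(bits = bits, depths = depths)
    },
    {
      mode <- if (spec$kind == "heuristic_seek_large") "seek_large" else "avoid_small"
      plan_stim <- reweight_stimulus(stimulus, mode, spec$k)
      bits <- cpp_traverse_strategy(stim_values(plan_stim), n, spec$r, spec$d, tie_random)
      list(bits = bits, depths = rep(spec$d, n - 1L))
    })
}

#' Simulate a cohort of synthetic actors
#'
#' Every actor spec is expanded to its \code{n} actors; each actor completes
#' \code{n_trials} trials. With \code{assign = "crossed"} each trial set runs
#' over every stimulus; with \code{assign = "random"} each trial uses one
#' uniformly drawn stimulus (as in the large validation cohorts).
#'
#' @param actors an \code{"actor_spec"} or list of them.
#' @param stimuli a \code{"stimulus"} or list of them.
#' @param n_trials trials per actor (per stimulus when crossed); must be >= 1.
#' @param seed optional integer seed.
#' @param assign \code{"crossed"} or \code{"random"}.
#' @param reaction_times emit log-normal reaction times (default TRUE).
#' @return a trial-log data.frame, one row per touch, with columns actor,
#'   kind, stimulus, speed, penalty, trial, touch, row, pos, depth (depth
#'   used for the step leaving this row, NA on the top row), hit, points, rt,
#'   total. The start touch awards 0 points.
#' @export
generate_cohort <- function(actors, stimuli, n_trials = 1L, seed = NULL,
                            assign = c("crossed", "random"),
                            reaction_times = TRUE) {
  assign <- match.arg(assign)
  if (n_trials <= 0L) stop("n_trials must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(actors, "actor_spec")) actors <- list(actors)
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  pieces <- list()
  pi <- 0L
  trial_id <- 0L
  for (spec in actors) {
    for (ai in seq_len(spec$n)) {
      actor_id <- if (spec$n > 1L) sprintf("%s_%04d", spec$id, ai) else spec$id
      reps <- if (assign == "crossed") rep(seq_along(stimuli), n_trials)
              else sample.int(length(stimuli), n_trials, replace = TRUE)
      for (si in reps) {
        stim <- stimuli[[si]]
        n <- stim$n_rows
        trial_id <- trial_id + 1L
        tr <- traverse_actor(spec, stim)
        pos <- c(0L, cumsum(tr$bits))
        row <- 0:(n - 1L)
        vals <- vapply(seq_len(n), function(t) stim$rows[[t]][pos[t] + 1L], numeric(1))
        miss <- c(FALSE, runif(n - 1L) < spec$miss_prob)
        points <- ifelse(miss, spec$penalty, vals)
        points[1] <- 0  # the start disk never scores
        rt <- if (reaction_times)
          rlnorm(n, meanlog = spec$rt_meanlog[[spec$speed]], sdlog = 0.4)
        else NA_real_
        pi <- pi + 1L
        pieces[[pi]] <- list(actor = actor_id, kind = spec$kind,
                             stimulus = stim$id, speed = spec$speed,
                             penalty = spec$penalty, trial = trial_id,
                             touch = row, row = row, pos = pos,
                             depth = c(tr$depths, NA_integer_),
                             hit = !miss, points = points, rt = rt,
                             total = sum(points))
      }
    }
  }
  data.frame(
    actor = rep(vapply(pieces, `[[`, "", "actor"), vapply(pieces, function(p) length(p$row), 0L)),
    kind = rep(vapply(pieces, `[[`, "", "kind"), vapply(pieces, function(p) length(p$row), 0L)),
    stimulus = rep(vapply(pieces, `[[`, "", "stimulus"), vapply(pieces, function(p) length(p$row), 0L)),
    speed = rep(vapply(pieces, `[[`, "", "speed"), vapply(pieces, function(p) length(p$row), 0L)),
    penalty = rep(vapply(pieces, `[[`, 0, "penalty"), vapply(pieces, function(p) length(p$row), 0L)),
    trial = rep(vapply(pieces, `[[`, 0L, "trial"), vapply(pieces, function(p) length(p$row), 0L)),
    touch = unlist(lapply(pieces, `[[`, "touch")),
    row = unlist(lapply(pieces, `[[`, "row")),
    pos = unlist(lapply(pieces, `[[`, "pos")),
    depth = unlist(lapply(pieces, `[[`, "depth")),
    hit = unlist(lapply(pieces, `[[`, "hit")),
    points = unlist(lapply(pieces, `[[`, "points")),
    rt = unlist(lapply(pieces, `[[`, "rt")),
    total = rep(vapply(pieces, `[[`, 0, "total"), vapply(pieces, function(p) length(p$row), 0L)),
    stringsAsFactors = FALSE)
}

#' Read and write trial logs as CSV
#'
#' One row per touch in the format produced by \code{\link{generate_cohort}}.
#' On read, each trial is checked against the lattice: consecutive touches
#' must obey the child relation (row increases by one, position unchanged or
#' incremented), and the stored per-trial totals must equal the recomputed
#' sums of points.
#'
#' @param trials trial-log data.frame.
#' @param file path.
#' @export
write_trials <- function(trials, file) {
  write.csv(trials, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  trials <- read.csv(file, stringsAsFactors = FALSE)
  for (id in unique(trials$trial)) {
    tt <- trials[trials$trial == id, ]
    tt <- tt[order(tt$touch), ]
    dr <- diff(tt$row)
    dp <- diff(tt$pos)
    if (any(dr != 1L))
      stop(sprintf("trial %s: touches skip or repeat a row", id))
    if (any(dp < 0L | dp > 1L))
      stop(sprintf("trial %s: touch violates the child relation", id))
    if (abs(sum(tt$points) - tt$total[1]) > 1e-9)
      stop(sprintf("trial %s: stored total %g does not match recomputed %g",
                   id, tt$total[1], sum(tt$points)))
  }
  trials
}
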