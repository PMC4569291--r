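# Export of the task as a partially observable Markov decision process in the
# pomdp.org text format. Solving (e.g. SARSOP) is delegated to external tools.

#' Build the task POMDP
#'
#' States are all disks of the included stimuli plus one terminal state
#' (\code{theEnd}). Actions are \code{look0..look5} (plan at depth d and take
#' one step) and \code{restart}. A \code{lookd} action from a disk moves to
#' its left child with probability \code{P_L} from
#' \code{\link{choice_probability}} applied to the depth-limited conditional
#' scores (depth 0 steps uniformly); from a top-row disk it moves to
#' \code{theEnd}. \code{restart} is a no-op on disks and redistributes
#' uniformly over the stimulus start disks from \code{theEnd}. Moving onto a
#' disk earns its value minus the linear look cost of d points; all other
#' transitions earn the look cost alone (zero for \code{restart}).
#' Observations are \code{move} after any look and \code{restart} after a
#' restart.
#'
#' @param stimuli list of \code{"stimulus"} objects (the analyses use a
#'   20-stimulus subsample by default).
#' @param beta,eta sigmoid choice parameters (defaults 1 and 0).
#' @param look_penalty cost of looking at depth d, in points (default
#'   \code{function(d) d}, the linear penalty).
#' @param gamma discount factor (default 0.5).
#' @param depths planning depths exposed as actions (default 0:5).
#' @return object of class \code{"pomdp_spec"}: list with \code{states},
#'   \code{actions}, \code{observations}, \code{start} (initial belief),
#'   \code{transitions} (data.frame action/from/to/prob),
#'   \code{rewards} (data.frame action/from/to/reward), \code{gamma}.
#' @export
build_pomdp <- function(stimuli, beta = 1, eta = 0, look_penalty = function(d) d,
                        gamma = 0.5, depths = 0:5) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  if (length(stimuli) == 0L) stop("empty stimulus set")
  stimuli <- as_stimulus_list(stimuli)
  state_of <- function(sid, row, pos) sprintf("%s_%d_%d", sid, row, pos)
  states <- character()
  for (s in stimuli)
    for (row in 0:(s$n_rows - 1L))
      for (pos in 0:row) states <- c(states, state_of(s$id, row, pos))
  states <- c(states, "theEnd")
  actions <- c(sprintf("look%d", depths), "restart")
  act <- character(); from <- character(); to <- character(); prob <- numeric()
  ract <- character(); rfrom <- character(); rto <- character(); rew <- numeric()
  add_t <- function(a, f, t, p) {
    act <<- c(act, a); from <<- c(from, f); to <<- c(to, t); prob <<- c(prob, p)
  }
  add_r <- function(a, f, t, rr) {
    ract <<- c(ract, a); rfrom <<- c(rfrom, f); rto <<- c(rto, t); rew <<- c(rew, rr)
  }
  for (s in stimuli) {
    vals <- stim_values(s)
    n <- s$n_rows
    for (row in 0:(n - 1L)) for (pos in 0:row) {
      sname <- state_of(s$id, row, pos)
      for (d in depths) {
        a <- sprintf("look%d", d)
        if (row == n - 1L) {
          add_t(a, sname, "theEnd", 1)
          add_r(a, sname, "theEnd", -look_penalty(d))
        } else {
          pl <- if (d == 0) 0.5 else {
            cs <- cpp_conditional_scores(vals, n, row, pos, d)
            choice_probability(cs[["sL"]] - cs[["sR"]], beta, eta)
          }
          lname <- state_of(s$id, row + 1L, pos)
          rname <- state_of(s$id, row + 1L, pos + 1L)
          add_t(a, sname, lname, pl)
          add_t(a, sname, rname, 1 - pl)
          add_r(a, sname, lname, s$rows[[row + 2L]][pos + 1L] - look_penalty(d))
          add_r(a, sname, rname, s$rows[[row + 2L]][pos + 2L] - look_penalty(d))
        }
      }
      add_t("restart", sname, sname, 1)
    }
  }
  for (d in depths) add_t(sprintf("look%d", d), "theEnd", "theEnd", 1)
  starts <- vapply(stimuli, function(s) state_of(s$id, 0L, 0L), "")
  for (st in starts) add_t("restart", "theEnd", st, 1 / length(starts))
  start_belief <- as.numeric(states %in% starts) / length(starts)
  structure(list(states = states, actions = actions,
                 observations = c("move", "restart"),
                 start = start_belief,
                 transitions = data.frame(action = act, from = from, to = to,
                                          prob = prob, stringsAsFactors = FALSE),
                 rewards = data.frame(action = ract, from = rfrom, to = rto,
                                      reward = rew, stringsAsFactors = FALSE),
                 gamma = gamma),
            class = "pomdp_spec")
}

#' @export
print.pomdp_spec <- function(x, ...) {
  cat(sprintf("POMDP: %d states, %d actions, %d observations, gamma = %g\n",
              length(x$states), length(x$actions), length(x$observations), x$gamma))
  invisible(x)
}

# every (action, state) transition row must sum to 1
check_pomdp <- function(spec, tol = 1e-12) {
  tt <- spec$transitions
  sums <- tapply(tt$prob, list(paste(tt$action, tt$from, sep = "\r")), sum)
  covered <- expand.grid(a = spec$actions, s = spec$states)
  keys <- paste(covered$a, covered$s, sep = "\r")
  miss <- setdiff(keys, names(sums))
  if (length(miss)) stop("transition rows missing for some (action, state) pairs")
  bad <- which(abs(sums - 1) > tol)
  if (length(bad))
    stop(sprintf("transition probabilities do not sum to 1 (first offender: %s)",
                 gsub("\r", " / ", names(sums)[bad[1]])))
  invisible(TRUE)
}

#' Write and read a POMDP in the pomdp.org format
#'
#' Writes a sparse \code{.pomdp} file (one \code{T:}/\code{R:} line per
#' non-zero entry, wildcard observation rows) with deterministic ordering, so
#' output is byte-stable across runs. A spec whose transition rows do not sum
#' to one is refused. \code{read_pomdp} parses the same dialect back (for
#' round-trip checks and for inspecting solver inputs); it supports the
#' subset of the format that \code{write_pomdp} emits.
#'
#' @param spec a \code{"pomdp_spec"}.
#' @param file path to the \code{.pomdp} file.
#' @return \code{read_pomdp}: a \code{"pomdp_spec"}.
#' @export
write_pomdp <- function(spec, file) {
  check_pomdp(spec)
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# multi-step lattice traversal task")
  w("discount: %s", fmt(spec$gamma))
  w("values: reward")
  w("states: %s", paste(spec$states, collapse = " "))
  w("actions: %s", paste(spec$actions, collapse = " "))
  w("observations: %s", paste(spec$observations, collapse = " "))
  w("start: %s", paste(fmt(spec$start), collapse = " "))
  tt <- spec$transitions
  tt <- tt[order(tt$action, tt$from, tt$to), ]
  for (i in seq_len(nrow(tt)))
    w("T: %s : %s : %s %s", tt$action[i], tt$from[i], tt$to[i], fmt(tt$prob[i]))
  for (a in spec$actions) {
    obs <- if (a == "restart") "restart" else "move"
    w("O: %s : * : %s 1.0", a, obs)
  }
  rr <- spec$rewards
  rr <- rr[order(rr$action, rr$from, rr$to), ]
  rr <- rr[rr$reward != 0, ]
  for (i in seq_len(nrow(rr)))
    w("R: %s : %s : %s : * %s", rr$action[i], rr$from[i], rr$to[i], fmt(rr$reward[i]))
  invisible(file)
}

#' @rdname write_pomdp
#' @export
read_pomdp <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  val <- function(key) sub(paste0("^", key, ":\\s*"), "", lines[startsWith(lines, paste0(key, ":"))][1])
  states <- strsplit(val("states"), "\\s+")[[1]]
  actions <- strsplit(val("actions"), "\\s+")[[1]]
  observations <- strsplit(val("observations"), "\\s+")[[1]]
  start <- as.numeric(strsplit(val("start"), "\\s+")[[1]])
  parse_sparse <- function(prefix, n_fields) {
    sel <- lines[startsWith(lines, prefix)]
    if (!length(sel)) return(NULL)
    parts <- lapply(sel, function(l) {
      body <- sub(paste0("^", prefix, "\\s*"), "", l)
      fields <- trimws(strsplit(body, ":", fixed = TRUE)[[1]])
      tail_bits <- strsplit(fields[n_fields], "\\s+")[[1]]
      c(fields[-n_fields], tail_bits)
    })
    do.call(rbind, parts)
  }
  tt <- parse_sparse("T:", 3L)
  rr <- parse_sparse("R:", 4L)
  transitions <- data.frame(action = tt[, 1], from = tt[, 2], to = tt[, 3],
                            prob = as.numeric(tt[, 4]), stringsAsFactors = FALSE)
  rewards <- if (is.null(rr)) NULL else
    data.frame(action = rr[, 1], from = rr[, 2], to = rr[, 3],
               reward = as.numeric(rr[, 5]), stringsAsFactors = FALSE)
  structure(list(states = states, actions = actions, observations = observations,
                 start = start, transitions = transitions, rewards = rewards,
                 gamma = as.numeric(val("discount"))),
            class = "pomdp_spec")
}
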