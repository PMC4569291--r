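#' @useDynLib lookahead, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm plogis rlnorm runif sd var vcov
#' @importFrom utils read.csv write.csv
NULL

#' Legal disk values
#'
#' Disk worth is one point per unit of disk area; the nine admissible values
#' are the squared integers 1, 4, 9, ..., 81.
#' @export
disk_values <- c(1, 4, 9, 16, 25, 36, 49, 64, 81)

#' Construct a triangular-lattice stimulus
#'
#' A stimulus is a triangular lattice of valued disks: row \code{k} (0-based,
#' bottom row first) contains \code{k + 1} disks, so a stimulus with
#' \code{n_rows} rows has \code{n_rows (n_rows + 1) / 2} disks (78 for the
#' canonical 12 rows). Every disk value must be one of \code{\link{disk_values}}.
#'
#' @param rows list of numeric vectors, bottom row first; element \code{k}
#'   must have length \code{k}.
#' @param id character label.
#' @return an object of class \code{"stimulus"}: a list with elements
#'   \code{id}, \code{n_rows} and \code{rows}.
#' @examples
#' s <- stimulus(list(1, c(16, 64), c(81, 9, 16)), id = "toy")
#' n_disks(s)
#' @export
stimulus <- function(rows, id = "stim") {
  rows <- lapply(rows, as.numeric)
  x <- structure(list(id = as.character(id), n_rows = length(rows), rows = rows),
                 class = "stimulus")
  validate_stimulus(x)
  x
}

#' Validate a stimulus object
#'
#' Checks the triangular row structure and that every disk value is a legal
#' squared integer, naming the offending disk on failure.
#' @param x a \code{"stimulus"}.
#' @return \code{x}, invisibly.
#' @export
validate_stimulus <- function(x) {
  if (!inherits(x, "stimulus")) stop("not a stimulus object")
  if (x$n_rows < 1L || length(x$rows) != x$n_rows) stop("missing or extra rows")
  for (k in seq_len(x$n_rows)) {
    v <- x$rows[[k]]
    if (length(v) != k)
      stop(sprintf("row %d must contain %d disks, found %d", k - 1L, k, length(v)))
    bad <- which(!(v %in% disk_values))
    if (length(bad))
      stop(sprintf("illegal disk value %s at row %d, pos %d (must be a squared integer 1..81)",
                   format(v[bad[1]]), k - 1L, bad[1] - 1L))
  }
  invisible(x)
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("Stimulus '%s': %d rows, %d disks\n", x$id, x$n_rows, n_disks(x)))
  for (k in rev(seq_len(x$n_rows)))
    cat(sprintf("  row %2d: %s\n", k - 1L, paste(format(x$rows[[k]]), collapse = " ")))
  invisible(x)
}

#' Number of disks in a stimulus
#' @param x a \code{"stimulus"}.
#' @export
n_disks <- function(x) x$n_rows * (x$n_rows + 1L) / 2L

# Flat value vector, row-major bottom-up; disk (row, pos) sits at
# row (row + 1) / 2 + pos + 1 (1-based).
stim_values <- function(x) unlist(x$rows, use.names = FALSE)

disk_index <- function(row, pos) row * (row + 1L) / 2L + pos + 1L

#' Value of one disk
#' @param x a \code{"stimulus"}.
#' @param coord integer vector \code{c(row, pos)}, both 0-based from the
#'   bottom-left.
#' @export
disk_value <- function(x, coord) {
  check_coord(x, coord)
  x$rows[[coord[1] + 1L]][coord[2] + 1L]
}

check_coord <- function(x, coord) {
  if (length(coord) != 2L) stop("coord must be c(row, pos)")
  row <- coord[1]; pos <- coord[2]
  if (row < 0 || row >= x$n_rows) stop(sprintf("row %d outside stimulus", row))
  if (pos < 0 || pos > row) stop(sprintf("pos %d illegal on row %d", pos, row))
  invisible(coord)
}

#' Children of a disk
#'
#' From disk (row, pos) only the two disks just above can be reached: step L
#' keeps the position, step R increments it.
#'
#' @param coord \code{c(row, pos)}, 0-based.
#' @param stimulus a \code{"stimulus"}.
#' @return list with elements \code{left} and \code{right}, each \code{c(row, pos)}.
#' @export
children <- function(coord, stimulus) {
  check_coord(stimulus, coord)
  if (coord[1] >= stimulus$n_rows - 1L)
    stop("top-row disk has no children")
  list(left = c(coord[1] + 1L, coord[2]), right = c(coord[1] + 1L, coord[2] + 1L))
}

# "L"/"R" character steps <-> integer 0/1 <-> packed bit code (bit i = step i+1)
steps_to_bits <- function(steps) {
  if (is.character(steps)) {
    if (length(steps) && any(!steps %in% c("L", "R"))) stop("steps must be 'L' or 'R'")
    as.integer(steps == "R")
  } else as.integer(steps)
}
bits_to_steps <- function(bits) if (length(bits)) c("L", "R")[bits + 1L] else character()
code_to_bits <- function(code, len) if (len) as.integer(bitwAnd(bitwShiftR(code, 0:(len - 1L)), 1L)) else integer()
bits_to_code <- function(bits) if (length(bits)) sum(bits * 2L^(seq_along(bits) - 1L)) else 0L

#' Score of a path across a stimulus
#'
#' Sums the values of the disks stepped onto after the start disk (the start
#' disk's own value is never counted: the worked three-row example totals
#' 64 + 16 = 80 for the depth-1 route and 16 + 81 = 97 for the depth-2 route).
#'
#' @param stimulus a \code{"stimulus"}.
#' @param steps character vector of \code{"L"}/\code{"R"} moves (or integer
#'   0/1); may be empty.
#' @param start \code{c(row, pos)} of the start disk (default bottom disk).
#' @return total points, a single number.
#' @export
path_score <- function(stimulus, steps, start = c(0L, 0L)) {
  check_coord(stimulus, start)
  bits <- steps_to_bits(steps)
  if (length(bits) == 0L) return(0)
  row <- start[1]; pos <- start[2]
  if (row + length(bits) > stimulus$n_rows - 1L)
    stop("path leaves the lattice")
  total <- 0
  for (b in bits) {
    row <- row + 1L
    pos <- pos + b
    total <- total + stimulus$rows[[row + 1L]][pos + 1L]
  }
  total
}

#' The worked three-row example stimulus
#'
#' The introductory decision tree: 16 and 64 points on the second row; 81 and
#' 16 points on the reachable corners of the third row. A depth-1 planner
#' steps right twice and collects 80 points; a depth-2 planner steps left
#' twice and collects 97. The unconstrained middle disk of the top row is not
#' printed in the source figure and is fixed at 9 points (the narrative
#' requires any legal value below 16).
#'
#' @return a 3-row \code{"stimulus"} with id \code{"fig1"}.
#' @export
fig1_stimulus <- function() {
  stimulus(list(1, c(16, 64), c(81, 9, 16)), id = "fig1")
}

#' Random stimulus with uniform disk values
#'
#' Draws every disk value independently and uniformly from the nine squared
#' integers; this is the initial condition of the stimulus-design annealer.
#'
#' @param n_rows number of rows (default 12).
#' @param id label.
#' @export
random_stimulus <- function(n_rows = 12L, id = "random") {
  rows <- lapply(seq_len(n_rows), function(k) sample(disk_values, k, replace = TRUE))
  stimulus(rows, id = id)
}

#' Read and write stimuli as JSON
#'
#' The file holds a JSON array of objects \code{{"id", "n_rows", "rows"}} with
#' rows listed bottom-up; the round trip is lossless and every stimulus is
#' validated on read.
#'
#' @param file path.
#' @param stimuli list of \code{"stimulus"} objects (or a single one).
#' @return \code{read_stimuli}: a list of \code{"stimulus"} objects.
#' @export
read_stimuli <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  lapply(raw, function(s) {
    if (is.null(s$rows)) stop("stimulus entry without rows")
    if (!is.null(s$n_rows) && length(s$rows) != s$n_rows)
      stop(sprintf("stimulus '%s': n_rows is %d but %d rows present",
                   as.character(s$id), s$n_rows, length(s$rows)))
    stimulus(lapply(s$rows, function(r) unlist(r)), id = if (is.null(s$id)) "stim" else s$id)
  })
}

#' @rdname read_stimuli
#' @export
write_stimuli <- function(stimuli, file) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  lapply(stimuli, validate_stimulus)
  payload <- lapply(stimuli, function(s)
    list(id = s$id, n_rows = s$n_rows, rows = lapply(s$rows, as.numeric)))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
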