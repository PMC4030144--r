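#' Construct an external input schedule
#'
#' A schedule is a set of (unit, onset, offset, magnitude) windows in
#' cycles. A window with onset `t0` and offset `t1` injects its magnitude
#' into the unit's net input during update cycles `t0 + 1, ..., t1`
#' (0-based cycle indices: the input "arrives" after `t0` cycles have
#' elapsed).
#'
#' @param unit character vector of unit ids.
#' @param onset,offset integer vectors of onset/offset cycles
#'   (onset < offset).
#' @param magnitude numeric vector of input magnitudes (>= 0), recycled.
#' @return An object of class `input_schedule` (a data frame).
#' @examples
#' input_schedule("location_target", 0, 50, 2)
#' @export
input_schedule <- function(unit = character(), onset = integer(),
                           offset = integer(), magnitude = numeric()) {
  d <- data.frame(unit = as.character(unit), onset = as.numeric(onset),
                  offset = as.numeric(offset),
                  magnitude = as.numeric(magnitude),
                  stringsAsFactors = FALSE)
  if (nrow(d) > 0L) {
    if (any(!is.finite(d$onset)) || any(!is.finite(d$offset)) ||
        any(!is.finite(d$magnitude))) {
      stop("schedule entries must be finite", call. = FALSE)
    }
    if (any(d$onset >= d$offset)) {
      stop("every schedule entry needs onset < offset", call. = FALSE)
    }
    if (any(d$magnitude < 0)) {
      stop("input magnitudes must be >= 0", call. = FALSE)
    }
  }
  class(d) <- c("input_schedule", "data.frame")
  d
}

#' Staggered-onset schedule for the input timing protocol
#'
#' Builds the canonical perceptual-timing schedule for a target sign:
#' location and orientation input from cycle 0, handshape from cycle 3
#' (about 30 ms at 10 ms/cycle) and movement from cycle 10, mirroring the
#' order in which signers identify the parameters. Only the target's own
#' sub-lexical units are scheduled; a neighbor receives input solely
#' through its shared unit.
#'
#' In `"cumulative"` mode every input stays on through `n_cycles` once it
#' has started (features remain visible once articulated). In
#' `"exclusive"` mode the windows partition the run: location/orientation
#' for cycles 0-3, handshape 3-10, movement 10-`n_cycles`.
#'
#' @param target a [sign_form()].
#' @param input_level input magnitude applied to every scheduled unit.
#' @param n_cycles trial length in cycles (> 10).
#' @param mode `"cumulative"` (default) or `"exclusive"`.
#' @return An [input_schedule()] with four entries.
#' @export
make_timing_schedule <- function(target = sign_form("target"),
                                 input_level = 2,
                                 n_cycles = 100,
                                 mode = c("cumulative", "exclusive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "sign_form"))
  if (n_cycles <= 10) {
    stop("n_cycles must exceed the last onset cycle (10)", call. = FALSE)
  }
  if (input_level <= 0) stop("input_level must be > 0", call. = FALSE)
  onsets <- c(location = 0, orientation = 0, handshape = 3, movement = 10)
  offsets <- if (mode == "cumulative") {
    rep(n_cycles, 4L)
  } else {
    c(location = 3, orientation = 3, handshape = 10, movement = n_cycles)
  }
  input_schedule(unit = unname(target$slots[names(onsets)]),
                 onset = unname(onsets),
                 offset = unname(offsets),
                 magnitude = input_level)
}

#' Simultaneous constant-input schedule on the target's units
#'
#' All four of the target's sub-lexical units receive the same magnitude
#' from cycle 0 through `n_cycles`.
#'
#' @inheritParams make_timing_schedule
#' @return An [input_schedule()].
#' @export
make_simultaneous_schedule <- function(target = sign_form("target"),
                                       input_level = 1,
                                       n_cycles = 100) {
  if (input_level <= 0) stop("input_level must be > 0", call. = FALSE)
  input_schedule(unit = unname(target$slots), onset = 0,
                 offset = n_cycles, magnitude = input_level)
}

#' Expand a schedule into a cycle-by-unit external input matrix
#'
#' @param schedule an [input_schedule()].
#' @param unit_ids character vector of all unit ids, in network order.
#' @param n_cycles number of update cycles.
#' @return An `n_cycles` x `length(unit_ids)` matrix; row `c` is the
#'   external input vector used for update cycle `c`.
#' @keywords internal
schedule_matrix <- function(schedule, unit_ids, n_cycles) {
  unknown <- setdiff(schedule$unit, unit_ids)
  if (length(unknown) > 0L) {
    stop("schedule references unknown unit id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ext <- matrix(0, nrow = n_cycles, ncol = length(unit_ids),
                dimnames = list(NULL, unit_ids))
  for (i in seq_len(nrow(schedule))) {
    j <- match(schedule$unit[i], unit_ids)
    from <- floor(schedule$onset[i]) + 1L
    to <- min(floor(schedule$offset[i]), n_cycles)
    if (from <= to) {
      ext[from:to, j] <- ext[from:to, j] + schedule$magnitude[i]
    }
  }
  ext
}
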