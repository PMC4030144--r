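#' Activation-gated lateral inhibition weight
#'
#' The inhibitory weight a lexical unit exerts on its competitors is a
#' steep logistic function of the *sending* unit's own activation:
#' \deqn{y(a) = \frac{s}{d + e^{-\beta (a - x_0)}}}
#' with steepness `beta`, midpoint `x0`, scale `s = gain_scale` and
#' denominator constant `d = gain_denom`. The weight is strictly positive,
#' strictly increasing in `a`, and saturates at `gain_scale / gain_denom`;
#' far below the midpoint it vanishes, so weakly active units exert
#' essentially no inhibition. This gating is what lets a weak neighbor be
#' a net helper (its feedback outweighs its negligible inhibition) while a
#' strong neighbor is a net competitor.
#'
#' @param a_sender activation of the sending unit (vectorized).
#' @param params an [activation_params()].
#' @return Inhibitory weight(s), same length as `a_sender`.
#' @examples
#' p <- activation_params()
#' inhibition_gain(p$x0, p) # 1 / (51.5 + 1)
#' @export
inhibition_gain <- function(a_sender, params = activation_params()) {
  params$gain_scale /
    (params$gain_denom + exp(-params$beta * (a_sender - params$x0)))
}

#' Create the initial network state for a topology
#'
#' @param topology a `sign_topology`.
#' @param params an [activation_params()].
#' @param rest_overrides optional named numeric vector of per-unit resting
#'   activations; unnamed units use `params$rest`.
#' @return An object of class `network_state`: named `activation` and
#'   `rest` vectors (activation equals rest) and `cycle_index = 0`.
#' @export
initial_state <- function(topology, params = activation_params(),
                          rest_overrides = NULL) {
  ids <- topology$units$id
  rest <- stats::setNames(rep(params$rest, length(ids)), ids)
  if (!is.null(rest_overrides)) {
    bad <- setdiff(names(rest_overrides), ids)
    if (length(bad) > 0L) {
      stop("rest_overrides name unknown unit(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(rest_overrides < params$a_min | rest_overrides > params$a_max)) {
      stop("rest_overrides must lie in [a_min, a_max]", call. = FALSE)
    }
    rest[names(rest_overrides)] <- rest_overrides
  }
  structure(list(activation = rest, rest = rest, cycle_index = 0L),
            class = "network_state")
}

# Internal: connection matrices for fast updates.
# M:   n_lex x n_sub membership indicator
# Inh: n_lex x n_lex indicator, Inh[i, j] = 1 if lexical j inhibits i
topology_matrices <- function(topology) {
  units <- topology$units
  sub_ids <- units$id[units$layer == "sublexical"]
  lex_ids <- units$id[units$layer == "lexical"]
  M <- matrix(0, nrow = length(lex_ids), ncol = length(sub_ids),
              dimnames = list(lex_ids, sub_ids))
  for (lex in names(topology$membership)) {
    M[lex, topology$membership[[lex]]] <- 1
  }
  Inh <- matrix(0, nrow = length(lex_ids), ncol = length(lex_ids),
                dimnames = list(lex_ids, lex_ids))
  if (nrow(topology$inhibition) > 0L) {
    Inh[cbind(match(topology$inhibition$to, lex_ids),
              match(topology$inhibition$from, lex_ids))] <- 1
  }
  list(sub_ids = sub_ids, lex_ids = lex_ids, M = M, Inh = Inh)
}

# Internal: net input given activation vector ordered (sub, lex).
net_input_raw <- function(a, mats, params, external) {
  ns <- length(mats$sub_ids)
  nl <- length(mats$lex_ids)
  out <- pmax(a, 0)
  out_sub <- out[seq_len(ns)]
  out_lex <- out[ns + seq_len(nl)]
  a_lex <- a[ns + seq_len(nl)]
  g <- inhibition_gain(a_lex, params)
  net_sub <- params$excitation_fb * as.numeric(crossprod(mats$M, out_lex))
  net_lex <- params$excitation_ff * as.numeric(mats$M %*% out_sub) -
    as.numeric(mats$Inh %*% (g * out_lex))
  c(net_sub, net_lex) + params$input_strength * external
}

#' Net input to every unit
#'
#' For a sub-lexical unit the net input is feedback excitation from its
#' member lexical units plus scaled external input; for a lexical unit it
#' is feedforward excitation from its four sub-lexical members minus
#' activation-gated inhibition from every other lexical unit, plus scaled
#' external input. Only positive activations are transmitted
#' (`output(u) = max(a_u, 0)`); there are no self-connections.
#'
#' @param state a `network_state` from [initial_state()] or [step()].
#' @param topology the `sign_topology` the state belongs to.
#' @param params an [activation_params()].
#' @param external named or unnamed numeric vector of external input, one
#'   entry per unit in `topology$units$id` order.
#' @return Named numeric vector of net inputs.
#' @export
net_input <- function(state, topology, params = activation_params(),
                      external = NULL) {
  ids <- topology$units$id
  if (length(state$activation) != length(ids)) {
    stop("state and topology dimensions disagree", call. = FALSE)
  }
  if (is.null(external)) external <- rep(0, length(ids))
  if (length(external) != length(ids)) {
    stop("external must have one entry per unit", call. = FALSE)
  }
  mats <- topology_matrices(topology)
  ord <- c(mats$sub_ids, mats$lex_ids)
  a <- state$activation[ord]
  ext <- if (!is.null(names(external))) external[ord] else
    external[match(ord, ids)]
  net <- net_input_raw(a, mats, params, as.numeric(ext))
  stats::setNames(net, ord)[ids]
}

# Internal: one synchronous update of the ordered activation vector.
step_raw <- function(a, rest, decay, mats, params, external) {
  net <- net_input_raw(a, mats, params, external)
  delta <- ifelse(net > 0,
                  net * (params$a_max - a),
                  net * (a - params$a_min))
  delta <- delta - decay * (a - rest)
  a2 <- a + params$step_size * delta
  if (any(!is.finite(a2))) {
    stop("non-finite activation after update; check parameter values",
         call. = FALSE)
  }
  pmin(pmax(a2, params$a_min), params$a_max)
}

#' One synchronous update cycle
#'
#' All units are updated from the previous state simultaneously. If the
#' net input is positive the activation moves toward the ceiling in
#' proportion to the remaining headroom, otherwise toward the floor in
#' proportion to the remaining depth; a decay term then pulls the unit
#' back toward its resting level, the whole change is scaled by
#' `step_size`, and the result is clipped to `[a_min, a_max]`. A
#' non-finite activation aborts with an error rather than being clipped
#' silently.
#'
#' @inheritParams net_input
#' @return The updated `network_state` with `cycle_index` incremented.
#' @export
step <- function(state, topology, params = activation_params(),
                 external = NULL) {
  ids <- topology$units$id
  if (is.null(external)) external <- rep(0, length(ids))
  mats <- topology_matrices(topology)
  ord <- c(mats$sub_ids, mats$lex_ids)
  decay <- c(rep(params$decay_sub, length(mats$sub_ids)),
             rep(params$decay_lex, length(mats$lex_ids)))
  ext <- if (!is.null(names(external))) external[ord] else
    external[match(ord, ids)]
  a2 <- step_raw(state$activation[ord], state$rest[ord], decay, mats,
                 params, as.numeric(ext))
  structure(list(
    activation = stats::setNames(a2, ord)[ids],
    rest = state$rest,
    cycle_index = state$cycle_index + 1L
  ), class = "network_state")
}

#' Run a full trial
#'
#' Iterates [step()] for `n_cycles` synchronous cycles under an external
#' input schedule, recording every unit's activation at every cycle. The
#' run is fully deterministic: identical inputs give identical
#' trajectories.
#'
#' @param topology a `sign_topology`.
#' @param params an [activation_params()].
#' @param schedule an [input_schedule()]; entries must reference units in
#'   the topology.
#' @param n_cycles number of cycles (>= 1).
#' @param rest_overrides optional named vector of per-unit resting
#'   activations (see [initial_state()]).
#' @return An object of class `sign_trajectory`: a list with `activation`
#'   (an `(n_cycles + 1) x n_units` matrix, row 1 = cycle 0 = rest),
#'   `units`, `params`, `schedule` and `rest`.
#' @examples
#' tp <- build_topology(spec = neighbor_spec("handshape", 1))
#' tr <- run_trial(tp, schedule = make_timing_schedule(n_cycles = 50),
#'                 n_cycles = 50)
#' tail(target_activation(tr), 3)
#' @export
run_trial <- function(topology, params = activation_params(),
                      schedule = input_schedule(), n_cycles = 100,
                      rest_overrides = NULL) {
  stopifnot(n_cycles >= 1)
  validate_params(params)
  ids <- topology$units$id
  mats <- topology_matrices(topology)
  ord <- c(mats$sub_ids, mats$lex_ids)
  state0 <- initial_state(topology, params, rest_overrides)
  ext <- schedule_matrix(schedule, ord, n_cycles)
  decay <- c(rep(params$decay_sub, length(mats$sub_ids)),
             rep(params$decay_lex, length(mats$lex_ids)))

  traj <- matrix(NA_real_, nrow = n_cycles + 1L, ncol = length(ord),
                 dimnames = list(NULL, ord))
  a <- state0$activation[ord]
  rest <- state0$rest[ord]
  traj[1L, ] <- a
  for (cyc in seq_len(n_cycles)) {
    a <- step_raw(a, rest, decay, mats, params, ext[cyc, ])
    traj[cyc + 1L, ] <- a
  }
  structure(list(
    activation = traj[, ids, drop = FALSE],
    units = topology$units,
    params = params,
    schedule = schedule,
    rest = stats::setNames(rest, ord)[ids],
    target = topology$target
  ), class = "sign_trajectory")
}

#' Extract a single unit's activation series from a trajectory
#'
#' @param trajectory a `sign_trajectory`.
#' @param unit unit id; defaults to the trajectory's target lexical unit.
#' @return Numeric vector of length `n_cycles + 1` (cycle 0 first).
#' @export
target_activation <- function(trajectory, unit = trajectory$target) {
  if (!unit %in% colnames(trajectory$activation)) {
    stop("unknown unit id: ", unit, call. = FALSE)
  }
  trajectory$activation[, unit]
}

#' @export
print.sign_trajectory <- function(x, ...) {
  cat(sprintf("<sign_trajectory> %d cycles x %d units (target '%s')\n",
              nrow(x$activation) - 1L, ncol(x$activation), x$target))
  fin <- x$activation[nrow(x$activation), x$target]
  cat(sprintf("  final target activation: %.6f\n", fin))
  invisible(x)
}

#' Time (in cycles) for a unit to reach an activation threshold
#'
#' Linearly interpolates between the cycles bracketing the first crossing;
#' returns 0 if the series starts at or above the threshold and `Inf` if
#' it never reaches it.
#'
#' @param activation numeric activation series (cycle 0 first) or a
#'   `sign_trajectory` (target unit used).
#' @param threshold activation level to reach.
#' @return Crossing time in (fractional) cycles.
#' @export
time_to_threshold <- function(activation, threshold = 0.5) {
  if (inherits(activation, "sign_trajectory")) {
    activation <- target_activation(activation)
  }
  i <- which(activation >= threshold)[1L]
  if (is.na(i)) return(Inf)
  if (i == 1L) return(0)
  (i - 2L) + (threshold - activation[i - 1L]) /
    (activation[i] - activation[i - 1L])
}
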