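#' Simulation 1: sub-lexical input timing
#'
#' Tests whether the order in which a sign's sub-lexical parameters become
#' available in perception determines the polarity of a neighbor's net
#' effect. The target's units receive input with staggered onsets
#' (location/orientation at cycle 0, handshape at cycle 3, movement at
#' cycle 10); a neighbor shares either an onset-0 unit ("early_shared",
#' the location case) or the cycle-3 unit ("late_shared", the handshape
#' case). Both are compared against the same no-neighbor baseline.
#'
#' Expected pattern: the early-shared neighbor turns on with the earliest
#' input, races the target, becomes strongly active and nets inhibition;
#' the late-shared neighbor only starts once the target is already ahead,
#' stays weak, and its shared-unit feedback nets facilitation.
#'
#' @param input_level external input magnitude (nominal scale; multiplied
#'   by `params$input_strength` inside the dynamics).
#' @param n_cycles trial length in cycles.
#' @param params an [activation_params()].
#' @param mode input persistence mode, see [make_timing_schedule()].
#' @param threshold recognition threshold for the net-effect summary.
#' @return A data frame with one row per condition (`early_shared`,
#'   `late_shared`) and the [net_effect()] summaries. The full
#'   `net_effect` objects and trajectories are attached as attributes
#'   `"effects"` and `"trajectories"`.
#' @examples
#' run_simulation_1(n_cycles = 50)[, c("condition", "label")]
#' @export
run_simulation_1 <- function(input_level = 2, n_cycles = 100,
                             params = activation_params(),
                             mode = c("cumulative", "exclusive"),
                             threshold = 0.5) {
  mode <- match.arg(mode)
  target <- sign_form("target")
  schedule <- make_timing_schedule(target, input_level, n_cycles, mode)

  base_tp <- build_topology(target, neighbor_spec(n_neighbors = 0L))
  base <- run_trial(base_tp, params, schedule, n_cycles)

  conds <- list(early_shared = "location", late_shared = "handshape")
  effects <- list()
  trajs <- list(baseline = base)
  rows <- list()
  for (nm in names(conds)) {
    tp <- build_topology(target, neighbor_spec(conds[[nm]], 1L))
    tr <- run_trial(tp, params, schedule, n_cycles)
    eff <- net_effect(tr, base, threshold = threshold)
    effects[[nm]] <- eff
    trajs[[nm]] <- tr
    rows[[nm]] <- effect_row("timing", nm, input_level, 1L, eff)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "effects") <- effects
  attr(out, "trajectories") <- trajs
  out
}

#' Simulation 2: sub-lexical resting activation
#'
#' Tests whether differences in how robustly sub-lexical units are encoded
#' (modeled as resting activation, a stand-in for sub-lexical frequency)
#' determine the polarity of a neighbor's net effect. The network carries
#' one fixed rest profile: the target's location unit rests at
#' `high_rest` (default 0.7) and every other sub-lexical unit at
#' `low_rest` (default 0.1). All four target units receive the same input
#' simultaneously. The neighbor shares either the high-rest unit
#' ("high_rest_shared", the frequent-location case) or a low-rest unit
#' ("low_rest_shared", the rare-handshape case); both conditions are
#' compared against the same no-neighbor baseline with an identical rest
#' profile on the target's units.
#'
#' @param input_level external input magnitude.
#' @param high_rest resting activation of the frequent (location) unit.
#' @param low_rest resting activation of every other sub-lexical unit.
#' @param rest_delta additive perturbation applied jointly to both rest
#'   levels (used by robustness sweeps).
#' @inheritParams run_simulation_1
#' @return A data frame with one row per condition (`high_rest_shared`,
#'   `low_rest_shared`); attributes as in [run_simulation_1()].
#' @examples
#' run_simulation_2(n_cycles = 50)[, c("condition", "label")]
#' @export
run_simulation_2 <- function(input_level = 1, high_rest = 0.7,
                             low_rest = 0.1, rest_delta = 0,
                             n_cycles = 100,
                             params = activation_params(),
                             threshold = 0.5) {
  hi <- high_rest + rest_delta
  lo <- low_rest + rest_delta
  if (any(c(hi, lo) < params$a_min) || any(c(hi, lo) > params$a_max)) {
    stop("rest levels leave [a_min, a_max]", call. = FALSE)
  }
  target <- sign_form("target")
  schedule <- make_simultaneous_schedule(target, input_level, n_cycles)

  rest_profile <- function(tp) {
    ids <- tp$units$id[tp$units$layer == "sublexical"]
    r <- stats::setNames(rep(lo, length(ids)), ids)
    r[target$slots[["location"]]] <- hi
    r
  }

  base_tp <- build_topology(target, neighbor_spec(n_neighbors = 0L))
  base <- run_trial(base_tp, params, schedule, n_cycles,
                    rest_overrides = rest_profile(base_tp))

  conds <- list(high_rest_shared = "location", low_rest_shared = "handshape")
  effects <- list()
  trajs <- list(baseline = base)
  rows <- list()
  for (nm in names(conds)) {
    tp <- build_topology(target, neighbor_spec(conds[[nm]], 1L))
    tr <- run_trial(tp, params, schedule, n_cycles,
                    rest_overrides = rest_profile(tp))
    eff <- net_effect(tr, base, threshold = threshold)
    effects[[nm]] <- eff
    trajs[[nm]] <- tr
    rows[[nm]] <- effect_row("resting_activation", nm, input_level, 1L, eff)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "effects") <- effects
  attr(out, "trajectories") <- trajs
  out
}

#' Simulation 3: neighborhood density
#'
#' Tests whether the *number* of neighbors (all activated by the same
#' shared sub-lexical unit) can by itself produce the facilitation /
#' inhibition reversal. Low density (LND) has one neighbor, high density
#' (HND) four; each is compared, at each input level, against a
#' no-neighbor baseline at that level. All of the target's sub-lexical
#' units receive the same input simultaneously, so the conditions differ
#' only lexically.
#'
#' Expected pattern: input level sets the polarity (low input ->
#' facilitation, high input -> inhibition for *both* densities) and the
#' neighbor count only scales the magnitude.
#'
#' @param input_levels numeric vector of input magnitudes (default
#'   `c(1, 9)`).
#' @param n_neighbors integer vector of neighborhood sizes (default
#'   `c(1, 4)` = LND, HND).
#' @param shared_slot the target slot all neighbors share.
#' @inheritParams run_simulation_1
#' @return A data frame with one row per (input level, density) cell;
#'   attribute `"effects"` holds the `net_effect` objects keyed
#'   `input<level>_k<n>`.
#' @examples
#' run_simulation_3(n_cycles = 50)[, c("condition", "input_level", "label")]
#' @export
run_simulation_3 <- function(input_levels = c(1, 9),
                             n_neighbors = c(1L, 4L),
                             shared_slot = "location",
                             n_cycles = 100,
                             params = activation_params(),
                             threshold = 0.5) {
  target <- sign_form("target")
  effects <- list()
  rows <- list()
  for (inp in input_levels) {
    schedule <- make_simultaneous_schedule(target, inp, n_cycles)
    base_tp <- build_topology(target, neighbor_spec(n_neighbors = 0L))
    base <- run_trial(base_tp, params, schedule, n_cycles)
    for (k in n_neighbors) {
      tp <- build_topology(target, neighbor_spec(shared_slot, k))
      tr <- run_trial(tp, params, schedule, n_cycles)
      eff <- net_effect(tr, base, threshold = threshold)
      key <- sprintf("input%g_k%d", inp, k)
      effects[[key]] <- eff
      cond <- if (k == max(n_neighbors) && length(n_neighbors) > 1L)
        "high_density" else if (k == min(n_neighbors) &&
                                length(n_neighbors) > 1L)
        "low_density" else sprintf("k%d", k)
      rows[[key]] <- effect_row("density", cond, inp, k, eff)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "effects") <- effects
  out
}
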