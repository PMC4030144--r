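#' Activation dynamics parameters
#'
#' Collects every scalar constant of the network dynamics. Defaults follow
#' the standard parameterization used in all three simulation protocols:
#' symmetric excitatory weights of 0.2 between the sub-lexical and lexical
#' layers, an inhibition gain that is a steep sigmoid of the sending
#' lexical unit's activation (`gain_scale / (gain_denom + exp(-beta * (a -
#' x0)))` with `beta = 35`, `x0 = 0.3`), resting activation 0, no decay,
#' and activations bounded in `[-0.2, 1]`.
#'
#' Two constants govern the granularity of the difference equation rather
#' than the network structure: `input_strength` scales external input
#' before it enters the net input (0.4, the conventional external-input
#' strength of interactive activation simulators), and `step_size` scales
#' the whole activation update (0.2). Together they keep the nominal input
#' magnitudes (1, 2, 9) in the graded regime of the dynamics instead of
#' pinning driven units at the ceiling within a single cycle; see the
#' methods vignette for the reasoning.
#'
#' @param excitation_ff weight of sub-lexical -> lexical connections.
#' @param excitation_fb weight of lexical -> sub-lexical (feedback)
#'   connections.
#' @param beta steepness of the inhibition-gating sigmoid.
#' @param x0 midpoint (in activation units) of the inhibition-gating
#'   sigmoid.
#' @param gain_scale numerator of the gain expression.
#' @param gain_denom additive constant in the denominator of the gain
#'   expression.
#' @param rest default resting activation for units without an explicit
#'   override.
#' @param decay_sub,decay_lex decay rate pulling sub-lexical / lexical
#'   units back toward rest.
#' @param a_min,a_max activation floor and ceiling.
#' @param input_strength multiplier applied to external input magnitudes.
#' @param step_size integration step of the synchronous update.
#' @param ms_per_cycle nominal real-time duration of one cycle, in
#'   milliseconds (used only to interpret onset lags).
#'
#' @return An object of class `activation_params` (a validated named list).
#' @examples
#' p <- activation_params()
#' p$beta
#' activation_params(gain_denom = 1.5) # alternative sigmoid reading
#' @export
activation_params <- function(excitation_ff = 0.2,
                              excitation_fb = 0.2,
                              beta = 35,
                              x0 = 0.3,
                              gain_scale = 1,
                              gain_denom = 51.5,
                              rest = 0,
                              decay_sub = 0,
                              decay_lex = 0,
                              a_min = -0.2,
                              a_max = 1.0,
                              input_strength = 0.4,
                              step_size = 0.2,
                              ms_per_cycle = 10) {
  p <- list(
    excitation_ff = excitation_ff, excitation_fb = excitation_fb,
    beta = beta, x0 = x0,
    gain_scale = gain_scale, gain_denom = gain_denom,
    rest = rest, decay_sub = decay_sub, decay_lex = decay_lex,
    a_min = a_min, a_max = a_max,
    input_strength = input_strength, step_size = step_size,
    ms_per_cycle = ms_per_cycle
  )
  class(p) <- "activation_params"
  validate_params(p)
  p
}

#' Validate an `activation_params` object
#'
#' Checks the structural invariants of the parameter set and fails with an
#' informative error on the first violation.
#'
#' @param p an `activation_params` object (or plain named list with the
#'   same fields).
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  required <- c(
    "excitation_ff", "excitation_fb", "beta", "x0", "gain_scale",
    "gain_denom", "rest", "decay_sub", "decay_lex", "a_min", "a_max",
    "input_strength", "step_size", "ms_per_cycle"
  )
  missing <- setdiff(required, names(p))
  if (length(missing) > 0L) {
    stop("activation_params is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- vapply(p[required], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) {
    stop("activation_params fields must be finite numeric scalars: ",
         paste(required[!num], collapse = ", "), call. = FALSE)
  }
  if (p$beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (p$gain_denom <= 0) stop("gain_denom must be > 0", call. = FALSE)
  if (p$gain_scale <= 0) stop("gain_scale must be > 0", call. = FALSE)
  if (p$a_min >= p$a_max) stop("a_min must be < a_max", call. = FALSE)
  if (p$rest < p$a_min || p$rest > p$a_max) {
    stop("rest must lie in [a_min, a_max]", call. = FALSE)
  }
  if (p$decay_sub < 0 || p$decay_lex < 0) {
    stop("decay rates must be >= 0", call. = FALSE)
  }
  if (p$ms_per_cycle <= 0) stop("ms_per_cycle must be > 0", call. = FALSE)
  if (p$step_size <= 0) stop("step_size must be > 0", call. = FALSE)
  if (p$input_strength <= 0) stop("input_strength must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.activation_params <- function(x, ...) {
  cat("<activation_params>\n")
  cat(sprintf("  excitation: ff %.3g / fb %.3g\n",
              x$excitation_ff, x$excitation_fb))
  cat(sprintf("  inhibition gain: %.3g / (%.3g + exp(-%.3g (a - %.3g)))\n",
              x$gain_scale, x$gain_denom, x$beta, x$x0))
  cat(sprintf("  rest %.3g, decay sub %.3g / lex %.3g, bounds [%.3g, %.3g]\n",
              x$rest, x$decay_sub, x$decay_lex, x$a_min, x$a_max))
  cat(sprintf("  input_strength %.3g, step_size %.3g, %.3g ms/cycle\n",
              x$input_strength, x$step_size, x$ms_per_cycle))
  invisible(x)
}
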