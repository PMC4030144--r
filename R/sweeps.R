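#' Robustness sweep over a protocol parameter
#'
#' Reruns a simulation protocol over a symmetric grid of perturbations
#' around its baseline and records, at every point, the per-condition
#' net-effect labels. The sweep's headline number is the *sign-preserving
#' radius*: the largest grid radius within which every point reproduces
#' the baseline label pattern.
#'
#' Two sweeps are supported:
#' * `param = "rest"` (resting-activation protocol): the high and low rest
#'   levels are perturbed jointly, by the same additive delta.
#' * `param = "input"` (timing or resting-activation protocol): the input
#'   level is swept multiplicatively over `input_factors`.
#'
#' @param simulation which protocol to sweep: 1 (timing) or 2 (resting
#'   activation).
#' @param param `"rest"` or `"input"`.
#' @param radius half-width of the additive rest grid.
#' @param step grid step of the additive rest grid.
#' @param input_factors multiplicative grid for input sweeps.
#' @param n_cycles,params,threshold forwarded to the protocol.
#' @param ... further arguments forwarded to the protocol function.
#' @return An object of class `sweep_result`: list with `table` (one row
#'   per grid point x condition), `baseline_labels`, and
#'   `sign_preserving_radius` (for additive sweeps) or
#'   `labels_constant` (for input sweeps).
#' @examples
#' sw <- robustness_sweep(2, "rest", radius = 0.1, step = 0.05,
#'                        n_cycles = 50)
#' sw$sign_preserving_radius
#' @export
robustness_sweep <- function(simulation = 2,
                             param = c("rest", "input"),
                             radius = 0.2, step = 0.05,
                             input_factors = c(0.5, 1, 2),
                             n_cycles = 100,
                             params = activation_params(),
                             threshold = 0.5, ...) {
  param <- match.arg(param)
  stopifnot(simulation %in% c(1, 2))
  run_at <- function(delta = 0, factor = 1) {
    if (simulation == 1) {
      run_simulation_1(input_level = 2 * factor, n_cycles = n_cycles,
                       params = params, threshold = threshold, ...)
    } else {
      run_simulation_2(input_level = 1 * factor, rest_delta = delta,
                       n_cycles = n_cycles, params = params,
                       threshold = threshold, ...)
    }
  }
  baseline <- run_at()
  base_labels <- stats::setNames(baseline$label, baseline$condition)

  if (param == "rest") {
    if (simulation != 2) {
      stop("rest sweeps apply to the resting-activation protocol",
           call. = FALSE)
    }
    if (step <= 0) stop("step must be > 0", call. = FALSE)
    deltas <- seq(-radius, radius, by = step)
    rows <- lapply(deltas, function(d) {
      res <- run_at(delta = d)
      data.frame(param = "rest", value = d, condition = res$condition,
                 summary = res$summary, label = res$label,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    match_at <- vapply(deltas, function(d) {
      sub <- tab[tab$value == d, ]
      all(stats::setNames(sub$label, sub$condition)[names(base_labels)] ==
            base_labels)
    }, logical(1))
    radii <- sort(unique(abs(deltas)))
    keep <- vapply(radii, function(r)
      all(match_at[abs(deltas) <= r + 1e-12]), logical(1))
    spr <- if (any(keep)) max(radii[keep]) else 0
    out <- list(table = tab, baseline_labels = base_labels,
                sign_preserving_radius = spr, param = "rest")
  } else {
    rows <- lapply(input_factors, function(f) {
      res <- run_at(factor = f)
      data.frame(param = "input", value = f, condition = res$condition,
                 summary = res$summary, label = res$label,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    const <- all(vapply(input_factors, function(f) {
      sub <- tab[tab$value == f, ]
      all(stats::setNames(sub$label, sub$condition)[names(base_labels)] ==
            base_labels)
    }, logical(1)))
    out <- list(table = tab, baseline_labels = base_labels,
                labels_constant = const, param = "input")
  }
  class(out) <- "sweep_result"
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> param:", x$param, "\n")
  cat("  baseline labels:",
      paste(names(x$baseline_labels), x$baseline_labels,
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$sign_preserving_radius)) {
    cat("  sign-preserving radius:", x$sign_preserving_radius, "\n")
  } else {
    cat("  labels constant across grid:", x$labels_constant, "\n")
  }
  invisible(x)
}

#' Locate a polarity boundary by bisection
#'
#' Finds a parameter value at which a deterministic net-effect summary
#' changes sign, given two values with opposite-sign summaries. If either
#' endpoint's summary is exactly zero that endpoint is returned.
#'
#' @param summary_fn function mapping a scalar parameter value to a
#'   net-effect summary.
#' @param lo,hi bracketing parameter values (`lo < hi`) with opposite-sign
#'   summaries.
#' @param tol absolute tolerance on the parameter value.
#' @param max_iter iteration cap.
#' @return The boundary value.
#' @examples
#' # input level at which a single neighbor flips from helper to competitor
#' f <- function(inp) {
#'   res <- run_simulation_3(input_levels = inp, n_neighbors = 1L,
#'                           n_cycles = 50)
#'   res$summary[1]
#' }
#' \donttest{polarity_boundary(f, 1, 9, tol = 0.05)}
#' @export
polarity_boundary <- function(summary_fn, lo, hi, tol = 1e-3,
                              max_iter = 100L) {
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  s_lo <- summary_fn(lo)
  if (s_lo == 0) return(lo)
  s_hi <- summary_fn(hi)
  if (s_hi == 0) return(hi)
  if (sign(s_lo) == sign(s_hi)) {
    stop("summaries at lo and hi have the same sign", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if ((hi - lo) / 2 < tol) return(mid)
    s_mid <- summary_fn(mid)
    if (s_mid == 0) return(mid)
    if (sign(s_mid) == sign(s_lo)) {
      lo <- mid; s_lo <- s_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
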