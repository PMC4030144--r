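# Deliberately naive reference stepper: scalar, unit-by-unit, written
# directly from the model definition with no shared code with the engine.
# Used to cross-check the vectorized implementation.

oracle_gain <- function(a, params) {
  params$gain_scale / (params$gain_denom +
                         exp(-params$beta * (a - params$x0)))
}

oracle_external <- function(schedule, ids, cycle) {
  # input active during update `cycle` (1-based) if onset <= cycle-1 < offset
  ext <- stats::setNames(rep(0, length(ids)), ids)
  if (nrow(schedule) == 0L) return(ext)
  for (i in seq_len(nrow(schedule))) {
    if (schedule$onset[i] <= cycle - 1 && cycle - 1 < schedule$offset[i]) {
      ext[schedule$unit[i]] <- ext[schedule$unit[i]] + schedule$magnitude[i]
    }
  }
  ext
}

oracle_run <- function(topology, params, schedule, n_cycles,
                       rest_overrides = NULL) {
  ids <- topology$units$id
  layer <- stats::setNames(topology$units$layer, ids)
  rest <- stats::setNames(rep(params$rest, length(ids)), ids)
  if (!is.null(rest_overrides)) rest[names(rest_overrides)] <- rest_overrides
  lex_ids <- ids[layer == "lexical"]
  a <- rest
  out <- matrix(NA_real_, nrow = n_cycles + 1L, ncol = length(ids),
                dimnames = list(NULL, ids))
  out[1L, ] <- a
  for (cyc in seq_len(n_cycles)) {
    ext <- oracle_external(schedule, ids, cyc)
    a_new <- a
    for (u in ids) {
      if (layer[u] == "sublexical") {
        net <- 0
        for (lex in lex_ids) {
          if (u %in% topology$membership[[lex]]) {
            net <- net + params$excitation_fb * max(a[lex], 0)
          }
        }
      } else {
        net <- 0
        for (m in topology$membership[[u]]) {
          net <- net + params$excitation_ff * max(a[m], 0)
        }
        inh <- topology$inhibition
        for (i in seq_len(nrow(inh))) {
          if (inh$to[i] == u) {
            sender <- inh$from[i]
            net <- net - oracle_gain(a[sender], params) * max(a[sender], 0)
          }
        }
      }
      net <- net + params$input_strength * ext[u]
      delta <- if (net > 0) net * (params$a_max - a[u]) else
        net * (a[u] - params$a_min)
      dec <- if (layer[u] == "sublexical") params$decay_sub else
        params$decay_lex
      delta <- delta - dec * (a[u] - rest[u])
      a_new[u] <- min(max(a[u] + params$step_size * delta, params$a_min),
                      params$a_max)
    }
    a <- a_new
    out[cyc + 1L, ] <- a
  }
  out
}
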