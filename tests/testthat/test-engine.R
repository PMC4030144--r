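test_that("net input matches hand-computed two-term sums", {
  p <- activation_params()
  tp <- build_topology(spec = neighbor_spec("location", 1))
  st <- initial_state(tp, p)

  # one sub-lexical unit at 0.5 feeding the target, competitor at 0.4
  sub <- tp$membership[["target"]][2]
  st$activation[sub] <- 0.5
  st$activation["neighbor1"] <- 0.4
  net <- net_input(st, tp, p)
  expect_equal(net[["target"]],
               p$excitation_ff * 0.5 - inhibition_gain(0.4, p) * 0.4,
               tolerance = 1e-15)

  # a competitor at negative activation transmits nothing
  st$activation["neighbor1"] <- -0.1
  net2 <- net_input(st, tp, p)
  expect_equal(net2[["target"]], p$excitation_ff * 0.5, tolerance = 1e-15)

  # everything at rest 0, no input: zero net everywhere
  st0 <- initial_state(tp, p)
  expect_true(all(net_input(st0, tp, p) == 0))
})

test_that("a resting network with no input is a fixed point", {
  p <- activation_params()
  tp <- build_topology(spec = neighbor_spec("handshape", 2))
  tr <- run_trial(tp, p, input_schedule(), n_cycles = 25)
  for (i in seq_len(nrow(tr$activation))) {
    expect_equal(unname(tr$activation[i, ]), unname(tr$rest),
                 tolerance = 0)
  }
})

test_that("the update rule honours its closed-form single-unit cases", {
  # with unit input strength and step, net 1 drives a resting unit to the
  # ceiling in one cycle: delta = 1 * (a_max - 0) = 1
  p <- activation_params(input_strength = 1, step_size = 1)
  tp <- build_topology(spec = neighbor_spec(n_neighbors = 0))
  unit <- tp$membership[["target"]][1]
  st <- initial_state(tp, p)
  ext <- stats::setNames(rep(0, nrow(tp$units)), tp$units$id)
  ext[unit] <- 1
  st1 <- step(st, tp, p, ext)
  expect_equal(st1$activation[[unit]], p$a_max)
  expect_equal(st1$cycle_index, 1L)

  # a unit already at the ceiling with positive net stays there
  st2 <- step(st1, tp, p, ext)
  expect_equal(st2$activation[[unit]], p$a_max)

  # scaled variant: default input_strength/step_size give
  # a' = step_size * input_strength * (a_max - 0)
  pd <- activation_params()
  std <- initial_state(tp, pd)
  st1d <- step(std, tp, pd, ext)
  expect_equal(st1d$activation[[unit]],
               pd$step_size * pd$input_strength * pd$a_max,
               tolerance = 1e-15)
})

test_that("vectorized engine matches the naive scalar oracle", {
  p <- activation_params()
  target <- sign_form("target")
  sched <- make_timing_schedule(target, input_level = 2, n_cycles = 50)
  cases <- list(
    list(spec = neighbor_spec(n_neighbors = 0), rest = NULL),
    list(spec = neighbor_spec("handshape", 1), rest = NULL),
    list(spec = neighbor_spec("location", 1), rest = NULL),
    list(spec = neighbor_spec("location", 4), rest = NULL)
  )
  for (cs in cases) {
    tp <- build_topology(target, cs$spec)
    got <- run_trial(tp, p, sched, n_cycles = 50)$activation
    want <- oracle_run(tp, p, sched, n_cycles = 50)
    expect_lt(max(abs(got - want[, colnames(got)])), 1e-12)
  }

  # with rest overrides and a simultaneous schedule
  tp <- build_topology(target, neighbor_spec("location", 1))
  ids <- tp$units$id[tp$units$layer == "sublexical"]
  rest <- stats::setNames(rep(0.1, length(ids)), ids)
  rest[target$slots[["location"]]] <- 0.7
  sched2 <- make_simultaneous_schedule(target, 1, 50)
  got <- run_trial(tp, p, sched2, 50, rest_overrides = rest)$activation
  want <- oracle_run(tp, p, sched2, 50, rest_overrides = rest)
  expect_lt(max(abs(got - want[, colnames(got)])), 1e-12)
})

test_that("activations stay within bounds on randomized configurations", {
  set.seed(42)
  p <- activation_params()
  for (i in 1:20) {
    k <- sample(0:4, 1)
    slot <- sample(c("location", "orientation", "handshape", "movement"), 1)
    target <- sign_form("target")
    tp <- build_topology(target, neighbor_spec(slot, k))
    ids <- tp$units$id
    n_entries <- sample(1:6, 1)
    units <- sample(ids[tp$units$layer == "sublexical"], n_entries,
                    replace = TRUE)
    onset <- sample(0:20, n_entries, replace = TRUE)
    sched <- input_schedule(unit = units, onset = onset,
                            offset = onset + sample(1:30, n_entries,
                                                    replace = TRUE),
                            magnitude = stats::runif(n_entries, 0, 10))
    rest <- stats::setNames(stats::runif(length(ids), p$a_min, p$a_max), ids)
    tr <- run_trial(tp, p, sched, n_cycles = 40, rest_overrides = rest)
    expect_true(all(tr$activation >= p$a_min - 1e-12))
    expect_true(all(tr$activation <= p$a_max + 1e-12))
  }
})

test_that("trials are deterministic and correctly shaped", {
  p <- activation_params()
  target <- sign_form("target")
  tp <- build_topology(target, neighbor_spec("handshape", 1))
  sched <- make_timing_schedule(target, 2, 30)
  t1 <- run_trial(tp, p, sched, n_cycles = 30)
  t2 <- run_trial(tp, p, sched, n_cycles = 30)
  expect_identical(t1$activation, t2$activation)
  expect_equal(nrow(t1$activation), 31L)
  expect_equal(unname(t1$activation[1, ]), unname(t1$rest))

  # constant drive on a lone target: lexical activation non-decreasing
  tp0 <- build_topology(target, neighbor_spec(n_neighbors = 0))
  tr <- run_trial(tp0, p, make_simultaneous_schedule(target, 1, 50), 50)
  expect_true(all(diff(target_activation(tr)) >= -1e-15))
})

test_that("non-finite activation aborts instead of being clipped", {
  p <- activation_params(input_strength = 1, step_size = 1)
  target <- sign_form("target")
  tp <- build_topology(target, neighbor_spec(n_neighbors = 0))
  # two maximal-magnitude windows on the same unit overflow the net input
  sched <- input_schedule(unit = rep(target$slots[["location"]], 2),
                          onset = c(0, 0), offset = c(5, 5),
                          magnitude = c(1e308, 1e308))
  expect_error(run_trial(tp, p, sched, n_cycles = 5), "non-finite")
})

test_that("time_to_threshold interpolates crossings", {
  expect_equal(time_to_threshold(c(0, 1), 0.5), 0.5)
  expect_equal(time_to_threshold(c(0, 0.25, 0.75, 1), 0.5), 1.5)
  expect_equal(time_to_threshold(c(0.6, 0.9), 0.5), 0)
  expect_true(is.infinite(time_to_threshold(c(0, 0.1, 0.2), 0.5)))
})
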