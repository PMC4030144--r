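test_that("identical runs give an all-zero difference and a null label", {
  p <- activation_params()
  target <- sign_form("target")
  tp <- build_topology(target, neighbor_spec("location", 1))
  sched <- make_simultaneous_schedule(target, 1, 30)
  t1 <- run_trial(tp, p, sched, 30)
  t2 <- run_trial(tp, p, sched, 30)
  eff <- net_effect(t1, t2)
  expect_true(all(eff$difference == 0))
  expect_equal(eff$label, "null")
  expect_equal(eff$rt_advantage, 0)
  expect_equal(eff$mean_diff, 0)
})

test_that("the difference series starts at zero when rests match", {
  s2 <- run_simulation_2(n_cycles = 40)
  for (eff in attr(s2, "effects")) {
    expect_equal(eff$difference[1], 0)
    expect_equal(length(eff$difference), 41L)
  }
})

test_that("labels agree with the sign of the recognition-time advantage", {
  s1 <- run_simulation_1(n_cycles = 60)
  for (eff in attr(s1, "effects")) {
    want <- if (eff$rt_advantage > eff$epsilon) "facilitatory" else
      if (eff$rt_advantage < -eff$epsilon) "inhibitory" else "null"
    expect_equal(eff$label, want)
  }
})

test_that("mismatched runs are rejected", {
  p <- activation_params()
  target <- sign_form("target")
  tp <- build_topology(target, neighbor_spec("location", 1))
  sched <- make_simultaneous_schedule(target, 1, 30)
  a <- run_trial(tp, p, sched, 30)
  b <- run_trial(tp, p, make_simultaneous_schedule(target, 1, 20), 20)
  expect_error(net_effect(a, b), "different lengths")
  p2 <- activation_params(beta = 20)
  c2 <- run_trial(tp, p2, sched, 30)
  expect_error(net_effect(a, c2), "different parameters")
  expect_error(net_effect(a, a, target_label = "nope"), "unknown unit")
})

test_that("with simultaneous onsets the two timing conditions coincide", {
  # isomorphic topologies + identical schedules => identical summaries
  p <- activation_params()
  target <- sign_form("target")
  sched <- make_simultaneous_schedule(target, 2, 50)
  base <- run_trial(build_topology(target, neighbor_spec(n_neighbors = 0)),
                    p, sched, 50)
  effs <- lapply(c("location", "handshape"), function(slot) {
    tp <- build_topology(target, neighbor_spec(slot, 1))
    net_effect(run_trial(tp, p, sched, 50), base)
  })
  expect_equal(effs[[1]]$difference, effs[[2]]$difference)
  expect_equal(effs[[1]]$rt_advantage, effs[[2]]$rt_advantage)
})

test_that("with a flat rest profile the two rest conditions coincide", {
  s2 <- run_simulation_2(high_rest = 0.1, low_rest = 0.1, n_cycles = 50)
  expect_equal(s2$summary[1], s2$summary[2])
  expect_equal(s2$label[1], s2$label[2])
})

test_that("zero neighbors produce a zero net effect", {
  s3 <- run_simulation_3(input_levels = 1, n_neighbors = 0L,
                         n_cycles = 30)
  expect_equal(s3$summary, 0)
  expect_equal(s3$label, "null")
  eff <- attr(s3, "effects")[[1]]
  expect_true(all(eff$difference == 0))
})
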