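test_that("unit and connection counts follow the neighborhood formula", {
  # no neighbor: a lone target
  tp0 <- build_topology(spec = neighbor_spec(n_neighbors = 0))
  expect_equal(sum(tp0$units$layer == "lexical"), 1L)
  expect_equal(sum(tp0$units$layer == "sublexical"), 4L)
  expect_equal(nrow(tp0$inhibition), 0L)

  # one handshape neighbor
  tp1 <- build_topology(spec = neighbor_spec("handshape", 1))
  expect_equal(sum(tp1$units$layer == "lexical"), 2L)
  expect_equal(sum(tp1$units$layer == "sublexical"), 7L)
  expect_equal(nrow(tp1$inhibition), 2L)

  # counting formula for k = 0..6: sub = 4 + 3k, lex = 1 + k,
  # ordered inhibition pairs = (1 + k) k
  for (k in 0:6) {
    tp <- build_topology(spec = neighbor_spec("location", k))
    expect_equal(sum(tp$units$layer == "sublexical"), 4L + 3L * k)
    expect_equal(sum(tp$units$layer == "lexical"), 1L + k)
    expect_equal(nrow(tp$inhibition), (1L + k) * k)
    expect_true(all(validate_topology(tp)$pass))
  }
})

test_that("neighbors share exactly the designated unit and nothing else", {
  tp <- build_topology(spec = neighbor_spec("movement", 4))
  tgt <- tp$membership[["target"]]
  for (i in 1:4) {
    nb <- tp$membership[[paste0("neighbor", i)]]
    expect_equal(intersect(nb, tgt), tp$shared_unit)
  }
  # pairwise: neighbors only overlap on the shared unit
  for (i in 1:3) for (j in (i + 1):4) {
    ov <- intersect(tp$membership[[paste0("neighbor", i)]],
                    tp$membership[[paste0("neighbor", j)]])
    expect_equal(ov, tp$shared_unit)
  }
})

test_that("validation flags hand-built defective topologies", {
  tp <- build_topology(spec = neighbor_spec("location", 2))

  # a neighbor with only 3 slots
  broken <- tp
  broken$membership[["neighbor1"]] <- broken$membership[["neighbor1"]][1:3]
  rep1 <- validate_topology(broken)
  expect_false(rep1$pass[rep1$check == "membership_arity"])

  # two neighbors sharing a non-target unit
  broken2 <- tp
  broken2$membership[["neighbor2"]][2] <- broken2$membership[["neighbor1"]][2]
  rep2 <- validate_topology(broken2)
  expect_false(rep2$pass[rep2$check == "sharing_pattern"])

  # missing an ordered inhibition pair
  broken3 <- tp
  broken3$inhibition <- broken3$inhibition[-1, ]
  rep3 <- validate_topology(broken3)
  expect_false(rep3$pass[rep3$check == "inhibition_pairs"])
})

test_that("the engine has no intrinsic slot identity (role symmetry)", {
  # sharing 'location' vs sharing 'handshape' gives isomorphic networks:
  # under a simultaneous schedule the target trajectories coincide exactly
  p <- activation_params()
  target <- sign_form("target")
  sched <- make_simultaneous_schedule(target, input_level = 1,
                                      n_cycles = 40)
  tr <- lapply(c("location", "handshape", "movement"), function(slot) {
    tp <- build_topology(target, neighbor_spec(slot, 2))
    run_trial(tp, p, sched, n_cycles = 40)
  })
  expect_identical(target_activation(tr[[1]]), target_activation(tr[[2]]))
  expect_identical(target_activation(tr[[1]]), target_activation(tr[[3]]))
})

test_that("topology JSON round-trips", {
  tp <- build_topology(spec = neighbor_spec("handshape", 3))
  f <- tempfile(fileext = ".json")
  write_topology_json(tp, f)
  tp2 <- read_topology_json(f)
  expect_equal(tp2$units, tp$units)
  expect_equal(tp2$membership, tp$membership)
  expect_setequal(paste(tp2$inhibition$from, tp2$inhibition$to),
                  paste(tp$inhibition$from, tp$inhibition$to))
  unlink(f)
})
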