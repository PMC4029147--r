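test_that("synchronous threshold update reproduces hand-evaluated cases", {
  net <- celegans_cell_cycle()

  # published trajectory step t=1 -> t=2
  expect_equal(format_state(successor_state(net, "10010111")), "00100101")

  # all-zero state: every input sum is 0, the tie rule holds every node
  expect_equal(successor_state(net, rep(0L, 8)), rep(0L, 8))

  # the largest attractor is a fixed point
  expect_equal(format_state(successor_state(net, "00010111")), "00010111")

  # toy network truth table (hand-derived)
  toy <- toy_ab()
  expect_equal(successor_state(toy, c(0L, 0L)), c(0L, 0L))
  expect_equal(successor_state(toy, c(0L, 1L)), c(0L, 0L))
  expect_equal(successor_state(toy, c(1L, 0L)), c(1L, 1L))
  expect_equal(successor_state(toy, c(1L, 1L)), c(1L, 1L))

  expect_error(successor_state(net, "1010"), "8 nodes")
})

test_that("cell-cycle trajectory reproduces the published 8-step pathway", {
  net <- celegans_cell_cycle()
  traj <- simulate_trajectory(net, "10010111")
  expect_equal(nrow(traj), 8L)
  expect_true(attr(traj, "absorbed"))
  expect_equal(traj$state, golden_wildtype_pathway$state)   # bit-exact, all 8 rows
  expect_equal(traj$phase, golden_wildtype_pathway$phase)
  expect_equal(traj$time, 1:8)
  # node columns are consistent with the bit-strings
  expect_equal(
    apply(as.matrix(traj[net$nodes]), 1, paste, collapse = ""),
    traj$state, ignore_attr = TRUE
  )
})

test_that("trajectories absorb and terminate correctly", {
  net <- celegans_cell_cycle()

  # start at a fixed point: length-1 absorbed trajectory
  traj <- simulate_trajectory(net, "00010111")
  expect_equal(nrow(traj), 1L)
  expect_true(attr(traj, "absorbed"))

  # toy net from (0,1): two states then absorption at (0,0)
  traj <- simulate_trajectory(toy_ab(), c(0L, 1L))
  expect_equal(traj$state, c("01", "00"))
  expect_true(attr(traj, "absorbed"))

  # once absorbed, the fixed point never re-appears mid-trajectory
  traj <- simulate_trajectory(net, "10010111")
  expect_equal(sum(traj$state == "00010111"), 1L)
  expect_equal(traj$state[nrow(traj)], "00010111")

  # a genuine 2-cycle is reported unabsorbed: A <-> not A
  osc <- as_threshold_network(
    data.frame(source = "A", target = "A", weight = -1), nodes = "A",
    thresholds = -0.5
  )
  expect_equal(format_state(successor_state(osc, 0L)), "1")
  traj <- simulate_trajectory(osc, 0L)
  expect_false(attr(traj, "absorbed"))
  expect_equal(nrow(traj), 2L)
})

test_that("exhaustive enumeration reproduces the published fixed-point table", {
  rep <- enumerate_attractors(celegans_cell_cycle())
  a <- rep$attractors
  expect_equal(nrow(a), 5L)
  expect_true(all(a$type == "fixed_point"))  # no limit cycles
  expect_equal(a$basin_size, golden_attractor_table$basin_size)
  expect_equal(a$state, golden_attractor_table$state)
  expect_equal(sum(a$basin_size), 256L)
  g <- glance(rep)
  expect_equal(g$n_fixed_points, 5L)
  expect_equal(g$largest_basin, 219L)
  # tidy() lays the table out with one 0/1 column per node
  td <- tidy(rep)
  expect_equal(td$basin_size, golden_attractor_table$basin_size)
  expect_equal(td$cki1, c(1L, 1L, 1L, 1L, 0L))
})

test_that("enumeration handles degenerate and toy networks", {
  # edgeless: every sum is 0, every state held -> all states fixed, basin 1
  rep <- enumerate_attractors(edgeless_net(2))
  expect_equal(nrow(rep$attractors), 4L)
  expect_true(all(rep$attractors$basin_size == 1L))

  # toy: two fixed points with basin 2 each (exhaustive 4-state oracle)
  rep <- enumerate_attractors(toy_ab())
  expect_equal(rep$attractors$basin_size, c(2L, 2L))
  expect_equal(sort(rep$attractors$state), c("00", "11"))

  # cap on exhaustive enumeration
  expect_error(enumerate_attractors(edgeless_net(21)), "capped")
  expect_silent(enumerate_attractors(edgeless_net(5), max_nodes = 5))
})

test_that("phase labels follow the CDK/cyclin readout", {
  net <- celegans_cell_cycle()
  expect_equal(label_phase(net, "10010111"), "S")
  expect_equal(label_phase(net, "00011000"), "M")
  expect_equal(label_phase(net, "00010111", is_fixed = TRUE), "M/S")
  expect_equal(label_phase(net, "00010000"), "S/M")
  expect_equal(label_phase(toy_ab(), c(1L, 0L)), "unlabeled")
})

test_that("basin conservation and out-degree-1 hold on arbitrary networks", {
  nets <- c(
    list(celegans_cell_cycle(), toy_ab(), edgeless_net(3)),
    lapply(1:6, function(s) random_small_net(5, 12, seed = 100 + s))
  )
  for (net in nets) {
    rep <- enumerate_attractors(net)
    expect_equal(sum(rep$attractors$basin_size), rep$total_states)
    expect_length(wormcycle:::all_successors(net), rep$total_states)
    # every reported fixed point satisfies successor(s) == s
    fp <- rep$attractors[rep$attractors$type == "fixed_point", ]
    for (st in fp$state) {
      expect_equal(format_state(successor_state(net, st)), st)
    }
  }
})

test_that("enumeration agrees with the naive orbit-following oracle on small networks", {
  nets <- c(
    list(toy_ab(), edgeless_net(2), edgeless_net(1)),
    lapply(1:8, function(s) random_small_net(4, sample(3:10, 1), seed = 200 + s)),
    lapply(1:4, function(s) random_small_net(3, 6, seed = 300 + s))
  )
  for (net in nets) {
    rep <- enumerate_attractors(net)
    orc <- oracle_attractors(net)
    expect_equal(length(rep$states), length(orc$states))
    expect_equal(unname(rep$attractors$basin_size), orc$basin)
    expect_equal(lapply(rep$states, sort), lapply(orc$states, as.integer))
  }
})
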