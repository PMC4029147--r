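test_that("single-edge perturbations edit a copy and compose as inverses", {
  net <- celegans_cell_cycle()
  W0 <- weight_matrix(net)

  del <- apply_perturbation(net, "delete", "cdc25_1", "cdk2_cyclinE")
  expect_equal(nrow(network_edges(del)), 20L)
  expect_identical(weight_matrix(net), W0)  # input untouched

  # delete then add back = identity
  back <- apply_perturbation(del, "add", "cdc25_1", "cdk2_cyclinE",
                             weight = 1)
  expect_identical(weight_matrix(back), W0)

  # switch is an involution
  sw <- apply_perturbation(net, "switch", "cki1", "cki1")
  expect_equal(weight_matrix(sw)["cki1", "cki1"], 1)
  sw2 <- apply_perturbation(sw, "switch", "cki1", "cki1")
  expect_identical(weight_matrix(sw2), W0)

  expect_error(apply_perturbation(net, "delete", "fzr1", "cdc25_1"),
               "no interaction")
  expect_error(apply_perturbation(net, "add", "cki1", "cki1", weight = -1),
               "already has")
  expect_error(apply_perturbation(net, "add", "fzr1", "cdc25_1"),
               "required")
  expect_error(apply_perturbation(net, "delete", "nope", "cki1"),
               "unknown node")
})

test_that("perturbation scan enumerates every applicable perturbation", {
  net <- celegans_cell_cycle()
  scan_del <- perturbation_scan(net, kinds = "delete")
  expect_equal(nrow(scan_del), 21L)
  scan_sw <- perturbation_scan(net, kinds = "switch")
  expect_equal(nrow(scan_sw), 21L)
  scan_add <- perturbation_scan(net, kinds = "add")
  expect_equal(nrow(scan_add), 2L * (64L - 21L))  # both signs per empty pair
  expect_true(all(scan_add$weight %in% c(-1, 1)))

  full <- dplyr::bind_rows(scan_del, scan_add, scan_sw)
  expect_true(all(full$B_original == 219L))
  expect_true(all(full$delta_rel >= -1))

  # mode of the dB/B distribution is at 0: the network is robust
  h <- delta_histogram(full)
  expect_equal(sum(h$probability), 1)
  expect_equal(h$delta_rel[which.max(h$probability)], 0)
})

test_that("perturbed basins agree with direct re-enumeration on a toy network", {
  toy <- toy_ab()
  scan <- perturbation_scan(toy, kinds = "switch")
  for (i in seq_len(nrow(scan))) {
    p <- apply_perturbation(toy, "switch", scan$source[i], scan$target[i])
    orc <- oracle_attractors(p)
    # referent: basin of the original largest attractor's state, else 0
    base <- enumerate_attractors(toy)
    top <- base$states[[1]][1]
    hit <- which(vapply(orc$states,
                        function(st) length(st) == 1 && st[1] == top,
                        logical(1)))
    expected <- if (length(hit)) orc$basin[hit] else 0L
    expect_equal(scan$B_perturbed[i], expected)
  }
})

test_that("largest-basin referent is available as the alternative reading", {
  net <- celegans_cell_cycle()
  a <- perturbation_scan(net, kinds = "delete", referent = "original_state")
  b <- perturbation_scan(net, kinds = "delete", referent = "largest")
  # the alternative can only report an equal or larger perturbed basin
  expect_true(all(b$B_perturbed >= a$B_perturbed))
})

test_that("basin conservation survives every perturbation of the built-in net", {
  net <- celegans_cell_cycle()
  perts <- wormcycle:::enumerate_perturbations(net, c("delete", "switch"))
  for (i in seq_len(nrow(perts))) {
    p <- apply_perturbation(net, perts$kind[i], perts$source[i],
                            perts$target[i])
    expect_equal(sum(enumerate_attractors(p)$attractors$basin_size), 256L)
  }
})

test_that("the cell-cycle network is more robust than matched random networks", {
  cmp <- ensemble_perturbation_comparison(
    celegans_cell_cycle(),
    ensemble_spec(n_networks = 40, seed = 13),
    kinds = c("delete", "add", "switch")
  )
  expect_equal(sum(cmp$reference_histogram$probability), 1)
  expect_equal(sum(cmp$ensemble_histogram$probability), 1)
  expect_gt(cmp$reference_p0, cmp$ensemble_mean_p0)

  # degenerate comparison: an "ensemble" whose stats are computed from
  # scans of networks identical in size to the reference still normalises
  expect_true(all(cmp$ensemble_p0$p0 >= 0 & cmp$ensemble_p0$p0 <= 1))
})
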