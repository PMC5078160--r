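# Conformer selection and path composition on the packaged set-1/set-3
# networks, plus the synthetic-network invariants.

test_that("conformer selection favours the tighter-binding non-reference ligand", {
  lig <- ligand_table(c("80", "82", "ref"), 1,
                      exp_dg = c(-32.6, -28.2, NA),
                      is_reference = c(FALSE, FALSE, TRUE))

  # ref -> X: the smaller ddG means X binds better
  e1 <- perturbation_edge("ref", "80", c(1.8, -3.6), c(0.5, 0.5))
  expect_equal(select_conformer(e1, lig)$value, -3.6)

  # X -> ref: the larger ddG means X binds better
  e2 <- perturbation_edge("82", "ref", c(13.3, 16.4), c(0.3, 0.3))
  expect_equal(select_conformer(e2, lig)$value, 16.4)

  # ties keep the first-listed candidate
  e3 <- perturbation_edge("82", "ref", c(8.3, 8.3), c(0.5, 0.6),
                          conformers = c("conf1", "conf2"))
  expect_equal(select_conformer(e3, lig)$conformer, "conf1")

  # ambiguous edge between two non-reference ligands is a configuration error
  e4 <- perturbation_edge("80", "82", c(-13.2, -16.4))
  expect_error(select_conformer(e4, lig), "non-reference")
  # unless a selection was recorded upstream
  e5 <- perturbation_edge("80", "82", c(-13.2, -16.4), selected = 1L)
  expect_equal(select_conformer(e5, lig)$value, -13.2)
})

test_that("the stereoisomer choice matches the published S-over-R preference", {
  net3 <- hsp90_network(3)
  # both X -> ref2 edges exist; the S form binds more favourably (larger ddG)
  sel <- fesbench:::pn_select_conformers(net3)
  vS <- sel$value[sel$from == "61S"]
  vR <- sel$value[sel$from == "61R"]
  expect_equal(vS, -4.8)
  expect_equal(vR, -19.8)
  expect_gt(vS, vR)
})

test_that("relative affinities compose along paths with quadrature errors", {
  net1 <- hsp90_network(1)

  # 81 -> 82 -> ref: -13.2 + 16.4 = 3.2, SE sqrt(0.5^2 + 0.3^2)
  est <- relative_affinity(net1, "81", "ref")
  expect_equal(est$value, 3.2, tolerance = 1e-12)
  expect_equal(est$se, sqrt(0.5^2 + 0.3^2), tolerance = 1e-12)
  expect_equal(est$n_edges, 2L)

  # identity and antisymmetry
  same <- relative_affinity(net1, "83", "83")
  expect_identical(same$value, 0)
  expect_identical(same$se, 0)
  ab <- relative_affinity(net1, "80", "82")
  ba <- relative_affinity(net1, "82", "80")
  expect_equal(ab$value, -12.8, tolerance = 1e-12)
  expect_equal(ba$value, 12.8, tolerance = 1e-12)
  expect_equal(ab$se, ba$se)

  # path bound errors
  expect_error(relative_affinity(net1, "81", "80", max_edges = 2),
               "more than")
  expect_error(relative_affinity(net1, "81", "nope"), "unknown")
})

test_that("the three comparison schemes enumerate the documented pair counts", {
  net1 <- hsp90_network(1)

  tab_all <- all_pairs_table(net1, "all_pairs")
  expect_equal(nrow(tab_all), 10L)
  expect_true(all(!is.na(tab_all$exp)))
  # composed from 0.1-rounded inputs, the all-pairs MAD is 10.76
  expect_equal(mean(abs(tab_all$calc - tab_all$exp)), 10.76, tolerance = 1e-9)

  tab_two <- all_pairs_table(net1, "max_two_edges")
  expect_equal(nrow(tab_two), 7L)

  tab_ref <- all_pairs_table(net1, "fixed_reference", reference = "82")
  expect_equal(nrow(tab_ref), 4L)
  expect_error(all_pairs_table(net1, "fixed_reference", reference = "ref"),
               "experimental")
})

test_that("set-3 scheme comparisons exclude the non-binder by default", {
  net3 <- hsp90_network(3)
  tab <- all_pairs_table(net3, "all_pairs")
  expect_false(any(grepl("^61", c(tab$from, tab$to))))
  tab_nb <- all_pairs_table(net3, "all_pairs", include_non_binders = TRUE)
  expect_gt(nrow(tab_nb), nrow(tab))
})

test_that("noise-free synthetic networks compose exactly and path-independently", {
  node_dg <- c(A = -30, B = -35, C = -28, ref = -20, ref2 = -22)
  # a cycle so several routes exist between pairs
  edges <- rbind(c("A", "ref"), c("B", "ref"), c("C", "ref2"),
                 c("ref", "ref2"), c("A", "ref2"))
  net <- generate_network(node_dg, edges, reference_ids = c("ref", "ref2"),
                          noise_sd = 0, seed = 1)
  for (a in c("A", "B", "C")) for (b in c("A", "B", "C")) {
    expect_equal(relative_affinity(net, a, b)$value,
                 node_dg[[b]] - node_dg[[a]], tolerance = 1e-12)
  }
})

test_that("conformer planting is always recovered without noise", {
  node_dg <- c(X = -40, Y = -33, ref = -25)
  edges <- rbind(c("X", "ref"), c("ref", "Y"))
  net <- generate_network(node_dg, edges, reference_ids = "ref",
                          noise_sd = 0, conformer_offset = 5, seed = 2)
  sel <- fesbench:::pn_select_conformers(net)
  expect_true(all(sel$conformer == "planted"))
  expect_equal(relative_affinity(net, "X", "Y")$value, 7, tolerance = 1e-12)
})

test_that("all-pairs noise scales like the quadrature path error", {
  node_dg <- c(A = -30, B = -35, C = -28, D = -31, ref = -20)
  edges <- rbind(c("A", "ref"), c("B", "ref"), c("C", "ref"), c("D", "ref"))
  sigma <- 1
  errs <- unlist(lapply(1:60, function(s) {
    net <- generate_network(node_dg, edges, reference_ids = "ref",
                            noise_sd = sigma, seed = s)
    tab <- all_pairs_table(net, "all_pairs")
    tab$calc - tab$exp
  }))
  # every pair is two one-edge hops: RMSE -> sigma * sqrt(2)
  expect_equal(sqrt(mean(errs^2)), sigma * sqrt(2), tolerance = 0.15)
})

test_that("network construction validates endpoints and duplicates", {
  lig <- ligand_table(c("A", "B"), 1)
  e <- perturbation_edge("A", "B", 1)
  expect_error(perturbation_network(lig, list(e, e)), "duplicate")
  e_bad <- perturbation_edge("A", "Z", 1)
  expect_error(perturbation_network(lig, list(e_bad)), "missing")
  expect_error(generate_network(c(A = 0, B = 1, C = 2),
                                rbind(c("A", "B")), seed = 1),
               "connect")
})
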