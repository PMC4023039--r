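test_that("reference trees are uniform-attachment, deterministic, right-sized", {
  t2 <- simulate_reference_tree(2, 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(t2$Nnode, 1L)
  expect_identical(ape::write.tree(simulate_reference_tree(12, 7)),
                   ape::write.tree(simulate_reference_tree(12, 7)))
  expect_false(identical(ape::write.tree(simulate_reference_tree(12, 7)),
                         ape::write.tree(simulate_reference_tree(12, 8))))
  big <- simulate_reference_tree(571, 3)
  expect_equal(big$Nnode, 570L)
  expect_error(simulate_reference_tree(1, 1), ">= 2")
})

test_that("tRNA families honour mutation and compensation settings", {
  tr <- simulate_reference_tree(6, 2)
  frozen <- evolve_trna_family(tr, sim_config(p_sub = 0), seed = 5)
  expect_true(all(frozen$seqs$sequence == trna_scaffold()$sequence))
  comp <- evolve_trna_family(tr, sim_config(p_sub = 0.1, p_comp = 1), seed = 5)
  for (i in seq_len(nrow(comp$seqs))) {
    s <- parse_dotbracket(comp$seqs$sequence[i], comp$seqs$structure[i])
    dec <- decompose_cloverleaf(s)
    expect_true(all(dec$present[dec$region != "variable_loop"]))
  }
  # determinism: identical output for identical (config, seed)
  again <- evolve_trna_family(tr, sim_config(p_sub = 0.1, p_comp = 1), seed = 5)
  expect_identical(comp$seqs, again$seqs)
})

test_that("evolved leaves always re-parse through the structure module", {
  tr <- simulate_reference_tree(8, 4)
  fam <- evolve_trna_family(tr, sim_config(), seed = 10)
  for (i in seq_len(nrow(fam$seqs))) {
    expect_no_error(parse_dotbracket(fam$seqs$sequence[i], fam$seqs$structure[i]))
  }
})

test_that("drift matrices start at the ancestral state and stay in range", {
  tr <- simulate_reference_tree(8, 6)
  m <- simulate_drift_matrix(tr, n_char = 40, seed = 11)
  expect_equal(dim(m), c(8L, 40L))
  expect_true(all(m$states >= 0 & m$states <= 23))
  expect_true(all(m$polarity == "low"))
  expect_identical(simulate_drift_matrix(tr, n_char = 40, seed = 11)$states,
                   m$states)
})

test_that("census accretion matches its degenerate settings", {
  tr <- simulate_reference_tree(10, 3)
  # birth probability 1: every domain born at the root, census has no zeros
  allroot <- simulate_domain_census(tr, sim_config(p_birth = 1), seed = 2)
  expect_true(all(allroot$census > 0))
  expect_true(all(allroot$domain_ages$depth == 0))
  # growth 1, no noise: constant abundance everywhere the domain exists
  flat <- simulate_domain_census(tr, sim_config(p_birth = 1, growth = 1,
                                                sigma = 0), seed = 2)
  expect_true(all(flat$census == flat$census[1, 1]))
  # truth tables are sufficient to score recoveries
  cen <- simulate_domain_census(tr, sim_config(), seed = 4)
  expect_true(all(cen$interaction_map$domain_id %in% cen$domain_ages$unit))
  expect_true(all(cen$substructure_ages$unit %in%
                    c("acceptor", "t_arm", "d_arm", "anticodon_arm",
                      "variable_loop")))
  # substructure ages inherit the defining domains' ages: anchoring the map
  # onto the true domain ages reproduces them
  anchored <- anchor_substructures(cen$domain_ages, cen$interaction_map)
  merged <- dplyr::inner_join(anchored, cen$substructure_ages, by = "unit")
  expect_equal(merged$age_gy.x, merged$age_gy.y)
})

test_that("domain ages decrease with birth depth and span the origin", {
  tr <- simulate_reference_tree(14, 9)
  cen <- simulate_domain_census(tr, sim_config(), seed = 8)
  da <- cen$domain_ages
  expect_true(all(diff(da$age_gy[order(da$depth)]) <= 0))
  expect_lte(max(da$age_gy), 3.8)
  expect_gt(min(da$age_gy), 0)
})

test_that("a root-born domain is basal in reconstructed domain trees", {
  # accretion + abundance coding + heuristic search, scored against truth
  ok <- 0
  for (sd in 1:8) {
    tr <- simulate_reference_tree(20, sd)
    cen <- simulate_domain_census(tr, sim_config(), seed = sd + 300)
    m <- attach_ancestor(code_abundance(cen$census))
    res <- heuristic_search(m, seed = sd, restarts = 3, g1_samples = 0)
    nd <- node_distances(res$trees[[1]])
    rootborn <- cen$domain_ages$unit[cen$domain_ages$depth == 0]
    basal <- nd$taxon[nd$nd == min(nd$nd)]
    ok <- ok + any(basal %in% rootborn)
  }
  expect_gte(ok / 8, 0.8)
})
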