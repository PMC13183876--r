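test_that("atom features honor toggles and normalization", {
  m <- parse_smiles("CC(=O)O")
  x <- featurize_atoms(m)
  expect_equal(ncol(x), 10)
  interval <- c("electronegativity", "hardness", "atomic_diameter",
                "ring_size", "n_hydrogens")
  expect_true(all(x[, interval] >= 0 & x[, interval] <= 1))
  hyb <- x[, c("hyb_sp", "hyb_sp2", "hyb_sp3", "hyb_other")]
  expect_equal(unname(rowSums(hyb)), rep(1, 4))
  # toggled-off features contribute zero vector length
  x2 <- featurize_atoms(m, toggles = list(atom.hardness = FALSE,
                                          atom.hybridization = FALSE))
  expect_equal(ncol(x2), 10 - 1 - 4)
  expect_false("hardness" %in% colnames(x2))
  # element one-hot adds one column per registry element
  x3 <- featurize_atoms(m, toggles = list(atom.element = TRUE))
  expect_equal(ncol(x3), 10 + nrow(element_registry()))
  expect_error(featurize_atoms(m, toggles = list(atom.mystery = TRUE)),
               "unknown feature toggle")
})

test_that("interval features of a random library stay in [0, 1]", {
  lib <- generate_synthetic_library(synthetic_spec(n_molecules = 100,
                                                   seed = 3))
  for (smi in lib$smiles) {
    x <- featurize_atoms(parse_smiles(smi))
    vals <- x[, !grepl("^(formal_charge|hyb_)", colnames(x))]
    expect_true(all(vals >= 0 & vals <= 1), info = smi)
  }
})

test_that("revised conjugation separates carboxylate from carboxylic acid", {
  base <- parse_smiles("CC(=O)[O-]")
  fb <- featurize_bonds(base, center = 4)
  co_bonds <- which(apply(base$bonds, 1, function(b)
    any(base$atoms$element[as.integer(b[1:2])] == "O")))
  expect_length(co_bonds, 2)
  # the two C-O bond vectors of acetate are identical (delocalized group)
  expect_equal(fb[co_bonds[1], ], fb[co_bonds[2], ])
  expect_equal(unname(fb[co_bonds[1], "enhanced_resonance"]), 1)

  acid <- parse_smiles("CC(=O)O")
  fa <- featurize_bonds(acid, center = 4)
  co_a <- which(apply(acid$bonds, 1, function(b)
    any(acid$atoms$element[as.integer(b[1:2])] == "O")))
  # the neutral acid's two C-O bonds differ, and neither is enhanced
  expect_false(isTRUE(all.equal(fa[co_a[1], ], fa[co_a[2], ])))
  expect_equal(unname(fa[, "enhanced_resonance"]), rep(0, 3))
  # ethane: nothing conjugated
  expect_equal(unname(revised_conjugation(parse_smiles("CC"))$flags[1, ]),
               c(0, 0))
})

test_that("directed polarization points away from the center and is antisymmetric", {
  m <- parse_smiles("FCC(=O)[O-]")     # fluoroacetate, center carboxylate O
  pol <- directed_polarization(m, center = 5)
  # C-F bond: F farther from the center -> EN(F) - EN(C) = +1.43
  expect_equal(pol[1], 3.98 - 2.55)
  # homonuclear C-C bond is zero
  expect_equal(pol[2], 0)
  # moving the center to the other end of a linear chain flips every sign
  chain <- parse_smiles("OCCCCN")
  p1 <- directed_polarization(chain, center = 1)
  p2 <- directed_polarization(chain, center = 6)
  expect_equal(p1, -p2)
  # equidistant endpoints in an odd cycle give zero
  ring <- parse_smiles("C1CC(O)C1")    # even ring: no tie; use 5-ring
  ring5 <- parse_smiles("OC1CCCC1")
  pol5 <- directed_polarization(ring5, center = 1)
  far_bond <- which(vapply(seq_len(nrow(ring5$bonds)), function(k) {
    d <- bond_distances(ring5, 1)
    d[ring5$bonds$i[k]] == d[ring5$bonds$j[k]]
  }, logical(1)))
  expect_true(length(far_bond) >= 1)
  expect_equal(pol5[far_bond], rep(0, length(far_bond)))
})

test_that("paired graphs have the documented feature lengths per mode", {
  p <- acid_base_pair("CC(=O)O", 4)
  full <- build_paired_graph(p$acid, p$base, p$center, mode = "full")
  expect_equal(ncol(full$e_attr), 14)
  expect_equal(ncol(full$x), 20)
  focused <- build_paired_graph(p$acid, p$base, p$center, mode = "focused")
  expect_equal(ncol(focused$e_attr), 10)
  acid_only <- build_paired_graph(p$acid, p$base, p$center, mode = "acid_only")
  base_only <- build_paired_graph(p$acid, p$base, p$center, mode = "base_only")
  expect_equal(ncol(acid_only$e_attr), 7)
  expect_equal(ncol(base_only$e_attr), 7)
  expect_equal(ncol(acid_only$x), 10)
  # center is relocated to index 1 with distance 0
  expect_equal(full$bond_dist[1], 0)
  expect_equal(full$mol_feats[["net_charge"]], -1)     # base form
  expect_equal(full$mol_feats[["center_charge"]], -1)
})

test_that("degenerate and mismatched pairs are handled", {
  # single heavy atom: H2S / HS-
  hs <- acid_base_pair("S", 1)
  g <- build_paired_graph(hs$acid, hs$base, 1)
  expect_equal(g$n_atoms, 1)
  expect_equal(nrow(g$edges), 0)
  expect_equal(g$mol_feats[["net_charge"]], -1)
  # different skeletons are refused
  expect_error(build_paired_graph(parse_smiles("CCO"), parse_smiles("CC[O-]C"),
                                  3), "structural mismatch")
  # same skeleton but wrong hydrogen delta is refused
  expect_error(build_paired_graph(parse_smiles("CCO"), parse_smiles("CCO"), 3),
               "one more\\s+hydrogen")
})

test_that("readout mask follows bond distance and always keeps the center", {
  p <- acid_base_pair(paste0("OC(=O)", strrep("C", 7)), 1)  # 9 heavy + O
  g <- build_paired_graph(p$acid, p$base, p$center)
  m6 <- compute_mask(g, 6)
  expect_true(m6[1])
  expect_equal(which(m6), which(g$bond_dist <= 6))
  expect_true(all(compute_mask(g, 99)))
  expect_equal(which(compute_mask(g, 0)), 1L)
  expect_error(compute_mask(g, -1), "non-negative")
})

test_that("graph randomization yields isomorphic graphs with the center fixed", {
  p <- acid_base_pair("OC(=O)CCCC", 1)
  g <- build_paired_graph(p$acid, p$base, p$center)
  set.seed(99)
  r <- randomize_graph(g)
  expect_equal(r$bond_dist[1], 0)
  expect_true(graphs_isomorphic(g, r))
  # features travel with their atoms: row multisets are preserved
  expect_equal(sort(apply(g$x, 1, paste, collapse = ",")),
               sort(apply(r$x, 1, paste, collapse = ",")))
  # identity on the trivial graph
  g1 <- build_paired_graph(parse_smiles("S"), parse_smiles("[SH-]"), 1)
  expect_identical(randomize_graph(g1), g1)
  # seeded determinism
  set.seed(5); a <- randomize_graph(g)
  set.seed(5); b <- randomize_graph(g)
  expect_identical(a, b)
})

test_that("featurization commutes with atom relabeling (fixing the center)", {
  mol <- parse_smiles("NCCC(F)C(=O)O")
  base <- remove_proton(mol, nrow(mol$atoms))
  g <- build_paired_graph(mol, base, nrow(mol$atoms))
  for (rep in 1:5) {
    n <- nrow(mol$atoms)
    perm <- c(sample(n - 1), n)  # keep the (last-atom) center in place
    pm <- permute_molecule(mol, perm)
    pb <- permute_molecule(base, perm)
    g2 <- build_paired_graph(pm, pb, which(perm == n), mode = "full")
    # same multiset of atom feature rows and bond feature rows
    expect_equal(sort(apply(g$x, 1, paste, collapse = ",")),
                 sort(apply(g2$x, 1, paste, collapse = ",")))
    expect_equal(sort(apply(g$e_attr, 1, paste, collapse = ",")),
                 sort(apply(g2$e_attr, 1, paste, collapse = ",")))
    expect_equal(sort(g$bond_dist), sort(g2$bond_dist))
  }
})
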