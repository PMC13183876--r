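test_that("parser perceives atoms, bonds and implicit hydrogens", {
  m <- parse_smiles("CC(=O)O")
  expect_equal(nrow(m$atoms), 4)
  expect_equal(nrow(m$bonds), 3)
  expect_equal(m$atoms$element, c("C", "C", "O", "O"))
  expect_equal(m$atoms$n_h, c(3L, 0L, 0L, 1L))
  expect_equal(net_charge(m), 0)

  # methylamine base vs methylammonium acid: valence bookkeeping
  base <- parse_smiles("CN")
  expect_equal(base$atoms$n_h[2], 2L)
  expect_equal(base$atoms$charge[2], 0L)
  acid <- parse_smiles("C[NH3+]")
  expect_equal(acid$atoms$n_h[2], 3L)
  expect_equal(acid$atoms$charge[2], 1L)
})

test_that("aromatic perception handles rings and bracket atoms", {
  ph <- parse_smiles("c1ccccc1O")
  expect_equal(sum(ph$atoms$aromatic), 6)
  expect_equal(ph$atoms$n_h, c(rep(1L, 5), 0L, 1L))
  pyr <- parse_smiles("c1cc[nH]c1")     # pyrrole needs bracketed nH
  expect_equal(pyr$atoms$n_h[4], 1L)
  naph <- parse_smiles("c1ccc2ccccc2c1")
  expect_equal(sum(naph$atoms$n_h), 8)  # fusion carbons carry no H
})

test_that("smallest-ring search labels ring atoms and leaves exocyclics at 0", {
  m <- parse_smiles("O=C1CCCC1")        # cyclopentanone
  ring <- smallest_ring_sizes(m)
  expect_equal(ring[1], 0L)             # exocyclic O
  expect_equal(ring[-1], rep(5L, 5))
  fused <- smallest_ring_sizes(parse_smiles("c1ccc2ccccc2c1"))
  expect_true(all(fused == 6L))
  big <- smallest_ring_sizes(parse_smiles("C1CCCCCCCCCC1"))  # 11-ring capped
  expect_true(all(big == 8L))
})

test_that("hybridization follows bond patterns", {
  m <- parse_smiles("N#CCC=CC")
  expect_equal(hybridizations(m), c("sp", "sp", "sp3", "sp2", "sp2", "sp3"))
  # hypervalent sulfonyl S stays sp3
  s <- parse_smiles("CS(=O)(=O)C")
  expect_equal(hybridizations(s)[2], "sp3")
})

test_that("multi-fragment input keeps the largest organic fragment", {
  expect_warning(m <- parse_smiles("[Na+].CC(=O)[O-]"), "largest fragment")
  expect_equal(nrow(m$atoms), 4)
  expect_equal(net_charge(m), -1)
})

test_that("malformed SMILES fail loudly with position information", {
  expect_error(parse_smiles("CC("), "unbalanced")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C%1"), "truncated")
  expect_error(parse_smiles("CXC"), "unsupported atom symbol")
})

test_that("perception agrees with an independent toolkit on a fixture set", {
  smiles <- c("CC(=O)O", "c1ccccc1O", "C[NH3+]", "NCC(=O)O", "c1cc[nH]c1",
              "O=S(=O)(N)c1ccccc1", "O=C1CCC(=O)N1", "N#CCCC(=O)O",
              "c1ccc2ccccc2c1", "NC(=N)N", "CC(=O)[O-]", "Clc1ccccc1S")
  script <- paste(
    "import sys, json",
    "from rdkit import Chem",
    "out = []",
    "for smi in json.load(sys.stdin):",
    "    m = Chem.MolFromSmiles(smi)",
    "    out.append({'n': m.GetNumAtoms(),",
    "                'h': [a.GetTotalNumHs() for a in m.GetAtoms()],",
    "                'ar': [a.GetIsAromatic() for a in m.GetAtoms()],",
    "                'q': [a.GetFormalCharge() for a in m.GetAtoms()]})",
    "print(json.dumps(out))", sep = "\n")
  res <- tryCatch(
    system2("python", c("-c", shQuote(script)),
            input = jsonlite::toJSON(smiles), stdout = TRUE, stderr = FALSE),
    error = function(e) NULL)
  expect_false(is.null(res))  # the oracle toolkit must be present
  ref <- jsonlite::fromJSON(paste(res, collapse = ""),
                            simplifyDataFrame = FALSE)
  for (k in seq_along(smiles)) {
    m <- parse_smiles(smiles[k])
    expect_equal(nrow(m$atoms), ref[[k]]$n, info = smiles[k])
    expect_equal(m$atoms$n_h, as.integer(ref[[k]]$h), info = smiles[k])
    expect_equal(m$atoms$aromatic, as.logical(ref[[k]]$ar), info = smiles[k])
    expect_equal(m$atoms$charge, as.integer(ref[[k]]$q), info = smiles[k])
  }
})
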