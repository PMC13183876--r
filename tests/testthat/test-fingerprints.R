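test_that("circular fingerprints are order-invariant and discriminate", {
  a <- morgan_fingerprint("c1ccccc1O")
  b <- morgan_fingerprint("Oc1ccccc1")
  expect_identical(a, b)
  expect_length(a, 2048)
  expect_true(all(a %in% c(0L, 1L)))
  expect_lt(tanimoto(morgan_fingerprint("CCCCO"),
                     morgan_fingerprint("c1ccncc1")), 0.3)
  expect_equal(tanimoto(a, a), 1)
})

test_that("tanimoto matrix agrees with the pairwise definition", {
  smiles <- c("CCO", "CCCO", "c1ccccc1", "CC(=O)O", "CCN")
  fps <- lapply(smiles, morgan_fingerprint)
  m <- tanimoto_matrix(fps)
  for (i in seq_along(fps)) for (j in seq_along(fps))
    expect_equal(m[i, j], tanimoto(fps[[i]], fps[[j]]))
})

test_that("records round-trip through CSV and rejects are reported", {
  lib <- generate_synthetic_library(synthetic_spec(n_molecules = 10, seed = 8))
  path <- tempfile(fileext = ".csv")
  write_records(lib, path)
  back <- read_records(path)
  expect_equal(back$smiles, lib$smiles)
  expect_equal(back$pka, lib$pka)
  expect_equal(back$center, lib$center)

  # one bad SMILES among five: four records, one logged reject
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("smiles,pka", "CCO,16", "CC(,4", "CCN,10.6", "CCS,10.5",
               "CC(=O)O,4.76"), path2)
  expect_warning(r <- read_records(path2), "rejected")
  expect_equal(nrow(r), 4)
  expect_equal(nrow(attr(r, "rejects")), 1)
  expect_equal(attr(r, "rejects")$smiles, "CC(")

  # empty file with header: empty tibble, no error
  path3 <- tempfile(fileext = ".csv")
  writeLines("smiles,pka", path3)
  expect_equal(nrow(read_records(path3)), 0)

  # conflicting duplicate labels: first kept, conflict logged
  path4 <- tempfile(fileext = ".csv")
  writeLines(c("smiles,pka", "CCO,16", "CCO,15.5"), path4)
  expect_warning(r4 <- read_records(path4), "conflicting")
  expect_equal(nrow(r4), 1)
  expect_equal(r4$pka, 16)
})

test_that("random split honors fractions and seeds", {
  lib <- generate_synthetic_library(synthetic_spec(n_molecules = 40, seed = 9))
  expect_true(all(random_split(lib, 0)$split == "train"))
  expect_true(all(random_split(lib, 1)$split == "test"))
  a <- random_split(lib, 0.3, seed = 7)
  b <- random_split(lib, 0.3, seed = 7)
  expect_identical(a$split, b$split)
  expect_equal(sum(a$split == "test"), 12)
})

test_that("cluster split enforces the similarity cap exactly", {
  lib <- generate_synthetic_library(synthetic_spec(n_molecules = 120,
                                                   seed = 10))
  sp <- cluster_split(lib, similarity_cap = 0.65, test_fraction = 0.2,
                      seed = 2)
  rep <- attr(sp, "split_report")
  expect_lte(rep$max_cross_similarity, 0.65)
  expect_lt(abs(rep$achieved_test_fraction - 0.2), 0.05 + 1e-9)
  # exhaustive post-hoc scan, independent of the split's own bookkeeping
  fps <- lapply(sp$smiles, morgan_fingerprint)
  is_test <- sp$split == "test"
  worst <- 0
  for (i in which(is_test)) for (j in which(!is_test))
    worst <- max(worst, tanimoto(fps[[i]], fps[[j]]))
  expect_lte(worst, 0.65)
})

test_that("near-duplicates are co-assigned and degenerate caps are refused", {
  recs <- tibble::tibble(
    smiles = c("CCCCCCCCO", "CCCCCCCCO", "c1ccncc1", "CC(=O)O", "CCCN",
               "CCSCC", "FC(F)(F)CO", "c1ccccc1", "CCCCS", "CNC"),
    pka = 1:10)
  sp <- cluster_split(recs, 0.65, 0.3, seed = 1)
  expect_equal(sp$split[1], sp$split[2])  # identical molecules stay together
  expect_error(cluster_split(recs, 1.0, 0.3), "strictly between")
  expect_error(cluster_split(recs, 0, 0.3), "strictly between")
})

test_that("augmentation produces labeled isomorphs with the center first", {
  lib <- generate_synthetic_library(synthetic_spec(n_molecules = 3, seed = 12))
  gs <- graphs_from_records(lib)
  aug <- augment(gs, n_copies = 50, seed = 4)
  expect_length(aug, 3 * 51)
  src <- attr(aug, "source")
  for (k in seq_along(aug)) {
    expect_equal(aug[[k]]$label, gs[[src[k]]]$label)
    expect_equal(aug[[k]]$bond_dist[1], 0)
    expect_true(graphs_isomorphic(aug[[k]], gs[[src[k]]]))
  }
  # n_copies = 0 returns only the originals
  expect_length(augment(gs, 0), 3)
  # seeded determinism
  a <- augment(gs, 5, seed = 9); b <- augment(gs, 5, seed = 9)
  expect_identical(a, b)
})
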