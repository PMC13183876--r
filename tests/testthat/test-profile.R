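test_that("the iterative protocol reproduces the glycine hand trace", {
  scorer <- rule_scorer(c(amine = 9.8, carboxylic_acid = 2.3))
  pr <- infer_ionization_profile("NCC(=O)O", scorer, pH = 7)
  expect_equal(nrow(pr$steps), 2)
  expect_equal(pr$steps$pka, c(9.8, 2.3))          # most basic first
  expect_equal(pr$steps$role, c("basic", "acidic"))
  st <- state_at_pH(pr, 7)
  expect_equal(st$net_charge, 0)                   # zwitterion
  expect_equal(st$mol$atoms$charge[1], 1L)         # ammonium up
  expect_equal(st$mol$atoms$charge[5], -1L)        # carboxylate down
})

test_that("one-site molecules need no iteration and match the scorer", {
  scorer <- rule_scorer(c(carboxylic_acid = 4.76))
  pr <- infer_ionization_profile("CC(=O)O", scorer)
  expect_equal(nrow(pr$steps), 1)
  expect_equal(pr$steps$pka, 4.76)
})

test_that("recorded values are strictly decreasing for injective scorers", {
  # three detected sites: two amines and one carboxylic acid
  smi <- "NCCCCC(N)C(=O)O"
  sites <- find_ionizable_sites(smi)
  expect_equal(nrow(sites), 3)
  vals <- c(10.7, 2.2, 9.1)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    assigned <- stats::setNames(vals[p], sites$atom_index)
    scorer <- function(mol, site) assigned[[as.character(site$atom_index)]]
    pr <- infer_ionization_profile(smi, scorer)
    expect_equal(nrow(pr$steps), 3)                 # exactly |sites| steps
    expect_true(all(diff(pr$steps$pka) < 0))        # strictly decreasing
    expect_setequal(pr$steps$pka, vals)
  }
})

test_that("ties go to the lowest atom index and symmetry is respected", {
  smi <- "OC(=O)CCC(=O)O"                           # succinic acid
  sites <- find_ionizable_sites(smi)
  expect_equal(nrow(sites), 2)
  scorer <- rule_scorer(c(carboxylic_acid = 4.2))
  pr <- infer_ionization_profile(smi, scorer)
  expect_equal(pr$steps$atom_index, sort(sites$atom_index))
  # reversing the input atom order leaves the recorded value pair unchanged
  pr2 <- infer_ionization_profile("OC(=O)CCC(=O)O", scorer)
  expect_equal(pr$steps$pka, pr2$steps$pka)
})

test_that("the final state is fully protonated regardless of the scorer", {
  smi <- "NCCCCC(N)C(=O)O"
  for (seedval in 1:3) {
    set.seed(seedval)
    noisy <- function(mol, site) stats::runif(1, 0, 14)
    pr <- infer_ionization_profile(smi, noisy)
    st <- state_at_pH(pr, -99)                      # protonate everything
    expect_equal(st$net_charge, 2)                  # 2 ammonium, 1 neutral acid
  }
})

test_that("pH extremes give the fully protonated and deprotonated states", {
  scorer <- rule_scorer(c(amine = 9.8, carboxylic_acid = 2.3))
  pr <- infer_ionization_profile("NCC(=O)O", scorer)
  lo <- state_at_pH(pr, 0)
  expect_equal(lo$net_charge, 1)                    # cation
  hi <- state_at_pH(pr, 14)
  expect_equal(hi$net_charge, -1)                   # anion
})

test_that("scorer failures propagate with the offending microstate attached", {
  bad <- function(mol, site) stop("boom")
  expect_error(infer_ionization_profile("NCC(=O)O", bad, pH = 7),
               "scorer failed on microstate")
  nonfinite <- function(mol, site) NaN
  expect_error(infer_ionization_profile("CC(=O)O", nonfinite),
               "non-finite")
})

test_that("profiles expose tidy, glance and JSON views", {
  scorer <- rule_scorer(c(amine = 9.8, carboxylic_acid = 2.3))
  pr <- infer_ionization_profile("NCC(=O)O", scorer, pH = 7)
  expect_equal(nrow(tidy(pr)), 2)
  gl <- glance(pr)
  expect_equal(gl$n_sites, 2)
  expect_equal(gl$net_charge_at_ph, 0)
  js <- jsonlite::fromJSON(profile_to_json(pr))
  expect_equal(js$n_sites, 2)
  expect_equal(js$state_at_ph$net_charge, 0)
})
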