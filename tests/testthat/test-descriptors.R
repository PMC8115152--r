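test_that("custom contribution tables: zeroed table, additivity, typing errors", {
  zero_tab <- alogp_table(data.frame(element = c("C", "O", "H"),
                                     hydrophobicity = 0, refractivity = 0))
  eth <- parse_smiles("CCO")
  expect_equal(alogp(eth, zero_tab), 0)
  expect_equal(molar_refractivity(eth, zero_tab), 0)

  tab <- alogp_table(data.frame(element = c("C", "O", "H"),
                                hydrophobicity = c(0.2, -0.1, 0.05),
                                refractivity = c(2.5, 1.6, 1.0)))
  frag <- parse_smiles("CCO")
  dimer <- parse_smiles("CCO.CCO")
  expect_equal(alogp(dimer, tab), 2 * alogp(frag, tab), tolerance = 1e-12)
  expect_equal(molar_refractivity(dimer, tab),
               2 * molar_refractivity(frag, tab), tolerance = 1e-12)

  no_o <- alogp_table(data.frame(element = c("C", "H"),
                                 hydrophobicity = 0.1, refractivity = 1))
  expect_error(alogp(eth, no_o), "atom 3 \\(O\\)")
})

test_that("default atom-contribution logP and MR agree with an independent reference implementation", {
  # frozen from RDKit's Crippen module (same published constants):
  # benzene 1.6866 / 26.442, ethanol -0.0014
  expect_equal(alogp(parse_smiles("c1ccccc1")), 1.6866, tolerance = 0.01)
  expect_equal(molar_refractivity(parse_smiles("c1ccccc1")), 26.442,
               tolerance = 0.1)
  expect_equal(alogp(parse_smiles("CCO")), -0.0014, tolerance = 0.01)
})

test_that("cosine-squared transform matches closed-form values and stays in [0, 1]", {
  expect_equal(cos2_transform(-4.31), 1)
  expect_equal(cos2_transform(8.66 * pi / 2 - 4.31), 0, tolerance = 1e-15)
  expect_equal(cos2_transform(4.35), cos(1)^2, tolerance = 1e-12)
  expect_equal(cos(1)^2, 0.29193, tolerance = 5e-5)

  vals <- cos2_transform(seq(-50, 50, length.out = 401))
  expect_true(all(vals >= 0 & vals <= 1))
  # periodic in A log P with period pi * 8.66
  x <- seq(-5, 5, length.out = 11)
  expect_equal(cos2_transform(x + pi * 8.66), cos2_transform(x),
               tolerance = 1e-12)
})

test_that("each qualifying functional-group pattern hits its positive and misses its negative", {
  cases <- list(
    benzene_ring       = c(pos = "c1ccccc1C", neg = "C1CCCCC1"),
    heterocyclic_ring  = c(pos = "c1ccncc1", neg = "c1ccccc1"),
    aliphatic_amine    = c(pos = "CCCN", neg = "Nc1ccccc1"),
    carboxamide        = c(pos = "CC(=O)N", neg = "CC(=O)C"),
    alcoholic_hydroxyl = c(pos = "CCO", neg = "Oc1ccccc1"),
    carboxy_ester      = c(pos = "CC(=O)OCC", neg = "CC(=O)O"),
    keto_group         = c(pos = "CC(=O)C", neg = "CC=O"))
  pats <- neoplastic_groups()
  for (nm in names(cases)) {
    for (side in c("pos", "neg")) {
      mol <- parse_smiles(cases[[nm]][[side]])
      hits <- ChemmineR::smartsSearchOB(skinperm:::.molblock_sdfset(mol$molblock),
                                        pats[[nm]], uniqueMatches = FALSE)
      expect_equal(unname(hits[1] > 0), side == "pos",
                   label = paste(nm, cases[[nm]][[side]]))
    }
  }
  expect_false(has_qualifying_group(parse_smiles("CCCCCC")))
  expect_true(has_qualifying_group(parse_smiles("CCO")))
})

test_that("the drug-likeness indicator requires the group and every bulk-property gate", {
  expect_equal(descriptor_vector("CCO")$neoplastic80, 0L)        # MW 46
  c30 <- paste(rep("C", 30), collapse = "")
  expect_equal(descriptor_vector(c30)$neoplastic80, 0L)          # no group

  # caffeine passes every gate (reference values: logP -1.03, MR ~51,
  # MW 194.19, 24 atoms, heterocyclic rings)
  caf <- descriptor_vector("Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  expect_equal(caf$neoplastic80, 1L)
  expect_gt(caf$mw, 180); expect_lt(caf$mw, 470)
  expect_gte(caf$n_atoms_total, 21); expect_lte(caf$n_atoms_total, 63)

  # gate independence: perturb one property out of range at a time
  mol <- parse_smiles("Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  ok <- list(alogp = caf$alogp, mr = caf$molar_refractivity, mw = caf$mw,
             n = caf$n_atoms_total)
  expect_equal(neoplastic80(mol, ok$alogp, ok$mr, ok$mw, ok$n), 1L)
  expect_equal(neoplastic80(mol, 5.0, ok$mr, ok$mw, ok$n), 0L)
  expect_equal(neoplastic80(mol, ok$alogp, 140, ok$mw, ok$n), 0L)
  expect_equal(neoplastic80(mol, ok$alogp, ok$mr, 500, ok$n), 0L)
  expect_equal(neoplastic80(mol, ok$alogp, ok$mr, ok$mw, 70), 0L)
  # group gate: n-hexane fails even with every bulk property in range
  expect_equal(neoplastic80(parse_smiles("CCCCCC"), 1, 60, 200, 30), 0L)
  # boundaries are inclusive
  expect_equal(neoplastic80(mol, -1.5, 43, 180, 21), 1L)
  expect_equal(neoplastic80(mol, 4.7, 128, 470, 63), 1L)
})

test_that("the descriptor vector is internally consistent", {
  d <- descriptor_vector("CCO")
  expect_equal(d$x3v, 0)
  expect_equal(d$neoplastic80, 0L)
  expect_equal(d$cos2_alogp, cos2_transform(d$alogp))
  expect_equal(d$n_atoms_total, 9L)

  tab <- descriptor_table(c("CCO", "c1ccccc1"), id = c("a", "b"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$cos2_alogp, cos2_transform(tab$alogp))
})
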