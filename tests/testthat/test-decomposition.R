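test_that("cyclo(Ala)6 yields 6 backbone amides and 6 identical capped units", {
  cp <- parseCyclicPeptide(cycloAlaSmiles(6), "cA6")
  cb <- cleavableBonds(cp)
  expect_equal(nrow(cb), 6L)
  expect_true(all(cb$class == "backbone_amide"))
  expect_equal(length(macrocycleAtoms(cp)), 18L)

  ss <- decomposePeptide(cp)
  expect_equal(nSubstructures(ss), 6L)
  expect_equal(length(unique(cappedSmiles(ss))), 1L)
  # capping rules applied by hand give CH3-NH-CH(CH3)-CHO
  expect_equal(unique(cappedSmiles(ss)), canonicalSmiles("CNC(C)C=O"))
})

test_that("disulfide-cyclized hexapeptide cleaves 5 amides + 1 S-S", {
  p <- generatePeptide(6, c("Ala", "Ser", "Phe"), seed = 3, disulfide = TRUE)
  cb <- identifyCleavableBonds(p$smiles, "ss6")
  expect_equal(sum(cb$class == "backbone_amide"), 5L)
  expect_equal(sum(cb$class == "disulfide"), 1L)

  ss <- decomposePeptide(p$smiles, "ss6")
  expect_equal(nSubstructures(ss), 6L)
  # the two cysteine fragments carry a free thiol
  expect_equal(sum(grepl("S", cappedSmiles(ss))), 2L)
})

test_that("side-chain amides are never divided", {
  smi <- cycloAla5Gln()
  mol <- MacrocyclePPB:::.parseMol(smi, "q6")
  # the molecule has 7 amide bonds in total: 6 backbone + 1 glutamine side
  expect_equal(nrow(MacrocyclePPB:::.amideBonds(mol)), 7L)
  cb <- identifyCleavableBonds(smi, "q6")
  expect_equal(nrow(cb), 6L)
  ss <- decomposePeptide(smi, "q6")
  expect_equal(nSubstructures(ss), 6L)
  # one fragment is the glutamine unit with its side-chain amide intact
  expect_equal(sum(cappedSmiles(ss) == canonicalSmiles("CNC(CCC(N)=O)C=O")), 1L)
})

test_that("decomposition partitions heavy atoms and orders fragments by ring adjacency", {
  set.seed(41)
  for (case in list(list(n = 5, ds = FALSE), list(n = 9, ds = TRUE),
                    list(n = 15, ds = FALSE))) {
    p <- generatePeptide(case$n, nMethylProb = 0.3, disulfide = case$ds)
    cp <- parseCyclicPeptide(p$smiles, "x")
    ss <- decomposePeptide(cp)
    expect_equal(nSubstructures(ss), case$n)
    pa <- parentAtoms(ss)
    # partition: every heavy atom in exactly one fragment
    expect_equal(sort(unlist(pa)), seq_along(cp@elem))
    # adjacency: consecutive fragments share a cleaved bond
    cb <- cleavableBonds(cp)
    for (i in seq_len(case$n)) {
      a <- pa[[i]]
      b <- pa[[(i %% case$n) + 1L]]
      joined <- any((cb$from %in% a & cb$to %in% b) |
                    (cb$from %in% b & cb$to %in% a))
      expect_true(joined, info = paste("positions", i - 1, "and", i %% case$n))
    }
  }
})

test_that("decomposition is deterministic and batch path matches single path", {
  p <- generatePeptide(8, seed = 12, nMethylProb = 0.25)
  s1 <- decomposePeptide(p$smiles, "a")
  s2 <- decomposePeptide(p$smiles, "a")
  expect_identical(s1@table, s2@table)
  batch <- decomposeSet(c(a = p$smiles))
  expect_identical(batch[["a"]]@table, s1@table)
})

test_that("non-cyclic and too-small inputs are rejected", {
  expect_error(parseCyclicPeptide("NC(C)C(=O)NC(C)C(=O)NC(C)C(=O)O", "lin"),
               "not a cyclic peptide")
  expect_error(parseCyclicPeptide("CCO", "ethanol"), "not a cyclic peptide")
  expect_error(parseCyclicPeptide(cycloAlaSmiles(4), "cA4"),
               "too few residues")
})
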