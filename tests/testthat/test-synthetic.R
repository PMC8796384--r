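test_that("homopolymer generation and decomposition agree by construction", {
  p <- generatePeptide(6, "Ala", seed = 1)
  ss <- decomposePeptide(p$smiles, "cA6")
  expect_equal(nSubstructures(ss), 6L)
  expect_equal(unique(cappedSmiles(ss)), canonicalSmiles("CNC(C)C=O"))
})

test_that("generator rejects invalid sizes and alphabets and is seeded", {
  expect_error(generatePeptide(4), "between 5 and 15")
  expect_error(generatePeptide(16), "between 5 and 15")
  expect_error(generatePeptide(6, c("Ala", "Xyz")), "unknown residue")
  s1 <- generatePeptide(8, seed = 42, nMethylProb = 0.3)
  s2 <- generatePeptide(8, seed = 42, nMethylProb = 0.3)
  expect_identical(s1, s2)
})

test_that("stitched generator graphs are canonically identical to parsed SMILES", {
  set.seed(17)
  for (rep in 1:6) {
    ds <- rep %% 3 == 0
    p <- generatePeptide(sample(5:12, 1), nMethylProb = 0.3, disulfide = ds)
    g <- get(p$smiles, envir = MacrocyclePPB:::.molCache)
    canG <- MacrocyclePPB:::.molBlocksToSmiles(
      MacrocyclePPB:::.molBlock(g$elem, g$coords, g$bonds, "g"))
    rm(list = p$smiles, envir = MacrocyclePPB:::.molCache)
    m <- MacrocyclePPB:::.parseMol(p$smiles, "m")
    canM <- MacrocyclePPB:::.molBlocksToSmiles(
      MacrocyclePPB:::.molBlock(m$elem, m$coords, m$bonds, "m"))
    expect_identical(canG, canM)
  }
})

test_that("every generated peptide decomposes with the requested residue count", {
  spec <- syntheticSpec(nPeptides = 30, seed = 23)
  ds <- generateDataset(spec)
  expect_equal(vapply(ds$decompositions, nSubstructures, integer(1),
                      USE.NAMES = FALSE),
               ds$truth$n_residues)
  expect_true(all(ds$records$ppb >= 0 & ds$records$ppb <= 100))
  expect_true(all(clampPPB(ds$records$ppb) >= 50 &
                  clampPPB(ds$records$ppb) <= 95))
})

test_that("default labels concentrate between the clamp boundaries with mass at both", {
  ds <- generateDataset(syntheticSpec(nPeptides = 150, seed = 31))
  y <- ds$records$ppb
  expect_gte(mean(y > 50 & y < 95), 0.6)
  expect_gte(sum(y <= 50), 1L)
  expect_gte(sum(y >= 95), 1L)
})

test_that("a noise-free label model is an exact function of the true features", {
  spec <- syntheticSpec(nPeptides = 40, sigma = 0, seed = 19)
  ds <- generateDataset(spec)
  pred <- spec$a + spec$b * ds$truth$mean_logp + spec$c * ds$truth$max_logp
  interior <- pred > 0 & pred < 100
  expect_gte(sum(interior), 10L)
  expect_equal(ds$records$ppb[interior], pred[interior], tolerance = 1e-12)
})

test_that("dataset generation is reproducible by seed", {
  d1 <- generateDataset(syntheticSpec(nPeptides = 12, seed = 77))
  d2 <- generateDataset(syntheticSpec(nPeptides = 12, seed = 77))
  expect_identical(d1$records, d2$records)
  expect_identical(d1$truth, d2$truth)
})
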