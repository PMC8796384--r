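test_that("descriptor computation covers the configured set and is pure", {
  expect_gte(length(availableDescriptors()), 40L)
  m <- computeDescriptors(c(benzene = "c1ccccc1", ethanol = "CCO"))
  expect_equal(dim(m), c(2L, length(availableDescriptors())))
  expect_true(all(is.finite(m)))
  expect_identical(attr(m, "engine"), MacrocyclePPB:::.DESCRIPTOR_ENGINE)
  # purity: recomputation gives the identical matrix
  expect_identical(m, computeDescriptors(c(benzene = "c1ccccc1", ethanol = "CCO")))
  # empty descriptor set
  e <- computeDescriptors("CCO", character(0))
  expect_equal(ncol(e), 0L)
  expect_error(computeDescriptors("CCO", "NoSuchDescriptor"), "unknown descriptor")
})

test_that("logP surrogate reproduces hydrophobicity orderings", {
  m <- computeDescriptors(c(benzene = "c1ccccc1", ethanol = "CCO",
                            ala = "CNC(C)C=O", phe = "CNC(Cc1ccccc1)C=O"),
                          "MolLogP")
  expect_gt(m["benzene", 1], m["ethanol", 1])
  expect_gt(m["phe", 1], m["ala", 1])
})

test_that("the default descriptors are finite on all 20 capped residue units", {
  units <- vapply(availableResidues(), function(r) {
    ss <- decomposePeptide(generatePeptide(5, r, seed = 1)$smiles, r)
    cappedSmiles(ss)[1]
  }, character(1))
  m <- computeDescriptors(units, defaultDescriptors())
  expect_true(all(is.finite(m)))
})

test_that("Z-score standardization matches its closed form", {
  x <- matrix(c(2, 4, 6), ncol = 1, dimnames = list(NULL, "d"))
  z <- standardizeDescriptors(x)
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # reference column statistics: mean 0, population sd 1 (tolerance 1e-9)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  # x equal to the reference mean maps to zero
  x2 <- matrix(4, 1, 1, dimnames = list(NULL, "d"))
  expect_equal(as.numeric(standardizeDescriptors(x2, x)), 0)
  # double standardization with the same reference is NOT idempotent
  z2 <- standardizeDescriptors(unclass(z), x)
  sigma <- sqrt(mean((c(2, 4, 6) - 4)^2))
  expect_equal(as.numeric(z2), (as.numeric(z) - 4) / sigma, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(as.numeric(z), as.numeric(z2))))
})

test_that("degenerate standardization columns are reported by name", {
  x <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2, dimnames = list(NULL, c("flat", "ok")))
  expect_error(fitStandardization(x), "flat")
})

test_that("frequency weighting scales rows by relative occurrence", {
  x <- matrix(1, 2, 3, dimnames = list(c("a", "b"), c("d1", "d2", "d3")))
  # equal counts: unchanged
  w1 <- weightByFrequency(x, c(a = 5, b = 5))
  expect_equal(unclass(w1)[, 1], c(a = 1, b = 1))
  # counts 10 vs 5: row b scaled by 0.5
  w2 <- weightByFrequency(x, c(a = 10, b = 5))
  expect_equal(unname(w2["b", ] / w2["a", ]), rep(0.5, 3))
  # sqrt strategy
  w3 <- weightByFrequency(x, c(a = 10, b = 5), "sqrt")
  expect_equal(unname(w3["b", 1]), sqrt(0.5))
  # "none" is the identity
  expect_equal(unclass(weightByFrequency(x, c(a = 10, b = 5), "none"))[, ],
               x[, ])
  # unseen substructures default to count 1
  w4 <- weightByFrequency(x, c(a = 10))
  expect_equal(unname(w4["b", 1]), 0.1)
  expect_error(weightByFrequency(x, c(a = 0, b = 1)), "counts")
})
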