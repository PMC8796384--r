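# Shared fixture builders. Everything is generated in code under fixed seeds.

# A centered feature map with seeded random values.
randomMap <- function(n, D = 3, seed = 1, id = "p") {
  set.seed(seed)
  buildFeatureMap(matrix(rnorm(D * n), D, n), id)
}

# Small same-length training set whose label is a monotone function of the
# first descriptor row.
tinyTrainSet <- function(npep = 10, n = 7, D = 3, seed = 2) {
  set.seed(seed)
  maps <- vector("list", npep)
  labels <- numeric(npep)
  for (i in seq_len(npep)) {
    block <- matrix(rnorm(D * n), D, n)
    maps[[i]] <- buildFeatureMap(block, paste0("p", i))
    labels[i] <- 50 + 45 * mean(pmax(block[1, ], 0))
  }
  list(maps = maps, labels = pmin(95, pmax(50, labels)))
}

# Low-capacity configuration that trains in seconds.
smallConfig <- function(variant = "baseline", epochs = 150L, seed = 1L,
                        batchSize = 16L, lr = 3e-3, ...) {
  ppbModelConfig(variant = variant, D = 3,
                 convLayers = list(list(kernel = 3, channels = 8),
                                   list(kernel = 3, channels = 16)),
                 fcLayers = c(16, 8), epochs = epochs, patience = Inf,
                 batchSize = batchSize, valFraction = 0, lr = lr,
                 seed = seed, ...)
}

# Training configuration used for the full synthetic-recovery experiments.
recoveryConfig <- function(seed = 1L, epochs = 120L) {
  ppbModelConfig(variant = "augmented", D = 3, epochs = epochs, patience = 20,
                 batchSize = 64, replicasPerEpoch = 8, seed = seed)
}

# cyclo(Ala)5-Gln: five alanines and one glutamine, head-to-tail.
cycloAla5Gln <- function() {
  paste0("N%99C(C)C(=O)", strrep("NC(C)C(=O)", 3),
         "NC(CCC(N)=O)C(=O)NC(C)C%99=O")
}
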