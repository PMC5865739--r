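# Small planted-signal cohort used across test files: 10 + 14 subjects,
# 20 regions, 60 time points, 5 planted pairs with a strong group contrast.
smallSpec <- function(seed = 3L) {
  syntheticSpec(n_group_a = 10L, n_group_b = 14L, n_regions = 20L,
                n_timepoints = 60L,
                planted_pairs = plantRandomPairs(5L, corr_a = 0.7,
                                                 corr_b = -0.3,
                                                 n_regions = 20L, seed = 5L),
                seed = seed)
}

smallDataset <- function(seed = 3L) {
  connectivityFeatures(generateCohort(smallSpec(seed)))
}

smallSplit <- function(ds, seed = 4L) {
  splitDataset(ds, sizes = c(16L, 2L, 6L), seed = seed)
}

# A scored small cluster for feature-selection tests.
smallCluster <- function(ds, split, k = 40L, seed = 5L) {
  cl <- buildCluster(ds, split, n = 16L, d = 14L, k = k, seed = seed)
  scoreMembers(cl, ds, split$validation_idx)
}

# A hand-made frequency table (bypassing featureFrequency) for contract tests.
freqTable <- function(feature, count, n_members = NA_integer_, d = NA_integer_) {
  structure(data.frame(feature = as.integer(feature),
                       count = as.integer(count)),
            n_members = n_members, d = d,
            class = c("featureFrequencyTable", "data.frame"))
}
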