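# Shared fixtures, built once per test run and cached. Everything is
# generated in code from the synthetic benchmark; no stored data files.

.fx <- new.env(parent = emptyenv())

# Small prepared benchmark (~600 compounds) for module-level tests.
fx_small <- function() {
  if (is.null(.fx$small)) {
    bm <- makeBenchmark("balanced", n_compounds = 600, seed = 7)
    cs <- suppressMessages(computeFeatureBlocks(bm$compounds))
    ca <- selectClusterCount(suppressMessages(conjointRepresentation(cs)),
                             k_range = c(11, 13), seed = 1)
    cs <- makeSplit(cs, ca$labels, seed = 1)
    cs <- suppressMessages(preprocessFeatures(cs))
    .fx$small <- encodeCompoundSet(cs)
  }
  .fx$small
}

# Full-scale prepared benchmark (n = 2000, 13 scaffold families) for the
# acceptance checks: automatic cluster-count selection, 3-cluster
# hold-out, 128-dimensional preprocessing.
fx_bench <- function() {
  if (is.null(.fx$bench)) {
    bm <- makeBenchmark("balanced", n_compounds = 2000, seed = 2026)
    cs <- suppressMessages(computeFeatureBlocks(bm$compounds))
    ca <- selectClusterCount(suppressMessages(conjointRepresentation(cs)),
                             k_range = 11:15, seed = 1)
    .fx$bench_quality <- ca$quality
    cs <- makeSplit(cs, ca$labels, seed = 1)
    cs <- suppressMessages(preprocessFeatures(cs))
    .fx$bench <- encodeCompoundSet(cs)
  }
  .fx$bench
}

# Severely imbalanced (~4:1) prepared benchmark for rebalancing checks.
fx_severe <- function() {
  if (is.null(.fx$severe)) {
    bm <- makeBenchmark("severe", n_compounds = 600, seed = 11)
    cs <- suppressMessages(computeFeatureBlocks(bm$compounds))
    ca <- selectClusterCount(suppressMessages(conjointRepresentation(cs)),
                             k_range = c(13), seed = 1)
    cs <- makeSplit(cs, ca$labels, seed = 1)
    cs <- suppressMessages(preprocessFeatures(cs))
    .fx$severe <- encodeCompoundSet(cs)
  }
  .fx$severe
}

# A property-matched decoy pool: same scaffold chemistry, no
# pharmacophore, generated apart from the benchmark library.
fx_decoy_pool <- function(n = 1200) {
  if (is.null(.fx$pool)) {
    spec <- syntheticSpec(n_compounds = n, p_pharmacophore = 0,
                          seed = 4242)
    .fx$pool <- generateLibrary(spec)$canonical_smiles
  }
  .fx$pool
}

expect_same_matrix <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a - b)) <= tol)
}
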