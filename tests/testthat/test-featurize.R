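test_that("descriptor rows are notation-invariant and chemically sensitive", {
  # ethanol in two notations, plus ethane
  cs <- CompoundSet(c("CCO", "OCC", "CC"))
  cs <- computeDescriptors(cs)
  m <- featureBlock(cs, "descriptors")
  expect_equal(ncol(m), length(descriptorPanel()))
  expect_equal(m[1, ], m[2, ])            # same molecule, two notations
  expect_true(any(m[1, ] != m[3, ]))      # ethanol differs from ethane
})

test_that("fingerprints have the canonical widths and are binary", {
  cs <- CompoundSet(c("CCO", "c1ccccc1C(=O)O"))
  cs <- computeFingerprint(cs, "maccs")
  cs <- computeFingerprint(cs, "ecfp4")
  maccs <- featureBlock(cs, "maccs"); ecfp <- featureBlock(cs, "ecfp4")
  expect_equal(ncol(maccs), 166L)
  expect_equal(ncol(ecfp), 2048L)
  expect_true(all(maccs %in% c(0L, 1L)))
  expect_true(all(ecfp %in% c(0L, 1L)))
  # Tanimoto self-similarity is 1
  tani <- ChemFusion:::.tanimoto(ecfp, ecfp)
  expect_equal(diag(tani), c(1, 1))
})

test_that("identical canonical SMILES give identical fingerprints", {
  cs <- fx_small()
  smi <- canonicalSmiles(cs)[1]
  one <- computeFingerprint(CompoundSet(smi), "ecfp4")
  two <- computeFingerprint(CompoundSet(smi), "ecfp4")
  expect_identical(featureBlock(one, "ecfp4"), featureBlock(two, "ecfp4"))
})

test_that("the zero-variance filter drops constant columns and records indices", {
  m <- cbind(a = c(1, 2, 3), b = c(0, 0, 0), c = c(5, 5, 6))
  r <- dropZeroVariance(m)
  expect_equal(ncol(r), 2L)
  expect_equal(attr(r, "kept"), c(1L, 3L))
  m2 <- cbind(c(1, 2), c(3, 1))
  expect_equal(ncol(dropZeroVariance(m2)), 2L)  # no constant columns: identity
  expect_error(dropZeroVariance(cbind(c(1, 1), c(2, 2))), "constant")
})

test_that("standardization hits mean 0 / population SD 1 on fit rows only", {
  m <- cbind(c(1, 2, 3))
  s <- fitApplyStandardizer(m)
  expect_equal(s$matrix[, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(s$matrix[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # idempotent on already-standardized fit rows
  s2 <- fitApplyStandardizer(s$matrix)
  expect_same_matrix(s2$matrix, s$matrix, tol = 1e-9)
  expect_error(fitApplyStandardizer(cbind(c(2, 2, 2))), "zero-variance")
  # held-out rows use the fit statistics
  m3 <- matrix(rnorm(40), 10)
  st <- fitApplyStandardizer(m3, fit_rows = 1:6)
  expect_lt(max(abs(colMeans(st$matrix[1:6, ]))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(st$matrix[1:6, ], 2,
    colMeans(st$matrix[1:6, ]))^2)) - 1)), 1e-9)
})

test_that("PCA projects to the target width with non-increasing variance", {
  set.seed(2)
  m <- matrix(rnorm(200 * 20), 200)
  p <- pcaReduce(m, target_dim = 10L)
  expect_equal(ncol(p$matrix), 10L)
  expect_true(all(diff(p$explained_variance) <= 1e-10))
  expect_error(pcaReduce(m, target_dim = 30L), "below target")
  expect_error(pcaReduce(m, fit_rows = 1:5, target_dim = 10L), "fit rows")
})

test_that("full-rank PCA preserves pairwise distances", {
  set.seed(3)
  base <- matrix(rnorm(40 * 5), 40)
  m <- base %*% matrix(rnorm(5 * 30), 5)  # exact rank 5 in 30 dims
  expect_error(pcaReduce(m, target_dim = 31L), "below target")
  p <- pcaReduce(m, target_dim = 5L)
  d0 <- dist(m); d1 <- dist(p$matrix)
  expect_lt(max(abs(d0 - d1)), 1e-8)
})

test_that("non-finite descriptor values are imputed by fit-row medians", {
  m <- cbind(c(1, NaN, 3, 5), c(2, 4, Inf, 8))
  r <- suppressMessages(imputeNonFinite(m, fit_rows = 1:4))
  expect_equal(r$matrix[2, 1], 3)   # median of 1,3,5
  expect_equal(r$matrix[3, 2], 4)   # median of 2,4,8
  expect_true(all(is.finite(r$matrix)))
})

test_that("preprocessing state depends only on the fit rows", {
  cs <- fx_small()
  st1 <- metadata(suppressMessages(preprocessFeatures(cs)))$preprocess
  cs2 <- cs
  test_rows <- which(partitions(cs2) == "test")
  blk <- featureBlock(cs2, "ecfp4")
  blk[test_rows, ] <- 1L - blk[test_rows, , drop = FALSE]  # corrupt test rows
  featureBlock(cs2, "ecfp4") <- blk
  st2 <- metadata(suppressMessages(preprocessFeatures(cs2)))$preprocess
  expect_equal(st1$states$ecfp4$rotation, st2$states$ecfp4$rotation)
  expect_equal(st1$states$ecfp4$center2, st2$states$ecfp4$center2)
})

test_that("fusion concatenates blocks in combo order with recoverable boundaries", {
  cs <- fx_small()
  f8 <- fuseBlocks(cs, 8)
  expect_equal(ncol(f8$matrix), 3L * 128L)
  expect_equal(f8$blocks, c("descriptors", "ecfp4", "maccs"))
  f1 <- fuseBlocks(cs, 1)
  expect_identical(f1$matrix, featureBlock(cs, "descriptors.128"))
  f7 <- fuseBlocks(cs, 7)
  expect_equal(f7$blocks, c("maccs", "ecfp4"))
  expect_identical(f7$matrix[, 1:128], featureBlock(cs, "maccs.128"))
  expect_identical(f7$matrix[, 129:256], featureBlock(cs, "ecfp4.128"))
  # slicing at the boundaries recovers the inputs exactly
  parts <- splitFused(f8)
  for (mod in f8$blocks)
    expect_identical(parts[[mod]], featureBlock(cs, paste0(mod, ".128")))
  expect_error(fuseBlocks(cs, 9), "unknown combo")
  expect_error(fuseBlocks(cs, 4), "token")
})

test_that("transforming new compounds reuses the fitted state exactly", {
  cs <- fx_small()
  st <- metadata(cs)$preprocess$states$ecfp4
  raw <- featureBlock(cs, "ecfp4")
  redo <- applyPreprocess(st, raw)
  expect_same_matrix(redo, featureBlock(cs, "ecfp4.128"), tol = 1e-8)
})
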