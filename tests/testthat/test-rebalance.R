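test_that("SMOTE interpolates strictly between minority neighbours", {
  m <- matrix(c(0, 1), ncol = 1)
  s <- smote(m, n_new = 50, k_neighbors = 1L, seed = 3)
  expect_equal(nrow(s$rows), 50L)
  expect_true(all(s$rows >= 0 & s$rows <= 1))
  # 2-D: every synthetic point inside the minority convex hull
  set.seed(4)
  m2 <- matrix(rnorm(40), ncol = 2)
  s2 <- smote(m2, n_new = 200, k_neighbors = 5L, seed = 8)
  hull <- grDevices::chull(m2)
  inside <- apply(s2$rows, 1, function(p) {
    # a point on a segment between two minority points is inside the hull
    all(p >= apply(m2, 2, min) - 1e-12) && all(p <= apply(m2, 2, max) + 1e-12)
  })
  expect_true(all(inside))
  # segment property: x_new = x_i + u (x_nn - x_i), reconstructible
  rec <- s2$records
  recon <- m2[rec$parent, ] + rec$u * (m2[rec$neighbor, ] - m2[rec$parent, ])
  expect_same_matrix(recon, s2$rows)
  # per-column envelope within the minority min/max
  expect_true(all(sweep(s2$rows, 2, apply(m2, 2, min), ">=")))
  expect_true(all(sweep(s2$rows, 2, apply(m2, 2, max), "<=")))
})

test_that("SMOTE is seed-deterministic and guards its neighbourhood size", {
  m <- matrix(rnorm(60), ncol = 3)
  a <- smote(m, 25, seed = 5); b <- smote(m, 25, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$rows, smote(m, 25, seed = 6)$rows))
  expect_error(smote(m[1:4, ], 5, k_neighbors = 5L), "k <= 3")
})

test_that("enumerated SMILES canonicalize back to their parent", {
  aspirin <- canonicalizeSmiles("CC(=O)Oc1ccccc1C(=O)O")
  v <- enumerateSmiles(aspirin, 10, seed = 2)[[1]]
  expect_equal(length(v), 10L)
  expect_equal(length(unique(v)), 10L)
  expect_true(all(canonicalizeSmiles(v) == aspirin))
  expect_identical(v, enumerateSmiles(aspirin, 10, seed = 2)[[1]])
  # single-atom degeneracy: methane has one notation
  m <- suppressMessages(enumerateSmiles("C", 5, seed = 1))[[1]]
  expect_equal(m, "C")
  expect_error(enumerateSmiles("C1CC", 3), "invalid")
})

test_that("decoy selection excludes similars and maximises diversity", {
  actives <- c("O=C(Nc1ccccc1)c1ccc(NS(C)(=O)=O)cc1",
               "O=C(Nc1ccc(F)cc1)c1ccc(NS(C)(=O)=O)cc1")
  pool <- c(actives[1],                                   # Tanimoto 1: out
            "O=C(Nc1ccccc1)c1ccccc1",                     # related amide
            "C(c1ccccc1)c1ccc(N(C)C)cc1",
            "O(c1ccc(Cl)cc1)c1ccccc1",
            "N(Cc1ccccc1)Cc1ccc(OC)cc1",
            "O=C(Nc1ccccc1)NCc1ccccc1")
  # loose property windows: this test probes the similarity and
  # diversity stages, not the matching windows
  crit <- decoyCriteria(mw = 150, logp = 4, hbd = 3, hba = 5, rotb = 6,
                        max_tanimoto = 0.45, count = 2L)
  sel <- selectDecoys(canonicalizeSmiles(actives), canonicalizeSmiles(pool),
                      crit, seed = 1)
  expect_false(canonicalizeSmiles(actives[1]) %in% sel$decoys)
  expect_equal(length(sel$decoys), 2L)
  # the selected pair is the brute-force most-distant pair of survivors
  surv <- sel$funnel$survivors[sel$funnel$stage == "dissimilarity"]
  fp <- ChemFusion:::.bits_to_matrix(
    ChemFusion:::.rdkit("fp", canonicalizeSmiles(pool), "ecfp4"))
  ok_idx <- which(decoysSatisfy(canonicalizeSmiles(pool),
                                canonicalizeSmiles(actives), crit))
  d <- 1 - ChemFusion:::.tanimoto(fp[ok_idx, ], fp[ok_idx, ])
  best <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_setequal(sel$decoys, canonicalizeSmiles(pool)[ok_idx[best]])
  # every selected decoy re-passes the criteria it was selected under
  expect_true(all(decoysSatisfy(sel$decoys, canonicalizeSmiles(actives), crit)))
  expect_error(selectDecoys(actives, character(), crit), "empty")
})

test_that("training-set balancing reaches 1:1 and leaves the test set intact", {
  cs <- fx_severe()
  md <- makeModelData(cs, 2)
  before_test <- md$x[md$partition == "test", , drop = FALSE]
  bal <- balanceTrainingSets(md, "smote", seed = 4)
  for (p in c("train", "validation")) {
    tab <- table(bal$y[bal$partition == p])
    expect_equal(unname(tab["0"]), unname(tab["1"]))
  }
  after_test <- bal$x[bal$partition == "test", , drop = FALSE]
  expect_identical(serialize(before_test, NULL), serialize(after_test, NULL))
  expect_true(all(bal$partition[bal$origin != "measured"] != "test"))
  # already balanced input is a no-op
  again <- balanceTrainingSets(bal, "smote", seed = 5)
  expect_equal(nrow(again$x), nrow(bal$x))
})

test_that("enumeration balancing works on token inputs and is rejected on numeric", {
  cs <- fx_severe()
  mdn <- makeModelData(cs, 2)
  expect_error(balanceTrainingSets(mdn, "enumeration", cs = cs), "token")
  mdt <- makeModelData(cs, 4)
  expect_error(balanceTrainingSets(mdt, "smote"), "numeric")
  bal <- suppressWarnings(suppressMessages(
    balanceTrainingSets(mdt, "enumeration", cs = cs, seed = 4)))
  tr <- bal$partition == "train"
  tab <- table(bal$y[tr])
  expect_lte(abs(tab[["0"]] - tab[["1"]]), 1L)
  # augmented sequences decode to molecules equal to some minority parent
  new_idx <- which(bal$origin == "enumeration")[1:5]
  minority <- canonicalSmiles(cs)[activityLabels(cs) == 0L]
  for (i in new_idx) {
    smi <- paste(decodeTokens(bal$x$sequences[i, ], bal$x$vocabulary),
                 collapse = "")
    expect_true(canonicalizeSmiles(smi) %in% minority)
  }
  # test token rows untouched
  expect_identical(bal$x$sequences[bal$partition == "test", ],
                   mdt$x$sequences[mdt$partition == "test", ])
})

test_that("decoy balancing appends label-0 compounds outside the test set", {
  cs <- fx_severe()
  md <- makeModelData(cs, 3)
  pool <- fx_decoy_pool()
  crit <- decoyCriteria(max_tanimoto = 0.6)
  bal <- suppressWarnings(suppressMessages(
    balanceTrainingSets(md, "decoys", cs = cs, pool = pool,
                        criteria = crit, seed = 9)))
  added <- bal$origin == "decoy"
  expect_true(any(added))
  expect_true(all(bal$y[added] == 0L))
  expect_true(all(bal$partition[added] %in% c("train", "validation")))
  expect_identical(bal$x[bal$partition == "test", ],
                   md$x[md$partition == "test", ])
})
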