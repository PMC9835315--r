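test_that("activity tables parse with field mapping and rejection report", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("smi,type,val,u,id",
               "CCO,IC50,500,nM,a",
               "CCN,Ki,2,uM,b",
               "CCC,Kd,1,pM,c",
               "CCF,IC50,oops,nM,d",
               ",IC50,1,nM,e"), f)
  rec <- suppressMessages(
    parseActivityTable(f, c(smiles = "smi", assay_type = "type",
                            value = "val", unit = "u", source_id = "id")))
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$smiles_raw, c("CCO", "CCN"))
  expect_equal(rec$value, c(500, 2))
  expect_equal(rec$unit, c("nM", "uM"))
  rej <- attr(rec, "rejected")
  expect_equal(nrow(rej), 3L)
  expect_setequal(rej$reason, c("unknown unit",
                                "unparseable or non-positive value",
                                "empty SMILES"))
})

test_that("an empty table yields an empty collection with a warning", {
  f <- tempfile(fileext = ".csv")
  writeLines("smiles,assay_type,value,unit", f)
  expect_warning(rec <- parseActivityTable(f), "empty")
  expect_equal(nrow(rec), 0L)
  expect_error(parseActivityTable(tempfile(), ), "not found")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), f2)
  expect_error(parseActivityTable(f2), "absent")
})

test_that("unit conversion to micromolar is exact and round-trips", {
  expect_equal(convertToMicromolar(500, "nM"), 0.5)
  expect_equal(convertToMicromolar(1.0, "uM"), 1.0)
  expect_equal(convertToMicromolar(0.002, "mM"), 2.0)
  expect_equal(convertToMicromolar(1, "µM"), 1)  # Greek mu spelling
  expect_error(convertToMicromolar(1, "pM"), "pM")
  # round trip uM -> nM -> uM at machine precision
  v <- c(0.037, 1.5, 820)
  nm <- v * 1e3
  expect_equal(convertToMicromolar(nm, "nM"), v)
})

test_that("canonicalization unifies notations and is idempotent", {
  out <- canonicalizeSmiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(out[1], out[2])
  out2 <- canonicalizeSmiles(c("OCC", "CCO"))
  expect_identical(out2[1], out2[2])
  expect_identical(canonicalizeSmiles(out), out)
  expect_error(canonicalizeSmiles("C1CC"), "C1CC")
  expect_identical(canonicalizeSmiles(character()), character())
})

test_that("duplicate aggregation takes the median and keeps the audit count", {
  agg <- aggregateDuplicates(c("CCO", "CCO"), c(0.4, 0.6))
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$activity_um, 0.5)
  expect_equal(agg$n_merged, 2L)
  agg3 <- aggregateDuplicates(c("CCO", "CCO", "CCO"), c(0.4, 0.5, 10.0))
  expect_equal(agg3$activity_um, 0.5)
  # all-unique input is the identity with n_merged 1
  u <- aggregateDuplicates(c("CCO", "CCN"), c(1, 2))
  expect_equal(u$activity_um, c(1, 2))
  expect_equal(u$n_merged, c(1L, 1L))
})

test_that("aggregation never increases counts and n_merged sums to input size", {
  set.seed(5)
  for (rep in 1:5) {
    smi <- sample(paste0("M", 1:8), 40, replace = TRUE)
    act <- stats::runif(40, 0.01, 100)
    agg <- aggregateDuplicates(smi, act)
    expect_lte(nrow(agg), 40L)
    expect_equal(sum(agg$n_merged), 40L)
    expect_false(anyDuplicated(agg$canonical_smiles) > 0)
  }
})

test_that("labels use strict < at the cutoff and report class counts", {
  cmp <- data.frame(canonical_smiles = c("A", "B", "C"),
                    activity_um = c(0.4, 0.5, 12))
  cs <- suppressMessages(assignLabels(cmp, 0.5))
  expect_equal(activityLabels(cs), c(1L, 0L, 0L))
  cs10 <- suppressMessages(assignLabels(cmp, 10))
  expect_equal(activityLabels(cs10), c(1L, 1L, 0L))
  expect_warning(suppressMessages(assignLabels(cmp, 2)), "standard set")
})

test_that("raising the cutoff never flips an active label to inactive", {
  set.seed(9)
  act <- 10^stats::runif(50, -3, 3)
  cmp <- data.frame(canonical_smiles = paste0("M", 1:50), activity_um = act)
  labs <- sapply(c(0.5, 1, 10), function(co)
    activityLabels(suppressMessages(assignLabels(cmp, co))))
  expect_true(all(diff(t(labs)) >= 0))
})

test_that("curation canonicalizes, merges and labels end to end", {
  rec <- data.frame(smiles_raw = c("OCC", "CCO", "C1CC1", "bogus("),
                    assay_type = "IC50",
                    value = c(300, 500, 2, 1), unit = c("nM", "nM", "uM", "uM"))
  cs <- suppressMessages(curateCompounds(rec, 0.5))
  expect_equal(length(cs), 2L)  # ethanol merged, invalid dropped
  cd <- compoundData(cs)
  eth <- cd[cd$n_merged == 2L, ]
  expect_equal(eth$activity_um, 0.4)  # median of 0.3 and 0.5
  expect_equal(eth$label, 1L)
})

test_that("the curated CSV schema round-trips", {
  cs <- suppressMessages(assignLabels(
    data.frame(canonical_smiles = c("CCO", "CCN"),
               activity_um = c(0.2, 30), n_merged = c(2L, 1L)), 1))
  f <- tempfile(fileext = ".csv")
  writeCuratedCsv(cs, f)
  cs2 <- readCuratedCsv(f)
  expect_equal(as.data.frame(compoundData(cs2)),
               as.data.frame(compoundData(cs)))
})

test_that("SDF activity records are read through ChemmineR", {
  sdf <- ChemmineR::smiles2sdf(c(mol1 = "CCO", mol2 = "c1ccccc1"))
  ChemmineR::datablock(sdf) <- list(
    c(assay_type = "IC50", value = "500", unit = "nM"),
    c(assay_type = "Ki", value = "2", unit = "uM"))
  f <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  rec <- readSdfActivities(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$value, c(500, 2))
  expect_equal(canonicalizeSmiles(rec$smiles_raw),
               canonicalizeSmiles(c("CCO", "c1ccccc1")))
})
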