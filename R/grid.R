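#' The 15-experiment design table
#'
#' Experiments 1-7 train the nine classical families on the seven numeric
#' feature combinations; 8-14 train the fusion network on the same
#' combinations; 15 trains the SMILES sequence network.
#'
#' @return data.frame with `experiment`, `model_kind`, `combo_id`.
#' @export
experimentTable <- function() {
  data.frame(
    experiment = 1:15,
    model_kind = c(rep("ML", 7), rep("FusionNet", 7), "SmilesNet"),
    combo_id = c(c(1, 2, 3, 5, 6, 7, 8), c(1, 2, 3, 5, 6, 7, 8), 4))
}

#' The fifteen experiment groups
#'
#' Groups I-V run the classical experiments at the three cutoffs and,
#' at 10 uM, with SMOTE (IV) or decoy selection (V); VI-X repeat the
#' pattern for the fusion network and XI-XV for the SMILES network (with
#' SMILES enumeration instead of SMOTE).
#'
#' @return data.frame with `group`, `experiments`, `cutoff_um`,
#'   `strategy`.
#' @export
groupTable <- function() {
  data.frame(
    group = c("I", "II", "III", "IV", "V",
              "VI", "VII", "VIII", "IX", "X",
              "XI", "XII", "XIII", "XIV", "XV"),
    experiments = c(rep("1-7", 5), rep("8-14", 5), rep("15", 5)),
    cutoff_um = rep(c(0.5, 1, 10, 10, 10), 3),
    strategy = rep(c("none", "none", "none", "balance", "decoys"), 3),
    stringsAsFactors = FALSE)
}

.group_experiments <- function(expts) {
  r <- as.integer(strsplit(expts, "-")[[1]])
  if (length(r) == 1L) r else seq(r[1], r[2])
}

# Strategy actually applied in a cell: "balance" means SMOTE for numeric
# inputs and SMILES enumeration for token inputs.
.cell_strategy <- function(strategy, model_kind) {
  if (strategy == "none") return("none")
  if (strategy == "decoys") return("decoys")
  if (model_kind == "SmilesNet") "enumeration" else "smote"
}

#' Prepare a labeled compound set for modelling
#'
#' Runs featurization, conjoint clustering, the cluster hold-out split,
#' leakage-free preprocessing and SMILES token encoding in order.
#'
#' @param cs A labeled [CompoundSet-class] (e.g. from [makeBenchmark()]
#'   or [curateCompounds()]).
#' @param k Either `"auto"` (select by internal indices over `k_range`)
#'   or a fixed integer cluster count.
#' @param k_range Candidate k values when `k = "auto"`.
#' @param seed Integer seed.
#' @param target_dim Processed block width (default 128).
#' @param max_len Token length cap (default 195).
#' @param n_test_clusters,val_fraction Split parameters ([makeSplit()]).
#' @return A prepared [CompoundSet-class]; cluster quality (when
#'   `k = "auto"`) is stored in `metadata(cs)$cluster_quality`.
#' @export
prepareDataset <- function(cs, k = "auto", k_range = 2:15, seed = 1L,
                           target_dim = 128L, max_len = 195L,
                           n_test_clusters = 3L, val_fraction = 0.05) {
  cs <- computeFeatureBlocks(cs)
  conj <- conjointRepresentation(cs)
  if (identical(k, "auto")) {
    ca <- selectClusterCount(conj, k_range = k_range, seed = seed)
    clusters <- ca$labels
    md <- metadata(cs); md$cluster_quality <- ca$quality; metadata(cs) <- md
  } else {
    clusters <- withSeed(seed, .kmeanspp(conj, as.integer(k))$cluster)
  }
  cs <- makeSplit(cs, clusters, n_test_clusters = n_test_clusters,
                  val_fraction = val_fraction, seed = seed)
  cs <- preprocessFeatures(cs, fit_scope = "train", target_dim = target_dim)
  encodeCompoundSet(cs, max_len = max_len)
}

# One seeded end-to-end cell run: optional rebalance, optional randomized
# search, train, evaluate on the (untouched) test partition.
.run_cell_seed <- function(cs, md, model_kind, family, strategy, seed,
                           search = TRUE, n_iter = 10L, n_folds = 5L,
                           net_config = attentionConfig(),
                           pool = NULL, criteria = decoyCriteria()) {
  if (strategy != "none")
    md <- balanceTrainingSets(md, strategy, cs = cs, pool = pool,
                              criteria = criteria, seed = seed)
  trval <- md$partition %in% c("train", "validation")
  test <- md$partition == "test"
  if (model_kind == "ML") {
    x <- md$x
    hyper <- if (search) {
      suppressWarnings(
        randomizedSearch(family, x[trval, , drop = FALSE], md$y[trval],
                         n_iter = n_iter, n_folds = n_folds,
                         seed = seed))$best
    } else list()
    fit <- trainClassifier(family, x[trval, , drop = FALSE], md$y[trval],
                           hyper, seed = seed)
    scores <- predictScores(fit, x[test, , drop = FALSE])
  } else {
    tr <- md$partition == "train"; va <- md$partition == "validation"
    if (model_kind == "FusionNet") {
      n_blocks <- length(featureCombos()[[as.character(md$combo_id)]])
      net <- buildFusionNet(net_config, n_blocks = n_blocks,
                            input_dim = ncol(md$x) / n_blocks, seed = seed)
      net <- trainNetwork(net, md$x[tr, , drop = FALSE], md$y[tr],
                          md$x[va, , drop = FALSE], md$y[va], seed = seed)
      scores <- predictScores(net, md$x[test, , drop = FALSE])
    } else {
      net <- buildSmilesNet(net_config, md$x$vocabulary, seed = seed)
      sel <- function(i) list(sequences = md$x$sequences[i, , drop = FALSE],
                              lengths = md$x$lengths[i],
                              vocabulary = md$x$vocabulary)
      net <- trainNetwork(net, sel(tr), md$y[tr], sel(va), md$y[va],
                          seed = seed)
      scores <- predictScores(net, sel(test))
    }
  }
  computeMetrics(as.integer(scores >= 0.5), scores, md$y[test])
}

#' Run (a subset of) the experiment grid
#'
#' Executes the requested cells of the group x experiment design on
#' prepared datasets, repeating each cell over the configured seeds and
#' aggregating ACC/F1/AUC (mean, population SD). Infeasible cells (an
#' augmentation strategy incompatible with the cell's input kind) are
#' skipped with a reason.
#'
#' @param datasets Named list of prepared [CompoundSet-class] objects
#'   keyed by cutoff (`"0.5"`, `"1"`, `"10"`); only the cutoffs used by
#'   the selected groups are required.
#' @param groups Group ids to run (default all 15).
#' @param experiments Experiment numbers to run within each group.
#' @param families Classical families for ML experiments.
#' @param seeds Seeds per cell (the study design uses 30).
#' @param search Run randomized hyperparameter search per seed (classical
#'   families).
#' @param n_iter,n_folds Randomized-search settings.
#' @param net_config [attentionConfig()] for the networks.
#' @param pool,criteria Decoy pool and criteria for decoy groups.
#' @return List with `results` (tidy data.frame: one row per cell x
#'   metric) and `summaries` (per-cell `MetricSummary`), plus `skipped`.
#' @export
runExperimentGrid <- function(datasets, groups = groupTable()$group,
                              experiments = 1:15,
                              families = setdiff(modelFamilies(),
                                                 c("FusionNet", "SmilesNet")),
                              seeds = 1:3, search = TRUE, n_iter = 10L,
                              n_folds = 5L, net_config = attentionConfig(),
                              pool = NULL, criteria = decoyCriteria()) {
  gt <- groupTable(); et <- experimentTable()
  results <- NULL; summaries <- list(); skipped <- list()
  for (g in groups) {
    grow <- gt[gt$group == g, ]
    cutoff_key <- as.character(grow$cutoff_um)
    if (!cutoff_key %in% names(datasets)) {
      skipped[[g]] <- sprintf("no dataset for cutoff %s uM", cutoff_key)
      next
    }
    cs <- datasets[[cutoff_key]]
    for (e in intersect(.group_experiments(grow$experiments), experiments)) {
      erow <- et[et$experiment == e, ]
      strat <- .cell_strategy(grow$strategy, erow$model_kind)
      if (strat == "enumeration" && erow$model_kind != "SmilesNet") {
        skipped[[paste(g, e)]] <- "enumeration needs token inputs"
        next
      }
      if (strat == "decoys" && is.null(pool)) {
        skipped[[paste(g, e)]] <- "decoy strategy requested without a pool"
        next
      }
      md0 <- makeModelData(cs, erow$combo_id)
      fams <- if (erow$model_kind == "ML") families else erow$model_kind
      for (fam in fams) {
        summ <- repeatOverSeeds(function(s)
          .run_cell_seed(cs, md0, erow$model_kind, fam, strat, s,
                         search = search, n_iter = n_iter,
                         n_folds = n_folds, net_config = net_config,
                         pool = pool, criteria = criteria),
          seeds)
        key <- sprintf("%s_exp%d_%s", g, e, fam)
        summaries[[key]] <- summ
        results <- rbind(results, data.frame(
          group = g, experiment = e, family = fam,
          combo_id = erow$combo_id, strategy = strat,
          metric = names(summ$mean),
          mean_pct = 100 * unname(summ$mean),
          sd_pct = 100 * unname(summ$sd),
          n_seeds = summ$n_seeds))
      }
    }
  }
  list(results = results, summaries = summaries, skipped = skipped)
}
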