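Package: ChemFusion
Title: Multimodal Molecular Representation Fusion for Bioactivity
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A ligand-based virtual-screening pipeline that classifies
    active versus inactive small-molecule inhibitors from multimodal
    molecular representations. Curates potency records (Ki/Kd/IC50,
    unit-normalised to micromolar) into binary labels at configurable
    activity cutoffs; computes physicochemical descriptor, MACCS-key and
    ECFP4 fingerprint blocks plus tokenized SMILES; performs early fusion
    of preprocessed 128-dimensional blocks; builds scaffold-cluster
    hold-out splits via K-means with internal-index model selection;
    rebalances training data by SMOTE, property-matched decoy selection
    or SMILES enumeration; trains nine classical classifiers and two
    self-attention neural networks (a fusion network and an LSTM SMILES
    network) behind one contract; and evaluates them with multi-seed
    ACC/F1/AUC summaries, Welch t-tests, prediction-overlap and
    chemical-space maps. A synthetic-molecule generator with a planted
    substructure-activity rule makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    rpart,
    class,
    cluster,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    ChemmineR,
    knitr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python'
Config/testthat/edition: 3
RoxygenNote: 7.3.3
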