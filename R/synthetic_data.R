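# Scaffold templates: 13 chemotype families written as SMILES with three
# substitution slots. Slot {R1} carries the planted pharmacophore on
# active compounds; {R2}/{R3} are decoration. Textual substitution with
# branch fragments keeps every product a valid SMILES by construction.
.scaffold_templates <- c(
  benzanilide     = "O=C(Nc1cc{R3}cc{R1}c1)c1ccc{R2}cc1",
  diphenylmethane = "C(c1cc{R3}cc{R1}c1)c1ccc{R2}cc1",
  diphenylether   = "O(c1cc{R3}cc{R1}c1)c1ccc{R2}cc1",
  dibenzylamine   = "N(Cc1cc{R3}cc{R1}c1)Cc1ccc{R2}cc1",
  nicotinamide    = "O=C(Nc1cc{R3}cc{R1}c1)c1ccc{R2}nc1",
  indole          = "Cn1cc(C(=O)Nc2cc{R3}cc{R1}c2)c2cc{R2}ccc21",
  naphthalene     = "O=C(Cc1ccc2cc{R2}ccc2c1)Nc1cc{R3}cc{R1}c1",
  furan           = "O=C(Nc1cc{R3}cc{R1}c1)c1cc{R2}co1",
  piperidine      = "O=C(N1CCC{R2}CC1)c1cc{R3}cc{R1}c1",
  pyrimidine      = "O=C(Nc1cc{R3}cc{R1}c1)c1nc{R2}ccn1",
  benzimidazole   = "Cn1c(CNc2cc{R3}cc{R1}c2)nc2cc{R2}ccc21",
  quinoline       = "O=C(Nc1cc{R3}cc{R1}c1)c1cnc2cc{R2}ccc2c1",
  phenylurea      = "O=C(Nc1cc{R3}cc{R1}c1)NCc1ccc{R2}cc1")

# Decoration substituents (as ring-branch fragments; "" = unsubstituted).
# None contains sulfur, so the sulfonamide pharmacophore below is the only
# S-bearing substructure in the library.
.substituents <- c(
  "", "(C)", "(CC)", "(CCC)", "(C(C)C)", "(F)", "(Cl)", "(Br)", "(I)",
  "(O)", "(OC)", "(OCC)", "(N)", "(NC)", "(N(C)C)", "(C#N)", "(C(F)(F)F)",
  "(CO)", "(CCO)", "(C(=O)C)", "(C(=O)OC)", "(C(=O)N)", "(CF)", "(CCl)",
  "(OC(C)C)", "(CCN)", "(OCC(C)C)", "(C=C)", "(CC#N)", "(OC(F)F)")

.pharmacophore <- "(NS(C)(=O)=O)"  # methanesulfonamide planted signal

#' Specify a synthetic molecule library
#'
#' Defines the generating conditions of the synthetic benchmark: scaffold
#' families, the fraction of compounds carrying the planted pharmacophore,
#' and a two-level log-normal potency model
#' `log10(activity_um) = mu + Normal(0, sigma)` with `mu = mu_active` when
#' the pharmacophore is present and `mu_inactive` otherwise.
#'
#' @param n_compounds Library size (default 4500, the scale of the curated
#'   study dataset).
#' @param n_families Number of scaffold families, 4-13 (default 13).
#' @param p_pharmacophore Fraction of compounds given the pharmacophore.
#' @param mu_active,mu_inactive Mean log10 potency (micromolar) with and
#'   without the pharmacophore (defaults 10^-1.3 ~ 0.05 uM and
#'   10^1.7 ~ 50 uM).
#' @param sigma SD of the log10 potency noise (default 0.55).
#' @param seed Integer seed.
#' @return A `SyntheticSpec` (list) for [generateLibrary()].
#' @export
syntheticSpec <- function(n_compounds = 4500L, n_families = 13L,
                          p_pharmacophore = 0.5, mu_active = -1.3,
                          mu_inactive = 1.7, sigma = 0.55, seed = 1L) {
  stopifnot(n_families >= 4L, n_families <= length(.scaffold_templates),
            p_pharmacophore >= 0, p_pharmacophore <= 1, sigma >= 0)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_families = as.integer(n_families),
                 p_pharmacophore = p_pharmacophore,
                 mu_active = mu_active, mu_inactive = mu_inactive,
                 sigma = sigma, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic molecule library
#'
#' Samples compounds as scaffold template + substituents, plants the
#' pharmacophore according to the spec, draws potencies from the two-level
#' log-normal model, canonicalizes every product (a failure to parse is a
#' generator bug and a hard error) and aggregates the rare textual
#' duplicates by median potency.
#'
#' @param spec A `SyntheticSpec` from [syntheticSpec()].
#' @return A `data.frame` with `canonical_smiles`, `activity_um`,
#'   `family`, `pharmacophore`, `potency_noiseless` (log10 uM), `n_merged`.
#' @export
generateLibrary <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  tmpl <- .scaffold_templates[seq_len(spec$n_families)]
  withSeed(spec$seed, {
    fam <- sample(names(tmpl), spec$n_compounds, replace = TRUE)
    pharm <- stats::runif(spec$n_compounds) < spec$p_pharmacophore
    r1 <- ifelse(pharm, .pharmacophore,
                 sample(.substituents, spec$n_compounds, replace = TRUE))
    r2 <- sample(.substituents, spec$n_compounds, replace = TRUE)
    r3 <- sample(.substituents, spec$n_compounds, replace = TRUE)
    smi <- tmpl[fam]
    smi <- mapply(function(s, a, b, c) {
      s <- sub("{R1}", a, s, fixed = TRUE)
      s <- sub("{R2}", b, s, fixed = TRUE)
      sub("{R3}", c, s, fixed = TRUE)
    }, smi, r1, r2, r3, USE.NAMES = FALSE)
    mu <- ifelse(pharm, spec$mu_active, spec$mu_inactive)
    log_potency <- mu + stats::rnorm(spec$n_compounds, 0, spec$sigma)
  })
  canon <- .rdkit("canon", smi)
  if (any(.rdkit_errors(canon)))
    stop("synthetic generator emitted invalid SMILES: ",
         paste(utils::head(smi[.rdkit_errors(canon)], 3), collapse = " "))
  if (any(nchar(smi) > 195L))
    stop("synthetic generator emitted SMILES longer than 195 characters")
  df <- data.frame(canonical_smiles = canon,
                   activity_um = 10^log_potency,
                   family = fam, pharmacophore = pharm,
                   potency_noiseless = mu,
                   stringsAsFactors = FALSE)
  # textual duplicates: aggregate potency by median, keep first metadata
  if (anyDuplicated(df$canonical_smiles)) {
    agg <- aggregateDuplicates(df$canonical_smiles, df$activity_um)
    first <- df[!duplicated(df$canonical_smiles), ]
    first <- first[match(agg$canonical_smiles, first$canonical_smiles), ]
    df <- data.frame(canonical_smiles = agg$canonical_smiles,
                     activity_um = agg$activity_um,
                     family = first$family,
                     pharmacophore = first$pharmacophore,
                     potency_noiseless = first$potency_noiseless,
                     n_merged = agg$n_merged,
                     stringsAsFactors = FALSE)
  } else df$n_merged <- 1L
  rownames(df) <- NULL
  df
}

#' Canned synthetic benchmarks mirroring the three imbalance regimes
#'
#' Three presets pair a pharmacophore prevalence with its activity cutoff
#' so the realized class ratio approximates the study regimes:
#' `"balanced"` (~1:1 at 0.5 uM), `"slight"` (~3:2 at 1 uM) and
#' `"severe"` (~4:1 at 10 uM).
#'
#' @param preset One of `"balanced"`, `"slight"`, `"severe"`.
#' @param n_compounds Library size (default 4500).
#' @param seed Integer seed.
#' @param ... Overrides passed to [syntheticSpec()].
#' @return A list with `compounds` (a labeled [CompoundSet-class] whose
#'   metadata carries the ground-truth manifest) and `manifest` (the
#'   planted rule: spec, per-compound family/pharmacophore flags and
#'   noiseless potency).
#' @export
makeBenchmark <- function(preset = c("balanced", "slight", "severe"),
                          n_compounds = 4500L, seed = 1L, ...) {
  preset <- match.arg(preset)
  p <- c(balanced = 0.5, slight = 0.6, severe = 0.8)[[preset]]
  cutoff <- c(balanced = 0.5, slight = 1, severe = 10)[[preset]]
  spec <- syntheticSpec(n_compounds = n_compounds, p_pharmacophore = p,
                        seed = seed, ...)
  lib <- generateLibrary(spec)
  cs <- suppressMessages(assignLabels(lib, cutoff))
  cd <- compoundData(cs)
  cd$family <- lib$family
  cd$pharmacophore <- lib$pharmacophore
  compoundData(cs) <- cd
  manifest <- list(preset = preset, spec = unclass(spec),
                   cutoff_um = cutoff,
                   pharmacophore_smarts = "NS(C)(=O)=O",
                   family = lib$family,
                   pharmacophore = lib$pharmacophore,
                   potency_noiseless = lib$potency_noiseless)
  md <- metadata(cs); md$manifest <- manifest; metadata(cs) <- md
  list(compounds = cs, manifest = manifest)
}

#' Permute activity labels (null benchmark)
#'
#' Randomly permutes the label column and leaves every feature untouched;
#' a leak-free model evaluated on the permuted set should score at chance.
#'
#' @param cs A labeled [CompoundSet-class].
#' @param seed Integer seed.
#' @return `cs` with permuted labels.
#' @export
permuteLabels <- function(cs, seed = 1L) {
  cd <- compoundData(cs)
  cd$label <- withSeed(seed, sample(cd$label))
  compoundData(cs) <- cd
  cs
}
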