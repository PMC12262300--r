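# Shared fixtures: small named reactions with derived RCs.

rxn <- function(smiles, id = "r") {
  suppressWarnings(deriveRcFromMap(parseReaction(smiles, id = id)))
}

# pyruvate -> lactate (ketone reduction of an alpha-keto acid)
pyruvateLactate <- function() rxn(
  "[CH3:1][C:2](=[O:3])[C:4](=[O:5])[OH:6]>>[CH3:1][CH:2]([OH:3])[C:4](=[O:5])[OH:6]",
  "pyr_lac")

# methyl / ethyl acetate hydrolysis (shared ester RC, different alkyl)
methylAcetateHydrolysis <- function() rxn(
  "[CH3:1][C:2](=[O:3])[O:4][CH3:5].[OH2:6]>>[CH3:1][C:2](=[O:3])[OH:6].[CH3:5][OH:4]",
  "me_hydrolysis")
ethylAcetateHydrolysis <- function() rxn(
  "[CH3:7][CH2:1][C:2](=[O:3])[O:4][CH3:5].[OH2:6]>>[CH3:7][CH2:1][C:2](=[O:3])[OH:6].[CH3:5][OH:4]",
  "et_hydrolysis")

ketoneReduction <- function() rxn(
  "[CH3:1][C:2](=[O:3])[CH3:4]>>[CH3:1][CH:2]([OH:3])[CH3:4]", "ketone_red")

esterHydrolysisOperator <- function() parseOperator(
  "[O:3]=[C:2][O:4].[OH2:6]>>[O:3]=[C:2][OH:6].[OH:4]", "ester_hydrolysis")

# small synthetic reaction set for oracle sweeps
smallSyntheticReactions <- function(n = 12, seed = 77) {
  cfg <- synthConfig(templates = 6, perTemplate = ceiling(n / 6),
                     maxDecor = 3, clusters = 2, perCluster = 2,
                     embeddingDim = 8, seqLength = 30, density = 0.1,
                     seed = seed)
  rx <- generateReactions(cfg)
  out <- rx[seq_len(n)]
  attr(out, "family") <- attr(rx, "family")[seq_len(n)]
  attr(out, "templateNames") <- attr(rx, "templateNames")
  out
}

# a tiny trainable dataset shared by model-level tests
tinyTrainingSetup <- function(seed = 5) {
  cfg <- synthConfig(templates = 3, perTemplate = 10, maxDecor = 2,
                     clusters = 3, perCluster = 8, embeddingDim = 32,
                     seqLength = 40, activeFraction = 1, density = 0.05,
                     seed = seed)
  rx <- generateReactions(cfg)
  pr <- generateProteins(cfg)
  pos <- plantPositives(rx, pr, cfg)
  ids <- names(rx)
  set.seed(seed)
  n <- length(ids)
  test <- sample(n, round(0.2 * n))
  cvf <- sample(rep(1:3, length.out = n - length(test)))
  tb <- data.frame(entity_id = ids,
                   fold = ifelse(seq_len(n) %in% test, "test", "trainval"),
                   cv_fold = NA_integer_, declared_lo = NA_real_,
                   declared_hi = NA_real_, realized_max_sim = NA_real_,
                   stringsAsFactors = FALSE)
  tb$cv_fold[tb$fold == "trainval"] <- cvf
  asg <- new("SplitAssignment", table = tb, bounds = c(0.4, 0.6, 0.8, 1.0),
             entity = "reaction", seed = as.integer(seed), info = list())
  list(cfg = cfg, reactions = rx, proteins = pr, positives = pos,
       assignment = asg)
}

# random-fold assignment over arbitrary reaction ids (no similarity control)
randomAssignment <- function(ids, seed = 3, testFraction = 0.2, k = 3) {
  set.seed(seed)
  n <- length(ids)
  test <- sample(n, round(testFraction * n))
  cvf <- sample(rep(seq_len(k), length.out = n - length(test)))
  tb <- data.frame(entity_id = ids,
                   fold = ifelse(seq_len(n) %in% test, "test", "trainval"),
                   cv_fold = NA_integer_, declared_lo = NA_real_,
                   declared_hi = NA_real_, realized_max_sim = NA_real_,
                   stringsAsFactors = FALSE)
  tb$cv_fold[tb$fold == "trainval"] <- cvf
  new("SplitAssignment", table = tb, bounds = c(0.4, 0.6, 0.8, 1.0),
      entity = "reaction", seed = as.integer(seed), info = list())
}
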