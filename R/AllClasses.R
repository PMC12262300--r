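#' @import methods
NULL

#' Molecule: a small-molecule graph
#'
#' Heavy-atom molecular graph with implicit hydrogens. Atoms are stored in a
#' data.frame with columns `element` (capitalised symbol), `aromatic`
#' (logical), `charge` (integer), `hcount` (explicit hydrogen count, integer)
#' and `map` (atom-map number, 0 when unmapped). Bonds are stored as a
#' data.frame with columns `a1`, `a2` (1-based atom indices) and `order`
#' (one of `"1"`, `"2"`, `"3"`, `"ar"`).
#'
#' @slot atoms data.frame of atom attributes.
#' @slot bonds data.frame of bonds.
#' @slot meta list of parse metadata (e.g. whether stereo markers were seen).
#' @export
setClass("Molecule",
  representation(atoms = "data.frame", bonds = "data.frame", meta = "list"),
  prototype(
    atoms = data.frame(element = character(), aromatic = logical(),
                       charge = integer(), hcount = integer(), map = integer(),
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = integer(), a2 = integer(), order = character(),
                       stringsAsFactors = FALSE),
    meta = list()
  )
)

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need <- c("element", "aromatic", "charge", "hcount", "map")
  if (!all(need %in% names(a))) msgs <- c(msgs, "atoms is missing columns")
  if (nrow(b) > 0) {
    if (!all(c("a1", "a2", "order") %in% names(b)))
      msgs <- c(msgs, "bonds is missing columns")
    else {
      if (any(b$a1 < 1 | b$a1 > nrow(a) | b$a2 < 1 | b$a2 > nrow(a)))
        msgs <- c(msgs, "bond references a non-existent atom")
      if (any(b$a1 == b$a2)) msgs <- c(msgs, "self-bond")
      if (!all(b$order %in% c("1", "2", "3", "ar")))
        msgs <- c(msgs, "invalid bond order")
    }
  }
  if (nrow(a) > 0 && any(a$hcount < 0)) msgs <- c(msgs, "negative H count")
  if (length(msgs)) msgs else TRUE
})

#' Reaction: reactant and product molecule sets with atom map and RC
#'
#' Reaction-center (RC) atoms are stored as global 1-based indices into the
#' concatenation of all reactant (resp. product) atoms, in molecule order.
#'
#' @slot id character reaction identifier.
#' @slot reactants list of [Molecule-class] objects.
#' @slot products list of [Molecule-class] objects.
#' @slot rcReactants integer vector of global reactant-side RC atom indices.
#' @slot rcProducts integer vector of global product-side RC atom indices.
#' @export
setClass("Reaction",
  representation(id = "character", reactants = "list", products = "list",
                 rcReactants = "integer", rcProducts = "integer"),
  prototype(id = NA_character_, reactants = list(), products = list(),
            rcReactants = integer(), rcProducts = integer())
)

setValidity("Reaction", function(object) {
  msgs <- character()
  for (m in c(object@reactants, object@products))
    if (!is(m, "Molecule")) msgs <- c(msgs, "non-Molecule member")
  if (length(msgs)) return(msgs)
  for (side in c("reactant", "product")) {
    at <- sideAtoms(object, side)
    maps <- at$map[at$map > 0]
    if (anyDuplicated(maps))
      msgs <- c(msgs, sprintf("duplicate atom-map number on %s side", side))
    rc <- if (side == "reactant") object@rcReactants else object@rcProducts
    if (length(rc) && (any(rc < 1) || any(rc > nrow(at))))
      msgs <- c(msgs, sprintf("RC index out of range on %s side", side))
  }
  # mapped partners must share an element
  ra <- sideAtoms(object, "reactant"); pa <- sideAtoms(object, "product")
  common <- intersect(ra$map[ra$map > 0], pa$map[pa$map > 0])
  if (length(common)) {
    re <- ra$element[match(common, ra$map)]
    pe <- pa$element[match(common, pa$map)]
    if (any(re != pe)) msgs <- c(msgs, "mapped atoms differ in element")
  }
  if (length(msgs)) msgs else TRUE
})

#' OperatorTemplate: a minimal reaction operator
#'
#' An atom-mapped core reaction used as a substructure pattern. The reactant
#' side is matched into a query reaction's reactants; the derived bond-change
#' list and hydrogen-count deltas are then applied to generate products. Atoms
#' whose bonding environment changes inside the template constitute the RC;
#' unchanged template atoms act as matching context only.
#'
#' @slot name character operator name.
#' @slot core the template [Reaction-class] (fully atom-mapped).
#' @slot bondChanges data.frame with columns `map1`, `map2`, `before`, `after`
#'   (orders as in [Molecule-class], `"0"` meaning absent).
#' @slot hDeltas data.frame with columns `map`, `delta`.
#' @slot rcMaps integer vector of map numbers forming the template RC.
#' @export
setClass("OperatorTemplate",
  representation(name = "character", core = "Reaction",
                 bondChanges = "data.frame", hDeltas = "data.frame",
                 rcMaps = "integer"))

setValidity("OperatorTemplate", function(object) {
  ra <- sideAtoms(object@core, "reactant")
  pa <- sideAtoms(object@core, "product")
  if (any(ra$map == 0) || any(pa$map == 0))
    return("operator core must be fully atom-mapped")
  if (!setequal(ra$map, pa$map))
    return("operator core map numbers must be a bijection across sides")
  TRUE
})

#' SimilarityMatrix: dense symmetric pairwise similarity scores
#'
#' @slot ids character vector of item identifiers (row/column order).
#' @slot scores numeric matrix in `[0, 1]`, symmetric, unit diagonal.
#' @slot metric character, `"rcmcs"` or `"gsi"`.
#' @slot flags data.frame of pairs where a bounded-search fallback was used
#'   (columns `id_a`, `id_b`), empty when all pairs were solved exactly.
#' @export
setClass("SimilarityMatrix",
  representation(ids = "character", scores = "matrix", metric = "character",
                 flags = "data.frame"),
  prototype(flags = data.frame(id_a = character(), id_b = character(),
                               stringsAsFactors = FALSE)))

setValidity("SimilarityMatrix", function(object) {
  s <- object@scores
  msgs <- character()
  if (nrow(s) != length(object@ids) || ncol(s) != length(object@ids))
    msgs <- c(msgs, "score matrix dimensions do not match ids")
  else {
    if (any(is.na(s))) msgs <- c(msgs, "NA scores")
    else {
      if (max(abs(s - t(s))) > 1e-12) msgs <- c(msgs, "matrix not symmetric")
      if (any(s < -1e-12) || any(s > 1 + 1e-12))
        msgs <- c(msgs, "scores outside [0, 1]")
      if (length(object@ids) && max(abs(diag(s) - 1)) > 1e-12)
        msgs <- c(msgs, "diagonal not 1")
    }
  }
  if (!object@metric %in% c("rcmcs", "gsi"))
    msgs <- c(msgs, "metric must be 'rcmcs' or 'gsi'")
  if (length(msgs)) msgs else TRUE
})

#' SplitAssignment: stratified similarity split layout
#'
#' @slot table data.frame with columns `entity_id`, `fold` (`"test"` or
#'   `"trainval"`), `cv_fold` (integer, `NA` for test), `declared_lo`,
#'   `declared_hi` (stratum interval), `realized_max_sim` (measured maximum
#'   similarity to the training pool; `NA` for trainval entities).
#' @slot bounds numeric ascending similarity bounds ending at 1.
#' @slot entity character, `"reaction"` or `"protein"`.
#' @slot seed integer seed used for sampling.
#' @slot info list of bookkeeping (per-stratum quotas and residual imbalance).
#' @export
setClass("SplitAssignment",
  representation(table = "data.frame", bounds = "numeric", entity = "character",
                 seed = "integer", info = "list"))

setValidity("SplitAssignment", function(object) {
  tb <- object@table
  need <- c("entity_id", "fold", "cv_fold", "declared_lo", "declared_hi",
            "realized_max_sim")
  if (!all(need %in% names(tb))) return("assignment table missing columns")
  if (anyDuplicated(tb$entity_id)) return("entity assigned more than once")
  if (!all(tb$fold %in% c("test", "trainval"))) return("invalid fold label")
  if (is.unsorted(object@bounds, strictly = TRUE)) return("bounds not ascending")
  if (length(object@bounds) && abs(object@bounds[length(object@bounds)] - 1) > 1e-12)
    return("last bound must be 1")
  TRUE
})

#' PairDataset: labelled enzyme-reaction pairs with fold membership
#'
#' @slot pairs data.frame with columns `protein_id`, `reaction_id`, `label`
#'   (0/1), `fold` (e.g. `"test"`, `"cv1"`, ...), `provenance`
#'   (`"observed"` or `"sampled"`).
#' @slot ratios named numeric negative:positive ratios per fold.
#' @slot seed integer sampling seed.
#' @export
setClass("PairDataset",
  representation(pairs = "data.frame", ratios = "numeric", seed = "integer"))

setValidity("PairDataset", function(object) {
  p <- object@pairs
  need <- c("protein_id", "reaction_id", "label", "fold", "provenance")
  if (!all(need %in% names(p))) return("pairs missing columns")
  if (!all(p$label %in% c(0, 1))) return("labels must be 0/1")
  key <- paste(p$protein_id, p$reaction_id)
  if (any(tapply(p$label, key, function(x) length(unique(x))) > 1))
    return("a pair appears with both labels")
  TRUE
})

#' ReactionGraph: encoder-ready directed graph of a reaction
#'
#' @slot nodeFeatures numeric matrix (nodes x atom-feature dim).
#' @slot edgeFeatures numeric matrix (directed edges x bond-feature dim).
#' @slot edgeSrc,edgeDst integer endpoints of each directed edge.
#' @slot revIndex integer index of each directed edge's reverse.
#' @slot side character per node: `"reactant"`, `"product"` or `"virtual"`.
#' @slot rcFlag logical per node.
#' @slot realAtoms integer indices of non-virtual nodes.
#' @slot virtualIndex integer index of the virtual node (or `NA`).
#' @slot variant character encoder variant the graph was built for.
#' @export
setClass("ReactionGraph",
  representation(nodeFeatures = "matrix", edgeFeatures = "matrix",
                 edgeSrc = "integer", edgeDst = "integer", revIndex = "integer",
                 side = "character", rcFlag = "logical", realAtoms = "integer",
                 virtualIndex = "integer", variant = "character"))

setValidity("ReactionGraph", function(object) {
  E <- length(object@edgeSrc)
  if (length(object@edgeDst) != E || length(object@revIndex) != E)
    return("edge arrays of unequal length")
  if (E > 0) {
    if (any(object@revIndex < 1 | object@revIndex > E))
      return("revIndex out of range")
    if (!all(object@edgeSrc == object@edgeDst[object@revIndex]))
      return("reverse edges inconsistent")
  }
  TRUE
})

#' ProteinSet: protein records with precomputed embeddings
#'
#' The enzyme side of the model: each protein carries an amino-acid sequence
#' and a fixed-length embedding vector (1280-dimensional by default, the
#' output dimension of the protein language model the pipeline consumes).
#'
#' @slot sequences named character vector of amino-acid sequences.
#' @slot embeddings numeric matrix (proteins x dim), rownames = protein ids.
#' @export
setClass("ProteinSet",
  representation(sequences = "character", embeddings = "matrix"))

setValidity("ProteinSet", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids)) return("sequences must have unique names")
  if (!identical(rownames(object@embeddings), ids))
    return("embedding rownames must equal sequence names")
  if (any(!is.finite(object@embeddings))) return("non-finite embeddings")
  TRUE
})

#' RcnetModel: a trained (or initialised) two-tower scorer
#'
#' @slot encoder list, the encoder configuration (see [encoderConfig()]).
#' @slot weights named list of weight matrices (`Win`, `Wm`, `Wread`, `Wout`,
#'   `Wp`; Morgan variant: `Wmrg`, `Wp`).
#' @slot threshold numeric decision threshold in (0, 1).
#' @slot proteinDim integer input protein-embedding dimension.
#' @slot log data.frame per-epoch training log.
#' @export
setClass("RcnetModel",
  representation(encoder = "list", weights = "list", threshold = "numeric",
                 proteinDim = "integer", log = "data.frame"),
  prototype(threshold = 0.5, log = data.frame()))

setValidity("RcnetModel", function(object) {
  if (!all(vapply(object@weights, function(w) all(is.finite(w)), logical(1))))
    return("non-finite model weights")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0, 1)")
  TRUE
})
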