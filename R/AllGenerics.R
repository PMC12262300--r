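#' @rdname Molecule-class
#' @param object,x an object.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname Molecule-class
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @rdname Molecule-class
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' @rdname Reaction-class
#' @export
setGeneric("reactionId", function(x) standardGeneric("reactionId"))
#' @rdname Reaction-class
#' @export
setGeneric("reactants", function(x) standardGeneric("reactants"))
#' @rdname Reaction-class
#' @export
setGeneric("products", function(x) standardGeneric("products"))
#' @rdname Reaction-class
#' @param side `"reactant"` or `"product"`.
#' @export
setGeneric("rcAtoms", function(x, side = "reactant") standardGeneric("rcAtoms"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("simIds", function(x) standardGeneric("simIds"))
#' @rdname SimilarityMatrix-class
#' @export
setGeneric("simScores", function(x) standardGeneric("simScores"))
#' @rdname SimilarityMatrix-class
#' @export
setGeneric("simMetric", function(x) standardGeneric("simMetric"))

#' @rdname SplitAssignment-class
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))

#' @rdname PairDataset-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname ProteinSet-class
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname ProteinSet-class
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))
#' @rdname ProteinSet-class
#' @export
setGeneric("proteinEmbeddings", function(x) standardGeneric("proteinEmbeddings"))

#' @rdname RcnetModel-class
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname RcnetModel-class
#' @export
setGeneric("decisionThreshold", function(x) standardGeneric("decisionThreshold"))
#' @rdname RcnetModel-class
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

setMethod("atomTable", "Molecule", function(x) x@atoms)
setMethod("bondTable", "Molecule", function(x) x@bonds)
setMethod("atomCount", "Molecule", function(x) nrow(x@atoms))

setMethod("reactionId", "Reaction", function(x) x@id)
setMethod("reactants", "Reaction", function(x) x@reactants)
setMethod("products", "Reaction", function(x) x@products)
setMethod("rcAtoms", "Reaction", function(x, side = "reactant") {
  side <- match.arg(side, c("reactant", "product"))
  if (side == "reactant") x@rcReactants else x@rcProducts
})

#' Total heavy-atom count of a reaction (both sides)
#' @param r a [Reaction-class].
#' @return integer.
#' @export
reactionAtomCount <- function(r) {
  sum(vapply(c(r@reactants, r@products), atomCount, integer(1)))
}

setMethod("simIds", "SimilarityMatrix", function(x) x@ids)
setMethod("simScores", "SimilarityMatrix", function(x) x@scores)
setMethod("simMetric", "SimilarityMatrix", function(x) x@metric)

setMethod("assignmentTable", "SplitAssignment", function(x) x@table)
setMethod("pairTable", "PairDataset", function(x) x@pairs)

setMethod("proteinIds", "ProteinSet", function(x) names(x@sequences))
setMethod("proteinSequences", "ProteinSet", function(x) x@sequences)
setMethod("proteinEmbeddings", "ProteinSet", function(x) x@embeddings)

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet: %d proteins, embedding dim %d\n",
              length(object@sequences), ncol(object@embeddings)))
})

#' Construct a ProteinSet
#' @param sequences named character vector of amino-acid sequences.
#' @param embeddings numeric matrix (proteins x dim) with rownames matching
#'   the sequence names.
#' @return a [ProteinSet-class].
#' @export
proteinSet <- function(sequences, embeddings) {
  embeddings <- as.matrix(embeddings)
  if (is.null(rownames(embeddings))) rownames(embeddings) <- names(sequences)
  obj <- new("ProteinSet", sequences = sequences,
             embeddings = embeddings[names(sequences), , drop = FALSE])
  validObject(obj)
  obj
}

setMethod("modelWeights", "RcnetModel", function(x) x@weights)
setMethod("decisionThreshold", "RcnetModel", function(x) x@threshold)
setMethod("trainingLog", "RcnetModel", function(x) x@log)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %d atoms, %d bonds | %s\n", nrow(object@atoms),
              nrow(object@bonds), writeSmiles(object)))
})

setMethod("show", "Reaction", function(object) {
  cat(sprintf("Reaction %s: %d reactant(s), %d product(s), %d atoms\n",
              object@id, length(object@reactants), length(object@products),
              reactionAtomCount(object)))
  cat(" ", writeReactionSmiles(object, withMaps = TRUE), "\n")
  if (length(object@rcReactants))
    cat(sprintf("  RC: %d reactant / %d product atoms\n",
                length(object@rcReactants), length(object@rcProducts)))
  else cat("  RC: unannotated\n")
})

setMethod("show", "OperatorTemplate", function(object) {
  cat(sprintf("OperatorTemplate '%s': %d-atom core, %d bond change(s)\n",
              object@name, reactionAtomCount(object@core),
              nrow(object@bondChanges)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d items", object@metric,
              length(object@ids)))
  if (nrow(object@flags)) cat(sprintf(", %d pair(s) used bounded fallback",
                                      nrow(object@flags)))
  cat("\n")
})

setMethod("show", "SplitAssignment", function(object) {
  tb <- object@table
  cat(sprintf("SplitAssignment (%s-level): %d entities, %d test / %d trainval\n",
              object@entity, nrow(tb), sum(tb$fold == "test"),
              sum(tb$fold == "trainval")))
})

setMethod("show", "PairDataset", function(object) {
  p <- object@pairs
  cat(sprintf("PairDataset: %d pairs (%d positive, %d negative) in %d fold(s)\n",
              nrow(p), sum(p$label == 1), sum(p$label == 0),
              length(unique(p$fold))))
})

setMethod("show", "RcnetModel", function(object) {
  cat(sprintf("RcnetModel: %s encoder, d = %d, threshold = %.3g\n",
              object@encoder$variant, object@encoder$d, object@threshold))
  if (nrow(object@log))
    cat(sprintf("  trained %d epochs, final train loss %.4f\n",
                max(object@log$epoch), object@log$train_loss[nrow(object@log)]))
})
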