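# File formats: reactions TSV, curation TSV, protein FASTA, embeddings TSV.

#' Write reactions as TSV
#'
#' Columns `reaction_id`, `smiles` (atom-mapped reaction SMILES) and the RC
#' annotations `rc_reactant_atoms` / `rc_product_atoms` as semicolon-separated
#' 0-based global atom indices.
#'
#' @param reactions list of [Reaction-class] objects.
#' @param path output file.
#' @export
writeReactionsTsv <- function(reactions, path) {
  df <- data.frame(
    reaction_id = vapply(reactions, reactionId, character(1)),
    smiles = vapply(reactions, writeReactionSmiles, character(1),
                    withMaps = TRUE),
    rc_reactant_atoms = vapply(reactions, function(r)
      paste(r@rcReactants - 1L, collapse = ";"), character(1)),
    rc_product_atoms = vapply(reactions, function(r)
      paste(r@rcProducts - 1L, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reactions from TSV
#'
#' Expects columns `reaction_id` and `smiles`; optional
#' `rc_reactant_atoms` / `rc_product_atoms` columns (semicolon-separated
#' 0-based indices) override RC derivation. Without an override, the RC is
#' derived from the atom map when the map is total; identity reactions
#' (empty RC) are rejected with a warning and dropped.
#'
#' @param path input file.
#' @param deriveRc derive RCs from atom maps when no override is present.
#' @return named list of [Reaction-class] objects.
#' @export
readReactionsTsv <- function(path, deriveRc = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("reaction_id", "smiles") %in% names(df)))
    stop("reactions TSV must have columns reaction_id and smiles")
  out <- list()
  for (i in seq_len(nrow(df))) {
    r <- parseReaction(df$smiles[i], id = df$reaction_id[i])
    hasOverride <- all(c("rc_reactant_atoms", "rc_product_atoms") %in%
                       names(df)) && nzchar(df$rc_reactant_atoms[i])
    if (hasOverride) {
      parse0 <- function(x) as.integer(strsplit(x, ";")[[1]]) + 1L
      r@rcReactants <- parse0(df$rc_reactant_atoms[i])
      r@rcProducts <- parse0(df$rc_product_atoms[i])
      validObject(r)
    } else if (deriveRc) {
      empty <- FALSE
      withCallingHandlers(
        r <- deriveRcFromMap(r),
        rcnet_empty_rc = function(w) {
          empty <<- TRUE
          invokeRestart("muffleWarning")
        })
      if (empty) {
        warning(sprintf("dropping identity reaction %s (empty RC)",
                        df$reaction_id[i]))
        next
      }
    }
    out[[df$reaction_id[i]]] <- r
  }
  out
}

#' Read a curation TSV
#'
#' Columns `protein_id`, `reaction_id`, `evidence`, `is_subunit`,
#' `is_transport` (logical or 0/1).
#'
#' @param path input file.
#' @return data.frame suitable for [filterCuration()].
#' @export
readCurationTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_subunit <- as.logical(df$is_subunit)
  df$is_transport <- as.logical(df$is_transport)
  df
}

#' Write / read protein sequences as FASTA
#' @param proteins a [ProteinSet-class] (writing) .
#' @param path file path.
#' @export
writeProteinFasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteinSequences(proteins))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname writeProteinFasta
#' @return for reading: a named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write / read protein embeddings as TSV
#'
#' First column `protein_id`, remaining columns the embedding dimensions.
#' @param proteins a [ProteinSet-class] (writing).
#' @param path file path.
#' @export
writeEmbeddingsTsv <- function(proteins, path) {
  emb <- proteinEmbeddings(proteins)
  df <- data.frame(protein_id = rownames(emb),
                   apply(emb, 2, function(col) sprintf("%.8g", col)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("protein_id", paste0("d", seq_len(ncol(emb))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddingsTsv
#' @return for reading: numeric matrix with protein ids as rownames.
#' @export
readEmbeddingsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(protein_id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein_id
  colnames(m) <- NULL
  m
}

#' Assemble a ProteinSet from FASTA and embeddings files
#' @param fastaPath FASTA of sequences.
#' @param embeddingsPath embeddings TSV.
#' @return a [ProteinSet-class].
#' @export
readProteinSet <- function(fastaPath, embeddingsPath) {
  seqs <- readProteinFasta(fastaPath)
  emb <- readEmbeddingsTsv(embeddingsPath)
  if (!setequal(names(seqs), rownames(emb)))
    stop("FASTA and embeddings cover different proteins")
  proteinSet(seqs, emb[names(seqs), , drop = FALSE])
}

#' Write reaction embeddings as TSV
#'
#' @param embeddings numeric matrix (reactions x d) with rownames.
#' @param path output file.
#' @export
writeReactionEmbeddingsTsv <- function(embeddings, path) {
  df <- data.frame(reaction_id = rownames(embeddings),
                   apply(embeddings, 2, function(col) sprintf("%.8g", col)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("reaction_id", paste0("d", seq_len(ncol(embeddings))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load model weights as a JSON checkpoint
#'
#' A text checkpoint: the encoder configuration, threshold and every weight
#' matrix (flattened with dimensions) in one JSON document.
#'
#' @param model an [RcnetModel-class].
#' @param path file path.
#' @export
saveModelJson <- function(model, path) {
  payload <- list(
    encoder = model@encoder,
    threshold = model@threshold,
    proteinDim = model@proteinDim,
    weights = lapply(model@weights, function(w)
      list(dim = dim(w), values = as.numeric(w))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModelJson
#' @return for loading: the reconstructed [RcnetModel-class].
#' @export
loadModelJson <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- as.list(payload$encoder)
  enc$M <- as.integer(enc$M); enc$hidden <- as.integer(enc$hidden)
  enc$d <- as.integer(enc$d); enc$radius <- as.integer(enc$radius)
  enc$nbits <- as.integer(enc$nbits); enc$seed <- as.integer(enc$seed)
  weights <- lapply(payload$weights, function(w)
    matrix(w$values, w$dim[1], w$dim[2]))
  new("RcnetModel", encoder = enc, weights = weights,
      threshold = payload$threshold,
      proteinDim = as.integer(payload$proteinDim), log = data.frame())
}
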