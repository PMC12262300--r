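# Reaction construction from reaction SMILES and reaction-level helpers.

#' Concatenated atom table of one reaction side
#'
#' Rows follow molecule order; columns add `mol` (molecule index), `local`
#' (atom index within its molecule) and `global` (1-based index into the
#' concatenation, the indexing used by RC atom sets).
#'
#' @param r a [Reaction-class].
#' @param side `"reactant"` or `"product"`.
#' @return data.frame.
#' @export
sideAtoms <- function(r, side = c("reactant", "product")) {
  side <- match.arg(side)
  mols <- if (side == "reactant") r@reactants else r@products
  if (!length(mols))
    return(data.frame(element = character(), aromatic = logical(),
                      charge = integer(), hcount = integer(), map = integer(),
                      mol = integer(), local = integer(), global = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_along(mols), function(i) {
    a <- mols[[i]]@atoms
    a$mol <- i
    a$local <- seq_len(nrow(a))
    a
  }))
  out$global <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Bond table of one reaction side in global atom indexing
#'
#' @param r a [Reaction-class].
#' @param side `"reactant"` or `"product"`.
#' @return data.frame with `a1`, `a2` (global indices) and `order`.
#' @export
sideBonds <- function(r, side = c("reactant", "product")) {
  side <- match.arg(side)
  mols <- if (side == "reactant") r@reactants else r@products
  offset <- 0L
  parts <- list()
  for (i in seq_along(mols)) {
    b <- mols[[i]]@bonds
    if (nrow(b)) {
      b$a1 <- b$a1 + offset; b$a2 <- b$a2 + offset
      parts[[length(parts) + 1]] <- b
    }
    offset <- offset + nrow(mols[[i]]@atoms)
  }
  if (!length(parts))
    return(data.frame(a1 = integer(), a2 = integer(), order = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Construct a Reaction
#'
#' @param reactants,products lists of [Molecule-class] objects.
#' @param id reaction identifier.
#' @param rcReactants,rcProducts integer global RC atom indices (optional).
#' @return a validated [Reaction-class].
#' @export
newReaction <- function(reactants, products, id = NA_character_,
                        rcReactants = integer(), rcProducts = integer()) {
  r <- new("Reaction", id = as.character(id), reactants = reactants,
           products = products, rcReactants = as.integer(rcReactants),
           rcProducts = as.integer(rcProducts))
  validObject(r)
  r
}

#' Parse a reaction SMILES string
#'
#' Follows the `reactants>agents>products` convention; the agents field is
#' parsed and discarded with a warning since only reactants and products enter
#' the model. Atom-map numbers are retained on atoms; RC sets start empty.
#'
#' @param text reaction SMILES, e.g. `"CC(=O)OC.O>>CC(=O)O.CO"`.
#' @param id reaction identifier.
#' @return a [Reaction-class].
#' @export
parseReaction <- function(text, id = NA_character_) {
  if (!is.character(text) || length(text) != 1)
    stop("reaction SMILES must be a single string")
  parts <- strsplit(text, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2 && grepl(">>", text, fixed = TRUE)) parts <- c(parts, "")
  if (length(parts) != 3)
    stop(sprintf("'%s' is not of the form reactants>agents>products", text))
  parseSide <- function(sideText, what) {
    if (!nzchar(sideText))
      stop(sprintf("empty %s side in '%s'", what, text))
    frags <- strsplit(sideText, ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    lapply(frags, function(f) {
      tryCatch(parseSmiles(f), error = function(e)
        stop(sprintf("failed to parse %s fragment '%s': %s",
                     what, f, conditionMessage(e)), call. = FALSE))
    })
  }
  if (nzchar(parts[2]))
    warning(sprintf("agents '%s' parsed and discarded", parts[2]))
  reactantsL <- parseSide(parts[1], "reactant")
  productsL <- parseSide(parts[3], "product")
  newReaction(reactantsL, productsL, id = id)
}

#' Serialize a reaction to reaction SMILES
#'
#' @param r a [Reaction-class].
#' @param withMaps write atom-map numbers.
#' @param canonicalOrder sort each side's molecule strings (default `TRUE`);
#'   with `withMaps = FALSE` the result is the canonical form of the reaction.
#' @return a reaction SMILES string (empty agents field omitted: `">>"`).
#' @export
writeReactionSmiles <- function(r, withMaps = FALSE, canonicalOrder = TRUE) {
  sideStr <- function(mols) {
    s <- vapply(mols, writeSmiles, character(1), withMaps = withMaps)
    if (canonicalOrder) s <- sort(s)
    paste(s, collapse = ".")
  }
  paste0(sideStr(r@reactants), ">>", sideStr(r@products))
}

#' Canonical form equality of two molecule multisets
#' @param molsA,molsB lists of [Molecule-class] objects.
#' @return logical.
#' @keywords internal
.sameMoleculeMultiset <- function(molsA, molsB) {
  if (length(molsA) != length(molsB)) return(FALSE)
  a <- sort(vapply(molsA, writeSmiles, character(1)))
  b <- sort(vapply(molsB, writeSmiles, character(1)))
  identical(a, b)
}

#' Per-element atom counts of one side
#'
#' A total atom map guarantees equal heavy-element counts on both sides.
#' Hydrogen totals (`includeH = TRUE`) balance too except for
#' hydrogen-transfer reactions written without their redox cofactor, where
#' implicit hydrogens enter or leave the represented system.
#'
#' @param r a [Reaction-class].
#' @param side `"reactant"` or `"product"`.
#' @param includeH also count implicit hydrogens.
#' @return named integer vector.
#' @export
elementCounts <- function(r, side = c("reactant", "product"),
                          includeH = TRUE) {
  at <- sideAtoms(r, match.arg(side))
  if (!nrow(at)) return(integer(0))
  tabs <- table(at$element)
  out <- as.integer(tabs); names(out) <- names(tabs)
  h <- sum(at$hcount)
  if (includeH && h > 0) out <- c(out, H = h)
  out[order(names(out))]
}
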