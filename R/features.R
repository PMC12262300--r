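# Atom/bond featurization and encoder-ready reaction graphs.

.ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")
.HYB_VOCAB <- c("sp", "sp2", "sp3")

#' Atom feature vector layout
#'
#' One-hot element (fixed vocabulary plus other), total degree 0-5, formal
#' charge -2..+2, explicit hydrogen count 0-4, hybridization (sp/sp2/sp3/
#' other), an aromaticity bit, the atomic mass scaled by 1/100 and (for
#' reaction graphs) a two-bit side tag. Out-of-range degrees, charges and
#' hydrogen counts are clamped into the last slot of their block.
#'
#' @return integer: the length of an atom feature vector (with side tag).
#' @export
atomFeatureLength <- function() {
  length(.ELEMENT_VOCAB) + 1 + 6 + 5 + 5 + (length(.HYB_VOCAB) + 1) + 1 + 1 + 2
}

#' @rdname atomFeatureLength
#' @return integer: the length of a bond feature vector.
#' @export
bondFeatureLength <- function() 4 + 1 + 1 + 1

# featurize the atoms of one molecule; side in "reactant"/"product"/"none"
.atomFeatureMatrix <- function(mol, side = "none") {
  n <- nrow(mol@atoms)
  deg <- atomDegrees(mol)
  hyb <- atomHybridization(mol)
  useSide <- side != "none"
  width <- atomFeatureLength() - if (useSide) 0 else 2
  out <- matrix(0, n, width)
  oneHot <- function(i, offset, pos) out[i, offset + pos] <<- 1
  for (i in seq_len(n)) {
    a <- mol@atoms[i, ]
    off <- 0
    el <- match(a$element, .ELEMENT_VOCAB)
    oneHot(i, off, if (is.na(el)) length(.ELEMENT_VOCAB) + 1 else el)
    off <- off + length(.ELEMENT_VOCAB) + 1
    oneHot(i, off, min(deg[i], 5L) + 1L)
    off <- off + 6
    oneHot(i, off, min(max(a$charge, -2L), 2L) + 3L)
    off <- off + 5
    oneHot(i, off, min(a$hcount, 4L) + 1L)
    off <- off + 5
    hy <- match(hyb[i], .HYB_VOCAB)
    oneHot(i, off, if (is.na(hy)) length(.HYB_VOCAB) + 1 else hy)
    off <- off + length(.HYB_VOCAB) + 1
    out[i, off + 1] <- as.numeric(a$aromatic)
    off <- off + 1
    mass <- .ATOMIC_MASS[[a$element]]
    out[i, off + 1] <- if (is.null(mass)) 0 else mass / 100
    off <- off + 1
    if (useSide) out[i, off + if (side == "reactant") 1 else 2] <- 1
  }
  out
}

# featurize the bonds of one molecule (order, conjugation, ring, virtual=0)
.bondFeatureMatrix <- function(mol) {
  nb <- nrow(mol@bonds)
  out <- matrix(0, nb, bondFeatureLength())
  if (!nb) return(out)
  ring <- bondInRing(mol)
  conj <- bondConjugated(mol)
  orderPos <- match(mol@bonds$order, c("1", "2", "3", "ar"))
  for (k in seq_len(nb)) {
    out[k, orderPos[k]] <- 1
    out[k, 5] <- as.numeric(conj[k])
    out[k, 6] <- as.numeric(ring[k])
  }
  out
}

.virtualEdgeFeature <- function() {
  f <- numeric(bondFeatureLength())
  f[7] <- 1
  f
}

#' Build an encoder-ready reaction graph
#'
#' `bag_of_molecules` uses the plain disjoint union of all reactant and
#' product molecular graphs; `rc_connected` and `rc_aggregated` add one
#' initially stateless virtual node wired by virtual edges to every RC atom
#' on both sides; `cgr` condenses each mapped reactant/product atom pair into
#' one node carrying the concatenated before/after atom features, with edges
#' carrying before/after bond-state features (an explicit absent state for
#' formed and broken bonds). Every bond contributes two directed edges.
#'
#' @param r a [Reaction-class] (RC-annotated for `rc_*`; fully mapped for
#'   `cgr`).
#' @param variant encoder variant name.
#' @return a [ReactionGraph-class].
#' @export
buildReactionGraph <- function(r, variant = c("bag_of_molecules",
                                              "rc_connected", "rc_aggregated",
                                              "cgr")) {
  variant <- match.arg(variant)
  if (variant == "cgr") return(.buildCgrGraph(r))
  needRc <- variant %in% c("rc_connected", "rc_aggregated")
  if (needRc && (!length(r@rcReactants) || !length(r@rcProducts)))
    stop(sprintf("variant %s requires a nonempty RC (reaction %s)", variant,
                 r@id))
  molsR <- r@reactants; molsP <- r@products
  X <- rbind(
    do.call(rbind, lapply(molsR, .atomFeatureMatrix, side = "reactant")),
    do.call(rbind, lapply(molsP, .atomFeatureMatrix, side = "product")))
  nR <- sum(vapply(molsR, atomCount, integer(1)))
  n <- nrow(X)
  side <- c(rep("reactant", nR), rep("product", n - nR))
  rcFlag <- logical(n)
  rcFlag[r@rcReactants] <- TRUE
  rcFlag[nR + r@rcProducts] <- TRUE
  bondsR <- sideBonds(r, "reactant")
  bondsP <- sideBonds(r, "product")
  if (nrow(bondsP)) { bondsP$a1 <- bondsP$a1 + nR; bondsP$a2 <- bondsP$a2 + nR }
  EfeatParts <- c(lapply(molsR, .bondFeatureMatrix),
                  lapply(molsP, .bondFeatureMatrix))
  bonds <- rbind(bondsR, bondsP)
  Efeat1 <- do.call(rbind, EfeatParts)
  virtualIndex <- NA_integer_
  if (needRc) {
    virtualIndex <- n + 1L
    X <- rbind(X, 0)
    side <- c(side, "virtual")
    rcFlag <- c(rcFlag, FALSE)
    rcIdx <- which(rcFlag[seq_len(n)])
    vb <- data.frame(a1 = rep(virtualIndex, length(rcIdx)), a2 = rcIdx,
                     order = "1", stringsAsFactors = FALSE)
    bonds <- rbind(bonds, vb)
    Efeat1 <- rbind(Efeat1,
                    matrix(rep(.virtualEdgeFeature(), length(rcIdx)),
                           ncol = bondFeatureLength(), byrow = TRUE))
    n <- n + 1L
  }
  nb <- nrow(bonds)
  edgeSrc <- integer(2 * nb); edgeDst <- integer(2 * nb)
  rev <- integer(2 * nb)
  Efeat <- matrix(0, 2 * nb, ncol(Efeat1))
  for (k in seq_len(nb)) {
    e1 <- 2L * k - 1L; e2 <- 2L * k
    edgeSrc[e1] <- bonds$a1[k]; edgeDst[e1] <- bonds$a2[k]
    edgeSrc[e2] <- bonds$a2[k]; edgeDst[e2] <- bonds$a1[k]
    rev[e1] <- e2; rev[e2] <- e1
    Efeat[e1, ] <- Efeat1[k, ]; Efeat[e2, ] <- Efeat1[k, ]
  }
  new("ReactionGraph", nodeFeatures = X, edgeFeatures = Efeat,
      edgeSrc = edgeSrc, edgeDst = edgeDst, revIndex = rev, side = side,
      rcFlag = rcFlag,
      realAtoms = which(side != "virtual"),
      virtualIndex = virtualIndex, variant = variant)
}

.buildCgrGraph <- function(r) {
  ra <- sideAtoms(r, "reactant"); pa <- sideAtoms(r, "product")
  if (any(ra$map == 0) || any(pa$map == 0) || !setequal(ra$map, pa$map))
    stop(sprintf("cgr requires a total atom map (reaction %s)", r@id))
  featR <- do.call(rbind, lapply(r@reactants, .atomFeatureMatrix,
                                 side = "none"))
  featP <- do.call(rbind, lapply(r@products, .atomFeatureMatrix,
                                 side = "none"))
  # one condensed node per mapped pair, ordered by reactant global index
  pIdx <- match(ra$map, pa$map)
  X <- cbind(featR, featP[pIdx, , drop = FALSE])
  n <- nrow(X)
  rcFlag <- logical(n)
  rcFlag[r@rcReactants] <- TRUE
  bondState <- function(side, feats) {
    b <- sideBonds(r, side)
    at <- if (side == "reactant") ra else pa
    keys <- if (nrow(b)) paste(pmin(at$map[b$a1], at$map[b$a2]),
                               pmax(at$map[b$a1], at$map[b$a2]), sep = "-")
            else character(0)
    stats::setNames(seq_len(nrow(b)), keys)
  }
  featBondsR <- do.call(rbind, c(lapply(r@reactants, .bondFeatureMatrix),
                                 list(matrix(0, 0, bondFeatureLength()))))
  featBondsP <- do.call(rbind, c(lapply(r@products, .bondFeatureMatrix),
                                 list(matrix(0, 0, bondFeatureLength()))))
  idxR <- bondState("reactant", featBondsR)
  idxP <- bondState("product", featBondsP)
  keys <- union(names(idxR), names(idxP))
  stateWidth <- bondFeatureLength()  # order(4) + conj + ring + absent
  mkState <- function(key, idx, feats) {
    if (key %in% names(idx)) feats[idx[[key]], seq_len(stateWidth - 1)] else
      NULL
  }
  edges <- list(); efeat <- list()
  nodeOfMap <- stats::setNames(seq_len(nrow(ra)), ra$map)
  for (key in keys) {
    mm <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    v1 <- nodeOfMap[[as.character(mm[1])]]
    v2 <- nodeOfMap[[as.character(mm[2])]]
    before <- mkState(key, idxR, featBondsR)
    after <- mkState(key, idxP, featBondsP)
    absent <- numeric(stateWidth); absent[stateWidth] <- 1
    f <- c(if (is.null(before)) absent else c(before, 0),
           if (is.null(after)) absent else c(after, 0))
    edges[[length(edges) + 1]] <- c(v1, v2)
    efeat[[length(efeat) + 1]] <- f
  }
  nb <- length(edges)
  edgeSrc <- integer(2 * nb); edgeDst <- integer(2 * nb); rev <- integer(2 * nb)
  Efeat <- matrix(0, 2 * nb, 2 * stateWidth)
  for (k in seq_len(nb)) {
    e1 <- 2L * k - 1L; e2 <- 2L * k
    edgeSrc[e1] <- edges[[k]][1]; edgeDst[e1] <- edges[[k]][2]
    edgeSrc[e2] <- edges[[k]][2]; edgeDst[e2] <- edges[[k]][1]
    rev[e1] <- e2; rev[e2] <- e1
    Efeat[e1, ] <- efeat[[k]]; Efeat[e2, ] <- efeat[[k]]
  }
  new("ReactionGraph", nodeFeatures = X, edgeFeatures = Efeat,
      edgeSrc = edgeSrc, edgeDst = edgeDst, revIndex = rev,
      side = rep("condensed", n), rcFlag = rcFlag,
      realAtoms = seq_len(n), virtualIndex = NA_integer_, variant = "cgr")
}
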