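# Reaction encoders: directed-edge message passing (bond-centric, with the
# reverse edge excluded from each aggregation) and the Morgan-fingerprint
# benchmark. Forward passes cache every intermediate needed for the manual
# backward pass used in training.

#' Encoder configuration
#'
#' @param variant one of `"bag_of_molecules"`, `"rc_connected"`,
#'   `"rc_aggregated"`, `"cgr"`, `"morgan"`.
#' @param M number of message passings (total, so the receptive field extends
#'   `M - 1` bonds); defaults to 4 for `rc_aggregated` and 6 otherwise.
#' @param hidden hidden (edge-state) dimension; defaults to `d`.
#' @param d output embedding dimension (default 300).
#' @param radius,nbits Morgan fingerprint radius and length.
#' @param seed RNG seed for weight initialization.
#' @return validated named list.
#' @export
encoderConfig <- function(variant = c("rc_aggregated", "rc_connected",
                                      "bag_of_molecules", "cgr", "morgan"),
                          M = NULL, hidden = NULL, d = 300, radius = 2,
                          nbits = 2048, seed = 1) {
  variant <- match.arg(variant)
  if (is.null(M)) M <- if (variant == "rc_aggregated") 4L else 6L
  if (is.null(hidden)) hidden <- d
  if (M < 1) stop("M must be at least 1")
  if (d < 1 || hidden < 1) stop("dimensions must be positive")
  list(variant = variant, M = as.integer(M), hidden = as.integer(hidden),
       d = as.integer(d), radius = as.integer(radius),
       nbits = as.integer(nbits), seed = as.integer(seed))
}

.glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize encoder (and scorer) weights
#'
#' @param config an [encoderConfig()].
#' @param proteinDim input protein-embedding dimension (default 1280).
#' @return named list of weight matrices: for GNN variants `Win`
#'   (hidden x (atomFeat+bondFeat)), `Wm` (hidden x hidden), `Wread`
#'   (hidden x (atomFeat+hidden)), `Wout` (d x hidden) and `Wp`
#'   (d x proteinDim); for `morgan`, `Wmrg` (d x nbits) and `Wp`.
#' @export
initWeights <- function(config, proteinDim = 1280) {
  set.seed(config$seed)
  d <- config$d; h <- config$hidden
  if (config$variant == "morgan") {
    return(list(Wmrg = .glorot(d, config$nbits),
                Wp = .glorot(d, proteinDim)))
  }
  fa <- if (config$variant == "cgr") 2 * (atomFeatureLength() - 2) else
    atomFeatureLength()
  fb <- if (config$variant == "cgr") 2 * bondFeatureLength() else
    bondFeatureLength()
  list(Win = .glorot(h, fa + fb), Wm = .glorot(h, h),
       Wread = .glorot(h, fa + h), Wout = .glorot(d, h),
       Wp = .glorot(d, proteinDim))
}

# aggregation matrices: A[e, e'] = 1 iff e' flows into the source of e and is
# not e's reverse; B[v, e] = 1 iff e points at v
.graphOperators <- function(g) {
  E <- length(g@edgeSrc)
  n <- nrow(g@nodeFeatures)
  A <- matrix(0, E, E)
  B <- matrix(0, n, E)
  for (e in seq_len(E)) {
    inc <- which(g@edgeDst == g@edgeSrc[e])
    inc <- inc[inc != g@revIndex[e]]
    if (length(inc)) A[e, inc] <- 1
    B[g@edgeDst[e], e] <- 1
  }
  list(A = A, B = B)
}

# full forward pass with caches; g may carry precomputed operators as attr
.encoderForward <- function(g, w, M, ops = NULL) {
  if (is.null(ops)) ops <- .graphOperators(g)
  X <- g@nodeFeatures
  E <- length(g@edgeSrc)
  h <- nrow(w$Win)
  if (E > 0) {
    H0in <- cbind(X[g@edgeSrc, , drop = FALSE], g@edgeFeatures)
    Z0 <- H0in %*% t(w$Win)
  } else {
    H0in <- matrix(0, 0, ncol(X) + ncol(g@edgeFeatures))
    Z0 <- matrix(0, 0, h)
  }
  Hs <- vector("list", M)
  Zs <- vector("list", M)
  Zs[[1]] <- Z0
  Hs[[1]] <- pmax(Z0, 0)
  if (M >= 2) for (t in 2:M) {
    Zs[[t]] <- Z0 + (ops$A %*% Hs[[t - 1]]) %*% t(w$Wm)
    Hs[[t]] <- pmax(Zs[[t]], 0)
  }
  nodeIn <- cbind(X, ops$B %*% Hs[[M]])
  nodeZ <- nodeIn %*% t(w$Wread)
  nodeH <- pmax(nodeZ, 0)
  list(ops = ops, H0in = H0in, Zs = Zs, Hs = Hs, nodeIn = nodeIn,
       nodeZ = nodeZ, nodeH = nodeH)
}

.aggregateForward <- function(g, fw, w) {
  if (g@variant == "rc_aggregated") {
    zraw <- fw$nodeH[g@virtualIndex, ]
  } else {
    zraw <- colMeans(fw$nodeH[g@realAtoms, , drop = FALSE])
  }
  list(zraw = zraw, z = as.numeric(w$Wout %*% zraw))
}

# backward: dz is dL/d(embedding); returns gradient list (Win, Wm, Wread,
# Wout) accumulated from this reaction
.encoderBackward <- function(g, fw, w, dz, M) {
  zraw <- if (g@variant == "rc_aggregated") fw$nodeH[g@virtualIndex, ] else
    colMeans(fw$nodeH[g@realAtoms, , drop = FALSE])
  dWout <- outer(dz, zraw)
  dzraw <- as.numeric(t(w$Wout) %*% dz)
  dNodeH <- matrix(0, nrow(fw$nodeH), ncol(fw$nodeH))
  if (g@variant == "rc_aggregated") {
    dNodeH[g@virtualIndex, ] <- dzraw
  } else {
    dNodeH[g@realAtoms, ] <- matrix(dzraw / length(g@realAtoms),
                                    length(g@realAtoms), length(dzraw),
                                    byrow = TRUE)
  }
  dNodeZ <- dNodeH * (fw$nodeZ > 0)
  dWread <- t(dNodeZ) %*% fw$nodeIn
  dNodeIn <- dNodeZ %*% w$Wread
  fa <- ncol(g@nodeFeatures)
  h <- nrow(w$Win)
  dHM <- t(fw$ops$B) %*% dNodeIn[, (fa + 1):(fa + h), drop = FALSE]
  dWm <- matrix(0, h, h)
  dZ0 <- matrix(0, nrow(dHM), h)
  dH <- dHM
  for (t in M:1) {
    dZ <- dH * (fw$Zs[[t]] > 0)
    dZ0 <- dZ0 + dZ
    if (t >= 2) {
      Msg <- fw$ops$A %*% fw$Hs[[t - 1]]
      dWm <- dWm + t(dZ) %*% Msg
      dH <- t(fw$ops$A) %*% (dZ %*% w$Wm)
    }
  }
  dWin <- if (nrow(fw$H0in)) t(dZ0) %*% fw$H0in else
    matrix(0, h, ncol(w$Win))
  list(Win = dWin, Wm = dWm, Wread = dWread, Wout = dWout)
}

#' Run message passing over a reaction graph
#'
#' Directed-edge message passing: the initial state of each directed edge is
#' a rectified linear transform of its source-node and edge features; each of
#' the `M - 1` update steps aggregates the states of edges flowing into the
#' edge's source, excluding its own reverse, and the final node embedding
#' combines the node features with the sum of incoming edge states.
#'
#' @param g a [ReactionGraph-class].
#' @param weights weight list from [initWeights()].
#' @param M number of message passings.
#' @return numeric matrix (nodes x hidden) of node embeddings.
#' @export
messagePassing <- function(g, weights, M) {
  if (M < 1) stop("M must be at least 1")
  if (!all(vapply(weights, function(w) all(is.finite(w)), logical(1))))
    stop("non-finite weights")
  .encoderForward(g, weights, M)$nodeH
}

#' Aggregate node embeddings into a reaction vector
#'
#' `rc_aggregated` reads out the virtual node's embedding; all other graph
#' variants use the mean over real atom nodes (the virtual node, not being an
#' atom, is excluded from the mean). The learned output projection maps the
#' result to the embedding dimension.
#'
#' @param nodeEmbeddings matrix from [messagePassing()].
#' @param g the [ReactionGraph-class] they were computed on.
#' @param weights weight list (uses `Wout`).
#' @return numeric embedding of length `d`.
#' @export
aggregateNodes <- function(nodeEmbeddings, g, weights) {
  zraw <- if (g@variant == "rc_aggregated") {
    if (is.na(g@virtualIndex)) stop("graph has no virtual node")
    nodeEmbeddings[g@virtualIndex, ]
  } else colMeans(nodeEmbeddings[g@realAtoms, , drop = FALSE])
  as.numeric(weights$Wout %*% zraw)
}

# ---- Morgan (ECFP-style) fingerprint -----------------------------------

.hashInts <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

.moleculeMorgan <- function(mol, radius, nbits) {
  n <- nrow(mol@atoms)
  counts <- numeric(nbits)
  if (!n) return(counts)
  deg <- atomDegrees(mol)
  elemCode <- match(mol@atoms$element, names(.ATOMIC_MASS))
  elemCode[is.na(elemCode)] <- 0L
  inv <- vapply(seq_len(n), function(i)
    .hashInts(c(elemCode[i], deg[i], mol@atoms$charge[i] + 10,
                mol@atoms$hcount[i], as.integer(mol@atoms$aromatic[i]))),
    numeric(1))
  b <- mol@bonds
  nbrs <- vector("list", n)
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    code <- .ORDER_CODE[[b$order[k]]]
    nbrs[[b$a1[k]]] <- rbind(nbrs[[b$a1[k]]], c(code, b$a2[k]))
    nbrs[[b$a2[k]]] <- rbind(nbrs[[b$a2[k]]], c(code, b$a1[k]))
  }
  record <- function(vals) for (v in vals)
    counts[(v %% nbits) + 1] <<- counts[(v %% nbits) + 1] + 1
  record(inv)
  for (r in seq_len(radius)) {
    newInv <- vapply(seq_len(n), function(i) {
      nb <- nbrs[[i]]
      if (is.null(nb)) return(.hashInts(c(r, inv[i])))
      pairKeys <- paste(sprintf("%012.0f", inv[nb[, 2]]), nb[, 1])
      ord <- order(pairKeys)
      .hashInts(c(r, inv[i],
                  as.numeric(t(cbind(nb[ord, 1], inv[nb[ord, 2]])))))
    }, numeric(1))
    inv <- newInv
    record(inv)
  }
  counts
}

#' Morgan reaction fingerprint
#'
#' Circular (ECFP-style) substructure count vectors are computed per molecule
#' by iterative neighbourhood hashing up to the given radius, summed per
#' reaction side; the reaction fingerprint is the elementwise absolute
#' difference of the two side sums (so swapping sides leaves it unchanged and
#' an identity reaction maps to the zero vector).
#'
#' @param r a [Reaction-class].
#' @param radius fingerprint radius (default 2).
#' @param nbits fingerprint length (default 2048).
#' @return numeric count vector of length `nbits`.
#' @export
morganFingerprint <- function(r, radius = 2, nbits = 2048) {
  sumSide <- function(mols) {
    out <- numeric(nbits)
    for (m in mols) out <- out + .moleculeMorgan(m, radius, nbits)
    out
  }
  abs(sumSide(r@reactants) - sumSide(r@products))
}

#' Embed a reaction
#'
#' Composes graph construction, message passing, aggregation and the output
#' projection (or, for `morgan`, the fingerprint and its linear projection).
#' Deterministic, and invariant to atom input order and to molecule order
#' within each side.
#'
#' @param r a [Reaction-class].
#' @param config an [encoderConfig()].
#' @param weights weight list from [initWeights()].
#' @return numeric embedding of length `config$d`.
#' @export
embedReaction <- function(r, config, weights) {
  if (config$variant == "morgan") {
    fp <- morganFingerprint(r, config$radius, config$nbits)
    return(as.numeric(weights$Wmrg %*% fp))
  }
  g <- buildReactionGraph(r, config$variant)
  fw <- .encoderForward(g, weights, config$M)
  .aggregateForward(g, fw, weights)$z
}
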