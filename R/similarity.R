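# Reaction similarity (RCMCS) and protein similarity (GSI).
#
# RCMCS definition used throughout: a common subgraph of two reactions is an
# injective, side-respecting partial correspondence between their atoms that
# (i) is compatible under the atom-match criteria, (ii) is edge-consistent
# (induced): two matched atom pairs are bonded in one reaction iff they are
# bonded in the other, with matching order when required, (iii) contains a
# full isomorphism between the two reaction centers (RC atoms match RC atoms,
# all of them), and (iv) every connected component of the common subgraph
# contains an RC atom pair, except components that cover an entire molecule
# in both reactions (fully matched spectator molecules). The RCMCS score is
# the atom count of the largest such correspondence divided by the total atom
# count of the larger reaction.

#' Atom-match criteria for common-subgraph search
#'
#' Element identity is always required; the remaining flags control how
#' strictly atoms and bonds must agree. The default matches aromaticity and
#' bond order but ignores charge (charges are neutralized upstream).
#'
#' @param matchAromaticity require equal aromatic flags.
#' @param matchCharge require equal formal charges.
#' @param matchBondOrder require equal bond orders on common edges.
#' @return named list of criteria flags.
#' @export
atomMatchCriteria <- function(matchAromaticity = TRUE, matchCharge = FALSE,
                              matchBondOrder = TRUE) {
  list(matchElement = TRUE, matchAromaticity = matchAromaticity,
       matchCharge = matchCharge, matchBondOrder = matchBondOrder)
}

.ORDER_CODE <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 4L)

# Joint (disjoint-union) graph of a reaction: reactant and product atoms with
# an integer adjacency matrix of bond-order codes.
.jointGraph <- function(r) {
  ra <- sideAtoms(r, "reactant"); pa <- sideAtoms(r, "product")
  nR <- nrow(ra); nP <- nrow(pa); n <- nR + nP
  side <- c(rep("R", nR), rep("P", nP))
  elem <- c(ra$element, pa$element)
  arom <- c(ra$aromatic, pa$aromatic)
  charge <- c(ra$charge, pa$charge)
  molKey <- c(paste0("R", ra$mol), paste0("P", pa$mol))
  rc <- logical(n)
  rc[r@rcReactants] <- TRUE
  rc[nR + r@rcProducts] <- TRUE
  M <- matrix(0L, n, n)
  rb <- sideBonds(r, "reactant")
  if (nrow(rb)) for (k in seq_len(nrow(rb))) {
    code <- .ORDER_CODE[[rb$order[k]]]
    M[rb$a1[k], rb$a2[k]] <- code; M[rb$a2[k], rb$a1[k]] <- code
  }
  pb <- sideBonds(r, "product")
  if (nrow(pb)) for (k in seq_len(nrow(pb))) {
    code <- .ORDER_CODE[[pb$order[k]]]
    M[nR + pb$a1[k], nR + pb$a2[k]] <- code
    M[nR + pb$a2[k], nR + pb$a1[k]] <- code
  }
  rcFreeMols <- list()
  for (s in c("reactant", "product")) {
    mols <- if (s == "reactant") r@reactants else r@products
    off <- if (s == "reactant") 0L else nR
    at <- if (s == "reactant") ra else pa
    for (mi in seq_along(mols)) {
      gidx <- off + at$global[at$mol == mi]
      if (!any(rc[gidx]))
        rcFreeMols[[length(rcFreeMols) + 1]] <-
          list(side = if (s == "reactant") "R" else "P", mol = mols[[mi]],
               natoms = length(gidx))
    }
  }
  list(n = n, side = side, elem = elem, arom = arom, charge = charge,
       molKey = molKey, rc = which(rc), M = M, rcFree = rcFreeMols)
}

.atomsCompatible <- function(g1, a, g2, b, crit) {
  g1$side[a] == g2$side[b] && g1$elem[a] == g2$elem[b] &&
    (!crit$matchAromaticity || g1$arom[a] == g2$arom[b]) &&
    (!crit$matchCharge || g1$charge[a] == g2$charge[b])
}

.bondsCompatible <- function(e1, e2, crit) {
  if (e1 == 0L && e2 == 0L) return(TRUE)
  if (e1 == 0L || e2 == 0L) return(FALSE)
  !crit$matchBondOrder || e1 == e2
}

# Whole-molecule matches between RC-free (spectator) molecules of the two
# reactions: exact isomorphism under the criteria, counted side by side.
.spectatorBonus <- function(g1, g2, crit) {
  key <- function(entry) {
    mol <- entry$mol
    mol@atoms$map <- 0L
    if (!crit$matchCharge) mol@atoms$charge <- 0L
    if (!crit$matchAromaticity) mol@atoms$aromatic <- FALSE
    paste0(entry$side, "|", writeSmiles(mol))
  }
  if (!length(g1$rcFree) || !length(g2$rcFree)) return(0L)
  k1 <- vapply(g1$rcFree, key, character(1))
  k2 <- vapply(g2$rcFree, key, character(1))
  n1 <- vapply(g1$rcFree, function(e) e$natoms, integer(1))
  bonus <- 0L
  for (k in intersect(unique(k1), unique(k2))) {
    cnt <- min(sum(k1 == k), sum(k2 == k))
    bonus <- bonus + cnt * n1[which(k1 == k)[1]]
  }
  bonus
}

# Enumerate RC-to-RC isomorphisms, then extend by anchored, edge-consistent
# growth. `useBound` enables best-first pruning (production); the oracle runs
# the same definition without pruning. `budget` caps visited search nodes;
# when exhausted the best correspondence found so far is returned with
# `exact = FALSE`.
.mcsSearch <- function(g1, g2, crit, useBound = TRUE, budget = Inf) {
  rc1 <- g1$rc; rc2 <- g2$rc
  if (sum(g1$side[rc1] == "R") != sum(g2$side[rc2] == "R") ||
      sum(g1$side[rc1] == "P") != sum(g2$side[rc2] == "P"))
    return(list(size = 0L, rcCompatible = FALSE, exact = TRUE, nodes = 0L))
  env <- new.env()
  env$best <- -1L
  env$nodes <- 0L
  env$exact <- TRUE
  env$rcFound <- FALSE
  map1 <- integer(g1$n)  # image in g2, 0 = unmatched
  matched2 <- logical(g2$n)
  consistentWithAll <- function(a, b) {
    ms <- which(map1 > 0)
    for (a2 in ms) {
      if (!.bondsCompatible(g1$M[a, a2], g2$M[b, map1[a2]], crit))
        return(FALSE)
    }
    TRUE
  }
  classKey1 <- paste(g1$side, g1$elem)
  classKey2 <- paste(g2$side, g2$elem)
  extend <- function(excluded) {
    env$nodes <- env$nodes + 1L
    if (env$nodes > budget) { env$exact <- FALSE; return(invisible()) }
    size <- sum(map1 > 0)
    if (useBound && env$best >= 0) {
      avail1 <- which(map1 == 0 & !excluded)
      avail2 <- which(!matched2)
      pot <- 0L
      t1 <- table(classKey1[avail1]); t2 <- table(classKey2[avail2])
      for (k in intersect(names(t1), names(t2)))
        pot <- pot + min(t1[[k]], t2[[k]])
      if (size + pot <= env$best) return(invisible())
    }
    ms <- which(map1 > 0)
    frontier <- NA_integer_
    for (a in seq_len(g1$n)) {
      if (map1[a] > 0 || excluded[a]) next
      if (any(g1$M[a, ms] != 0L)) { frontier <- a; break }
    }
    if (is.na(frontier)) {
      if (size > env$best) env$best <- size
      return(invisible())
    }
    a <- frontier
    anchors <- ms[g1$M[a, ms] != 0L]
    cand <- integer(0)
    for (a2 in anchors) {
      b2 <- map1[a2]
      cand <- c(cand, which(g2$M[b2, ] != 0L & !matched2))
    }
    for (b in unique(cand)) {
      if (!.atomsCompatible(g1, a, g2, b, crit)) next
      if (!consistentWithAll(a, b)) next
      map1[a] <<- b; matched2[b] <<- TRUE
      extend(excluded)
      map1[a] <<- 0L; matched2[b] <<- FALSE
      if (!env$exact) return(invisible())
    }
    excluded[a] <- TRUE
    extend(excluded)
  }
  rcR1 <- rc1[g1$side[rc1] == "R"]; rcP1 <- rc1[g1$side[rc1] == "P"]
  rcOrder <- c(rcR1, rcP1)
  assignRc <- function(step) {
    if (env$nodes > budget) { env$exact <- FALSE; return(invisible()) }
    if (step > length(rcOrder)) {
      env$rcFound <- TRUE
      extend(logical(g1$n))
      return(invisible())
    }
    a <- rcOrder[step]
    for (b in rc2) {
      if (matched2[b]) next
      if (!.atomsCompatible(g1, a, g2, b, crit)) next
      if (!consistentWithAll(a, b)) next
      map1[a] <<- b; matched2[b] <<- TRUE
      assignRc(step + 1)
      map1[a] <<- 0L; matched2[b] <<- FALSE
      if (!env$exact) return(invisible())
    }
  }
  env$nodes <- env$nodes + 1L
  assignRc(1)
  if (!env$rcFound && env$exact)
    return(list(size = 0L, rcCompatible = FALSE, exact = TRUE,
                nodes = env$nodes))
  list(size = max(env$best, 0L), rcCompatible = env$rcFound || !env$exact,
       exact = env$exact, nodes = env$nodes)
}

.checkRcmcsInput <- function(r) {
  if (!length(r@rcReactants) || !length(r@rcProducts))
    stop(sprintf("reaction %s has an empty RC; RCMCS requires annotated RCs",
                 r@id))
}

#' Reaction-center maximum common subgraph similarity
#'
#' Ratio of the atom count of the largest RC-containing common subgraph of
#' the two reactions to the total atom count of the larger reaction. Pairs
#' whose RCs admit no criteria-compatible correspondence score 0. Symmetric,
#' bounded in `[0, 1]`, and 1 exactly for canonically identical reactions.
#'
#' @param r1,r2 [Reaction-class] objects with nonempty RC annotations.
#' @param criteria see [atomMatchCriteria()].
#' @param budget maximum number of search nodes before the deterministic
#'   bounded-search fallback result is returned (attribute `exact` is then
#'   `FALSE`).
#' @return numeric score in `[0, 1]` with attributes `numerator` (matched
#'   atoms) and `exact`.
#' @export
rcmcs <- function(r1, r2, criteria = atomMatchCriteria(), budget = 2e5) {
  .checkRcmcsInput(r1); .checkRcmcsInput(r2)
  g1 <- .jointGraph(r1); g2 <- .jointGraph(r2)
  res <- .mcsSearch(g1, g2, criteria, useBound = TRUE, budget = budget)
  num <- if (res$rcCompatible)
    res$size + .spectatorBonus(g1, g2, criteria) else 0L
  den <- max(reactionAtomCount(r1), reactionAtomCount(r2))
  out <- num / den
  attr(out, "numerator") <- num
  attr(out, "exact") <- res$exact
  out
}

#' Exhaustive common-subgraph oracle
#'
#' Exhaustive search over RC-containing common-subgraph correspondences under
#' the same definition as [rcmcs()], without pruning; exponential time is
#' accepted, so inputs are size-guarded.
#'
#' @param r1,r2 [Reaction-class] objects with nonempty RCs.
#' @param criteria see [atomMatchCriteria()].
#' @param maxAtoms refuse reactions with more atoms than this per side.
#' @return integer: atom count of the maximum common subgraph.
#' @export
mcsOracle <- function(r1, r2, criteria = atomMatchCriteria(), maxAtoms = 16) {
  .checkRcmcsInput(r1); .checkRcmcsInput(r2)
  for (r in list(r1, r2)) {
    nR <- sum(vapply(r@reactants, atomCount, integer(1)))
    nP <- sum(vapply(r@products, atomCount, integer(1)))
    if (max(nR, nP) > maxAtoms)
      stop(sprintf("reaction %s exceeds the oracle size guard (%d atoms/side)",
                   r@id, maxAtoms))
  }
  g1 <- .jointGraph(r1); g2 <- .jointGraph(r2)
  res <- .mcsSearch(g1, g2, criteria, useBound = FALSE, budget = Inf)
  if (!res$rcCompatible) return(0L)
  as.integer(res$size + .spectatorBonus(g1, g2, criteria))
}

# ---- protein similarity -------------------------------------------------

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.checkProteinSeq <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    stop(sprintf("%s: empty sequence", what))
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% .AA_ALPHABET)
  if (length(bad))
    stop(sprintf("%s: non-standard residue '%s' at position %d", what,
                 chars[bad[1]], bad[1]))
}

#' Global sequence identity from a local alignment
#'
#' Aligns the two sequences locally (Smith-Waterman via
#' [Biostrings::pairwiseAlignment()], BLOSUM62, gap open 11 / extend 1) and
#' returns the number of identical aligned positions divided by the length of
#' the longer sequence. Symmetric; 1 for identical sequences; 0 when no
#' positive-scoring local alignment exists.
#'
#' @param seq1,seq2 amino-acid sequences (standard alphabet plus `X`).
#' @return numeric score in `[0, 1]`.
#' @export
gsi <- function(seq1, seq2) {
  .checkProteinSeq(seq1, "seq1"); .checkProteinSeq(seq2, "seq2")
  aln <- Biostrings::pairwiseAlignment(
    seq1, seq2, type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(aln) / max(nchar(seq1), nchar(seq2))
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Vectorized GSI of one sequence against many (shared alignment parameters).
.gsiRow <- function(seq, others) {
  aln <- Biostrings::pairwiseAlignment(
    others, seq, type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(aln) / pmax(nchar(others), nchar(seq))
}

#' Pairwise similarity matrix
#'
#' Computes all pairwise similarities (upper triangle, mirrored). For RCMCS,
#' pairs that exhaust the per-pair search budget fall back to the best
#' correspondence found within the budget and are recorded in the matrix's
#' `flags` slot.
#'
#' @param items for `metric = "rcmcs"`: a list of RC-annotated
#'   [Reaction-class] objects; for `metric = "gsi"`: a named character vector
#'   of amino-acid sequences.
#' @param metric `"rcmcs"` or `"gsi"`.
#' @param criteria RCMCS atom-match criteria.
#' @param budget RCMCS per-pair search-node budget.
#' @return a [SimilarityMatrix-class].
#' @export
pairwiseMatrix <- function(items, metric = c("rcmcs", "gsi"),
                           criteria = atomMatchCriteria(), budget = 2e5) {
  metric <- match.arg(metric)
  if (metric == "rcmcs") {
    if (length(items) < 2) stop("need at least 2 items")
    ids <- vapply(items, reactionId, character(1))
    if (anyDuplicated(ids)) stop("duplicate reaction ids")
    for (r in items) .checkRcmcsInput(r)
    n <- length(items)
    s <- diag(1, n)
    flags <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sc <- rcmcs(items[[i]], items[[j]], criteria, budget)
      if (!attr(sc, "exact"))
        flags[[length(flags) + 1]] <- data.frame(
          id_a = ids[i], id_b = ids[j], stringsAsFactors = FALSE)
      s[i, j] <- s[j, i] <- as.numeric(sc)
    }
    flagDf <- if (length(flags)) do.call(rbind, flags) else
      data.frame(id_a = character(), id_b = character(),
                 stringsAsFactors = FALSE)
    if (nrow(flagDf))
      message(sprintf("bounded-search fallback used for %d pair(s)",
                      nrow(flagDf)))
    new("SimilarityMatrix", ids = ids, scores = s, metric = "rcmcs",
        flags = flagDf)
  } else {
    if (length(items) < 2) stop("need at least 2 items")
    ids <- names(items)
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
      stop("sequences must have unique nonempty names")
    for (i in seq_along(items)) .checkProteinSeq(items[[i]], ids[i])
    n <- length(items)
    s <- diag(1, n)
    for (i in seq_len(n - 1)) {
      vals <- .gsiRow(items[[i]], unname(items[(i + 1):n]))
      s[i, (i + 1):n] <- vals
      s[(i + 1):n, i] <- vals
    }
    new("SimilarityMatrix", ids = ids, scores = s, metric = "gsi")
  }
}

#' Write a similarity matrix as long-format TSV
#'
#' Columns `id_a`, `id_b`, `score`, upper triangle including the diagonal,
#' in id order, so the matrix and its id order are fully recoverable.
#'
#' @param m a [SimilarityMatrix-class].
#' @param path output file.
#' @export
writeSimilarityTsv <- function(m, path) {
  ids <- m@ids; s <- m@scores
  n <- length(ids)
  idx <- which(upper.tri(s, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
                   score = sprintf("%.10g", s[idx]),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# metric=", m@metric), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [writeSimilarityTsv()]
#' @param path input file.
#' @return a [SimilarityMatrix-class].
#' @export
readSimilarityTsv <- function(path) {
  first <- readLines(path, n = 1)
  metric <- sub("^# metric=", "", first)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ids <- unique(c(df$id_a, df$id_b))
  n <- length(ids)
  s <- matrix(0, n, n, dimnames = NULL)
  ia <- match(df$id_a, ids); ib <- match(df$id_b, ids)
  s[cbind(ia, ib)] <- df$score
  s[cbind(ib, ia)] <- df$score
  new("SimilarityMatrix", ids = ids, scores = s, metric = metric)
}
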