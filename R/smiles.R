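# Restricted SMILES reader/writer for heavy-atom molecular graphs.
#
# Supported: organic-subset atoms (B C N O P S F Cl Br I), aromatic lowercase
# (b c n o p s), bracket atoms with isotope (discarded), H count, charge and
# atom-map number, bonds - = # :, branches, ring closures (incl. %nn), and
# disconnected components. Stereo markers (@, @@, /, \) are accepted and
# dropped (recorded in molecule metadata); the modelling pipeline removes
# stereochemistry anyway.

.ORGANIC_TWO <- c("Cl", "Br")
.ORGANIC_ONE <- c("B", "C", "N", "O", "P", "S", "F", "I")
.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

.VALENCES <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                  S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

.ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904,
                  I = 126.904)

.bondOrderValue <- function(order) {
  v <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5)
  unname(v[order])
}

#' Construct a Molecule from atom and bond tables
#'
#' @param atoms data.frame with columns `element`, `aromatic`, `charge`,
#'   `hcount`, `map`.
#' @param bonds data.frame with columns `a1`, `a2`, `order`.
#' @param meta list of metadata.
#' @return a [Molecule-class].
#' @export
newMolecule <- function(atoms, bonds = NULL, meta = list()) {
  if (is.null(bonds) || nrow(bonds) == 0)
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = character(),
                        stringsAsFactors = FALSE)
  atoms$element <- as.character(atoms$element)
  atoms$aromatic <- as.logical(atoms$aromatic)
  atoms$charge <- as.integer(atoms$charge)
  atoms$hcount <- as.integer(atoms$hcount)
  atoms$map <- as.integer(atoms$map)
  bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
  bonds$order <- as.character(bonds$order)
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  new("Molecule", atoms = atoms, bonds = bonds, meta = meta)
}

.parseBracket <- function(content, fragment) {
  i <- 1; n <- nchar(content)
  chars <- strsplit(content, "")[[1]]
  stereo <- FALSE
  # isotope
  while (i <= n && grepl("[0-9]", chars[i])) i <- i + 1
  if (i > n) stop(sprintf("unparseable bracket atom in '%s'", fragment))
  # element (possibly aromatic lowercase)
  aromatic <- FALSE
  if (chars[i] %in% .AROMATIC_ORGANIC &&
      !(i < n && grepl("[a-z]", chars[i + 1]) && chars[i] != "s")) {
    element <- toupper(chars[i]); aromatic <- TRUE; i <- i + 1
  } else if (grepl("[A-Z]", chars[i])) {
    element <- chars[i]; i <- i + 1
    if (i <= n && grepl("[a-z]", chars[i]) && chars[i] != "H" &&
        paste0(element, chars[i]) %in% names(.ATOMIC_MASS)) {
      element <- paste0(element, chars[i]); i <- i + 1
    }
  } else stop(sprintf("unparseable bracket atom in '%s'", fragment))
  hcount <- 0L; charge <- 0L; map <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "@") { stereo <- TRUE; i <- i + 1 }
    else if (ch == "H") {
      i <- i + 1; digits <- ""
      while (i <= n && grepl("[0-9]", chars[i])) { digits <- paste0(digits, chars[i]); i <- i + 1 }
      hcount <- if (nzchar(digits)) as.integer(digits) else 1L
    } else if (ch %in% c("+", "-")) {
      sign <- if (ch == "+") 1L else -1L
      i <- i + 1; reps <- 1L; digits <- ""
      while (i <= n && chars[i] == ch) { reps <- reps + 1L; i <- i + 1 }
      while (i <= n && grepl("[0-9]", chars[i])) { digits <- paste0(digits, chars[i]); i <- i + 1 }
      charge <- sign * (if (nzchar(digits)) as.integer(digits) else reps)
    } else if (ch == ":") {
      i <- i + 1; digits <- ""
      while (i <= n && grepl("[0-9]", chars[i])) { digits <- paste0(digits, chars[i]); i <- i + 1 }
      if (!nzchar(digits)) stop(sprintf("empty atom-map number in '%s'", fragment))
      map <- as.integer(digits)
    } else stop(sprintf("unparseable bracket atom '[%s]' in '%s'", content, fragment))
  }
  list(element = element, aromatic = aromatic, charge = charge,
       hcount = hcount, map = map, stereo = stereo)
}

#' Parse a single-component (or dot-free) molecule SMILES
#'
#' @param text a molecule SMILES string.
#' @return a [Molecule-class]; implicit hydrogens of organic-subset atoms are
#'   resolved to explicit counts via standard default valences.
#' @export
parseSmiles <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text))
    stop("empty molecule SMILES")
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  el <- character(); arom <- logical(); chg <- integer(); hc <- integer()
  mp <- integer(); bracket <- logical()
  b1 <- integer(); b2 <- integer(); bo <- character()
  prev <- NA_integer_; stack <- integer(); pending <- ""
  rings <- list(); stereoSeen <- FALSE
  addAtom <- function(element, aromatic, charge, hcount, map, isBracket) {
    el[length(el) + 1] <<- element; arom[length(arom) + 1] <<- aromatic
    chg[length(chg) + 1] <<- charge; hc[length(hc) + 1] <<- hcount
    mp[length(mp) + 1] <<- map; bracket[length(bracket) + 1] <<- isBracket
    idx <- length(el)
    if (!is.na(prev)) addBond(prev, idx, pending)
    pending <<- ""; prev <<- idx
    idx
  }
  addBond <- function(a, b, sym) {
    order <- switch(sym, "-" = "1", "=" = "2", "#" = "3", ":" = "ar",
                    if (arom[a] && arom[b]) "ar" else "1")
    b1[length(b1) + 1] <<- a; b2[length(b2) + 1] <<- b
    bo[length(bo) + 1] <<- order
  }
  i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":")) { pending <- ch; i <- i + 1 }
    else if (ch %in% c("/", "\\")) { stereoSeen <- TRUE; pending <- "-"; i <- i + 1 }
    else if (ch == "(") {
      if (is.na(prev)) stop(sprintf("branch before any atom in '%s'", text))
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (!length(stack)) stop(sprintf("unbalanced ')' in '%s'", text))
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1
    } else if (ch == "[") {
      close <- i + 1
      while (close <= n && chars[close] != "]") close <- close + 1
      if (close > n) stop(sprintf("unclosed bracket in '%s'", text))
      info <- .parseBracket(paste(chars[(i + 1):(close - 1)], collapse = ""), text)
      if (info$stereo) stereoSeen <- TRUE
      addAtom(info$element, info$aromatic, info$charge, info$hcount,
              info$map, TRUE)
      i <- close + 1
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (is.na(prev)) stop(sprintf("ring closure before any atom in '%s'", text))
      if (ch == "%") {
        if (i + 2 > n) stop(sprintf("truncated %% ring closure in '%s'", text))
        num <- paste(chars[(i + 1):(i + 2)], collapse = ""); i <- i + 3
      } else { num <- ch; i <- i + 1 }
      key <- as.character(as.integer(num))
      if (!is.null(rings[[key]])) {
        open <- rings[[key]]
        sym <- if (nzchar(pending)) pending else open$sym
        if (nzchar(open$sym) && nzchar(pending) && open$sym != pending)
          stop(sprintf("conflicting ring-bond symbols for closure %s in '%s'",
                       key, text))
        addBond(open$atom, prev, sym)
        rings[[key]] <- NULL; pending <- ""
      } else {
        rings[[key]] <- list(atom = prev, sym = pending); pending <- ""
      }
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% .ORGANIC_TWO) {
        addAtom(two, FALSE, 0L, NA_integer_, 0L, FALSE); i <- i + 2
      } else if (ch %in% .ORGANIC_ONE) {
        addAtom(ch, FALSE, 0L, NA_integer_, 0L, FALSE); i <- i + 1
      } else if (ch %in% .AROMATIC_ORGANIC) {
        addAtom(toupper(ch), TRUE, 0L, NA_integer_, 0L, FALSE); i <- i + 1
      } else {
        stop(sprintf("unparseable character '%s' at position %d of '%s'",
                     ch, i, text))
      }
    }
  }
  if (length(stack)) stop(sprintf("unbalanced '(' in '%s'", text))
  if (length(rings)) stop(sprintf("unclosed ring bond in '%s'", text))
  if (!length(el)) stop(sprintf("no atoms in '%s'", text))
  atoms <- data.frame(element = el, aromatic = arom, charge = chg, hcount = hc,
                      map = mp, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = b1, a2 = b2, order = bo, stringsAsFactors = FALSE)
  if (anyDuplicated(pmin(bonds$a1, bonds$a2) * 1e6 + pmax(bonds$a1, bonds$a2)))
    stop(sprintf("duplicate bond in '%s'", text))
  # resolve implicit hydrogens of organic-subset atoms
  for (a in which(is.na(atoms$hcount))) {
    nb <- which(bonds$a1 == a | bonds$a2 == a)
    orders <- bonds$order[nb]
    if (atoms$aromatic[a]) {
      sigma <- length(nb)
      v <- .VALENCES[[atoms$element[a]]][1]
      atoms$hcount[a] <- max(0L, as.integer(v - sigma - 1L))
    } else {
      bsum <- sum(.bondOrderValue(orders))
      vs <- .VALENCES[[atoms$element[a]]]
      v <- vs[vs >= bsum][1]
      atoms$hcount[a] <- if (is.na(v)) 0L else as.integer(v - bsum)
    }
  }
  newMolecule(atoms, bonds, meta = list(stereoStripped = stereoSeen))
}

# ---- derived atom/bond properties --------------------------------------

#' Heavy-atom degrees
#' @param mol a [Molecule-class].
#' @return integer vector.
#' @export
atomDegrees <- function(mol) {
  d <- integer(nrow(mol@atoms))
  b <- mol@bonds
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    d[b$a1[k]] <- d[b$a1[k]] + 1L
    d[b$a2[k]] <- d[b$a2[k]] + 1L
  }
  d
}

.adjacency <- function(mol) {
  adj <- vector("list", nrow(mol@atoms))
  b <- mol@bonds
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  adj
}

#' Ring membership of each bond
#' @param mol a [Molecule-class].
#' @return logical vector over bonds: in a cycle or not.
#' @export
bondInRing <- function(mol) {
  b <- mol@bonds
  out <- logical(nrow(b))
  if (!nrow(b)) return(out)
  for (k in seq_len(nrow(b))) {
    # bond is in a ring iff endpoints stay connected without it
    src <- b$a1[k]; dst <- b$a2[k]
    seen <- src; frontier <- src
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        nb <- which((b$a1 == v | b$a2 == v) & seq_len(nrow(b)) != k)
        ns <- ifelse(b$a1[nb] == v, b$a2[nb], b$a1[nb])
        nxt <- c(nxt, setdiff(ns, seen))
      }
      nxt <- unique(nxt)
      if (dst %in% nxt) { out[k] <- TRUE; break }
      seen <- c(seen, nxt); frontier <- nxt
    }
  }
  out
}

#' Conjugation flag of each bond
#'
#' A bond counts as conjugated when it is aromatic or when both of its atoms
#' are pi centers (carry at least one double, triple or aromatic bond).
#' @param mol a [Molecule-class].
#' @return logical vector over bonds.
#' @export
bondConjugated <- function(mol) {
  b <- mol@bonds
  if (!nrow(b)) return(logical(0))
  pi <- logical(nrow(mol@atoms))
  for (k in seq_len(nrow(b))) if (b$order[k] %in% c("2", "3", "ar")) {
    pi[b$a1[k]] <- TRUE; pi[b$a2[k]] <- TRUE
  }
  b$order == "ar" | (pi[b$a1] & pi[b$a2])
}

#' Simple hybridization assignment
#'
#' `sp` for atoms with a triple bond or two double bonds, `sp2` for atoms with
#' a double or aromatic bond, else `sp3`.
#' @param mol a [Molecule-class].
#' @return character vector over atoms.
#' @export
atomHybridization <- function(mol) {
  b <- mol@bonds
  nd <- integer(nrow(mol@atoms)); nt <- integer(nrow(mol@atoms))
  na_ <- integer(nrow(mol@atoms))
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    for (a in c(b$a1[k], b$a2[k])) {
      if (b$order[k] == "2") nd[a] <- nd[a] + 1L
      if (b$order[k] == "3") nt[a] <- nt[a] + 1L
      if (b$order[k] == "ar") na_[a] <- na_[a] + 1L
    }
  }
  ifelse(nt > 0 | nd >= 2, "sp",
         ifelse(nd > 0 | na_ > 0, "sp2", "sp3"))
}

.components <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- .adjacency(mol)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s; comp[s] <- cur
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur; nxt <- c(nxt, w)
      }
      frontier <- nxt
    }
  }
  comp
}

# ---- canonicalization ---------------------------------------------------

.initialRanks <- function(mol) {
  b <- mol@bonds
  codes <- vapply(seq_len(nrow(mol@atoms)), function(a) {
    nb <- which(b$a1 == a | b$a2 == a)
    paste(sort(b$order[nb]), collapse = "")
  }, character(1))
  key <- paste(mol@atoms$element, mol@atoms$aromatic, mol@atoms$charge,
               mol@atoms$hcount, atomDegrees(mol), codes, sep = "|")
  match(key, sort(unique(key)))
}

.refineRanks <- function(mol, ranks) {
  b <- mol@bonds
  adj <- vector("list", length(ranks))
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- rbind(adj[[b$a1[k]]], c(b$order[k], b$a2[k]))
    adj[[b$a2[k]]] <- rbind(adj[[b$a2[k]]], c(b$order[k], b$a1[k]))
  }
  repeat {
    key <- vapply(seq_along(ranks), function(a) {
      nb <- adj[[a]]
      nbkey <- if (is.null(nb)) "" else
        paste(sort(paste0(nb[, 1], ":", sprintf("%08.1f", ranks[as.integer(nb[, 2])]))),
              collapse = ",")
      paste0(sprintf("%08.1f", ranks[a]), "|", nbkey)
    }, character(1))
    newRanks <- match(key, sort(unique(key)))
    if (length(unique(newRanks)) == length(unique(ranks))) return(newRanks)
    ranks <- newRanks
  }
}

.emitComponent <- function(mol, nodes, ranks, withMaps) {
  b <- mol@bonds
  adj <- vector("list", nrow(mol@atoms))
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- rbind(adj[[b$a1[k]]], c(b$a2[k], k))
    adj[[b$a2[k]]] <- rbind(adj[[b$a2[k]]], c(b$a1[k], k))
  }
  root <- nodes[which.min(ranks[nodes])]
  visited <- logical(nrow(mol@atoms))
  usedEdge <- logical(nrow(b))
  ringAt <- vector("list", nrow(mol@atoms))
  ringCounter <- 0L
  treeChildren <- vector("list", nrow(mol@atoms))
  # iterative DFS to classify edges and allocate ring-closure numbers
  dfs <- function(v) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    ord <- order(ranks[as.integer(nb[, 1])], as.integer(nb[, 1]))
    for (j in ord) {
      w <- as.integer(nb[j, 1]); k <- as.integer(nb[j, 2])
      if (usedEdge[k]) next
      if (!visited[w]) {
        usedEdge[k] <<- TRUE
        treeChildren[[v]] <<- rbind(treeChildren[[v]], c(w, k))
        dfs(w)
      } else {
        usedEdge[k] <<- TRUE
        ringCounter <<- ringCounter + 1L
        ringAt[[v]] <<- rbind(ringAt[[v]], c(ringCounter, k, 1L))
        ringAt[[w]] <<- rbind(ringAt[[w]], c(ringCounter, k, 0L))
      }
    }
  }
  dfs(root)
  atomToken <- function(a) {
    at <- mol@atoms[a, ]
    sym <- if (at$aromatic) tolower(at$element) else at$element
    h <- if (at$hcount == 0) "" else if (at$hcount == 1) "H" else
      paste0("H", at$hcount)
    ch <- if (at$charge == 0) "" else if (at$charge == 1) "+" else
      if (at$charge == -1) "-" else if (at$charge > 0)
        paste0("+", at$charge) else paste0("-", abs(at$charge))
    mapstr <- if (withMaps && at$map > 0) paste0(":", at$map) else ""
    paste0("[", sym, h, ch, mapstr, "]")
  }
  bondSym <- function(k) {
    o <- b$order[k]; a1 <- b$a1[k]; a2 <- b$a2[k]
    bothAr <- mol@atoms$aromatic[a1] && mol@atoms$aromatic[a2]
    switch(o,
      "1" = if (bothAr) "-" else "",
      "2" = "=", "3" = "#",
      "ar" = if (bothAr) "" else ":")
  }
  ringToken <- function(num) if (num < 10) as.character(num) else
    sprintf("%%%02d", num)
  build <- function(v) {
    out <- atomToken(v)
    ra <- ringAt[[v]]
    if (!is.null(ra)) {
      ra <- ra[order(ra[, 1]), , drop = FALSE]
      for (j in seq_len(nrow(ra))) {
        sym <- if (ra[j, 3] == 1L) bondSym(ra[j, 2]) else ""
        out <- paste0(out, sym, ringToken(ra[j, 1]))
      }
    }
    ch <- treeChildren[[v]]
    if (!is.null(ch)) {
      m <- nrow(ch)
      for (j in seq_len(m)) {
        sub <- paste0(bondSym(ch[j, 2]), build(ch[j, 1]))
        out <- paste0(out, if (j < m) paste0("(", sub, ")") else sub)
      }
    }
    out
  }
  build(root)
}

.canonicalEmit <- function(mol, ranks, withMaps) {
  comp <- .components(mol)
  parts <- vapply(sort(unique(comp)), function(ci)
    .emitComponent(mol, which(comp == ci), ranks, withMaps), character(1))
  paste(sort(parts), collapse = ".")
}

.canonicalResolve <- function(mol, ranks, withMaps, depth = 0) {
  tab <- table(ranks)
  tied <- as.numeric(names(tab)[tab > 1])
  if (!length(tied) || depth > 24)
    return(.canonicalEmit(mol, ranks, withMaps))
  cls <- min(tied)
  members <- which(ranks == cls)
  best <- NULL
  for (a in members) {
    r2 <- ranks; r2[a] <- r2[a] - 0.5
    r2 <- .refineRanks(mol, r2)
    s <- .canonicalResolve(mol, r2, withMaps, depth + 1)
    if (is.null(best) || s < best) best <- s
  }
  best
}

#' Canonical SMILES of a molecule
#'
#' Canonicalization uses iterative invariant refinement with full
#' individualization branching, so isomorphic graphs always serialize to the
#' same string. All atoms are written in bracket form with explicit hydrogen
#' counts, making `parseSmiles(writeSmiles(m))` an exact graph round trip.
#'
#' @param mol a [Molecule-class].
#' @param withMaps write atom-map numbers (default `FALSE`).
#' @return a SMILES string.
#' @export
writeSmiles <- function(mol, withMaps = FALSE) {
  if (nrow(mol@atoms) == 0) stop("cannot serialize an empty molecule")
  ranks <- .refineRanks(mol, .initialRanks(mol))
  .canonicalResolve(mol, ranks, withMaps)
}
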