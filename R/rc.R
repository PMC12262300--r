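# Reaction-center derivation: from atom maps and from operator templates.

# Diff a fully mapped reaction: changed bonds, hydrogen-count deltas and the
# map numbers of atoms whose environment changes.
.mapDiff <- function(r) {
  ra <- sideAtoms(r, "reactant"); pa <- sideAtoms(r, "product")
  if (any(ra$map == 0) || any(pa$map == 0) || !setequal(ra$map, pa$map))
    stop(sprintf("reaction %s: atom map is not total", r@id))
  bondsByMap <- function(side, at) {
    b <- sideBonds(r, side)
    if (!nrow(b)) return(stats::setNames(character(0), character(0)))
    m1 <- at$map[b$a1]; m2 <- at$map[b$a2]
    key <- paste(pmin(m1, m2), pmax(m1, m2), sep = "-")
    stats::setNames(b$order, key)
  }
  rb <- bondsByMap("reactant", ra); pb <- bondsByMap("product", pa)
  keys <- union(names(rb), names(pb))
  before <- ifelse(keys %in% names(rb), rb[keys], "0")
  after <- ifelse(keys %in% names(pb), pb[keys], "0")
  changed <- before != after
  bc <- data.frame(
    map1 = as.integer(sub("-.*", "", keys[changed])),
    map2 = as.integer(sub(".*-", "", keys[changed])),
    before = unname(before[changed]), after = unname(after[changed]),
    stringsAsFactors = FALSE)
  hr <- stats::setNames(ra$hcount, ra$map)
  hp <- stats::setNames(pa$hcount, pa$map)
  maps <- ra$map
  delta <- hp[as.character(maps)] - hr[as.character(maps)]
  hd <- data.frame(map = maps[delta != 0], delta = unname(delta[delta != 0]))
  rcMaps <- sort(unique(c(bc$map1, bc$map2, hd$map)))
  list(bondChanges = bc, hDeltas = hd, rcMaps = as.integer(rcMaps))
}

#' Derive the reaction center from a total atom map
#'
#' The RC is the set of atoms incident to a bond that is formed, broken or
#' changes order between the two sides, plus atoms whose hydrogen count
#' changes (so hydrogenations and redox steps with implicit hydrogens have a
#' nonempty RC; hydrogens themselves are implicit and never RC atoms). The
#' two sides' RC sets correspond under the atom map.
#'
#' @param r a fully atom-mapped [Reaction-class].
#' @return the reaction with `rcReactants`/`rcProducts` filled. An identity
#'   reaction (no change anywhere) yields empty RC sets and signals a warning
#'   of class `rcnet_empty_rc`.
#' @export
deriveRcFromMap <- function(r) {
  d <- .mapDiff(r)
  ra <- sideAtoms(r, "reactant"); pa <- sideAtoms(r, "product")
  r@rcReactants <- sort(ra$global[ra$map %in% d$rcMaps])
  r@rcProducts <- sort(pa$global[pa$map %in% d$rcMaps])
  if (!length(d$rcMaps))
    warning(warningCondition(
      sprintf("reaction %s is an identity reaction (empty RC)", r@id),
      class = "rcnet_empty_rc"))
  r
}

# Induced sub-molecules of one side restricted to a global atom index set,
# split into connected components.
.inducedSideMolecules <- function(r, side, keep) {
  at <- sideAtoms(r, side)
  mols <- if (side == "reactant") r@reactants else r@products
  out <- list()
  for (mi in seq_along(mols)) {
    sel <- at$local[at$mol == mi & at$global %in% keep]
    if (!length(sel)) next
    mol <- mols[[mi]]
    amap <- match(seq_len(nrow(mol@atoms)), sel)  # old -> new index
    sub <- newMolecule(
      mol@atoms[sel, , drop = FALSE],
      {
        b <- mol@bonds
        b <- b[b$a1 %in% sel & b$a2 %in% sel, , drop = FALSE]
        if (nrow(b)) { b$a1 <- amap[b$a1]; b$a2 <- amap[b$a2] }
        b
      })
    comp <- .components(sub)
    for (ci in sort(unique(comp))) {
      csel <- which(comp == ci)
      cmap <- match(seq_len(nrow(sub@atoms)), csel)
      cb <- sub@bonds[sub@bonds$a1 %in% csel & sub@bonds$a2 %in% csel, ,
                      drop = FALSE]
      if (nrow(cb)) { cb$a1 <- cmap[cb$a1]; cb$a2 <- cmap[cb$a2] }
      out[[length(out) + 1]] <- newMolecule(sub@atoms[csel, , drop = FALSE], cb)
    }
  }
  out
}

#' Extract the reaction center as a reaction of its own
#'
#' Returns the induced subgraph reaction on RC atoms: reactant-side RC
#' fragments on the left, product-side RC fragments on the right, with atom
#' attributes (including hydrogen counts) and the restricted atom map
#' preserved. Every atom of the returned reaction is in its RC.
#'
#' @param r a [Reaction-class] with nonempty RC sets.
#' @return a [Reaction-class].
#' @export
rcAsReaction <- function(r) {
  if (!length(r@rcReactants) || !length(r@rcProducts))
    stop(sprintf("reaction %s has an empty RC", r@id))
  ra <- sideAtoms(r, "reactant"); pa <- sideAtoms(r, "product")
  mr <- ra$map[ra$global %in% r@rcReactants]
  mp <- pa$map[pa$global %in% r@rcProducts]
  if (any(mr > 0) && any(mp > 0) && !setequal(mr[mr > 0], mp[mp > 0]))
    stop(sprintf("reaction %s: RC sets do not correspond under the atom map",
                 r@id))
  core <- new("Reaction",
              id = paste0(r@id, ":rc"),
              reactants = .inducedSideMolecules(r, "reactant", r@rcReactants),
              products = .inducedSideMolecules(r, "product", r@rcProducts))
  nR <- sum(vapply(core@reactants, atomCount, integer(1)))
  nP <- sum(vapply(core@products, atomCount, integer(1)))
  core@rcReactants <- seq_len(nR)
  core@rcProducts <- seq_len(nP)
  validObject(core)
  core
}

# ---- operator templates -------------------------------------------------

#' Build an operator template from a mapped core reaction
#'
#' @param text atom-mapped reaction SMILES of the core.
#' @param name operator name.
#' @return an [OperatorTemplate-class]; the bond-change list, hydrogen deltas
#'   and RC map numbers are derived from the template's own map diff.
#' @export
parseOperator <- function(text, name = "operator") {
  core <- parseReaction(text, id = name)
  d <- .mapDiff(core)
  if (!length(d$rcMaps))
    stop(sprintf("operator '%s' changes nothing", name))
  op <- new("OperatorTemplate", name = name, core = core,
            bondChanges = d$bondChanges, hDeltas = d$hDeltas,
            rcMaps = d$rcMaps)
  validObject(op)
  op
}

#' Read an operator file
#'
#' One template per line: an atom-mapped reaction SMILES optionally followed
#' by a tab and a name. Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return list of [OperatorTemplate-class] objects.
#' @export
readOperators <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    nm <- if (length(fields) >= 2) fields[2] else sprintf("op%d", i)
    parseOperator(fields[1], name = nm)
  })
}

# Subgraph matching of a pattern (multi-component molecule set) into a target
# side graph. Atoms match on element, aromatic flag and charge; every pattern
# bond must be present in the target with the same order; target atoms may
# carry extra bonds and differing hydrogen counts (substitution is free).
# Returns a list of integer vectors: image[patternAtom] = target global index.
.matchPattern <- function(patAtoms, patBonds, tgtAtoms, tgtBonds) {
  nP <- nrow(patAtoms); nT <- nrow(tgtAtoms)
  if (nP == 0 || nP > nT) return(list())
  tAdj <- vector("list", nT)
  if (nrow(tgtBonds)) for (k in seq_len(nrow(tgtBonds))) {
    tAdj[[tgtBonds$a1[k]]] <- rbind(tAdj[[tgtBonds$a1[k]]],
                                    c(tgtBonds$a2[k], k))
    tAdj[[tgtBonds$a2[k]]] <- rbind(tAdj[[tgtBonds$a2[k]]],
                                    c(tgtBonds$a1[k], k))
  }
  tgtBondOrder <- function(a, b) {
    nb <- tAdj[[a]]
    if (is.null(nb)) return(NA_character_)
    hit <- which(nb[, 1] == b)
    if (!length(hit)) return(NA_character_)
    tgtBonds$order[nb[hit[1], 2]]
  }
  pAdj <- vector("list", nP)
  if (nrow(patBonds)) for (k in seq_len(nrow(patBonds))) {
    pAdj[[patBonds$a1[k]]] <- rbind(pAdj[[patBonds$a1[k]]],
                                    c(patBonds$a2[k], k))
    pAdj[[patBonds$a2[k]]] <- rbind(pAdj[[patBonds$a2[k]]],
                                    c(patBonds$a1[k], k))
  }
  compatible <- function(p, t) {
    patAtoms$element[p] == tgtAtoms$element[t] &&
      patAtoms$aromatic[p] == tgtAtoms$aromatic[t] &&
      patAtoms$charge[p] == tgtAtoms$charge[t]
  }
  # order pattern atoms so each (after the first of its component) touches an
  # already-placed atom where possible
  orderAtoms <- function() {
    placed <- logical(nP); ord <- integer(0)
    while (length(ord) < nP) {
      cand <- which(!placed & vapply(seq_len(nP), function(p) {
        nb <- pAdj[[p]]
        !is.null(nb) && any(placed[nb[, 1]])
      }, logical(1)))
      nxt <- if (length(cand)) cand[1] else which(!placed)[1]
      placed[nxt] <- TRUE; ord <- c(ord, nxt)
    }
    ord
  }
  ord <- orderAtoms()
  matches <- list()
  image <- integer(nP)
  used <- logical(nT)
  recurse <- function(step) {
    if (step > nP) {
      matches[[length(matches) + 1]] <<- image
      return(invisible())
    }
    p <- ord[step]
    nb <- pAdj[[p]]
    anchored <- !is.null(nb) && any(image[nb[, 1]] > 0)
    candidates <- if (anchored) {
      placedNb <- nb[image[nb[, 1]] > 0, , drop = FALSE]
      a0 <- image[placedNb[1, 1]]
      tnb <- tAdj[[a0]]
      if (is.null(tnb)) integer(0) else tnb[, 1]
    } else seq_len(nT)
    for (t in candidates) {
      if (used[t] || !compatible(p, t)) next
      ok <- TRUE
      if (!is.null(nb)) for (j in seq_len(nrow(nb))) {
        q <- nb[j, 1]
        if (image[q] > 0) {
          to <- tgtBondOrder(t, image[q])
          if (is.na(to) || to != patBonds$order[nb[j, 2]]) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      image[p] <<- t; used[t] <<- TRUE
      recurse(step + 1)
      image[p] <<- 0L; used[t] <<- FALSE
    }
  }
  recurse(1)
  matches
}

# Apply an operator's bond changes / H deltas at a concrete match of its
# reactant pattern in the reactant union graph; returns the resulting product
# molecules or NULL when the edit is invalid (e.g. negative hydrogen count).
.applyOperatorAt <- function(r, op, image, patAtoms) {
  at <- sideAtoms(r, "reactant")
  b <- sideBonds(r, "reactant")
  mapToTarget <- function(m) image[which(patAtoms$map == m)[1]]
  bc <- op@bondChanges
  for (k in seq_len(nrow(bc))) {
    t1 <- mapToTarget(bc$map1[k]); t2 <- mapToTarget(bc$map2[k])
    hit <- which((b$a1 == t1 & b$a2 == t2) | (b$a1 == t2 & b$a2 == t1))
    if (bc$before[k] == "0") {
      if (length(hit)) return(NULL)
      b <- rbind(b, data.frame(a1 = t1, a2 = t2, order = bc$after[k],
                               stringsAsFactors = FALSE))
    } else {
      if (!length(hit) || b$order[hit[1]] != bc$before[k]) return(NULL)
      if (bc$after[k] == "0") b <- b[-hit[1], , drop = FALSE]
      else b$order[hit[1]] <- bc$after[k]
    }
  }
  hd <- op@hDeltas
  hc <- at$hcount
  for (k in seq_len(nrow(hd))) {
    t1 <- mapToTarget(hd$map[k])
    hc[t1] <- hc[t1] + hd$delta[k]
    if (hc[t1] < 0) return(NULL)
  }
  atoms <- data.frame(element = at$element, aromatic = at$aromatic,
                      charge = at$charge, hcount = hc, map = at$map,
                      stringsAsFactors = FALSE)
  whole <- newMolecule(atoms, b)
  comp <- .components(whole)
  lapply(sort(unique(comp)), function(ci) {
    sel <- which(comp == ci)
    cmap <- match(seq_len(nrow(atoms)), sel)
    cb <- whole@bonds[whole@bonds$a1 %in% sel & whole@bonds$a2 %in% sel, ,
                      drop = FALSE]
    if (nrow(cb)) { cb$a1 <- cmap[cb$a1]; cb$a2 <- cmap[cb$a2] }
    newMolecule(atoms[sel, , drop = FALSE], cb)
  })
}

#' Assign reaction centers by applying an operator template
#'
#' Every match of the operator's reactant-side pattern in the reaction's
#' reactants is tried in turn (equivalent to protecting all other matches):
#' the operator's bond changes and hydrogen deltas are applied at the match
#' and the generated products are compared with the actual products up to
#' canonical-form equality. Each match that reproduces the products yields one
#' RC assignment: the reactant atoms matched by the template atoms whose
#' environment the template changes.
#'
#' @param r a standardized [Reaction-class].
#' @param op an [OperatorTemplate-class].
#' @return list of RC assignments (sorted integer vectors of global
#'   reactant-atom indices), ordered by match atom indices; empty when no
#'   match reproduces the products.
#' @export
assignRcViaOperator <- function(r, op) {
  patAtoms <- sideAtoms(op@core, "reactant")
  patBonds <- sideBonds(op@core, "reactant")
  tgtAtoms <- sideAtoms(r, "reactant")
  tgtBonds <- sideBonds(r, "reactant")
  matches <- .matchPattern(patAtoms, patBonds, tgtAtoms, tgtBonds)
  assignments <- list()
  for (image in matches) {
    prods <- .applyOperatorAt(r, op, image, patAtoms)
    if (is.null(prods)) next
    if (!.sameMoleculeMultiset(prods, r@products)) next
    rcIdx <- sort(image[patAtoms$map %in% op@rcMaps])
    assignments[[length(assignments) + 1]] <- rcIdx
  }
  if (!length(assignments)) return(list())
  keys <- vapply(assignments, function(x) paste(x, collapse = ","), character(1))
  assignments <- assignments[!duplicated(keys)]
  ordKeys <- vapply(assignments, function(x)
    paste(sprintf("%06d", x), collapse = ","), character(1))
  assignments[order(ordKeys)]
}
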