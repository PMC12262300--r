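# Reaction standardization and curation filtering.

#' Default standardization rule set
#'
#' Condition-dependent charges are neutralized according to an explicit rule
#' table: oxy- and thio-anions with a single heavy-atom neighbourhood slot
#' free (carboxylate, phosphate, thiolate oxygens/sulfurs) are protonated, and
#' protonated amines are deprotonated. Permanently charged centers (e.g.
#' quaternary nitrogen with no hydrogens) are left untouched.
#'
#' @param protonateOxyanions protonate O-/S- with charge -1.
#' @param deprotonateAmmonium remove one proton from N+ carrying hydrogens.
#' @return a named list of rule flags.
#' @export
standardizeRules <- function(protonateOxyanions = TRUE,
                             deprotonateAmmonium = TRUE) {
  list(protonateOxyanions = protonateOxyanions,
       deprotonateAmmonium = deprotonateAmmonium)
}

.maxValence <- function(element) {
  v <- .VALENCES[[element]]
  if (is.null(v)) 8 else max(v)
}

.standardizeMolecule <- function(mol, rules, where) {
  report <- list()
  note <- function(transform, atom)
    report[[length(report) + 1]] <<- data.frame(
      transform = transform, where = where, atom = atom,
      stringsAsFactors = FALSE)
  if (isTRUE(mol@meta$stereoStripped)) {
    note("stereo_removed", NA_integer_)
    mol@meta$stereoStripped <- FALSE
  }
  a <- mol@atoms
  b <- mol@bonds
  bsum <- function(i) {
    nb <- which(b$a1 == i | b$a2 == i)
    sum(.bondOrderValue(b$order[nb]))
  }
  for (i in seq_len(nrow(a))) {
    if (isTRUE(rules$protonateOxyanions) && a$charge[i] == -1 &&
        a$element[i] %in% c("O", "S")) {
      newval <- bsum(i) + a$hcount[i] + 1
      if (newval > .maxValence(a$element[i]))
        stop(sprintf("protonating atom %d (%s) would exceed its valence",
                     i, a$element[i]))
      a$charge[i] <- 0L; a$hcount[i] <- a$hcount[i] + 1L
      note("protonate_anion", i)
    } else if (isTRUE(rules$deprotonateAmmonium) && a$charge[i] == 1 &&
               a$element[i] == "N" && a$hcount[i] >= 1) {
      a$charge[i] <- 0L; a$hcount[i] <- a$hcount[i] - 1L
      note("deprotonate_ammonium", i)
    }
  }
  mol@atoms <- a
  list(mol = mol,
       report = if (length(report)) do.call(rbind, report) else NULL)
}

#' Standardize a reaction
#'
#' Drops stereochemistry (already removed at parse time; reported here),
#' neutralizes condition-dependent charges per the rule table and
#' re-canonicalizes every molecule. The operation is idempotent.
#'
#' @param r a [Reaction-class].
#' @param rules rule flags from [standardizeRules()].
#' @return a list with elements `reaction` (the standardized
#'   [Reaction-class]) and `report` (data.frame of fired transforms with
#'   columns `transform`, `where`, `atom`; zero rows when the input was
#'   already standard).
#' @export
standardizeReaction <- function(r, rules = standardizeRules()) {
  reports <- list()
  doSide <- function(mols, sideName) {
    lapply(seq_along(mols), function(i) {
      res <- .standardizeMolecule(mols[[i]], rules,
                                  sprintf("%s:%d", sideName, i))
      if (!is.null(res$report)) reports[[length(reports) + 1]] <<- res$report
      res$mol
    })
  }
  newReactants <- doSide(r@reactants, "reactant")
  newProducts <- doSide(r@products, "product")
  out <- new("Reaction", id = r@id, reactants = newReactants,
             products = newProducts, rcReactants = r@rcReactants,
             rcProducts = r@rcProducts)
  validObject(out)
  report <- if (length(reports)) do.call(rbind, reports) else
    data.frame(transform = character(), where = character(),
               atom = integer(), stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(reaction = out, report = report)
}

.EVIDENCE_LEVELS <- c("experimental", "inferred-from-homology", "predicted",
                      "uncertain")

#' Filter curation records
#'
#' Retains records with experimental evidence that are neither transport
#' reactions nor subunits of multi-unit complexes. Each rejected record is
#' tallied under the first matching rule in the fixed order
#' transport, then subunit, then evidence.
#'
#' @param records data.frame with columns `protein_id`, `reaction_id`,
#'   `evidence`, `is_subunit`, `is_transport`.
#' @return list with `retained` (data.frame) and `tally` (named integer
#'   vector with entries `transport`, `subunit`, `evidence`).
#' @export
filterCuration <- function(records) {
  need <- c("protein_id", "reaction_id", "evidence", "is_subunit",
            "is_transport")
  if (!all(need %in% names(records)))
    stop("curation records must have columns ",
         paste(need, collapse = ", "))
  if (nrow(records) && !all(records$evidence %in% .EVIDENCE_LEVELS))
    stop("evidence must be one of: ", paste(.EVIDENCE_LEVELS, collapse = ", "))
  tally <- c(transport = 0L, subunit = 0L, evidence = 0L)
  if (!nrow(records))
    return(list(retained = records, tally = tally))
  isTransport <- as.logical(records$is_transport)
  isSubunit <- as.logical(records$is_subunit)
  badEvidence <- records$evidence != "experimental"
  rule <- ifelse(isTransport, "transport",
                 ifelse(isSubunit, "subunit",
                        ifelse(badEvidence, "evidence", "keep")))
  tally["transport"] <- sum(rule == "transport")
  tally["subunit"] <- sum(rule == "subunit")
  tally["evidence"] <- sum(rule == "evidence")
  retained <- records[rule == "keep", , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, tally = tally)
}
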