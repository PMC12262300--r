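# Parsing, standardization, curation filtering and RC derivation.

test_that("reaction SMILES parsing extracts molecules, maps and agents", {
  r <- parseReaction(
    "[CH3:1][C:2](=[O:3])[C:4](=[O:5])[OH:6]>>[CH3:1][CH:2]([OH:3])[C:4](=[O:5])[OH:6]",
    id = "pyr")
  expect_length(reactants(r), 1)
  expect_length(products(r), 1)
  ra <- sideAtoms(r, "reactant"); pa <- sideAtoms(r, "product")
  expect_equal(sum(ra$map > 0), 6)
  expect_equal(sum(pa$map > 0), 6)
  expect_length(rcAtoms(r), 0)  # RC starts empty

  minimal <- parseReaction("C>>C", id = "min")
  expect_equal(reactionAtomCount(minimal), 2)
  expect_equal(sum(sideAtoms(minimal, "reactant")$map), 0)

  # hand enumeration: methyl acetate C3H6O2 has 5 heavy atoms, water 1;
  # acetic acid 4, methanol 2 — heavy atoms balance 6 = 6
  hyd <- parseReaction("CC(=O)OC.O>>CC(=O)O.CO", id = "hyd")
  expect_equal(vapply(reactants(hyd), atomCount, integer(1)), c(5L, 1L))
  expect_equal(vapply(products(hyd), atomCount, integer(1)), c(4L, 2L))

  expect_warning(parseReaction("C>O>C", id = "ag"), "discarded")
  expect_error(parseReaction("C(Q)>>C", id = "bad"), "fragment")
  expect_error(parseReaction("[CH3:1][CH3:1]>>[CH3:1][CH3:2]", id = "dup"),
               "duplicate")
})

test_that("parse/serialize round trip preserves the molecular graph", {
  cases <- c("CC(=O)OC", "c1ccccc1", "Cc1ccc(O)cc1", "C1CC1CO",
             "O=C(O)CCN", "[NH4+]", "CC(C)(C)S", "C#N", "OCC(O)C(O)CO")
  for (s in cases) {
    m <- parseSmiles(s)
    m2 <- parseSmiles(writeSmiles(m))
    expect_identical(writeSmiles(m2), writeSmiles(m), label = s)
    expect_equal(atomCount(m2), atomCount(m))
  }
  # graph-isomorphism oracle (igraph VF2) on permuted writings
  a <- parseSmiles("CC(N)C(=O)O")
  b <- parseSmiles(writeSmiles(a))
  # colors must come from one shared level set so vf2 compares categories
  levs <- sort(unique(c(paste(a@atoms$element, a@atoms$hcount),
                        paste(b@atoms$element, b@atoms$hcount))))
  toIgraph <- function(m) {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = m@bonds$a1, to = m@bonds$a2),
      directed = FALSE,
      vertices = data.frame(name = seq_len(atomCount(m))))
    igraph::V(g)$color <- match(paste(m@atoms$element, m@atoms$hcount), levs)
    g
  }
  expect_true(igraph::isomorphic(toIgraph(a), toIgraph(b),
                                 method = "vf2"))
})

test_that("canonical form is invariant to input atom ordering", {
  variants <- c("OC(=O)C(N)C", "CC(N)C(O)=O", "NC(C)C(=O)O")
  canon <- vapply(variants, function(s) writeSmiles(parseSmiles(s)),
                  character(1))
  expect_length(unique(canon), 1)
  # third-party readability: openbabel maps all variants (and our canonical
  # form) to one canonical SMILES of its own
  ob <- vapply(c(variants, canon[1]), function(s)
    system2("obabel", c(paste0("-:", shQuote(s)), "-ocan"),
            stdout = TRUE, stderr = FALSE)[1], character(1))
  expect_length(unique(trimws(ob)), 1)
})

test_that("round trip holds across many random synthetic reactions", {
  rx <- smallSyntheticReactions(n = 24, seed = 101)
  for (r in rx) {
    s <- writeReactionSmiles(r, withMaps = TRUE)
    r2 <- parseReaction(s, id = reactionId(r))
    expect_identical(writeReactionSmiles(r2), writeReactionSmiles(r))
    # heavy-element conservation for fully mapped standardized reactions
    # (hydrogen totals shift in the redox templates, whose cofactor pool is
    # not part of the represented system)
    expect_identical(elementCounts(r, "reactant", includeH = FALSE),
                     elementCounts(r, "product", includeH = FALSE))
  }
})

test_that("standardization drops stereo, neutralizes charges, idempotent", {
  res <- standardizeReaction(
    parseReaction("C[C@H](O)C(=O)[O-]>>C[C@H](O)C(=O)[O-]", id = "lac"))
  expect_setequal(unique(res$report$transform),
                  c("stereo_removed", "protonate_anion"))
  want <- writeSmiles(parseSmiles("CC(O)C(=O)O"))
  expect_identical(writeSmiles(res$reaction@reactants[[1]]), want)

  res2 <- standardizeReaction(res$reaction)
  expect_equal(nrow(res2$report), 0)  # fixpoint
  expect_identical(writeReactionSmiles(res2$reaction),
                   writeReactionSmiles(res$reaction))

  # ammonium handling follows the rule flag
  amm <- parseReaction("[NH4+]>>[NH4+]", id = "amm")
  on <- standardizeReaction(amm)$reaction
  expect_equal(sideAtoms(on, "reactant")$charge, 0L)
  expect_equal(sideAtoms(on, "reactant")$hcount, 3L)
  off <- standardizeReaction(
    amm, standardizeRules(deprotonateAmmonium = FALSE))$reaction
  expect_equal(sideAtoms(off, "reactant")$charge, 1L)

  # permanently charged quaternary nitrogen is left alone, not an error
  quat <- standardizeReaction(
    parseReaction("C[N+](C)(C)C>>C[N+](C)(C)C", id = "quat"))
  expect_equal(max(sideAtoms(quat$reaction, "reactant")$charge), 1L)
})

test_that("curation filter keeps experimental non-subunit non-transport", {
  rec <- data.frame(
    protein_id = paste0("p", 1:4), reaction_id = paste0("r", 1:4),
    evidence = c("experimental", "experimental", "predicted", "experimental"),
    is_subunit = c(FALSE, TRUE, FALSE, FALSE),
    is_transport = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  res <- filterCuration(rec)
  expect_equal(nrow(res$retained), 1)
  expect_equal(res$retained$protein_id, "p4")
  expect_equal(res$tally, c(transport = 1L, subunit = 1L, evidence = 1L))

  all_ok <- filterCuration(rec[4, ])
  expect_equal(nrow(all_ok$retained), 1)
  expect_equal(sum(all_ok$tally), 0)

  # a record that is both transport and subunit counts once, under transport
  both <- rec[1, ]; both$is_subunit <- TRUE
  res2 <- filterCuration(both)
  expect_equal(res2$tally, c(transport = 1L, subunit = 0L, evidence = 0L))

  empty <- filterCuration(rec[0, ])
  expect_equal(nrow(empty$retained), 0)
})

test_that("RC derivation from the atom map matches a bond/H diff oracle", {
  r <- pyruvateLactate()
  # independent oracle: tabulate bonds and H counts by map number by hand
  bondKey <- function(rr, side) {
    at <- sideAtoms(rr, side); b <- sideBonds(rr, side)
    sort(paste(pmin(at$map[b$a1], at$map[b$a2]),
               pmax(at$map[b$a1], at$map[b$a2]), b$order))
  }
  before <- bondKey(r, "reactant"); after <- bondKey(r, "product")
  changedBonds <- union(setdiff(before, after), setdiff(after, before))
  changedMaps <- sort(unique(as.integer(unlist(
    lapply(strsplit(changedBonds, " "), `[`, 1:2)))))
  ra <- sideAtoms(r, "reactant"); pa <- sideAtoms(r, "product")
  hChanged <- ra$map[ra$hcount != pa$hcount[match(ra$map, pa$map)]]
  oracle <- sort(unique(c(changedMaps, hChanged)))
  expect_equal(sort(ra$map[rcAtoms(r, "reactant")]), oracle)
  expect_equal(oracle, c(2L, 3L))  # the carbonyl carbon and oxygen

  h <- methylAcetateHydrolysis()
  hm <- sideAtoms(h, "reactant")$map[rcAtoms(h)]
  expect_setequal(hm, c(2L, 4L, 6L))  # carbonyl C, ester O, water O

  expect_warning(deriveRcFromMap(parseReaction("[CH4:1]>>[CH4:1]",
                                               id = "idn")),
                 class = "rcnet_empty_rc")
  expect_error(deriveRcFromMap(parseReaction("CC>>CC", id = "nomap")),
               "not total")
})

test_that("operator-template RC assignment validates against products", {
  op <- esterHydrolysisOperator()
  h <- methylAcetateHydrolysis()
  asg <- assignRcViaOperator(h, op)
  expect_length(asg, 1)
  expect_identical(asg[[1]], rcAtoms(h))  # agrees with the map route

  sym <- parseReaction("COC(=O)C(=O)OC.O>>COC(=O)C(=O)O.CO", id = "sym")
  expect_length(assignRcViaOperator(sym, op), 2)  # symmetric diester

  ket <- ketoneReduction()
  expect_length(assignRcViaOperator(ket, op), 0)  # pattern absent
})

test_that("operator and map routes agree across generated reactions", {
  ops <- readOperators(system.file("extdata", "operators.tsv",
                                   package = "rcnet"))
  names(ops) <- vapply(ops, function(o) o@name, character(1))
  cfg <- synthConfig(templates = 6, perTemplate = 3, maxDecor = 3,
                     clusters = 2, perCluster = 2, embeddingDim = 8,
                     seqLength = 30, density = 0.1, seed = 55)
  rx <- generateReactions(cfg)
  fam <- attr(rx, "family")
  tnames <- attr(rx, "templateNames")
  for (i in seq_along(rx)) {
    op <- ops[[tnames[fam[i]]]]
    asg <- assignRcViaOperator(rx[[i]], op)
    expect_true(length(asg) >= 1, label = reactionId(rx[[i]]))
    keys <- vapply(asg, paste, character(1), collapse = ",")
    expect_true(paste(rcAtoms(rx[[i]]), collapse = ",") %in% keys,
                label = reactionId(rx[[i]]))
  }
})

test_that("the RC extracts as a valid reaction of its own", {
  r <- pyruvateLactate()
  core <- rcAsReaction(r)
  expect_identical(writeReactionSmiles(core, withMaps = TRUE),
                   writeReactionSmiles(
                     parseReaction("[C:2]=[O:3]>>[CH:2][OH:3]", id = "c"),
                     withMaps = TRUE))
  expect_equal(rcAtoms(core), seq_len(reactionAtomCount(core) -
                                      sum(vapply(core@products, atomCount,
                                                 integer(1)))))
  # two decorations of one template share one canonical core
  a <- methylAcetateHydrolysis(); b <- ethylAcetateHydrolysis()
  expect_identical(writeReactionSmiles(rcAsReaction(a)),
                   writeReactionSmiles(rcAsReaction(b)))
  # a reaction whose RC covers everything round-trips to itself
  whole <- ketoneReduction()
  whole@rcReactants <- seq_len(4L); whole@rcProducts <- seq_len(4L)
  expect_identical(writeReactionSmiles(rcAsReaction(whole)),
                   writeReactionSmiles(whole))
  norc <- parseReaction("C>>C", id = "norc")
  expect_error(rcAsReaction(norc), "empty RC")
})
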