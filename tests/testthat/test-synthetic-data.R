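# Synthetic generator: reactions, proteins, planted positives.

test_that("bare templates come back when decoration is disabled", {
  cfg <- synthConfig(templates = 5, perTemplate = 1, maxDecor = 0,
                     clusters = 2, perCluster = 2, embeddingDim = 8,
                     seqLength = 30, density = 0.2, seed = 1)
  rx <- generateReactions(cfg)
  expect_length(rx, 5)
  for (i in seq_along(rx)) {
    tmpl <- suppressWarnings(deriveRcFromMap(parseReaction(
      synthTemplates()[[i]]$smiles, id = "t")))
    expect_identical(writeReactionSmiles(rx[[i]]),
                     writeReactionSmiles(tmpl))
  }
})

test_that("derived RCs always recover the template core", {
  cfg <- synthConfig(templates = 6, perTemplate = 4, maxDecor = 4,
                     clusters = 2, perCluster = 2, embeddingDim = 8,
                     seqLength = 30, density = 0.1, seed = 77)
  rx <- generateReactions(cfg)
  fam <- attr(rx, "family")
  for (i in seq_along(rx)) {
    tmpl <- suppressWarnings(deriveRcFromMap(parseReaction(
      synthTemplates()[[fam[i]]]$smiles, id = "t")))
    coreMaps <- sideAtoms(tmpl, "reactant")$map[rcAtoms(tmpl)]
    gotMaps <- sideAtoms(rx[[i]], "reactant")$map[rcAtoms(rx[[i]])]
    expect_setequal(gotMaps, coreMaps)
    # standardization is a fixpoint on generated reactions
    expect_equal(nrow(standardizeReaction(rx[[i]])$report), 0)
    expect_gt(length(rcAtoms(rx[[i]])), 0)
  }
  # two decorations of one template stay RC-compatible and bounded below
  same <- which(fam == fam[1])[1:2]
  s <- rcmcs(rx[[same[1]]], rx[[same[2]]])
  core <- rcAsReaction(rx[[same[1]]])
  expect_gte(as.numeric(s), reactionAtomCount(core) /
             max(reactionAtomCount(rx[[same[1]]]),
                 reactionAtomCount(rx[[same[2]]])))
})

test_that("protein clusters order GSI and embeddings as planted", {
  cfg <- synthConfig(templates = 2, perTemplate = 2, clusters = 4,
                     perCluster = 5, embeddingDim = 16, seqLength = 50,
                     mutationRate = 0.1, noise = 0, density = 0.1, seed = 3)
  pr <- generateProteins(cfg)
  cl <- attr(pr, "cluster")
  emb <- proteinEmbeddings(pr)
  # zero noise: identical embeddings within a cluster
  for (c in unique(cl)) {
    rows <- emb[cl == c, , drop = FALSE]
    expect_equal(max(abs(sweep(rows, 2, rows[1, ]))), 0)
  }
  # within-cluster GSI strictly above between-cluster GSI on average
  seqs <- proteinSequences(pr)
  set.seed(4)
  within <- replicate(50, {
    c <- sample(unique(cl), 1); ij <- sample(which(cl == c), 2)
    gsi(seqs[[ij[1]]], seqs[[ij[2]]])
  })
  between <- replicate(50, {
    cc <- sample(unique(cl), 2)
    gsi(seqs[[sample(which(cl == cc[1]), 1)]],
        seqs[[sample(which(cl == cc[2]), 1)]])
  })
  expect_gt(min(within), max(between))

  pr2 <- generateProteins(cfg)
  expect_identical(proteinSequences(pr2), seqs)
  expect_identical(proteinEmbeddings(pr2), emb)
})

test_that("planted positives hit the target density and block structure", {
  cfg <- synthConfig(seed = 19)  # defaults: 200 x 200, density 0.01
  rx <- generateReactions(cfg)
  pr <- generateProteins(cfg)
  pos <- plantPositives(rx, pr, cfg)
  n <- length(rx) * length(proteinIds(pr))
  expect_equal(nrow(pos), 400, tolerance = 0.1)  # 400 +- 40 (binomial)
  expect_equal(attr(pos, "density"), cfg$density, tolerance = 0.1)
  # misassignment-bound consistency at full coverage
  expect_equal(misassignmentBound(attr(pos, "density"), 1),
               attr(pos, "density"))

  # zero promiscuity: strictly block-diagonal adjacency
  cfg0 <- synthConfig(clusters = 4, perCluster = 10, templates = 4,
                      perTemplate = 10, embeddingDim = 8, seqLength = 30,
                      activeFraction = 1, promiscuity = 0, density = 0.05,
                      seed = 21)
  rx0 <- generateReactions(cfg0); pr0 <- generateProteins(cfg0)
  pos0 <- plantPositives(rx0, pr0, cfg0)
  fam <- attr(rx0, "family"); cl <- attr(pr0, "cluster")
  famOfCluster <- ((cl - 1) %% cfg0$templates) + 1
  pf <- famOfCluster[match(pos0$protein_id, proteinIds(pr0))]
  rf <- fam[match(pos0$reaction_id, names(rx0))]
  expect_true(all(pf == rf))
  expect_equal(attr(pos0, "withinFraction"), 1)
})

test_that("dataset emission writes consistent pipeline files", {
  cfg <- synthConfig(templates = 3, perTemplate = 4, clusters = 3,
                     perCluster = 4, embeddingDim = 8, seqLength = 30,
                     density = 0.1, seed = 5)
  dir <- file.path(tempdir(), "synthout")
  res <- synthesizeDataset(cfg, dir)
  expect_true(all(file.exists(file.path(dir,
    c("reactions.tsv", "proteins.fasta", "embeddings.tsv",
      "positives.tsv", "families.tsv", "clusters.tsv")))))
  rx <- readReactionsTsv(file.path(dir, "reactions.tsv"))
  expect_length(rx, 12)
  expect_identical(writeReactionSmiles(rx[[1]]),
                   writeReactionSmiles(res$reactions[[1]]))
  expect_identical(rcAtoms(rx[[3]]), rcAtoms(res$reactions[[3]]))
  pr <- readProteinSet(file.path(dir, "proteins.fasta"),
                       file.path(dir, "embeddings.tsv"))
  expect_identical(proteinSequences(pr), proteinSequences(res$proteins))
  expect_equal(proteinEmbeddings(pr), proteinEmbeddings(res$proteins),
               tolerance = 1e-6)
})
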