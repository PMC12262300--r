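# Stratified similarity splitting and negative sampling.

test_that("clustering at a bound gives single-linkage components", {
  s <- matrix(0, 4, 4); diag(s) <- 1
  s[1, 2] <- s[2, 1] <- 1; s[3, 4] <- s[4, 3] <- 1
  m <- new("SimilarityMatrix", ids = letters[1:4], scores = s, metric = "gsi")
  cl <- clusterAtBound(m, 0.5)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, paste, character(1), collapse = ""),
                  c("ab", "cd"))
  expect_length(clusterAtBound(m, 1.0), 2)  # pairs at exactly 1 stay joined
  s2 <- s; s2[1, 2] <- s2[2, 1] <- 0.9; s2[3, 4] <- s2[4, 3] <- 0.9
  m2 <- new("SimilarityMatrix", ids = letters[1:4], scores = s2,
            metric = "gsi")
  expect_length(clusterAtBound(m2, 1.0), 4)  # all singletons at bound 1

  # transitivity along a chain: a-b and b-c strong, a-c weak
  s3 <- diag(1, 3)
  s3[1, 2] <- s3[2, 1] <- 0.7; s3[2, 3] <- s3[3, 2] <- 0.7
  s3[1, 3] <- s3[3, 1] <- 0.1
  m3 <- new("SimilarityMatrix", ids = c("a", "b", "c"), scores = s3,
            metric = "gsi")
  expect_length(clusterAtBound(m3, 0.6), 1)
})

test_that("stratified split puts whole clusters in test and verifies", {
  m <- generatePlantedSimilarity(n = 200)
  cfg <- splitConfig(bounds = c(0.4, 0.6, 0.8, 1.0), entity = "protein",
                     testFraction = 0.2, cvFolds = 3, seed = 7)
  asg <- stratifiedSimilaritySplit(m, cfg)
  tb <- assignmentTable(asg)
  # partition: every entity in exactly one fold, cv folds cover trainval
  expect_setequal(tb$entity_id, simIds(m))
  expect_true(all(tb$fold %in% c("test", "trainval")))
  expect_true(all(!is.na(tb$cv_fold[tb$fold == "trainval"])))
  expect_true(all(is.na(tb$cv_fold[tb$fold == "test"])))

  ver <- verifySplit(asg, m)
  expect_true(ver$allPass)
  # every realized max-train similarity sits strictly below its stratum cap
  test <- tb[tb$fold == "test", ]
  expect_true(all(test$realized_max_sim < test$declared_hi |
                  test$declared_hi == 1))
  # with the planted hierarchy, every declared stratum is realized
  expect_gte(nrow(ver$strata), 3)
  expect_equal(sum(ver$strata$n), sum(tb$fold == "test"))

  # determinism: identical seed, byte-identical split files
  asg2 <- stratifiedSimilaritySplit(m, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeSplitTsv(asg, f1); writeSplitTsv(asg2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and the TSV round-trips
  back <- readSplitTsv(f1)
  expect_equal(assignmentTable(back)$fold, tb$fold)
})

test_that("an all-similar matrix collapses with an error naming the bound", {
  n <- 60
  s <- matrix(0.99, n, n); diag(s) <- 1
  m <- new("SimilarityMatrix", ids = sprintf("x%02d", 1:n), scores = s,
           metric = "gsi")
  expect_error(
    stratifiedSimilaritySplit(m, splitConfig(entity = "protein", seed = 1)),
    "collapse at bound 0.40")
})

test_that("verifySplit flags a deliberately corrupted assignment", {
  m <- generatePlantedSimilarity(n = 96)
  asg <- stratifiedSimilaritySplit(
    m, splitConfig(entity = "protein", seed = 11))
  expect_true(verifySplit(asg, m)$allPass)
  tb <- assignmentTable(asg)
  # swap one test entity with a trainval member of a different cluster
  i <- which(tb$fold == "test")[1]
  j <- which(tb$fold == "trainval" &
             abs(match(tb$entity_id, simIds(m)) -
                 match(tb$entity_id[i], simIds(m))) > 20)[1]
  tb$fold[c(i, j)] <- tb$fold[c(j, i)]
  tb$cv_fold[j] <- NA_integer_; tb$cv_fold[i] <- 1L
  tb[j, c("declared_lo", "declared_hi", "realized_max_sim")] <-
    tb[i, c("declared_lo", "declared_hi", "realized_max_sim")]
  tb[i, c("declared_lo", "declared_hi", "realized_max_sim")] <- NA_real_
  bad <- new("SplitAssignment", table = tb, bounds = asg@bounds,
             entity = "protein", seed = asg@seed, info = list())
  ver <- verifySplit(bad, m)
  expect_false(ver$allPass)
  expect_true(tb$entity_id[j] %in%
              ver$perEntity$entity_id[!ver$perEntity$pass])
})

test_that("negative sampling hits exact ratios and avoids positives", {
  setup <- tinyTrainingSetup(seed = 9)
  pd <- sampleNegatives(setup$positives, proteinIds(setup$proteins),
                        names(setup$reactions), setup$assignment,
                        negativeRatios(3, valFold = 2), seed = 4)
  p <- pairTable(pd)
  for (fl in unique(p$fold)) {
    nPos <- sum(p$fold == fl & p$label == 1)
    nNeg <- sum(p$fold == fl & p$label == 0)
    want <- if (fl %in% c("test", "cv2")) 1 else 3
    expect_equal(nNeg, want * nPos, label = fl)
  }
  posKey <- paste(setup$positives$protein_id, setup$positives$reaction_id)
  negKey <- paste(p$protein_id[p$label == 0], p$reaction_id[p$label == 0])
  expect_length(intersect(posKey, negKey), 0)
  expect_false(anyDuplicated(negKey) > 0)

  pd2 <- sampleNegatives(setup$positives, proteinIds(setup$proteins),
                         names(setup$reactions), setup$assignment,
                         negativeRatios(3, valFold = 2), seed = 4)
  expect_identical(pairTable(pd2), p)

  # complete bipartite positives leave nothing to sample
  allPairs <- expand.grid(protein_id = proteinIds(setup$proteins),
                          reaction_id = names(setup$reactions),
                          stringsAsFactors = FALSE)
  expect_error(
    sampleNegatives(allPairs, proteinIds(setup$proteins),
                    names(setup$reactions), setup$assignment,
                    negativeRatios(3), seed = 1),
    "unobserved pairs exist")
})

test_that("the misassignment bound is density over coverage", {
  expect_equal(misassignmentBound(0.0003, 0.10), 0.003)
  expect_equal(misassignmentBound(0.0003, 1.0), 0.0003)
  expect_equal(misassignmentBound(0.0003, 0.01), 0.03)
  expect_error(misassignmentBound(0.05, 0.01), "cannot be below")
  expect_error(misassignmentBound(0, 0.5), "positive")
})
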