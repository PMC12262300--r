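# Stratified similarity splitting and global negative sampling.

#' Split configuration
#'
#' @param bounds ascending similarity bounds, last equal to 1. Stratum `i` is
#'   the half-open interval from the previous bound (0 for the first) to
#'   `bounds[i]`.
#' @param entity `"reaction"` or `"protein"`: the controlled split entity.
#' @param testFraction target fraction of entities in the test fold.
#' @param quotas per-stratum test quota fractions (must sum to
#'   `testFraction`); defaults to an even spread over the strata.
#' @param cvFolds inner cross-validation fold count.
#' @param seed RNG seed.
#' @return validated named list.
#' @export
splitConfig <- function(bounds = c(0.4, 0.6, 0.8, 1.0),
                        entity = c("reaction", "protein"),
                        testFraction = 0.2, quotas = NULL, cvFolds = 3,
                        seed = 1) {
  entity <- match.arg(entity)
  if (is.unsorted(bounds, strictly = TRUE)) stop("bounds must be ascending")
  if (abs(bounds[length(bounds)] - 1) > 1e-12) stop("last bound must be 1")
  if (any(bounds <= 0)) stop("bounds must be in (0, 1]")
  if (is.null(quotas)) quotas <- rep(testFraction / length(bounds),
                                     length(bounds))
  if (length(quotas) != length(bounds))
    stop("one quota per bound required")
  if (abs(sum(quotas) - testFraction) > 1e-9)
    stop("quotas must sum to the test fraction")
  if (cvFolds < 2) stop("cvFolds must be at least 2")
  list(bounds = bounds, entity = entity, testFraction = testFraction,
       quotas = quotas, cvFolds = as.integer(cvFolds), seed = as.integer(seed))
}

#' Cluster items at a similarity bound
#'
#' Single-linkage clusters: connected components of the graph with an edge
#' wherever the similarity score is at least `bound`, so the maximum
#' similarity between items of different clusters is strictly below `bound`.
#'
#' @param m a [SimilarityMatrix-class].
#' @param bound similarity bound in (0, 1].
#' @return list of character vectors of item ids.
#' @export
clusterAtBound <- function(m, bound) {
  if (bound <= 0 || bound > 1) stop("bound must be in (0, 1]")
  .clusterIndices(m@scores, seq_along(m@ids), bound) |>
    lapply(function(ix) m@ids[ix])
}

# connected components at `bound` restricted to matrix row indices `pool`
.clusterIndices <- function(s, pool, bound) {
  if (!length(pool)) return(list())
  sub <- s[pool, pool, drop = FALSE] >= bound
  diag(sub) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  memb <- igraph::components(g)$membership
  lapply(sort(unique(memb)), function(ci) pool[memb == ci])
}

# Sample whole clusters from `pool` into a fold, relaxing bounds upward.
# quotasN: per-bound entity quotas. Returns list(sampled indices, declared
# stratum index per sampled entity) or signals a collapse error.
.stratSample <- function(s, pool, bounds, quotasN, what = "test") {
  sampled <- integer(0)
  declared <- integer(0)
  for (bi in seq_along(bounds)) {
    bound <- bounds[bi]
    remaining <- quotasN[bi]
    if (remaining <= 0) next
    overshoot <- max(1L, quotasN[bi])
    repeat {
      if (remaining <= 0) break
      cl <- .clusterIndices(s, setdiff(pool, sampled), bound)
      sizes <- lengths(cl)
      eligible <- which(sizes <= remaining + overshoot)
      if (!length(eligible)) {
        if (length(cl) <= 1)
          stop(sprintf(
            "similarity split collapse at bound %.2f: the %s pool forms a single cluster of %d entities",
            bound, what, if (length(cl)) sizes[1] else 0L))
        # clusters exist but all exceed the remaining quota: record the
        # shortfall and relax to the next bound
        break
      }
      pick <- if (length(eligible) == 1) eligible else
        sample(eligible, 1, prob = sizes[eligible])
      take <- cl[[pick]]
      sampled <- c(sampled, take)
      declared <- c(declared, rep(bi, length(take)))
      remaining <- remaining - length(take)
    }
  }
  list(sampled = sampled, declared = declared)
}

.strataOf <- function(values, bounds) {
  lo <- c(0, bounds[-length(bounds)])
  idx <- vapply(values, function(v) {
    hit <- which(v >= lo & (v < bounds | bounds == 1))
    hit[length(hit)]
  }, integer(1))
  idx
}

#' Stratified similarity split
#'
#' Iterates the similarity bounds in ascending order; at each bound the
#' not-yet-assigned pool is clustered ([clusterAtBound()]) and whole clusters
#' are sampled (uniformly, weighted by size) into the test fold until the
#' stratum quota is met, after which the bound is relaxed. The remaining
#' entities form the train/validation pool, which is divided into inner CV
#' folds by the same procedure. Afterwards every test entity's maximum
#' similarity to the train/validation pool is measured and its stratum
#' recorded from that measurement; strata left short are topped up for at
#' most two repair iterations, after which the residual imbalance is
#' reported in the assignment's `info`.
#'
#' Whole-cluster sampling guarantees that every test entity's realized
#' maximum cross-split similarity is strictly below its sampling bound; the
#' lower edge of each stratum is measured, never assumed. If at some bound
#' the pool has collapsed into clusters too large to sample, a collapse error
#' names the bound.
#'
#' @param m a [SimilarityMatrix-class] covering all split entities.
#' @param cfg a [splitConfig()].
#' @return a [SplitAssignment-class]; deterministic given `cfg$seed`.
#' @export
stratifiedSimilaritySplit <- function(m, cfg) {
  s <- m@scores
  ids <- m@ids
  n <- length(ids)
  set.seed(cfg$seed)
  quotasN <- round(cfg$quotas * n)
  res <- .stratSample(s, seq_len(n), cfg$bounds, quotasN, what = "test")
  test <- res$sampled
  declared <- res$declared
  trainval <- setdiff(seq_len(n), test)
  realizedMax <- function(testIdx, poolIdx)
    vapply(testIdx, function(i) max(s[i, poolIdx]), numeric(1))
  # measure, re-label, and repair quota shortfalls (at most 2 iterations)
  for (iter in 1:3) {
    realized <- realizedMax(test, trainval)
    declared <- .strataOf(realized, cfg$bounds)
    counts <- tabulate(declared, nbins = length(cfg$bounds))
    deficit <- quotasN - counts
    if (iter > 2 || all(deficit <= 0)) break
    for (bi in which(deficit > 0)) {
      extra <- tryCatch(
        .stratSample(s, trainval, cfg$bounds[bi], deficit[bi], what = "test"),
        error = function(e) NULL)
      if (is.null(extra)) next
      test <- c(test, extra$sampled)
      trainval <- setdiff(trainval, extra$sampled)
    }
  }
  residual <- quotasN - tabulate(declared, nbins = length(cfg$bounds))
  # inner CV folds over the train/validation pool, re-stratified
  cvFold <- integer(n)
  poolLeft <- trainval
  foldTarget <- floor(length(trainval) / cfg$cvFolds)
  cvQuota <- round(cfg$quotas / sum(cfg$quotas) * foldTarget)
  for (j in seq_len(cfg$cvFolds - 1)) {
    fr <- .stratSample(s, poolLeft, cfg$bounds, cvQuota,
                       what = sprintf("cv fold %d", j))
    cvFold[fr$sampled] <- j
    poolLeft <- setdiff(poolLeft, fr$sampled)
  }
  cvFold[poolLeft] <- cfg$cvFolds
  lo <- c(0, cfg$bounds[-length(cfg$bounds)])
  tb <- data.frame(
    entity_id = ids,
    fold = ifelse(seq_len(n) %in% test, "test", "trainval"),
    cv_fold = ifelse(seq_len(n) %in% test, NA_integer_, cvFold),
    declared_lo = NA_real_, declared_hi = NA_real_,
    realized_max_sim = NA_real_,
    stringsAsFactors = FALSE)
  tb$declared_lo[test] <- lo[declared]
  tb$declared_hi[test] <- cfg$bounds[declared]
  tb$realized_max_sim[test] <- realizedMax(test, trainval)
  out <- new("SplitAssignment", table = tb, bounds = cfg$bounds,
             entity = cfg$entity, seed = cfg$seed,
             info = list(quotas = quotasN, residual_imbalance = residual))
  validObject(out)
  out
}

#' Verify a split assignment against the similarity matrix
#'
#' Recomputes every test entity's maximum similarity to the train/validation
#' pool and checks it lies inside the declared stratum. Returns per-entity
#' results, per-stratum counts and a histogram of realized similarities
#' (for distribution plots).
#'
#' @param assignment a [SplitAssignment-class].
#' @param m the [SimilarityMatrix-class] it was built from.
#' @param breaks histogram breaks over `[0, 1]`.
#' @return list with `perEntity` (data.frame with `pass` column), `strata`
#'   (per-stratum counts), `histogram` and `allPass`.
#' @export
verifySplit <- function(assignment, m, breaks = seq(0, 1, by = 0.1)) {
  tb <- assignment@table
  if (!setequal(tb$entity_id, m@ids))
    stop("assignment and similarity matrix cover different entities")
  s <- m@scores
  pos <- match(tb$entity_id, m@ids)
  testRows <- which(tb$fold == "test")
  trainIdx <- pos[tb$fold == "trainval"]
  realized <- vapply(testRows, function(k) max(s[pos[k], trainIdx]),
                     numeric(1))
  hi <- tb$declared_hi[testRows]; lo <- tb$declared_lo[testRows]
  pass <- realized >= lo & (realized < hi | (hi == 1 & realized <= 1))
  perEntity <- data.frame(
    entity_id = tb$entity_id[testRows],
    declared_lo = lo, declared_hi = hi,
    realized_max_sim = realized, pass = pass,
    stringsAsFactors = FALSE)
  strata <- stats::aggregate(
    list(n = perEntity$entity_id),
    by = list(declared_lo = lo, declared_hi = hi), FUN = length)
  h <- graphics::hist(realized, breaks = breaks, plot = FALSE)
  list(perEntity = perEntity, strata = strata,
       histogram = data.frame(bin_lo = h$breaks[-length(h$breaks)],
                              bin_hi = h$breaks[-1], count = h$counts),
       allPass = all(pass))
}

#' Analytic bound on negative misassignment probability
#'
#' With a globally sampled negative pair, the probability that it is in fact
#' an unobserved true positive is at most the observed adjacency density
#' divided by the assumed coverage of true promiscuity.
#'
#' @param observedDensity observed positive density of the adjacency matrix.
#' @param assumedCoverage assumed fraction of true catalysis pairs already
#'   observed, in `(0, 1]`.
#' @return the probability bound `observedDensity / assumedCoverage`.
#' @export
misassignmentBound <- function(observedDensity, assumedCoverage) {
  if (!is.numeric(observedDensity) || observedDensity <= 0)
    stop("observedDensity must be positive")
  if (assumedCoverage > 1) stop("assumedCoverage must be at most 1")
  if (assumedCoverage < observedDensity)
    stop("assumedCoverage cannot be below the observed density")
  observedDensity / assumedCoverage
}

#' Default fold roles for negative sampling ratios
#'
#' @param cvFolds number of inner CV folds.
#' @param valFold which CV fold currently serves as validation (negatives at
#'   the validation ratio); `NULL` for none.
#' @param trainRatio,valRatio,testRatio negative:positive ratios.
#' @return named numeric vector over fold labels.
#' @export
negativeRatios <- function(cvFolds = 3, valFold = NULL, trainRatio = 3,
                           valRatio = 1, testRatio = 1) {
  labels <- c("test", paste0("cv", seq_len(cvFolds)))
  ratios <- c(testRatio, rep(trainRatio, cvFolds))
  names(ratios) <- labels
  if (!is.null(valFold)) ratios[paste0("cv", valFold)] <- valRatio
  ratios
}

.pairFoldLabels <- function(assignment) {
  tb <- assignment@table
  ifelse(tb$fold == "test", "test", paste0("cv", tb$cv_fold))
}

#' Sample negative pairs globally, per fold
#'
#' For each fold, negatives are drawn uniformly without replacement from the
#' product of the fold's split entities with all counterpart entities, minus
#' the global positive set, until the fold's ratio times its positive count
#' is reached. Deterministic given `seed`.
#'
#' @param positives data.frame with columns `protein_id`, `reaction_id`.
#' @param proteinIds,reactionIds all entity identifiers.
#' @param assignment the [SplitAssignment-class] of the split entity.
#' @param ratios named negative:positive ratios per fold label (see
#'   [negativeRatios()]).
#' @param seed RNG seed.
#' @return a [PairDataset-class].
#' @export
sampleNegatives <- function(positives, proteinIds, reactionIds, assignment,
                            ratios = negativeRatios(), seed = 1) {
  if (any(ratios <= 0) || any(ratios != round(ratios)))
    stop("ratios must be positive integers")
  tb <- assignment@table
  foldLabel <- .pairFoldLabels(assignment)
  names(foldLabel) <- tb$entity_id
  byReaction <- assignment@entity == "reaction"
  entityOf <- function(df) if (byReaction) df$reaction_id else df$protein_id
  posFold <- foldLabel[entityOf(positives)]
  if (any(is.na(posFold)))
    stop("positives reference entities missing from the split assignment")
  posKey <- paste(positives$protein_id, positives$reaction_id, sep = "\r")
  set.seed(seed)
  negParts <- list()
  for (fl in names(ratios)) {
    nPos <- sum(posFold == fl)
    if (nPos == 0) next
    need <- ratios[[fl]] * nPos
    foldEntities <- tb$entity_id[foldLabel == fl]
    if (byReaction) {
      cand <- expand.grid(protein_id = proteinIds,
                          reaction_id = foldEntities,
                          stringsAsFactors = FALSE)
    } else {
      cand <- expand.grid(protein_id = foldEntities,
                          reaction_id = reactionIds,
                          stringsAsFactors = FALSE)
    }
    candKey <- paste(cand$protein_id, cand$reaction_id, sep = "\r")
    cand <- cand[!candKey %in% posKey, , drop = FALSE]
    if (nrow(cand) < need)
      stop(sprintf(
        "fold %s: need %d negatives but only %d unobserved pairs exist",
        fl, need, nrow(cand)))
    take <- cand[sample(nrow(cand), need), , drop = FALSE]
    take$label <- 0L; take$fold <- fl; take$provenance <- "sampled"
    negParts[[length(negParts) + 1]] <- take
  }
  pos <- data.frame(protein_id = positives$protein_id,
                    reaction_id = positives$reaction_id,
                    label = 1L, fold = unname(posFold),
                    provenance = "observed", stringsAsFactors = FALSE)
  pairs <- rbind(pos, if (length(negParts)) do.call(rbind, negParts))
  rownames(pairs) <- NULL
  out <- new("PairDataset", pairs = pairs, ratios = ratios,
             seed = as.integer(seed))
  validObject(out)
  out
}

#' Write / read a split assignment as TSV
#'
#' Columns `entity_id`, `fold`, `cv_fold`, `declared_stratum`
#' (`"[lo,hi)"`), `realized_max_sim`.
#' @param assignment a [SplitAssignment-class].
#' @param path file path.
#' @export
writeSplitTsv <- function(assignment, path) {
  tb <- assignment@table
  df <- data.frame(
    entity_id = tb$entity_id, fold = tb$fold, cv_fold = tb$cv_fold,
    declared_stratum = ifelse(is.na(tb$declared_lo), "",
                              sprintf("[%.6g,%.6g)", tb$declared_lo,
                                      tb$declared_hi)),
    realized_max_sim = ifelse(is.na(tb$realized_max_sim), "",
                              sprintf("%.10g", tb$realized_max_sim)),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# entity=%s bounds=%s seed=%d", assignment@entity,
                     paste(assignment@bounds, collapse = ","),
                     assignment@seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSplitTsv
#' @export
readSplitTsv <- function(path) {
  header <- readLines(path, n = 1)
  entity <- sub(".*entity=(\\S+).*", "\\1", header)
  bounds <- as.numeric(strsplit(sub(".*bounds=(\\S+).*", "\\1", header),
                                ",")[[1]])
  seed <- as.integer(sub(".*seed=(\\d+).*", "\\1", header))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(entity_id = "character"))
  stratum <- df$declared_stratum
  lo <- suppressWarnings(as.numeric(sub("^\\[([^,]+),.*", "\\1", stratum)))
  hi <- suppressWarnings(as.numeric(sub(".*,([^)]+)\\)$", "\\1", stratum)))
  tb <- data.frame(entity_id = as.character(df$entity_id), fold = df$fold,
                   cv_fold = df$cv_fold, declared_lo = lo, declared_hi = hi,
                   realized_max_sim = suppressWarnings(
                     as.numeric(df$realized_max_sim)),
                   stringsAsFactors = FALSE)
  new("SplitAssignment", table = tb, bounds = bounds, entity = entity,
      seed = seed, info = list())
}

#' Write / read a pair dataset as TSV
#' @param dataset a [PairDataset-class].
#' @param path file path.
#' @export
writePairsTsv <- function(dataset, path) {
  utils::write.table(dataset@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePairsTsv
#' @export
readPairsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(protein_id = "character",
                                         reaction_id = "character"))
  new("PairDataset", pairs = df, ratios = numeric(), seed = NA_integer_)
}
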