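# Classification metrics, similarity-binned evaluation and the RC-proximity
# embedding analysis.

#' ROC curve and area by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (descending) and
#' integrates the resulting ROC points with the trapezoid rule.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return the area under the ROC curve, with the curve points in the
#'   `points` attribute; `NA` when only one class is present.
#' @export
rocAuc <- function(scores, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  cumTp <- cumsum(y == 1); cumFp <- cumsum(y == 0)
  # one operating point per distinct score (all ties flip together)
  last <- which(!duplicated(s, fromLast = TRUE))
  tpr <- c(0, cumTp[last] / nPos, 1)
  fpr <- c(0, cumFp[last] / nNeg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  attr(auc, "points") <- data.frame(fpr = fpr, tpr = tpr)
  auc
}

#' Confusion-matrix metrics at a threshold
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels binary labels.
#' @param tau decision threshold; a pair is predicted positive when its score
#'   is at least `tau`.
#' @return list with `counts` (tp/fp/tn/fn), `precision`, `recall`, `f1`,
#'   `accuracy`, `auc`, `roc` (data.frame of curve points) and `undefined`
#'   (names of metrics that are undefined on this input, reported as `NA`
#'   rather than an error).
#' @export
computeMetrics <- function(scores, labels, tau = 0.5) {
  if (!length(scores) || length(scores) != length(labels))
    stop("scores and labels must be nonempty and of equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- as.integer(scores >= tau)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  undefined <- character()
  precision <- if (tp + fp == 0) { undefined <- c(undefined, "precision"); NA }
    else tp / (tp + fp)
  recall <- if (tp + fn == 0) { undefined <- c(undefined, "recall"); NA }
    else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (2 * tp + fp + fn == 0) { undefined <- c(undefined, "f1"); NA } else
      2 * tp / (2 * tp + fp + fn)
  } else 2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / length(labels)
  auc <- rocAuc(scores, labels)
  roc <- attr(auc, "points")
  if (is.na(auc)) undefined <- c(undefined, "auc")
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       precision = precision, recall = recall, f1 = f1, accuracy = accuracy,
       auc = as.numeric(auc), roc = roc, tau = tau, n = length(labels),
       undefined = undefined)
}

#' Per-bin performance over maximum train similarity
#'
#' Assigns each test pair to the bin of its split entity's realized maximum
#' similarity to the training pool (measured by [verifySplit()] /
#' [stratifiedSimilaritySplit()]) and computes metrics per bin. Bins
#' partition `[0, 1]`; the last bin is closed.
#'
#' @param pairs data.frame of test pairs (`protein_id`, `reaction_id`,
#'   `label`).
#' @param scores numeric scores aligned with `pairs`.
#' @param assignment the [SplitAssignment-class] carrying realized
#'   similarities for its test entities.
#' @param binEdges ascending bin edges from 0 to 1.
#' @param tau decision threshold.
#' @param minN bins with fewer pairs are flagged low-confidence.
#' @return list with `bins` (data.frame of per-bin metrics, `n` and flags)
#'   and `perBin` (list of full [computeMetrics()] reports; `NULL` for empty
#'   bins).
#' @export
binnedPerformance <- function(pairs, scores, assignment,
                              binEdges = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
                              tau = 0.5, minN = 10) {
  if (binEdges[1] != 0 || binEdges[length(binEdges)] != 1 ||
      is.unsorted(binEdges, strictly = TRUE))
    stop("binEdges must ascend from 0 to 1")
  tb <- assignment@table
  key <- if (assignment@entity == "reaction") pairs$reaction_id else
    pairs$protein_id
  realized <- tb$realized_max_sim[match(key, tb$entity_id)]
  if (any(is.na(realized)))
    stop("realized similarity missing for entity ",
         key[which(is.na(realized))[1]])
  nb <- length(binEdges) - 1
  binOf <- pmin(findInterval(realized, binEdges, rightmost.closed = TRUE), nb)
  rows <- list(); reports <- vector("list", nb)
  for (bi in seq_len(nb)) {
    sel <- binOf == bi
    row <- data.frame(bin_lo = binEdges[bi], bin_hi = binEdges[bi + 1],
                      n = sum(sel), precision = NA_real_, recall = NA_real_,
                      f1 = NA_real_, accuracy = NA_real_, auc = NA_real_,
                      low_confidence = sum(sel) < minN)
    if (any(sel)) {
      rep <- computeMetrics(scores[sel], pairs$label[sel], tau)
      reports[[bi]] <- rep
      row$precision <- as.numeric(rep$precision)
      row$recall <- as.numeric(rep$recall)
      row$f1 <- as.numeric(rep$f1)
      row$accuracy <- rep$accuracy
      row$auc <- rep$auc
    }
    rows[[bi]] <- row
  }
  list(bins = do.call(rbind, rows), perBin = reports)
}

#' RC-proximity embedding analysis
#'
#' Groups reactions sharing a reaction center (equal canonical form of
#' [rcAsReaction()]), embeds every member and the RC-as-reaction itself with
#' the model's encoder, and scores the proximity of the members' mean
#' embedding to the RC embedding the same way enzyme-reaction pairs are
#' scored: `sigmoid` of their dot product. An encoder that has learned
#' mechanism-relevant patterns maps reactions of a common RC near the RC
#' itself, so the fraction of groups with proximity at least 0.8 summarizes
#' mechanism awareness.
#'
#' @param model an [RcnetModel-class].
#' @param reactions list of RC-annotated [Reaction-class] objects.
#' @param threshold proximity threshold for the summary fraction.
#' @return list with `groups` (data.frame: RC canonical form, member count,
#'   proximity score, degeneracy flag for single-member groups) and
#'   `fractionHigh` (fraction of groups with score at least `threshold`).
#' @export
rcProximityAnalysis <- function(model, reactions, threshold = 0.8) {
  if (!length(reactions)) stop("no reactions")
  rcCores <- lapply(reactions, rcAsReaction)
  keys <- vapply(rcCores, function(core)
    writeReactionSmiles(core, withMaps = FALSE), character(1))
  rows <- list()
  for (key in unique(keys)) {
    sel <- which(keys == key)
    memberEmb <- vapply(reactions[sel], embedReaction, numeric(model@encoder$d),
                        config = model@encoder, weights = model@weights)
    meanEmb <- if (is.matrix(memberEmb)) rowMeans(memberEmb) else memberEmb
    rcEmb <- embedReaction(rcCores[[sel[1]]], model@encoder, model@weights)
    s <- stats::plogis(sum(meanEmb * rcEmb))
    rows[[length(rows) + 1]] <- data.frame(
      rc = key, n = length(sel), proximity = s,
      degenerate = length(sel) == 1, stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, rows)
  list(groups = groups,
       fractionHigh = mean(groups$proximity >= threshold))
}

#' Compare two encoders' RC proximity, RC by RC
#'
#' @param resA,resB results of [rcProximityAnalysis()] for two models over
#'   the same reactions.
#' @return list with `table` (per-RC proximities and winner) and
#'   `fractionAWins` (fraction of shared RC groups where the first model's
#'   mean embedding is closer to the RC embedding).
#' @export
compareRcProximity <- function(resA, resB) {
  shared <- intersect(resA$groups$rc, resB$groups$rc)
  if (!length(shared)) stop("no shared RC groups")
  a <- resA$groups[match(shared, resA$groups$rc), ]
  b <- resB$groups[match(shared, resB$groups$rc), ]
  tab <- data.frame(rc = shared, proximity_a = a$proximity,
                    proximity_b = b$proximity,
                    winner = ifelse(a$proximity > b$proximity, "A",
                                    ifelse(a$proximity < b$proximity, "B",
                                           "tie")),
                    stringsAsFactors = FALSE)
  list(table = tab, fractionAWins = mean(tab$winner == "A"))
}
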