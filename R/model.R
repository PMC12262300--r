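# Two-tower scorer: projected protein embedding dotted with the reaction
# embedding, squashed through a sigmoid, trained with a weighted binary
# cross-entropy loss.

#' Loss configuration
#'
#' The training loss is
#' `l(x, y) = -[ m p y log(sigmoid(x)) + (1 - y) log(1 - sigmoid(x)) ]`
#' with `m` the negative multiple and `p` the positive multiplier, so the
#' positive term carries weight `m * p` (9 at the defaults, compensating the
#' 3:1 negative oversampling in training folds). With `m * p = 1` it reduces
#' to plain binary cross-entropy.
#'
#' @param m negative multiple (default 3).
#' @param p positive multiplier (default 3).
#' @return named list.
#' @export
lossConfig <- function(m = 3, p = 3) {
  if (m <= 0 || p <= 0) stop("m and p must be positive")
  list(m = m, p = p)
}

#' Training configuration
#'
#' @param epochs training epochs (default 25).
#' @param batchSize pairs per batch; `Inf` (default) for full-batch updates.
#' @param lr learning rate of the adaptive moment optimizer.
#' @param seed optimizer/shuffling seed.
#' @return named list.
#' @export
trainConfig <- function(epochs = 25, batchSize = Inf, lr = 1e-3, seed = 1) {
  if (epochs < 1) stop("epochs must be at least 1")
  list(epochs = as.integer(epochs), batchSize = batchSize, lr = lr,
       seed = as.integer(seed))
}

.softplus <- function(t) ifelse(t > 30, t, log1p(exp(t)))

#' Weighted binary cross-entropy loss
#'
#' Numerically stabilized: evaluated through softplus so large-magnitude
#' logits neither overflow nor produce NaN.
#'
#' @param x numeric logits (model outputs before the sigmoid).
#' @param y labels in `{0, 1}`.
#' @param cfg a [lossConfig()].
#' @return numeric vector of per-pair losses (nonnegative).
#' @export
pairLoss <- function(x, y, cfg = lossConfig()) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  cfg$m * cfg$p * y * .softplus(-x) + (1 - y) * .softplus(x)
}

#' Analytic gradient of [pairLoss()] with respect to the logit
#' @inheritParams pairLoss
#' @return numeric vector `d loss / d x`.
#' @export
pairLossGradient <- function(x, y, cfg = lossConfig()) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  s <- stats::plogis(x)
  (1 - y) * s - cfg$m * cfg$p * y * (1 - s)
}

#' Construct an (untrained) model
#'
#' @param encoder an [encoderConfig()].
#' @param proteinDim protein-embedding input dimension.
#' @param threshold decision threshold.
#' @return an [RcnetModel-class] with freshly initialized weights.
#' @export
rcnetModel <- function(encoder, proteinDim = 1280, threshold = 0.5) {
  new("RcnetModel", encoder = encoder,
      weights = initWeights(encoder, proteinDim),
      threshold = threshold, proteinDim = as.integer(proteinDim),
      log = data.frame())
}

#' Score an enzyme-reaction pair
#'
#' `sigmoid( < embedReaction(r), Wp e > )` where `e` is the protein's
#' precomputed embedding and `Wp` the learned protein projection.
#'
#' @param model an [RcnetModel-class].
#' @param r a [Reaction-class].
#' @param proteinEmbedding numeric vector of length `proteinDim`.
#' @return probability in (0, 1).
#' @export
scorePair <- function(model, r, proteinEmbedding) {
  if (length(proteinEmbedding) != model@proteinDim)
    stop(sprintf("protein embedding has dim %d, model expects %d",
                 length(proteinEmbedding), model@proteinDim))
  zr <- embedReaction(r, model@encoder, model@weights)
  zp <- as.numeric(model@weights$Wp %*% proteinEmbedding)
  stats::plogis(sum(zr * zp))
}

# prepare per-reaction forward caches reused across epochs
.reactionCaches <- function(reactions, config) {
  lapply(reactions, function(r) {
    if (config$variant == "morgan") {
      list(fp = morganFingerprint(r, config$radius, config$nbits))
    } else {
      g <- buildReactionGraph(r, config$variant)
      list(g = g, ops = .graphOperators(g))
    }
  })
}

.embedAll <- function(caches, config, w) {
  d <- config$d
  Z <- matrix(0, length(caches), d)
  fws <- vector("list", length(caches))
  for (i in seq_along(caches)) {
    cc <- caches[[i]]
    if (config$variant == "morgan") {
      Z[i, ] <- as.numeric(w$Wmrg %*% cc$fp)
    } else {
      fw <- .encoderForward(cc$g, w, config$M, ops = cc$ops)
      Z[i, ] <- .aggregateForward(cc$g, fw, w)$z
      fws[[i]] <- fw
    }
  }
  list(Z = Z, fws = fws)
}

.adamInit <- function(w) lapply(w, function(x) list(m = 0 * x, v = 0 * x))

.adamStep <- function(w, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g[[nm]]
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g[[nm]]^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

#' Train the two-tower scorer
#'
#' Minimizes the mean weighted binary cross-entropy over training pairs with
#' an adaptive moment optimizer; all gradients are computed by the package's
#' own backward pass through the encoder and projections. Deterministic given
#' the seeds (single-threaded).
#'
#' @param dataset a [PairDataset-class]; pairs in folds named `cv*` are used
#'   (the `test` fold is never touched). If `valFold` is given, that CV fold
#'   is held out for per-epoch validation metrics and threshold selection.
#' @param reactions named list of [Reaction-class] objects.
#' @param proteins a [ProteinSet-class].
#' @param encoder an [encoderConfig()].
#' @param train a [trainConfig()].
#' @param loss a [lossConfig()].
#' @param valFold integer CV fold held out for validation, or `NULL`.
#' @return a trained [RcnetModel-class] with a per-epoch log.
#' @export
trainModel <- function(dataset, reactions, proteins, encoder = encoderConfig(),
                       train = trainConfig(), loss = lossConfig(),
                       valFold = NULL) {
  pairs <- dataset@pairs
  cvPairs <- pairs[startsWith(pairs$fold, "cv"), , drop = FALSE]
  if (!is.null(valFold)) {
    valLab <- paste0("cv", valFold)
    trainPairs <- cvPairs[cvPairs$fold != valLab, , drop = FALSE]
    valPairs <- cvPairs[cvPairs$fold == valLab, , drop = FALSE]
  } else {
    trainPairs <- cvPairs
    valPairs <- cvPairs[0, , drop = FALSE]
  }
  if (!nrow(trainPairs)) stop("no training pairs")
  rids <- unique(c(trainPairs$reaction_id, valPairs$reaction_id))
  missingR <- setdiff(rids, names(reactions))
  if (length(missingR)) stop("unknown reaction ids: ",
                             paste(utils::head(missingR), collapse = ", "))
  Ep <- proteinEmbeddings(proteins)
  pids <- unique(c(trainPairs$protein_id, valPairs$protein_id))
  if (!all(pids %in% rownames(Ep))) stop("pairs reference unknown proteins")
  caches <- .reactionCaches(reactions[rids], encoder)
  D <- ncol(Ep)
  w <- initWeights(encoder, D)
  state <- .adamInit(w)
  set.seed(train$seed)
  nTr <- nrow(trainPairs)
  rxIdx <- match(trainPairs$reaction_id, rids)
  pIdx <- match(trainPairs$protein_id, rownames(Ep))
  yTr <- trainPairs$label
  vRx <- match(valPairs$reaction_id, rids)
  vP <- match(valPairs$protein_id, rownames(Ep))
  batchSize <- if (is.finite(train$batchSize)) min(train$batchSize, nTr) else
    nTr
  logRows <- list()
  stepCount <- 0
  for (epoch in seq_len(train$epochs)) {
    ord <- if (batchSize < nTr) sample.int(nTr) else seq_len(nTr)
    starts <- seq(1, nTr, by = batchSize)
    epochLoss <- 0
    for (s0 in starts) {
      sel <- ord[s0:min(s0 + batchSize - 1, nTr)]
      emb <- .embedAll(caches, encoder, w)
      Zp <- Ep %*% t(w$Wp)
      logits <- rowSums(emb$Z[rxIdx[sel], , drop = FALSE] *
                        Zp[pIdx[sel], , drop = FALSE])
      li <- pairLoss(logits, yTr[sel], loss)
      if (any(!is.finite(li)))
        stop("non-finite training loss; aborting (check inputs and lr)")
      epochLoss <- epochLoss + sum(li)
      dlogit <- pairLossGradient(logits, yTr[sel], loss) / length(sel)
      dZr <- rowsum(dlogit * Zp[pIdx[sel], , drop = FALSE],
                    group = rxIdx[sel])
      dZp <- rowsum(dlogit * emb$Z[rxIdx[sel], , drop = FALSE],
                    group = pIdx[sel])
      usedP <- as.integer(rownames(dZp))
      grads <- list(Wp = t(dZp) %*% Ep[usedP, , drop = FALSE])
      if (encoder$variant == "morgan") {
        dWmrg <- matrix(0, encoder$d, encoder$nbits)
        for (k in seq_len(nrow(dZr))) {
          ri <- as.integer(rownames(dZr))[k]
          dWmrg <- dWmrg + outer(dZr[k, ], caches[[ri]]$fp)
        }
        grads$Wmrg <- dWmrg
      } else {
        enc <- list(Win = 0 * w$Win, Wm = 0 * w$Wm, Wread = 0 * w$Wread,
                    Wout = 0 * w$Wout)
        for (k in seq_len(nrow(dZr))) {
          ri <- as.integer(rownames(dZr))[k]
          gb <- .encoderBackward(caches[[ri]]$g, emb$fws[[ri]], w,
                                 dZr[k, ], encoder$M)
          for (nm in names(enc)) enc[[nm]] <- enc[[nm]] + gb[[nm]]
        }
        grads <- c(grads, enc)
      }
      stepCount <- stepCount + 1
      upd <- .adamStep(w, grads, state, train$lr, stepCount)
      w <- upd$w; state <- upd$state
    }
    row <- data.frame(epoch = epoch, train_loss = epochLoss / nTr)
    if (nrow(valPairs)) {
      emb <- .embedAll(caches, encoder, w)
      Zp <- Ep %*% t(w$Wp)
      vLogit <- rowSums(emb$Z[vRx, , drop = FALSE] * Zp[vP, , drop = FALSE])
      row$val_loss <- mean(pairLoss(vLogit, valPairs$label, loss))
      row$val_auc <- rocAuc(stats::plogis(vLogit), valPairs$label)
    }
    logRows[[epoch]] <- row
  }
  log <- do.call(rbind, logRows)
  threshold <- 0.5
  if (nrow(valPairs) && length(unique(valPairs$label)) == 2) {
    emb <- .embedAll(caches, encoder, w)
    Zp <- Ep %*% t(w$Wp)
    vScore <- stats::plogis(rowSums(emb$Z[vRx, , drop = FALSE] *
                                    Zp[vP, , drop = FALSE]))
    threshold <- selectThreshold(vScore, valPairs$label)
  }
  model <- new("RcnetModel", encoder = encoder, weights = w,
               threshold = as.numeric(threshold), proteinDim = as.integer(D),
               log = log)
  validObject(model)
  model
}

#' Score a table of pairs
#'
#' @param model an [RcnetModel-class].
#' @param pairs data.frame with `protein_id`, `reaction_id`.
#' @param reactions named list of [Reaction-class] objects.
#' @param proteins a [ProteinSet-class].
#' @return numeric vector of probabilities, one per row of `pairs`.
#' @export
scorePairs <- function(model, pairs, reactions, proteins) {
  rids <- unique(pairs$reaction_id)
  caches <- .reactionCaches(reactions[rids], model@encoder)
  emb <- .embedAll(caches, model@encoder, model@weights)
  Ep <- proteinEmbeddings(proteins)
  Zp <- Ep %*% t(model@weights$Wp)
  stats::plogis(rowSums(emb$Z[match(pairs$reaction_id, rids), , drop = FALSE] *
                        Zp[match(pairs$protein_id, rownames(Ep)), ,
                           drop = FALSE]))
}

#' Select the decision threshold on validation scores
#'
#' Maximizes F1 over the grid of midpoints of adjacent distinct observed
#' scores; ties resolve to the smallest threshold. When all scores coincide
#' the midpoints with the 0/1 bounds are used and the result carries a
#' `degenerate` attribute.
#'
#' @param scores validation scores in (0, 1).
#' @param labels binary labels (both classes must be present).
#' @return the selected threshold.
#' @export
selectThreshold <- function(scores, labels) {
  if (length(unique(labels)) < 2)
    stop("threshold selection requires both classes")
  u <- sort(unique(scores))
  degenerate <- length(u) == 1
  cand <- if (degenerate) c(u / 2, (u + 1) / 2) else
    (u[-length(u)] + u[-1]) / 2
  f1 <- vapply(cand, function(tau) {
    pred <- as.integer(scores >= tau)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  tau <- cand[which.max(f1)]  # which.max takes the first (smallest) maximum
  if (degenerate) attr(tau, "degenerate") <- TRUE
  tau
}

#' Grid search with k-fold cross-validation
#'
#' Trains every grid cell on each rotation of the inner CV folds (negatives
#' resampled per rotation so validation folds carry the validation ratio) and
#' returns the cell with the highest mean validation F1, ties resolving to
#' the earliest cell in grid order.
#'
#' @param positives data.frame of positive pairs (`protein_id`,
#'   `reaction_id`).
#' @param reactions named list of [Reaction-class] objects.
#' @param proteins a [ProteinSet-class].
#' @param assignment a [SplitAssignment-class] providing the inner folds.
#' @param grid list of [encoderConfig()] objects (the grid cells).
#' @param k inner fold count (default 3).
#' @param train a [trainConfig()].
#' @param loss a [lossConfig()].
#' @param seed negative-sampling seed.
#' @return list with `best` (encoder config), `bestIndex` and `table`
#'   (per-cell mean and sd of F1 and accuracy).
#' @export
crossValidate <- function(positives, reactions, proteins, assignment, grid,
                          k = 3, train = trainConfig(), loss = lossConfig(),
                          seed = 1) {
  if (!length(grid)) stop("empty hyperparameter grid")
  proteinIdsAll <- proteinIds(proteins)
  reactionIdsAll <- names(reactions)
  rows <- list()
  for (ci in seq_along(grid)) {
    f1s <- numeric(k); accs <- numeric(k)
    for (j in seq_len(k)) {
      pd <- sampleNegatives(positives, proteinIdsAll, reactionIdsAll,
                            assignment, negativeRatios(k, valFold = j),
                            seed = seed + j)
      model <- trainModel(pd, reactions, proteins, encoder = grid[[ci]],
                          train = train, loss = loss, valFold = j)
      valPairs <- pd@pairs[pd@pairs$fold == paste0("cv", j), , drop = FALSE]
      sc <- scorePairs(model, valPairs, reactions, proteins)
      mr <- computeMetrics(sc, valPairs$label, model@threshold)
      f1s[j] <- mr$f1; accs[j] <- mr$accuracy
    }
    rows[[ci]] <- data.frame(cell = ci, mean_f1 = mean(f1s),
                             sd_f1 = stats::sd(f1s), mean_accuracy = mean(accs),
                             sd_accuracy = stats::sd(accs))
  }
  tab <- do.call(rbind, rows)
  bestIndex <- which.max(tab$mean_f1)
  list(best = grid[[bestIndex]], bestIndex = bestIndex, table = tab)
}
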