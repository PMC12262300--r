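# Synthetic dataset generator: reaction families sharing a reaction center,
# clustered protein embeddings, and a sparse planted catalysis relation.

# Hand-written, chemically valid mapped reaction cores. Attachment map
# numbers mark the R-group positions where substituent trees may be grown
# (identically on both sides, preserving the atom map).
.SYNTH_TEMPLATES <- list(
  list(name = "ester_hydrolysis",
       smiles = "[CH3:1][C:2](=[O:3])[O:4][CH3:5].[OH2:6]>>[CH3:1][C:2](=[O:3])[OH:6].[CH3:5][OH:4]",
       attachments = c(1L, 5L)),
  list(name = "ketone_reduction",
       smiles = "[CH3:1][C:2](=[O:3])[CH3:4]>>[CH3:1][CH:2]([OH:3])[CH3:4]",
       attachments = c(1L, 4L)),
  list(name = "decarboxylation",
       smiles = "[CH3:1][C:2](=[O:3])[C:4](=[O:5])[OH:6]>>[CH3:1][CH:2]=[O:3].[O:5]=[C:4]=[O:6]",
       attachments = c(1L)),
  list(name = "amide_hydrolysis",
       smiles = "[CH3:1][C:2](=[O:3])[NH:4][CH3:5].[OH2:6]>>[CH3:1][C:2](=[O:3])[OH:6].[CH3:5][NH2:4]",
       attachments = c(1L, 5L)),
  list(name = "alcohol_oxidation",
       smiles = "[CH3:1][CH:2]([OH:3])[CH3:4]>>[CH3:1][C:2](=[O:3])[CH3:4]",
       attachments = c(1L, 4L)),
  list(name = "esterification",
       smiles = "[CH3:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6]>>[CH3:1][C:2](=[O:3])[O:6][CH3:5].[OH2:4]",
       attachments = c(1L, 5L))
)

#' Built-in synthetic reaction templates
#' @return list of template descriptors (`name`, mapped `smiles`,
#'   `attachments` map numbers).
#' @export
synthTemplates <- function() .SYNTH_TEMPLATES

#' Synthetic data configuration
#'
#' @param templates number of RC templates used (up to
#'   `length(synthTemplates())`).
#' @param perTemplate reactions generated per template.
#' @param maxDecor maximum substituent-tree size per reaction (atoms).
#' @param vocab named substituent element probabilities; heteroatoms are
#'   attached as leaves only.
#' @param clusters number of protein clusters.
#' @param perCluster proteins per cluster.
#' @param embeddingDim protein embedding dimension.
#' @param seqLength protein sequence length.
#' @param mutationRate per-position within-cluster mutation probability.
#' @param noise within-cluster embedding noise scale.
#' @param activeFraction fraction of protein clusters with catalytic
#'   activity toward the sampled reaction families; the remaining clusters
#'   catalyze nothing (beyond promiscuity), which keeps the planted blocks
#'   dense enough to be learnable at sparse overall density.
#' @param promiscuity fraction of positives planted across families.
#' @param density target positive density of the protein x reaction
#'   adjacency matrix.
#' @param seed RNG seed.
#' @return validated named list.
#' @export
synthConfig <- function(templates = 5, perTemplate = 40, maxDecor = 4,
                        vocab = c(C = 0.7, O = 0.15, N = 0.15),
                        clusters = 10, perCluster = 20, embeddingDim = 1280,
                        seqLength = 120, mutationRate = 0.1, noise = 0.3,
                        activeFraction = 0.2, promiscuity = 0.05,
                        density = 0.01, seed = 1) {
  if (templates < 2 || templates > length(.SYNTH_TEMPLATES))
    stop(sprintf("templates must be in 2..%d", length(.SYNTH_TEMPLATES)))
  if (clusters < 2) stop("need at least 2 protein clusters")
  if (promiscuity < 0 || promiscuity >= 1) stop("promiscuity must be in [0, 1)")
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (activeFraction <= 0 || activeFraction > 1)
    stop("activeFraction must be in (0, 1]")
  list(templates = as.integer(templates), perTemplate = as.integer(perTemplate),
       maxDecor = as.integer(maxDecor), vocab = vocab,
       clusters = as.integer(clusters), perCluster = as.integer(perCluster),
       embeddingDim = as.integer(embeddingDim),
       seqLength = as.integer(seqLength), mutationRate = mutationRate,
       noise = noise, activeFraction = activeFraction,
       promiscuity = promiscuity, density = density,
       seed = as.integer(seed))
}

.DEFAULT_LEAF_H <- c(C = 3L, O = 1L, N = 2L)

# add one substituent atom to both sides of a mapped reaction, bonded to the
# atom carrying `parentMap`; returns NULL when the parent has no free valence
.decorateOnce <- function(r, parentMap, element, newMap) {
  for (side in c("reactant", "product")) {
    mols <- if (side == "reactant") r@reactants else r@products
    hit <- NULL
    for (mi in seq_along(mols)) {
      li <- which(mols[[mi]]@atoms$map == parentMap)
      if (length(li)) { hit <- c(mi, li); break }
    }
    if (is.null(hit)) return(NULL)
    mol <- mols[[hit[1]]]
    if (mol@atoms$hcount[hit[2]] < 1) return(NULL)
    mol@atoms$hcount[hit[2]] <- mol@atoms$hcount[hit[2]] - 1L
    mol@atoms <- rbind(mol@atoms, data.frame(
      element = element, aromatic = FALSE, charge = 0L,
      hcount = .DEFAULT_LEAF_H[[element]], map = newMap,
      stringsAsFactors = FALSE))
    mol@bonds <- rbind(mol@bonds, data.frame(
      a1 = hit[2], a2 = nrow(mol@atoms), order = "1",
      stringsAsFactors = FALSE))
    if (side == "reactant") r@reactants[[hit[1]]] <- mol else
      r@products[[hit[1]]] <- mol
  }
  r
}

#' Generate synthetic RC-annotated reactions
#'
#' Each reaction starts from one of the mapped template cores and grows a
#' random substituent tree (identically on both sides, preserving the atom
#' map) at the designated attachment points; heteroatoms are attached as
#' leaves, carbons may branch further. The RC annotation is derived from the
#' atom map and always equals the template's changed core.
#'
#' @param cfg a [synthConfig()].
#' @return named list of [Reaction-class] objects with attributes `family`
#'   (template index per reaction) and `templateNames`.
#' @export
generateReactions <- function(cfg = synthConfig()) {
  set.seed(cfg$seed)
  n <- cfg$templates * cfg$perTemplate
  out <- vector("list", n)
  family <- integer(n)
  elements <- names(cfg$vocab)
  for (i in seq_len(n)) {
    ti <- ((i - 1L) %% cfg$templates) + 1L
    family[i] <- ti
    tmpl <- .SYNTH_TEMPLATES[[ti]]
    r <- suppressWarnings(parseReaction(tmpl$smiles,
                                        id = sprintf("R%04d", i)))
    k <- sample(0:cfg$maxDecor, 1)
    nextMap <- max(sideAtoms(r, "reactant")$map) + 1L
    growable <- tmpl$attachments  # map numbers that can accept substituents
    tries <- 0
    while (k > 0 && tries < 20 && length(growable)) {
      parentMap <- if (length(growable) == 1) growable else
        sample(growable, 1)
      el <- sample(elements, 1, prob = cfg$vocab)
      r2 <- .decorateOnce(r, parentMap, el, nextMap)
      tries <- tries + 1
      if (is.null(r2)) {
        growable <- setdiff(growable, parentMap)
        next
      }
      r <- r2
      if (el == "C") growable <- c(growable, nextMap)
      nextMap <- nextMap + 1L
      k <- k - 1
    }
    out[[i]] <- deriveRcFromMap(r)
  }
  names(out) <- vapply(out, reactionId, character(1))
  attr(out, "family") <- family
  attr(out, "templateNames") <- vapply(.SYNTH_TEMPLATES[seq_len(cfg$templates)],
                                       function(t) t$name, character(1))
  out
}

#' Generate clustered synthetic proteins
#'
#' Cluster centroids are drawn isotropically in embedding space; members are
#' centroid plus Gaussian noise. Sequences are mutated copies of a per-cluster
#' centroid sequence, so within-cluster GSI is high and between-cluster GSI
#' is at the random-background level.
#'
#' @param cfg a [synthConfig()].
#' @return a [ProteinSet-class] with attribute `cluster` (cluster index per
#'   protein).
#' @export
generateProteins <- function(cfg = synthConfig()) {
  set.seed(cfg$seed + 1L)
  aa <- setdiff(.AA_ALPHABET, "X")
  nP <- cfg$clusters * cfg$perCluster
  centroidSeq <- replicate(cfg$clusters,
                           paste(sample(aa, cfg$seqLength, replace = TRUE),
                                 collapse = ""))
  centroidEmb <- matrix(stats::rnorm(cfg$clusters * cfg$embeddingDim),
                        cfg$clusters)
  cluster <- rep(seq_len(cfg$clusters), each = cfg$perCluster)
  seqs <- character(nP); emb <- matrix(0, nP, cfg$embeddingDim)
  for (j in seq_len(nP)) {
    cseq <- strsplit(centroidSeq[cluster[j]], "")[[1]]
    mut <- stats::runif(cfg$seqLength) < cfg$mutationRate
    cseq[mut] <- sample(aa, sum(mut), replace = TRUE)
    seqs[j] <- paste(cseq, collapse = "")
    emb[j, ] <- centroidEmb[cluster[j], ] +
      cfg$noise * stats::rnorm(cfg$embeddingDim)
  }
  ids <- sprintf("P%04d", seq_len(nP))
  names(seqs) <- ids; rownames(emb) <- ids
  out <- proteinSet(seqs, emb)
  attr(out, "cluster") <- cluster
  out
}

#' Plant a sparse catalysis relation
#'
#' Protein cluster `c` catalyzes the reactions of family `((c - 1) mod F) + 1`
#' with a within-block probability tuned so the overall positive density hits
#' the target; a configurable fraction of positives is planted across
#' families (promiscuity). The planted signal is RC-local by construction:
#' labels depend only on the reaction's template family, never on the
#' substituents.
#'
#' @param reactions output of [generateReactions()].
#' @param proteins output of [generateProteins()].
#' @param cfg the [synthConfig()] both were generated from.
#' @return data.frame of positive pairs (`protein_id`, `reaction_id`) with
#'   attributes `density` (realized) and `withinFraction`.
#' @export
plantPositives <- function(reactions, proteins, cfg = synthConfig()) {
  set.seed(cfg$seed + 2L)
  family <- attr(reactions, "family")
  cluster <- attr(proteins, "cluster")
  if (is.null(family) || is.null(cluster))
    stop("reactions/proteins must carry family/cluster attributes")
  rids <- names(reactions); pids <- proteinIds(proteins)
  nActive <- max(1L, ceiling(cfg$activeFraction * cfg$clusters))
  famOfCluster <- ifelse(cluster <= nActive,
                         ((cluster - 1L) %% cfg$templates) + 1L, 0L)
  within <- outer(famOfCluster, family, "==")
  N <- length(within); W <- sum(within)
  target <- cfg$density * N
  qWithin <- (1 - cfg$promiscuity) * target / W
  qCross <- if (N > W) cfg$promiscuity * target / (N - W) else 0
  if (qWithin > 1)
    stop(sprintf("target density %.4g unreachable: within-block probability %.3g exceeds 1",
                 cfg$density, qWithin))
  draws <- matrix(stats::runif(N), nrow(within))
  pos <- which(ifelse(within, draws < qWithin, draws < qCross),
               arr.ind = TRUE)
  out <- data.frame(protein_id = pids[pos[, 1]],
                    reaction_id = rids[pos[, 2]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$reaction_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "density") <- nrow(out) / N
  attr(out, "withinFraction") <- mean(within[pos])
  out
}

#' Planted hierarchical similarity matrix
#'
#' A synthetic similarity matrix with nested block structure: entities share
#' similarity `levels[k + 1]` when they fall in the same block of size
#' `blockSizes[k]` (blocks nest), and `levels[1]` otherwise. Diagonal 1.
#' Used to exercise the stratified similarity split with known strata.
#'
#' @param n number of entities.
#' @param levels ascending similarity levels, background first.
#' @param blockSizes descending nested block sizes (one fewer than levels).
#' @param prefix entity-id prefix.
#' @return a [SimilarityMatrix-class] (metric tag `"gsi"`).
#' @export
generatePlantedSimilarity <- function(n = 200, levels = c(0.1, 0.5, 0.7, 0.9),
                                      blockSizes = c(8, 4, 2),
                                      prefix = "E") {
  if (length(blockSizes) != length(levels) - 1)
    stop("need one block size per non-background level")
  idx <- 0:(n - 1)
  s <- matrix(levels[1], n, n)
  for (k in seq_along(blockSizes)) {
    same <- outer(idx %/% blockSizes[k], idx %/% blockSizes[k], "==")
    s[same] <- levels[k + 1]
  }
  diag(s) <- 1
  new("SimilarityMatrix", ids = sprintf("%s%04d", prefix, seq_len(n)),
      scores = s, metric = "gsi")
}

#' Generate and write a complete synthetic dataset
#'
#' Emits the files the pipeline consumes: `reactions.tsv` (mapped reaction
#' SMILES with RC annotations), `proteins.fasta`, `embeddings.tsv`,
#' `positives.tsv` and `families.tsv` (generator ground truth).
#'
#' @param cfg a [synthConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory `reactions`, `proteins` and
#'   `positives`.
#' @export
synthesizeDataset <- function(cfg = synthConfig(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  reactions <- generateReactions(cfg)
  proteins <- generateProteins(cfg)
  positives <- plantPositives(reactions, proteins, cfg)
  writeReactionsTsv(reactions, file.path(dir, "reactions.tsv"))
  writeProteinFasta(proteins, file.path(dir, "proteins.fasta"))
  writeEmbeddingsTsv(proteins, file.path(dir, "embeddings.tsv"))
  utils::write.table(positives, file.path(dir, "positives.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- data.frame(reaction_id = names(reactions),
                      family = attr(reactions, "family"))
  utils::write.table(truth, file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  clusters <- data.frame(protein_id = proteinIds(proteins),
                         cluster = attr(proteins, "cluster"))
  utils::write.table(clusters, file.path(dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(reactions = reactions, proteins = proteins,
                 positives = positives))
}
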