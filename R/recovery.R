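#' @include AllClasses.R
NULL

#' Pairwise Pearson co-abundance for requested protein pairs
#'
#' Pearson correlation of two proteins' log2 abundances over jointly
#' non-missing samples. Pairs with fewer than \code{minOverlap} shared
#' samples are omitted; pairs in which either profile has zero variance over
#' the shared samples are omitted with a warning.
#'
#' @param x a log2-scale \linkS4class{AbundanceSet}.
#' @param pairs data.frame (or 2-column matrix) of protein id pairs.
#' @param minOverlap minimum jointly non-missing sample count (default 6).
#' @return data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{r}, \code{n_overlap}.
#' @export
pairwiseCorrelations <- function(x, pairs, minOverlap = 6L) {
  if (abundanceScale(x) != "log2")
    stop("pairwiseCorrelations requires log2-scale data")
  m <- abundances(x)
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  ia <- match(pairs[, 1L], rownames(m))
  ib <- match(pairs[, 2L], rownames(m))
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  r <- n <- numeric(length(ia))
  zeroVar <- 0L
  for (k in seq_along(ia)) {
    va <- m[ia[k], ]; vb <- m[ib[k], ]
    ok <- !is.na(va) & !is.na(vb)
    n[k] <- sum(ok)
    if (n[k] < minOverlap) { r[k] <- NA_real_; next }
    va <- va[ok]; vb <- vb[ok]
    if (stats::var(va) == 0 || stats::var(vb) == 0) {
      r[k] <- NA_real_; zeroVar <- zeroVar + 1L; next
    }
    r[k] <- stats::cor(va, vb)
  }
  if (zeroVar) warning(zeroVar, " pair(s) omitted for zero variance")
  out <- data.frame(protein_a = pairs[keep, 1L], protein_b = pairs[keep, 2L],
                    r = r, n_overlap = as.integer(n),
                    stringsAsFactors = FALSE)
  out[!is.na(out$r), , drop = FALSE]
}

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# All unordered within-module pairs of a catalog, restricted to `quantified`.
.modulePairs <- function(catalog, quantified) {
  keys <- unlist(lapply(moduleMembers(catalog), function(mem) {
    mem <- intersect(mem, quantified)
    if (length(mem) < 2L) return(character())
    cmb <- utils::combn(sort(mem), 2L)
    paste(cmb[1L, ], cmb[2L, ], sep = "\r")
  }), use.names = FALSE)
  unique(keys)
}

#' Condition-positive and sampled condition-negative pairs for one category
#'
#' Positives are protein pairs sharing a module of the category (for
#' \code{interaction} sources: pairs above the combined-score cutoff; for
#' chromosome/housekeeping/essential catalogs the flag sets are modules, so
#' positives are pairs of co-flagged proteins). For pathway catalogs, pairs
#' that also co-occur in a complex are removed from the positives when
#' \code{excludeComplexes} is supplied, so pathway co-variation is not
#' credited to complex membership. Negatives are drawn uniformly without
#' replacement from quantified pairs in no module of the category (for
#' interaction sources: pairs absent from the table), matched in number to
#' the positives.
#'
#' @param source a \linkS4class{ModuleCatalog} or
#'   \linkS4class{InteractionTable}.
#' @param quantified character vector of quantified protein ids.
#' @param seed integer seed for the negative sampling.
#' @param scoreCutoff combined-score cutoff for interaction positives
#'   (default 0.7, high confidence; 0.5 and 0 are the published
#'   alternatives).
#' @param excludeComplexes optional complex \linkS4class{ModuleCatalog} whose
#'   within-complex pairs are removed from pathway positives.
#' @return list with data.frames \code{positives} and \code{negatives}
#'   (columns \code{protein1}, \code{protein2}).
#' @export
buildConditionSets <- function(source, quantified, seed = 1L,
                               scoreCutoff = 0.7, excludeComplexes = NULL) {
  quantified <- unique(as.character(quantified))
  if (is(source, "InteractionTable")) {
    d <- interactions(source)
    inUniverse <- d$protein1 %in% quantified & d$protein2 %in% quantified
    posKeys <- .pairKey(d$protein1, d$protein2)[inUniverse &
                                                d$combined_score > scoreCutoff]
    exclKeys <- .pairKey(d$protein1, d$protein2)[inUniverse]
  } else if (is(source, "ModuleCatalog")) {
    posKeys <- .modulePairs(source, quantified)
    exclKeys <- posKeys
    if (moduleCategory(source) == "pathway" && !is.null(excludeComplexes))
      posKeys <- setdiff(posKeys, .modulePairs(excludeComplexes, quantified))
  } else stop("source must be a ModuleCatalog or InteractionTable")
  nPos <- length(posKeys)
  if (!nPos) stop("no condition-positive pairs among quantified proteins")
  nq <- length(quantified)
  nAvail <- choose(nq, 2) - length(exclKeys)
  if (nAvail < nPos)
    stop(sprintf("only %.0f negative pairs available for %d positives",
                 nAvail, nPos))
  restore <- .localSeed(seed)
  on.exit(restore(), add = TRUE)
  negKeys <- character(0)
  tries <- 0L
  while (length(negKeys) < nPos && tries < 200L) {
    draw <- ceiling((nPos - length(negKeys)) * 1.5) + 10L
    a <- quantified[sample.int(nq, draw, replace = TRUE)]
    b <- quantified[sample.int(nq, draw, replace = TRUE)]
    k <- .pairKey(a, b)[a != b]
    negKeys <- unique(c(negKeys, setdiff(k, exclKeys)))
    tries <- tries + 1L
  }
  if (length(negKeys) < nPos)
    stop("negative sampling failed to reach |positives|")
  negKeys <- negKeys[seq_len(nPos)]
  split2 <- function(keys) {
    ab <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(protein1 = vapply(ab, `[`, "", 1L),
               protein2 = vapply(ab, `[`, "", 2L), stringsAsFactors = FALSE)
  }
  list(positives = split2(posKeys), negatives = split2(negKeys))
}

#' ROC curve and trapezoidal AUC from positive and negative correlations
#'
#' Sweeps a descending threshold over the union of observed correlation
#' values; all pairs tied at a threshold cross together (no optimistic
#' staircase). The AUC is the trapezoidal-rule area under the resulting
#' (FPR, TPR) curve, which equals the Mann-Whitney concordance probability
#' with ties counted one half.
#'
#' @param posR,negR numeric correlation values of condition positives /
#'   negatives (non-empty).
#' @return list with \code{rocPoints} (data.frame \code{fpr}, \code{tpr},
#'   monotone from (0,0) to (1,1)), \code{auc}, \code{nPos}, \code{nNeg}.
#' @examples
#' rocAuc(c(0.9, 0.8), c(0.1, 0.2))$auc   # 1: perfect separation
#' @export
rocAuc <- function(posR, negR) {
  posR <- posR[!is.na(posR)]; negR <- negR[!is.na(negR)]
  if (!length(posR) || !length(negR))
    stop("both positive and negative correlation lists must be non-empty")
  u <- sort(unique(c(posR, negR)))
  tp <- rev(cumsum(rev(tabulate(match(posR, u), length(u))))) / length(posR)
  fp <- rev(cumsum(rev(tabulate(match(negR, u), length(u))))) / length(negR)
  fpr <- c(0, rev(fp)); tpr <- c(0, rev(tp))     # thresholds high -> low
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(rocPoints = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       nPos = length(posR), nNeg = length(negR))
}

#' Conservative Mann-Whitney p by repeated subsampling
#'
#' Applies the one-sided Mann-Whitney U test (alternative: positives shifted
#' higher) \code{nIter} times to random subsamples of \code{nSample} items
#' from each distribution and returns the mean p-value — a conservative
#' effect-size estimate that does not grow with the full list sizes. Lists
#' shorter than \code{nSample} are resampled with replacement, longer lists
#' subsampled without replacement.
#'
#' @param posR,negR numeric correlation values (non-empty).
#' @param nIter number of subsampled tests (default 1000).
#' @param nSample items drawn per distribution per test (default 1000).
#' @param seed integer seed.
#' @return the mean one-sided p-value over iterations.
#' @export
subsampledMWU <- function(posR, negR, nIter = 1000L, nSample = 1000L,
                          seed = 1L) {
  posR <- posR[!is.na(posR)]; negR <- negR[!is.na(negR)]
  if (!length(posR) || !length(negR)) stop("empty correlation list")
  restore <- .localSeed(seed)
  on.exit(restore(), add = TRUE)
  draw <- function(v) if (length(v) >= nSample) sample(v, nSample)
                      else sample(v, nSample, replace = TRUE)
  ps <- vapply(seq_len(nIter), function(i) {
    suppressWarnings(stats::wilcox.test(draw(posR), draw(negR),
                                        alternative = "greater",
                                        exact = FALSE)$p.value)
  }, 0)
  mean(ps)
}

#' Module-recovery AUC for one dataset and one module source
#'
#' Builds condition sets, computes pair correlations, and summarizes the
#' dataset's power to recover the category as a ROC/AUC record with the
#' subsampled Mann-Whitney mean p.
#'
#' @param x a log2-scale \linkS4class{AbundanceSet}.
#' @param source \linkS4class{ModuleCatalog} or
#'   \linkS4class{InteractionTable}.
#' @param category label for the record (defaults to the source's category,
#'   or "interaction").
#' @param seed integer seed (negative sampling + subsampled tests).
#' @param minOverlap minimum jointly quantified samples per pair.
#' @param minPositives minimum usable condition positives for a valid AUC;
#'   below this the record carries \code{NA} with a warning.
#' @param nIterMwu,nSampleMwu subsampled Mann-Whitney parameters.
#' @param ... passed to \code{\link{buildConditionSets}}.
#' @return one-row data.frame: \code{dataset_id}, \code{category},
#'   \code{auc}, \code{n_pos}, \code{n_neg}, \code{mwu_mean_p}; the ROC
#'   points are attached as attribute \code{"rocPoints"}.
#' @export
covariationRecord <- function(x, source, category = NULL, seed = 1L,
                              minOverlap = 6L, minPositives = 100L,
                              nIterMwu = 1000L, nSampleMwu = 1000L, ...) {
  if (is.null(category))
    category <- if (is(source, "InteractionTable")) "interaction"
                else moduleCategory(source)
  quantified <- rownames(x)[rowSums(!is.na(abundances(x))) >= minOverlap]
  sets <- buildConditionSets(source, quantified, seed = seed, ...)
  posR <- pairwiseCorrelations(x, sets$positives, minOverlap)$r
  negR <- pairwiseCorrelations(x, sets$negatives, minOverlap)$r
  if (length(posR) < minPositives || !length(negR)) {
    warning("category \"", category, "\" in dataset \"", datasetId(x),
            "\" has ", length(posR), " usable positives (< ", minPositives,
            "); AUC reported missing")
    rec <- data.frame(dataset_id = datasetId(x), category = category,
                      auc = NA_real_, n_pos = length(posR),
                      n_neg = length(negR), mwu_mean_p = NA_real_,
                      stringsAsFactors = FALSE)
    return(rec)
  }
  roc <- rocAuc(posR, negR)
  rec <- data.frame(dataset_id = datasetId(x), category = category,
                    auc = roc$auc, n_pos = roc$nPos, n_neg = roc$nNeg,
                    mwu_mean_p = subsampledMWU(posR, negR, nIterMwu,
                                               nSampleMwu, seed = seed + 1L),
                    stringsAsFactors = FALSE)
  attr(rec, "rocPoints") <- roc$rocPoints
  rec
}

#' Module-recovery AUC matrix across datasets and categories
#'
#' Runs \code{\link{covariationRecord}} for every dataset x category cell and
#' assembles the AUC table, with categories ordered by their average AUC
#' across datasets (best-recovered first).
#'
#' @param datasets list of log2-scale \linkS4class{AbundanceSet}s.
#' @param sources named list of module sources; names are the category
#'   labels.
#' @param seed integer master seed (one sub-seed per cell).
#' @param ... passed through to \code{\link{covariationRecord}}.
#' @return list with \code{records} (long data.frame) and \code{auc}
#'   (datasets x categories matrix, columns ordered by mean AUC).
#' @export
recoveryMatrix <- function(datasets, sources, seed = 1L, ...) {
  records <- list()
  for (i in seq_along(datasets)) for (j in seq_along(sources)) {
    records[[length(records) + 1L]] <-
      covariationRecord(datasets[[i]], sources[[j]],
                        category = names(sources)[j],
                        seed = seed + 1000L * i + j, ...)
  }
  records <- do.call(rbind, records)
  auc <- matrix(NA_real_, length(datasets), length(sources),
                dimnames = list(vapply(datasets, datasetId, ""),
                                names(sources)))
  for (k in seq_len(nrow(records)))
    auc[records$dataset_id[k], records$category[k]] <- records$auc[k]
  ord <- order(colMeans(auc, na.rm = TRUE), decreasing = TRUE)
  list(records = records, auc = auc[, ord, drop = FALSE])
}
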